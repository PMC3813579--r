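test_that("single-marker test recovers a known allelic log odds ratio", {
  set.seed(51)
  n <- 10000                     # 20,000 alleles
  g <- rbinom(n, 2, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * g))
  d <- tibble::tibble(status = y, s1 = g)
  res <- single_marker_test(d, "s1")
  expect_equal(res$df, 1L)
  expect_lt(abs(res$estimate - 0.5) / res$se, 3)
  expect_equal(res$odds_ratio, exp(res$estimate))
  # balanced null: coefficient near 0
  set.seed(52)
  d0 <- tibble::tibble(status = rbinom(n, 1, 0.5), s1 = rbinom(n, 2, 0.5))
  res0 <- single_marker_test(d0, "s1")
  expect_lt(abs(res0$estimate) / res0$se, 3)
  # monomorphic SNP errors
  dm <- tibble::tibble(status = rep(c(0, 1), 10), s1 = rep(2, 20))
  expect_error(single_marker_test(dm, "s1"), "monomorphic")
})

test_that("dominance test detects recessive deviation and needs hets", {
  set.seed(53)
  n <- 6000
  meds <- vapply(1:7, function(i) {
    g <- rbinom(n, 2, 0.5)
    y <- rbinom(n, 1, ifelse(g == 2, 0.15, 0.10))  # hom RR 1.5
    dominance_test(tibble::tibble(status = y, s1 = g), "s1")$p_value
  }, 0)
  expect_lt(median(meds), 0.05)
  # additive-only SNP: dominance p is null-like (not tiny)
  set.seed(54)
  p_add <- vapply(1:7, function(i) {
    g <- rbinom(n, 2, 0.5)
    y <- rbinom(n, 1, plogis(-2 + 0.3 * g))
    dominance_test(tibble::tibble(status = y, s1 = g), "s1")$p_value
  }, 0)
  expect_gt(median(p_add), 0.05)
  d_nohet <- tibble::tibble(status = rep(c(0, 1), 10),
                            s1 = rep(c(0, 2), 10))
  expect_error(dominance_test(d_nohet, "s1"), "heterozygotes")
})

test_that("interaction term counts match the stated degrees of freedom", {
  set.seed(55)
  d <- toy_dataset(n = 2000, q = c(0.5, 0.5, 0.5), seed = 55)
  p2a <- pairwise_interaction_test(d, "s1", "s2", mode = "allelic")
  expect_equal(p2a$df, 1L)
  p2g <- pairwise_interaction_test(d, "s1", "s2", mode = "genotypic")
  expect_equal(p2g$df, 4L)
  expect_false(p2g$rank_adjusted)
  p3a <- threeway_interaction_test(d, "s1", "s2", "s3", mode = "allelic")
  expect_equal(p3a$df, 1L)
  p3g <- threeway_interaction_test(d, "s1", "s2", "s3", mode = "genotypic")
  expect_equal(p3g$df, 8L)
  expect_false(p3g$rank_adjusted)
})

test_that("comparator p-values do not depend on SNP order", {
  set.seed(56)
  d <- toy_dataset(n = 1500, q = c(0.3, 0.5, 0.7), seed = 56,
                   p_case = function(G) plogis(-0.5 + 0.2 * G[, 1] * G[, 2]))
  for (mode in c("allelic", "genotypic")) {
    a <- pairwise_interaction_test(d, "s1", "s2", mode = mode)
    b <- pairwise_interaction_test(d, "s2", "s1", mode = mode)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-8)
    t1 <- threeway_interaction_test(d, "s1", "s2", "s3", mode = mode)
    t2 <- threeway_interaction_test(d, "s3", "s1", "s2", mode = mode)
    expect_equal(t1$p_value, t2$p_value, tolerance = 1e-8)
  }
})

test_that("perfectly correlated SNPs trigger the rank-deficiency flag", {
  set.seed(57)
  g <- rbinom(500, 2, 0.5)
  y <- rbinom(500, 1, 0.5)
  d <- tibble::tibble(status = y, s1 = g, s2 = g)
  res <- pairwise_interaction_test(d, "s1", "s2", mode = "allelic")
  expect_true(res$rank_adjusted)
  expect_gt(res$dropped_terms, 0)
})

test_that("both interaction modes detect a strong double-recessive pair", {
  # the genotypic product block spans the recessive-by-recessive contrast
  # exactly ( r1*r2 = ((a1-d1)/2) * ((a2-d2)/2) ), so a pure
  # double-recessive signal is detectable in either mode
  set.seed(58)
  n <- 6000
  ps <- vapply(1:5, function(i) {
    g1 <- rbinom(n, 2, 0.5); g2 <- rbinom(n, 2, 0.5)
    y <- rbinom(n, 1, ifelse(g1 == 2 & g2 == 2, 0.20, 0.03))
    d <- tibble::tibble(status = y, s1 = g1, s2 = g2)
    pg <- pairwise_interaction_test(d, "s1", "s2", mode = "genotypic")
    pa <- pairwise_interaction_test(d, "s1", "s2", mode = "allelic")
    c(pg$p_value, pa$p_value)
  }, c(0, 0))
  expect_lt(median(ps[1, ]), 1e-4)
  expect_lt(median(ps[2, ]), 1e-4)
})

test_that("best_of_set enumerates the full combinatorics", {
  set.seed(59)
  d <- toy_dataset(n = 300, q = rep(0.5, 10), seed = 59)
  singles <- best_of_set(d, test = "single_marker")
  expect_equal(singles$n_tests, 10L)
  pairs <- best_of_set(d, test = "pairwise", alpha = 0.05,
                       alpha_policy = "bonferroni")
  expect_equal(pairs$n_tests, choose(10, 2))
  expect_equal(pairs$alpha_threshold, 0.05 / 45)
  triples <- best_of_set(d, test = "threeway")
  expect_equal(triples$n_tests, 120L)
  expect_equal(nrow(attr(triples, "tests")), 120L)
  expect_equal(min(attr(pairs, "tests")$p_value, na.rm = TRUE),
               pairs$min_p)
  expect_error(best_of_set(d[, 1:3], test = "pairwise"), "smaller")
})
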