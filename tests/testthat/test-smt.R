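test_that("p_final is the Bonferroni-corrected minimum by construction", {
  set.seed(31)
  rep1 <- sample_case_control(rez_model("A"), 500, 500)
  fit <- smt_test(rep1$data, rep1$spec)
  expect_equal(fit$p_final, min(1, fit$v * fit$min_p))
  expect_gte(fit$p_final, fit$min_p)
  expect_equal(fit$v, nrow(fit$profile))
  expect_true(all(diff(fit$profile$threshold) > 0))
  # arithmetic on a published-style profile: nine cut-offs, smallest
  # uncorrected p 9.16e-4 -> corrected 8.244e-3
  expect_equal(min(1, 9 * 9.16e-4), 8.244e-3, tolerance = 1e-12)
})

test_that("jointly permuting individuals leaves the result unchanged", {
  set.seed(32)
  rep1 <- sample_case_control(rez_model("B"), 400, 400)
  fit1 <- smt_test(rep1$data, rep1$spec)
  perm <- sample(nrow(rep1$data))
  fit2 <- smt_test(rep1$data[perm, ], rep1$spec)
  expect_equal(fit1$p_final, fit2$p_final, tolerance = 1e-9)
  expect_equal(fit1$profile$p_value, fit2$profile$p_value, tolerance = 1e-9)
  expect_equal(fit1$best_threshold, fit2$best_threshold)
})

test_that("threshold profile carries the two-by-two odds ratios", {
  # above threshold 2 <=> genotype (1, 1); the below group mixes (0,0),
  # (1,0), (0,1) so no indicator is collinear with a single SNP column
  below_mix <- function(k) {
    n1 <- ceiling(k / 3); n2 <- ceiling((k - n1) / 2); n3 <- k - n1 - n2
    cbind(c(rep(0, n1), rep(1, n2), rep(0, n3)),
          c(rep(0, n1), rep(0, n2), rep(1, n3)))
  }
  # 40/60 cases above/below, 20/80 controls
  G <- rbind(matrix(1, 40, 2), below_mix(60),
             matrix(1, 20, 2), below_mix(80))
  d <- tibble::tibble(status = rep(c(1, 0), c(100, 100)),
                      s1 = G[, 1], s2 = G[, 2])
  prof <- threshold_profile(d, snps = c("s1", "s2"))
  row2 <- prof[prof$threshold == 2, ]
  expect_equal(row2$or, (40 * 80) / (60 * 20), tolerance = 1e-12)
  expect_equal(row2$se_log_or, sqrt(1 / 40 + 1 / 60 + 1 / 20 + 1 / 80),
               tolerance = 1e-12)
  expect_equal(row2$freq_cases, 0.40)
  expect_equal(row2$freq_controls, 0.20)
  # equal above-threshold frequencies in cases and controls: OR = 1
  G2 <- rbind(matrix(1, 25, 2), below_mix(75),
              matrix(1, 25, 2), below_mix(75))
  d2 <- tibble::tibble(status = rep(c(1, 0), c(100, 100)),
                       s1 = G2[, 1], s2 = G2[, 2])
  prof2 <- threshold_profile(d2, snps = c("s1", "s2"))
  expect_equal(prof2$or[prof2$threshold == 2], 1)
})

test_that("degenerate threshold sets fall back to p_final = 1", {
  d <- tibble::tibble(status = rep(c(1, 0), 10),
                      s1 = rep(1, 20), s2 = rep(1, 20))
  expect_warning(fit <- smt_test(d, snps = c("s1", "s2")),
                 "no valid threshold")
  expect_equal(fit$p_final, 1)
  expect_equal(fit$v, 0L)
})

test_that("an indicator duplicating a covariate is a named error", {
  set.seed(33)
  rep1 <- sample_case_control(rez_model("A"), 200, 200)
  d <- rep1$data
  L <- d$snp01 + d$snp02 + d$snp03
  d$dup <- as.numeric(L >= 4)
  expect_error(
    smt_test(d, snps = c("snp01", "snp02", "snp03"), covariates = "dup"),
    "threshold 4.*collinear.*dup")
})

test_that("individuals with missing genotypes are excluded with a message", {
  set.seed(34)
  rep1 <- sample_case_control(rez_model("A"), 300, 300)
  d <- rep1$data
  d$snp02[1:7] <- NA
  expect_message(fit <- smt_test(d, rep1$spec), "excluding 7")
  expect_equal(fit$n, 593)
})

test_that("empty adjustment lists reproduce the unadjusted test", {
  set.seed(35)
  rep1 <- sample_case_control(rez_model("C"), 300, 300)
  plain <- smt_test(rep1$data, rep1$spec)
  adj <- smt_adjusted(rep1$data, rep1$spec)
  expect_equal(adj$p_final, plain$p_final)
  expect_equal(tidy(adj), tidy(plain))
})

test_that("adjustment covariates change the fit and duplicates error", {
  set.seed(36)
  rep1 <- sample_case_control(rez_model("B"), 400, 400)
  snps <- rep1$spec$snp_id
  adj <- smt_adjusted(rep1$data, rep1$spec, dominance_snps = snps[1],
                      interaction_pairs = list(snps[2:3]))
  expect_s3_class(adj, "smt_fit")
  expect_error(
    smt_adjusted(rep1$data, rep1$spec, dominance_snps = c(snps[1], snps[1])),
    "duplicate")
  expect_error(
    smt_adjusted(rep1$data, rep1$spec,
                 interaction_pairs = list(snps[1:2], snps[2:1])),
    "duplicate")
  expect_error(
    smt_adjusted(rep1$data, rep1$spec,
                 interaction_pairs = list(c(snps[1], snps[1]))),
    "repeats")
})

test_that("tidy/glance/autoplot expose the scan", {
  set.seed(37)
  rep1 <- sample_case_control(rez_model("A"), 200, 200)
  fit <- smt_test(rep1$data, rep1$spec)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("threshold", "p_value", "pi", "se", "or",
                    "freq_cases", "freq_controls") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$v, fit$v)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("wald-mode p-values agree with LRT-mode to leading order", {
  set.seed(38)
  rep1 <- sample_case_control(rez_model("A"), 500, 500)
  f_lrt <- smt_test(rep1$data, rep1$spec, test = "lrt")
  f_wald <- smt_test(rep1$data, rep1$spec, test = "wald")
  expect_equal(f_lrt$v, f_wald$v)
  expect_equal(f_lrt$best_threshold, f_wald$best_threshold)
  # the two references must agree closely on the threshold ranking
  keep <- !f_lrt$profile$separated
  expect_gt(cor(f_lrt$profile$p_value[keep], f_wald$profile$p_value[keep],
                method = "spearman"), 0.8)
  # identical estimates either way
  expect_equal(f_lrt$profile$pi, f_wald$profile$pi)
})
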