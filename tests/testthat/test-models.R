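test_that("recessive penetrances follow the preset scenarios", {
  mA <- rez_model("A")
  expect_equal(penetrance(mA, c(2, 2, 2)), 0.20, ignore_attr = TRUE)
  expect_equal(penetrance(mA, c(2, 2, 1)), 0.03, ignore_attr = TRUE)
  expect_equal(mA$q, c(0.2, 0.5, 0.8))
  expect_equal(rez_model("B")$p_high, 0.70)
  expect_equal(rez_model("C")$q, c(0.4, 0.5, 0.6))
  expect_equal(rez_model("D")$p_high, 0.05)
  # exact prevalence: f0 + (p - f0) * prod(q^2)
  expect_equal(prevalence(mA), 0.03 + 0.17 * (0.2 * 0.5 * 0.8)^2)
})

test_that("liability models split penetrance at the load threshold", {
  m <- lplm_model(p1 = 0.7, n_snps = 30)
  at <- rep(c(2, 1), c(m$threshold %/% 2, 30 - m$threshold %/% 2))
  # loads exactly at / just below the threshold
  g_at <- rep(0, 30); g_at[seq_len(m$threshold %/% 2)] <- 2
  if (m$threshold %% 2 == 1) g_at[m$threshold %/% 2 + 1] <- 1
  expect_equal(penetrance(m, g_at), 0.7, ignore_attr = TRUE)
  g_below <- g_at
  i <- which(g_below > 0)[1]
  g_below[i] <- g_below[i] - 1
  expect_equal(penetrance(m, g_below), 0.03, ignore_attr = TRUE)
})

test_that("threshold calibration matches exact binomial tails", {
  cal <- calibrate_lplm_threshold(rep(0.5, 10))
  expect_equal(cal$threshold, 15)
  expect_equal(cal$tail, 21700 / 2^20, tolerance = 1e-12)
  expect_equal(sum(load_distribution(rep(0.5, 10))$prob), 1,
               tolerance = 1e-12)
  # single SNP: no tail near 1.5%; the closest achievable tail is reported
  cal1 <- calibrate_lplm_threshold(0.5)
  expect_equal(cal1$threshold, 2)
  expect_equal(cal1$tail, 0.25)
  expect_error(calibrate_lplm_threshold(numeric(0)), "degenerate|empty")
})

test_that("weighted load distributions agree with Monte-Carlo draws", {
  set.seed(61)
  q <- c(0.3, 0.5, 0.7, 0.4, 0.6, 0.5)
  w <- assign_modified_weights(6)
  d <- load_distribution(q, w)
  m <- lplm_model(p1 = 0.5, q = q, weights = w)
  n <- 200000
  G <- sapply(q, function(qq) rbinom(n, 2, qq))
  L <- drop(G %*% w)
  tail_mc <- mean(L >= m$threshold)
  tail_exact <- sum(d$prob[d$load >= m$threshold])
  se <- sqrt(tail_exact * (1 - tail_exact) / n)
  expect_lt(abs(tail_mc - tail_exact), 3 * se + 1e-12)
})

test_that("modified-model weights split the set in ordered thirds", {
  expect_equal(assign_modified_weights(3), c(0.5, 1, 2))
  w30 <- assign_modified_weights(30)
  expect_equal(w30, rep(c(0.5, 1, 2), each = 10))
  expect_equal(sum(w30), 35)
})

test_that("the weighted threshold model recalibrates to the 1.5% tail", {
  m <- weighted_lplm_model(p1 = 0.7, n_snps = 30)
  expect_equal(m$type, "weighted_lplm")
  expect_lt(abs(m$tail - 0.015), 0.01)
  d <- m$load_dist
  expect_equal(sum(d$prob[d$load >= m$threshold]), m$tail, tolerance = 1e-12)
})

test_that("multiplicative models hit the target prevalence and cap rule", {
  set.seed(62)
  m <- multiplicative_model(q = runif(20, 0.1, 0.9),
                            rr = runif(20, 1.2, 1.5))
  expect_equal(prevalence(m), 0.01, tolerance = 0.002)
  expect_lt(m$cap_prob, 0.001)
  # a configuration capping a visible share of the population is rejected
  expect_error(
    multiplicative_model(q = rep(0.5, 40), rr = rep(1.5, 40),
                         target_prevalence = 0.2),
    "capped")
  # null model reduction: rr = 1 everywhere gives flat penetrance
  m0 <- multiplicative_model(q = rep(0.4, 5), rr = rep(1, 5),
                             target_prevalence = 0.05)
  expect_equal(unique(penetrance(m0, diag(2, 5))), 0.05, ignore_attr = TRUE)
  eff <- marginal_allelic_effect(m0)
  expect_equal(eff$rr, rep(1, 5))
  expect_equal(eff$or, rep(1, 5))
})

test_that("marginal allelic effects bracket the printed recessive ranges", {
  printed <- list(A = c(1.05, 1.19), B = c(1.03, 1.06),
                  C = c(1.05, 1.08), D = c(1.10, 1.13))
  for (w in names(printed)) {
    eff <- marginal_allelic_effect(rez_model(w))
    lo <- min(eff$rr, eff$or)
    hi <- max(eff$rr, eff$or)
    expect_lt(abs(lo - printed[[w]][1]), 0.011)
    expect_lt(abs(hi - printed[[w]][2]), 0.011)
  }
})

test_that("multiplicative marginal effects recover the input relative
           risks for a rare trait", {
  m <- multiplicative_model(q = c(0.3, 0.6), rr = c(1.3, 1.45),
                            target_prevalence = 0.01)
  eff <- marginal_allelic_effect(m)
  expect_equal(eff$rr, c(1.3, 1.45), tolerance = 0.01)
})

test_that("semi-null constructors wire the deviation blocks correctly", {
  q <- rep(0.5, 4)
  b1 <- dominance_semi_null_model(q, rr = rep(1.3, 4), rr_hom = 1.5,
                                  recessive_snps = 1:2,
                                  target_prevalence = 0.02)
  # recessive SNPs: het carries no extra risk, hom carries rr_hom
  f_base <- penetrance(b1, c(0, 0, 0, 0))
  expect_equal(penetrance(b1, c(1, 0, 0, 0)), f_base, ignore_attr = TRUE)
  expect_equal(penetrance(b1, c(2, 0, 0, 0)) / f_base, 1.5,
               ignore_attr = TRUE)
  expect_equal(penetrance(b1, c(0, 0, 1, 0)) / f_base, 1.3,
               ignore_attr = TRUE)
  b2 <- pairwise_semi_null_model(q, rr = rep(1.3, 4), rr_double = 2,
                                 pairs = matrix(c(1, 2), 1),
                                 target_prevalence = 0.02)
  f_base2 <- penetrance(b2, c(0, 0, 0, 0))
  expect_equal(penetrance(b2, c(2, 2, 0, 0)) / f_base2, 2,
               ignore_attr = TRUE)
  expect_equal(penetrance(b2, c(2, 1, 0, 0)) / f_base2, 1,
               ignore_attr = TRUE)
  expect_error(pairwise_semi_null_model(q, rep(1.3, 4), 2,
                                        pairs = matrix(c(1, 2, 2, 3), 2,
                                                       byrow = TRUE),
                                        target_prevalence = 0.02))
})

test_that("liability marginal effects shrink as the SNP set grows", {
  # the above-threshold tail is held at ~1.5% either way, so each SNP
  # contributes less marginal signal in the larger model
  eff10 <- marginal_allelic_effect(lplm_model(p1 = 0.5, n_snps = 10))
  eff30 <- marginal_allelic_effect(lplm_model(p1 = 0.5, n_snps = 30))
  expect_gt(max(eff10$rr), max(eff30$rr))
  expect_gt(min(eff10$rr), 1)
})

test_that("invalid model parameters are rejected", {
  expect_error(lplm_model(p1 = 0.01, n_snps = 10), "p1")
  expect_error(recessive_model(c(0.2, 0.5), 0.2), "three SNPs")
  expect_error(recessive_model(c(0.2, 0.5, 0.8), 0.01), "penetrance")
  expect_error(multiplicative_model(q = c(0, 0.5), rr = c(1.2, 1.2)),
               "frequencies")
})
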