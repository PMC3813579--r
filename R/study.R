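#' Monte-Carlo studies of empirical level and power
#'
#' `run_level_study()` estimates the empirical type-I error (or, under
#' semi-null models, the level excess) of the Bonferroni-corrected
#' supra-multiplicativity test across replicate simulations;
#' `run_power_study()` estimates power of the SMT and/or the comparator
#' battery; `run_subset_curve()` estimates SMT power when only the "first"
#' `k` SNPs of a liability model are available to the analyst.
#'
#' The master seed spawns one child seed per replicate (drawn once as
#' `sample.int(2147483646, n_reps)` after seeding with the master), so any
#' single replicate can be reproduced in isolation and results do not
#' depend on how replicates are scheduled.  Per-replicate p-values are
#' attached to every result as attribute `"p_values"`, so additional
#' significance levels can be evaluated without resimulation (see
#' [reject_at()]).
#'
#' @param model A `pen_model`, or a function of the replicate index
#'   returning one (use this to redraw frequencies/effects per replicate,
#'   e.g. [multiplicative_null_draw()]).
#' @param n_reps Number of replicate data sets.
#' @param n_cases,n_controls Per-replicate sample sizes.
#' @param alpha Vector of nominal significance levels.
#' @param seed Master seed.
#' @param adjust Optional list with elements `dominance_snps`,
#'   `interaction_pairs`, `interaction_triples` passed to [smt_adjusted()];
#'   when given, both the unadjusted and the adjusted SMT are run.
#' @param ... Passed to [smt_test()].
#' @return A tibble with one row per (test, alpha): columns `test`,
#'   `alpha`, `rejections`, `n_reps`, `rate` (the level/power estimate) and
#'   `se` (binomial Monte-Carlo standard error), with per-replicate
#'   p-values in attribute `"p_values"`.
#' @name study_runner
NULL

replicate_seeds <- function(seed, n_reps) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(2147483646L, n_reps, replace = FALSE)
}

study_summary <- function(p_values, alpha, policy_threshold = NULL) {
  grid <- tidyr::crossing(test = unique(p_values$test), alpha = alpha)
  purrr::pmap(grid, function(test, alpha) {
    pv <- p_values[p_values$test == test, ]
    thr <- if (is.null(policy_threshold)) alpha else
      policy_threshold(alpha, pv$m)
    rejections <- sum(!is.na(pv$p) & pv$p <= thr)
    rate <- rejections / nrow(pv)
    tibble::tibble(test = test, alpha = alpha, rejections = rejections,
                   n_reps = nrow(pv), rate = rate,
                   se = sqrt(rate * (1 - rate) / nrow(pv)))
  }) |> dplyr::bind_rows()
}

#' @rdname study_runner
#' @export
run_level_study <- function(model, n_reps = 1000, n_cases = 3000,
                            n_controls = 3000,
                            alpha = c(0.05, 0.005, 5e-4), seed = NULL,
                            adjust = NULL, ...) {
  stopifnot(n_reps >= 1, all(alpha > 0), all(alpha < 1))
  seeds <- replicate_seeds(seed, n_reps)
  rows <- purrr::map(seq_len(n_reps), function(i) {
    set.seed(seeds[i])
    m <- if (is.function(model)) model(i) else model
    rep_i <- sample_case_control(m, n_cases, n_controls)
    out <- tibble::tibble(
      rep = i, test = "smt",
      p = smt_test(rep_i$data, rep_i$spec, ...)$p_final, m = 1L)
    if (!is.null(adjust)) {
      fit_adj <- smt_adjusted(
        rep_i$data, rep_i$spec,
        dominance_snps = adjust$dominance_snps,
        interaction_pairs = adjust$interaction_pairs,
        interaction_triples = adjust$interaction_triples, ...)
      out <- dplyr::bind_rows(
        out, tibble::tibble(rep = i, test = "smt_adjusted",
                            p = fit_adj$p_final, m = 1L))
    }
    out
  })
  p_values <- dplyr::bind_rows(rows)
  res <- study_summary(p_values, alpha)
  attr(res, "p_values") <- p_values
  res
}

#' @rdname study_runner
#' @param tests Character vector choosing the battery:
#'   `"smt"`, `"single_marker"`, `"pair_allelic"`, `"pair_genotypic"`,
#'   `"triple_allelic"`, `"triple_genotypic"`.
#' @param alpha_policy `"uncorrected"` compares the most significant member
#'   test against `alpha` itself; `"bonferroni"` against `alpha / m` with
#'   `m` the number of member tests.  The SMT p-value is already corrected
#'   over thresholds and is always compared against `alpha`.
#' @export
run_power_study <- function(model, tests = "smt", n_reps = 200,
                            n_cases = 3000, n_controls = 3000, alpha = 0.05,
                            alpha_policy = c("uncorrected", "bonferroni"),
                            seed = NULL, ...) {
  alpha_policy <- match.arg(alpha_policy)
  known <- c("smt", "single_marker", "pair_allelic", "pair_genotypic",
             "triple_allelic", "triple_genotypic")
  bad <- setdiff(tests, known)
  if (length(bad)) {
    stop("unknown test(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(tests) == 0L) stop("no tests configured", call. = FALSE)
  seeds <- replicate_seeds(seed, n_reps)
  rows <- purrr::map(seq_len(n_reps), function(i) {
    set.seed(seeds[i])
    m <- if (is.function(model)) model(i) else model
    rep_i <- sample_case_control(m, n_cases, n_controls)
    purrr::map(tests, function(tst) {
      if (tst == "smt") {
        tibble::tibble(rep = i, test = tst,
                       p = smt_test(rep_i$data, rep_i$spec, ...)$p_final,
                       m = 1L)
      } else {
        kind <- switch(tst, single_marker = "single_marker",
                       pair_allelic = , pair_genotypic = "pairwise",
                       triple_allelic = , triple_genotypic = "threeway")
        md <- if (grepl("genotypic", tst)) "genotypic" else "allelic"
        b <- best_of_set(rep_i$data, test = kind, mode = md)
        tibble::tibble(rep = i, test = tst, p = b$min_p, m = b$n_tests)
      }
    }) |> dplyr::bind_rows()
  })
  p_values <- dplyr::bind_rows(rows)
  thr_fun <- if (alpha_policy == "bonferroni") {
    function(alpha, m) alpha / m
  } else {
    NULL
  }
  res <- study_summary(p_values, alpha, policy_threshold = thr_fun)
  res$alpha_policy <- alpha_policy
  attr(res, "p_values") <- p_values
  res
}

#' @rdname study_runner
#' @param subset_sizes Integer vector of subset sizes `k`; for each, the SMT
#'   sees only the first `k` SNPs in set order while the data are generated
#'   under the full model.  Values must lie in `[2, n_snps]`.
#' @param tag_r2 Optional squared correlation; when given, the causal SNPs
#'   are replaced by LD proxies via [make_tagged_proxies()] before testing.
#' @export
run_subset_curve <- function(model, subset_sizes, n_reps = 200,
                             n_cases = 3000, n_controls = 3000,
                             alpha = 5e-8, seed = NULL, tag_r2 = NULL, ...) {
  m0 <- if (is.function(model)) model(1L) else model
  if (!inherits(m0, "lplm_model")) {
    stop("subset-power curves are defined for liability (LPLM) models",
         call. = FALSE)
  }
  if (any(subset_sizes > m0$n_snps)) {
    stop("subset size exceeds the number of model SNPs", call. = FALSE)
  }
  if (any(subset_sizes < 2L)) {
    stop("the SMT needs at least 2 SNPs per subset", call. = FALSE)
  }
  seeds <- replicate_seeds(seed, n_reps)
  rows <- purrr::map(seq_len(n_reps), function(i) {
    set.seed(seeds[i])
    m <- if (is.function(model)) model(i) else model
    rep_i <- sample_case_control(m, n_cases, n_controls)
    dat <- rep_i$data
    if (!is.null(tag_r2)) {
      dat <- make_tagged_proxies(dat, r2 = tag_r2, model = m)
    }
    purrr::map(subset_sizes, function(k) {
      spec_k <- rep_i$spec[seq_len(k), , drop = FALSE]
      tibble::tibble(
        rep = i, test = paste0("smt_k", k), subset_k = k,
        p = smt_test(dat, spec_k, ...)$p_final, m = 1L)
    }) |> dplyr::bind_rows()
  })
  p_values <- dplyr::bind_rows(rows)
  res <- study_summary(p_values, alpha)
  res$subset_k <- as.integer(sub("^smt_k", "", res$test))
  res <- dplyr::arrange(res, .data$alpha, .data$subset_k)
  attr(res, "p_values") <- p_values
  res
}

#' Re-evaluate a study at additional significance levels
#'
#' Uses the per-replicate p-values persisted in a study result to compute
#' rejection rates at new levels without resimulation.  The minimum p-value
#' of each battery is compared against `alpha` directly (the uncorrected
#' rule); rebuild the study for a Bonferroni decision rule.
#'
#' @param study A result of [run_level_study()], [run_power_study()] or
#'   [run_subset_curve()].
#' @param alpha Vector of significance levels.
#' @return A tibble like the study result.
#' @export
reject_at <- function(study, alpha) {
  p_values <- attr(study, "p_values")
  if (is.null(p_values)) {
    stop("study carries no per-replicate p-values", call. = FALSE)
  }
  study_summary(p_values, alpha)
}

#' Plot a power or subset-power curve
#'
#' @param study A study result tibble; results with a `subset_k` column are
#'   drawn as power against subset size, others as power against the
#'   nominal level.
#' @return A ggplot object.
#' @export
plot_power_curve <- function(study) {
  if ("subset_k" %in% names(study)) {
    ggplot2::ggplot(study,
                    ggplot2::aes(x = .data$subset_k, y = .data$rate,
                                 colour = factor(.data$alpha))) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = pmax(0, .data$rate - .data$se),
                     ymax = pmin(1, .data$rate + .data$se)),
        width = 0.2) +
      ggplot2::labs(x = "available SNPs (first k of the model)",
                    y = "empirical power", colour = "alpha") +
      ggplot2::ylim(0, 1)
  } else {
    ggplot2::ggplot(study,
                    ggplot2::aes(x = .data$alpha, y = .data$rate,
                                 colour = .data$test)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "nominal level", y = "empirical rate",
                    colour = "test") +
      ggplot2::ylim(0, 1)
  }
}
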