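#' Supra-multiplicativity test (SMT) for a SNP set
#'
#' One-degree-of-freedom test for deviation from multiplicative risk-allele
#' effects in a pre-specified set of 2 to 500 SNPs.  For every valid
#' risk-allele-load cut-off `T`, the logistic model with an intercept, the
#' additive marginal SNP terms and any extra covariates is compared against
#' the same model plus the indicator `I(load >= T)`.  The minimum
#' per-threshold p-value is Bonferroni-corrected by the number `v` of valid
#' cut-offs: `p_final = min(1, v * min_T p_T)`.
#'
#' Per-threshold fits that separate (or lose rank for reasons other than an
#' indicator duplicating a covariate column) contribute `p = 1`, so a single
#' degenerate cut-off cannot abort a large scan; an indicator that exactly
#' duplicates an existing covariate column is an error naming the threshold.
#'
#' @param data Data frame with one row per individual: a binary `status`
#'   column, one numeric column per SNP (risk-oriented counts or dosages in
#'   `[0, 2]`), and optionally extra covariate columns.  Individuals with a
#'   missing genotype, status or covariate are excluded (with a message).
#' @param spec Optional risk-allele specification (columns `snp_id`,
#'   optional `weight`); defines the SNP order and load weights.
#' @param snps Character vector of SNP column names (defaults to the spec
#'   order, or all numeric non-reserved columns).
#' @param status Name of the binary phenotype column.
#' @param covariates Character vector of extra covariate column names
#'   included in both the null and the alternative model.
#' @param test `"lrt"` (default) for likelihood-ratio per-threshold p-values
#'   or `"wald"` for Wald p-values; the indicator estimate and its standard
#'   error are reported either way.
#' @param max_iter,tol IRLS control, see [fit_logistic()].
#'
#' @return An object of class `smt_fit` with elements `profile` (tibble, one
#'   row per threshold: `threshold`, `p_value`, `pi`, `se`, `or`,
#'   `se_log_or`, `freq_cases`, `freq_controls`, `n_above`, `separated`,
#'   `or_corrected`), `v`, `best_threshold`, `min_p`, `p_final`, sample
#'   counts and settings.  Use [tidy()] for the profile, [glance()] for the
#'   one-row summary and [autoplot()] for the threshold curve.
#' @seealso [smt_adjusted()], [threshold_profile()], [best_of_set()]
#' @examples
#' set.seed(1)
#' rep1 <- sample_case_control(rez_model("A"), 300, 300)
#' fit <- smt_test(rep1$data, rep1$spec)
#' glance(fit)
#' @export
smt_test <- function(data, spec = NULL, snps = NULL, status = "status",
                     covariates = NULL, test = c("lrt", "wald"),
                     max_iter = 100L, tol = 1e-10) {
  test <- match.arg(test)
  if (!status %in% names(data)) {
    stop("status column '", status, "' not found", call. = FALSE)
  }
  snps <- resolve_snps(data, spec, snps, status = status,
                       covariates = covariates)
  if (length(snps) < 2L) {
    stop("the SMT requires a set of at least 2 SNPs", call. = FALSE)
  }
  if (length(snps) > 500L) {
    stop("SNP sets larger than 500 are not supported", call. = FALSE)
  }
  w <- resolve_weights(spec, snps)

  y <- as.numeric(data[[status]])
  G <- genotype_matrix(data, snps)
  Z <- NULL
  if (!is.null(covariates)) {
    miss <- setdiff(covariates, names(data))
    if (length(miss)) {
      stop("covariate column(s) not found: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    Z <- as.matrix(data[covariates])
    storage.mode(Z) <- "double"
  }

  keep <- !is.na(y) & stats::complete.cases(G)
  if (!is.null(Z)) keep <- keep & stats::complete.cases(Z)
  n_excluded <- sum(!keep)
  if (n_excluded > 0L) {
    message("excluding ", n_excluded,
            " individual(s) with missing genotype, status or covariate")
    y <- y[keep]
    G <- G[keep, , drop = FALSE]
    if (!is.null(Z)) Z <- Z[keep, , drop = FALSE]
  }
  if (!all(y %in% c(0, 1)) || all(y == 0) || all(y == 1)) {
    stop("degenerate phenotype: both cases and controls are required",
         call. = FALSE)
  }

  L <- drop(G %*% w)
  thresholds <- valid_thresholds(L)
  n <- length(y)
  n_cases <- sum(y == 1)
  n_controls <- n - n_cases

  if (length(thresholds) == 0L) {
    warning("all allele loads are identical: no valid threshold, p_final = 1",
            call. = FALSE)
    return(new_smt_fit(empty_profile(), v = 0L, best_threshold = NA_real_,
                       min_p = NA_real_, p_final = 1, n = n,
                       n_cases = n_cases, n_controls = n_controls,
                       snps = snps, test = test, n_excluded = n_excluded,
                       null_loglik = NA_real_, covariates = covariates))
  }

  Xnull <- cbind(`(Intercept)` = rep(1, n), G, Z)
  qrX <- qr(Xnull, tol = 1e-9)
  if (qrX$rank < ncol(Xnull)) {
    bad <- colnames(Xnull)[qrX$pivot[seq(qrX$rank + 1L, ncol(Xnull))]]
    bad_core <- setdiff(bad, colnames(Z))
    if (length(bad_core)) {
      stop("null design matrix is rank deficient; collinear column(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    # dependent extra covariates carry no additional information: drop them
    message("dropping ", length(bad),
            " collinear covariate column(s): ", paste(bad, collapse = ", "))
    Xnull <- Xnull[, setdiff(colnames(Xnull), bad), drop = FALSE]
  }

  # an indicator that exactly duplicates a covariate column is a hard error
  above <- outer(L, thresholds, ">=")
  if (ncol(Xnull) > 1L) {
    covcols <- Xnull[, -1L, drop = FALSE]
    sds <- apply(covcols, 2L, sd)
    nondeg <- sds > 0
    if (any(nondeg)) {
      cc <- suppressWarnings(cor(above * 1, covcols[, nondeg, drop = FALSE]))
      dup <- which(abs(cc) > 1 - 1e-12, arr.ind = TRUE)
      if (nrow(dup)) {
        stop("threshold ", thresholds[dup[1L, 1L]],
             ": indicator is collinear with covariate '",
             colnames(covcols[, nondeg, drop = FALSE])[dup[1L, 2L]], "'",
             call. = FALSE)
      }
    }
  }

  scan <- cpp_smt_scan(Xnull, y, L, thresholds, as.integer(max_iter), tol)
  bad_null <- isTRUE(scan$null_separated) || isTRUE(scan$null_singular)
  if (bad_null) {
    warning("null model fit is degenerate (separation); all threshold ",
            "p-values set to 1", call. = FALSE)
  }

  # two-by-two table per threshold: case/control status vs below/above load.
  # An empty cell is quasi-complete separation for the indicator: its MLE
  # is infinite, so the Wald-scale estimate and standard error are reported
  # as NA there, while the likelihood-ratio p-value remains well-defined.
  a <- colSums(above & y == 1)            # cases above
  b <- n_cases - a                        # cases below
  cc_above <- colSums(above & y == 0)     # controls above
  d <- n_controls - cc_above              # controls below
  zero_cell <- a == 0 | b == 0 | cc_above == 0 | d == 0

  usable <- scan$converged & !scan$separated & !scan$singular & !bad_null
  estimable <- usable & !zero_cell
  stat <- pmax(0, 2 * (scan$alt_loglik - scan$null_loglik))
  p_thr <- if (test == "lrt") {
    ifelse(usable, pchisq(stat, df = 1, lower.tail = FALSE), 1)
  } else {
    ifelse(estimable,
           pchisq((scan$pi / scan$se)^2, df = 1, lower.tail = FALSE), 1)
  }
  pi_hat <- ifelse(estimable, scan$pi, NA_real_)
  pi_se <- ifelse(estimable, scan$se, NA_real_)

  ah <- a + 0.5 * zero_cell
  bh <- b + 0.5 * zero_cell
  ch <- cc_above + 0.5 * zero_cell
  dh <- d + 0.5 * zero_cell
  or <- (ah * dh) / (bh * ch)
  se_log_or <- sqrt(1 / ah + 1 / bh + 1 / ch + 1 / dh)

  profile <- tibble::tibble(
    threshold = thresholds,
    p_value = p_thr,
    pi = pi_hat,
    se = pi_se,
    or = or,
    se_log_or = se_log_or,
    freq_cases = a / n_cases,
    freq_controls = cc_above / n_controls,
    n_above = a + cc_above,
    separated = !usable,
    or_corrected = zero_cell
  )

  v <- length(thresholds)
  min_p <- min(profile$p_value)
  best_threshold <- profile$threshold[which(profile$p_value == min_p)[1L]]
  p_final <- min(1, v * min_p)

  new_smt_fit(profile, v = v, best_threshold = best_threshold, min_p = min_p,
              p_final = p_final, n = n, n_cases = n_cases,
              n_controls = n_controls, snps = snps, test = test,
              n_excluded = n_excluded, null_loglik = scan$null_loglik,
              covariates = covariates)
}

new_smt_fit <- function(profile, v, best_threshold, min_p, p_final, n,
                        n_cases, n_controls, snps, test, n_excluded,
                        null_loglik, covariates) {
  structure(
    list(profile = profile, v = v, best_threshold = best_threshold,
         min_p = min_p, p_final = p_final, n = n, n_cases = n_cases,
         n_controls = n_controls, n_snps = length(snps), snps = snps,
         test = test, n_excluded = n_excluded, null_loglik = null_loglik,
         covariates = covariates),
    class = "smt_fit"
  )
}

empty_profile <- function() {
  tibble::tibble(
    threshold = numeric(0), p_value = numeric(0), pi = numeric(0),
    se = numeric(0), or = numeric(0), se_log_or = numeric(0),
    freq_cases = numeric(0), freq_controls = numeric(0),
    n_above = numeric(0), separated = logical(0), or_corrected = logical(0)
  )
}

#' Threshold profile of the supra-multiplicativity scan
#'
#' Convenience wrapper around [smt_test()] returning only the per-threshold
#' profile: indicator estimate and standard error, uncorrected p-value,
#' above-threshold frequency among cases and controls, and the two-by-two
#' odds ratio (load below vs above the cut-off against case-control status)
#' with the standard error of its logarithm.  Zero cells receive the
#' Haldane-Anscombe 0.5 correction and are flagged in `or_corrected`.
#'
#' @inheritParams smt_test
#' @return A tibble, one row per valid threshold.
#' @export
threshold_profile <- function(data, spec = NULL, snps = NULL,
                              status = "status", covariates = NULL, ...) {
  tidy(smt_test(data, spec = spec, snps = snps, status = status,
                covariates = covariates, ...))
}

#' Covariate-adjusted supra-multiplicativity test
#'
#' Adds dominance and interaction covariates to both the null and the
#' alternative model of the threshold scan, so that known lower-order
#' effects cannot drive a significant SMT.  For each SNP in `dominance_snps`
#' a heterozygote indicator is added.  For each pair in `interaction_pairs`
#' the heterozygote indicators of both SNPs plus the four genotypic product
#' terms spanning \{additive, dominance\}^2 are added (this block absorbs an
#' arbitrary pairwise interaction, including double-recessive effects).  For
#' each triple in `interaction_triples` all lower-order terms among the
#' three SNPs plus the eight genotypic three-way products are added.
#' Constructed terms shared between adjustments are deduplicated silently;
#' listing the same SNP, pair or triple twice is an error.
#'
#' @inheritParams smt_test
#' @param dominance_snps Character vector of SNP names.
#' @param interaction_pairs List of length-2 character vectors (or a
#'   2-column matrix) of SNP names.
#' @param interaction_triples List of length-3 character vectors (or a
#'   3-column matrix) of SNP names.
#' @return An `smt_fit`, as [smt_test()].
#' @export
smt_adjusted <- function(data, spec = NULL, snps = NULL, status = "status",
                         dominance_snps = NULL, interaction_pairs = NULL,
                         interaction_triples = NULL, covariates = NULL, ...) {
  snps <- resolve_snps(data, spec, snps, status = status,
                       covariates = covariates)
  pairs <- normalize_tuples(interaction_pairs, 2L, snps, "interaction pair")
  triples <- normalize_tuples(interaction_triples, 3L, snps,
                              "interaction triple")
  dominance_snps <- unique_or_stop(as.character(dominance_snps %||% character()),
                                   "dominance SNP")
  unknown <- setdiff(dominance_snps, snps)
  if (length(unknown)) {
    stop("dominance SNP(s) not in the set: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }

  terms <- list()
  add_dom <- function(s) {
    nm <- paste0("dom_", s)
    if (is.null(terms[[nm]])) {
      g <- data[[s]]
      if (any(abs(g - round(g)) > 1e-8, na.rm = TRUE)) {
        stop("dominance adjustment requires hard-call genotypes (SNP '", s,
             "')", call. = FALSE)
      }
      terms[[nm]] <<- as.numeric(round(g) == 1)
    }
    nm
  }
  add_pair_block <- function(p) {
    a1 <- data[[p[1L]]]; a2 <- data[[p[2L]]]
    nm1 <- add_dom(p[1L]); nm2 <- add_dom(p[2L])
    d1 <- terms[[nm1]]; d2 <- terms[[nm2]]
    base <- paste(p, collapse = ".")
    blk <- list(aa = a1 * a2, ad = a1 * d2, da = d1 * a2, dd = d1 * d2)
    for (k in names(blk)) {
      nm <- paste0(base, "_", k)
      if (is.null(terms[[nm]])) terms[[nm]] <<- blk[[k]]
    }
  }
  for (s in dominance_snps) add_dom(s)
  for (p in pairs) add_pair_block(p)
  for (tr in triples) {
    for (p in combn(tr, 2L, simplify = FALSE)) add_pair_block(p)
    a <- lapply(tr, function(s) data[[s]])
    dom_names <- vapply(tr, add_dom, character(1))
    d <- lapply(dom_names, function(nm) terms[[nm]])
    base <- paste(tr, collapse = ".")
    for (k1 in c("a", "d")) for (k2 in c("a", "d")) for (k3 in c("a", "d")) {
      nm <- paste0(base, "_", k1, k2, k3)
      t1 <- if (k1 == "a") a[[1L]] else d[[1L]]
      t2 <- if (k2 == "a") a[[2L]] else d[[2L]]
      t3 <- if (k3 == "a") a[[3L]] else d[[3L]]
      if (is.null(terms[[nm]])) terms[[nm]] <- t1 * t2 * t3
    }
  }

  if (length(terms) == 0L) {
    return(smt_test(data, spec = spec, snps = snps, status = status,
                    covariates = covariates, ...))
  }
  aug <- tibble::as_tibble(data)
  for (nm in names(terms)) aug[[nm]] <- terms[[nm]]
  smt_test(aug, spec = spec, snps = snps, status = status,
           covariates = c(covariates, names(terms)), ...)
}

normalize_tuples <- function(x, size, snps, what) {
  if (is.null(x)) return(list())
  if (is.matrix(x) || is.data.frame(x)) {
    x <- lapply(seq_len(nrow(x)), function(i) as.character(unlist(x[i, ])))
  }
  x <- lapply(x, as.character)
  lens <- lengths(x)
  if (any(lens != size)) {
    stop("each ", what, " must name exactly ", size, " SNPs", call. = FALSE)
  }
  x <- lapply(x, function(p) {
    if (anyDuplicated(p)) {
      stop(what, " repeats a SNP: ", paste(p, collapse = ", "), call. = FALSE)
    }
    unknown <- setdiff(p, snps)
    if (length(unknown)) {
      stop(what, " names SNP(s) not in the set: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    p[order(match(p, snps))]
  })
  keys <- vapply(x, paste, character(1), collapse = ".")
  if (anyDuplicated(keys)) {
    stop("duplicate ", what, " specification: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "), call. = FALSE)
  }
  x
}

unique_or_stop <- function(x, what) {
  if (anyDuplicated(x)) {
    stop("duplicate ", what, " specification: ",
         paste(unique(x[duplicated(x)]), collapse = ", "), call. = FALSE)
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- methods ----------------------------------------------------------------

#' @export
print.smt_fit <- function(x, ...) {
  cat("Supra-multiplicativity test:", x$n_snps, "SNPs,", x$n_cases, "cases /",
      x$n_controls, "controls\n")
  cat("valid thresholds v =", x$v, "| best threshold:",
      format(x$best_threshold), "\n")
  cat("min uncorrected p =", format(x$min_p),
      "| Bonferroni-corrected p_final =", format(x$p_final), "\n")
  invisible(x)
}

#' @rdname smt_test
#' @param x An `smt_fit` object.
#' @param ... Passed on / ignored.
#' @export
tidy.smt_fit <- function(x, ...) {
  x$profile
}

#' @rdname smt_test
#' @export
glance.smt_fit <- function(x, ...) {
  tibble::tibble(
    n_snps = x$n_snps, n = x$n, n_cases = x$n_cases,
    n_controls = x$n_controls, v = x$v, best_threshold = x$best_threshold,
    min_p = x$min_p, p_final = x$p_final, test = x$test,
    n_excluded = x$n_excluded
  )
}

#' @rdname smt_test
#' @param object An `smt_fit` object.
#' @export
autoplot.smt_fit <- function(object, ...) {
  prof <- object$profile
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$threshold, y = .data$pi)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$pi - 1.96 * .data$se,
                   ymax = .data$pi + 1.96 * .data$se),
      fill = "grey80", na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = object$best_threshold,
                        linetype = 3, colour = "red3") +
    ggplot2::labs(
      x = "risk allele load threshold T",
      y = expression(hat(pi)[T] ~ "(indicator estimate)"),
      title = "Supra-multiplicativity threshold profile",
      subtitle = paste0("v = ", object$v, ", p_final = ",
                        signif(object$p_final, 3))
    )
}
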