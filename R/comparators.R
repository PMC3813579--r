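#' Standard single-marker, dominance and interaction tests
#'
#' The comparator battery against which the supra-multiplicativity test is
#' benchmarked: per-SNP additive tests, dominance-deviation tests, and
#' two-/three-way logistic interaction tests in allelic mode (products of
#' additive terms only; 1 d.f. per order) or genotypic mode (products
#' spanning additive and dominance terms; 4 d.f. for pairs, 8 d.f. for
#' triples).  All are likelihood-ratio tests of the interaction block over
#' the corresponding lower-order model.  When empty genotype cells make a
#' term block rank deficient, the dependent terms are dropped, the degrees
#' of freedom reduced, and the result flagged in `rank_adjusted`.
#'
#' @param data Data frame with a binary `status` column and numeric SNP
#'   columns (risk-allele counts).
#' @param snp,snp1,snp2,snp3 SNP column names.
#' @param status Name of the binary phenotype column.
#' @param mode `"allelic"` or `"genotypic"` interaction coding.
#' @return A one-row tibble: test identity columns, `statistic`, `df`,
#'   `p_value`, plus estimate columns where a single parameter is tested and
#'   `dropped_terms`/`rank_adjusted` for the block tests.
#' @name comparator_tests
NULL

#' @rdname comparator_tests
#' @export
single_marker_test <- function(data, snp, status = "status") {
  d <- comparator_frame(data, snp, status)
  g <- d$g[[1L]]
  if (length(unique(g)) < 2L) {
    stop("monomorphic SNP: '", snp, "'", call. = FALSE)
  }
  n <- length(d$y)
  null_fit <- fit_logistic(design_matrix(list(), n), d$y)
  alt_fit <- fit_logistic(design_matrix(setNames(list(g), snp), n), d$y)
  res <- likelihood_ratio_test(null_fit, alt_fit, df = 1L)
  tibble::tibble(
    snp = snp,
    statistic = res$statistic,
    df = res$df,
    p_value = res$p_value,
    estimate = unname(alt_fit$coefficients[snp]),
    se = unname(alt_fit$std_errors[snp]),
    odds_ratio = exp(unname(alt_fit$coefficients[snp]))
  )
}

#' @rdname comparator_tests
#' @export
dominance_test <- function(data, snp, status = "status") {
  d <- comparator_frame(data, snp, status)
  g <- d$g[[1L]]
  het <- as.numeric(round(g) == 1)
  if (sum(het) == 0) {
    stop("no heterozygotes at SNP '", snp,
         "': dominance deviation is not estimable", call. = FALSE)
  }
  n <- length(d$y)
  terms_null <- setNames(list(g), snp)
  terms_alt <- c(terms_null, setNames(list(het), paste0("dom_", snp)))
  null_fit <- fit_logistic(design_matrix(terms_null, n), d$y)
  alt_fit <- fit_logistic(design_matrix(terms_alt, n), d$y)
  res <- likelihood_ratio_test(null_fit, alt_fit, df = 1L)
  dom_lab <- paste0("dom_", snp)
  tibble::tibble(
    snp = snp,
    statistic = res$statistic,
    df = res$df,
    p_value = res$p_value,
    estimate = unname(alt_fit$coefficients[dom_lab]),
    se = unname(alt_fit$std_errors[dom_lab])
  )
}

#' @rdname comparator_tests
#' @export
pairwise_interaction_test <- function(data, snp1, snp2, status = "status",
                                      mode = c("allelic", "genotypic")) {
  mode <- match.arg(mode)
  d <- comparator_frame(data, c(snp1, snp2), status)
  a1 <- d$g[[1L]]; a2 <- d$g[[2L]]
  if (length(unique(a1)) < 2L || length(unique(a2)) < 2L) {
    stop("monomorphic SNP in pair (", snp1, ", ", snp2, ")", call. = FALSE)
  }
  if (mode == "allelic") {
    null_terms <- setNames(list(a1, a2), c(snp1, snp2))
    int_terms <- setNames(list(a1 * a2), paste0(snp1, ".", snp2, "_aa"))
  } else {
    d1 <- as.numeric(round(a1) == 1); d2 <- as.numeric(round(a2) == 1)
    null_terms <- setNames(list(a1, d1, a2, d2),
                           c(snp1, paste0("dom_", snp1),
                             snp2, paste0("dom_", snp2)))
    base <- paste0(snp1, ".", snp2)
    int_terms <- setNames(
      list(a1 * a2, a1 * d2, d1 * a2, d1 * d2),
      paste0(base, c("_aa", "_ad", "_da", "_dd")))
  }
  out <- lrt_block(d$y, null_terms, int_terms)
  dplyr::bind_cols(
    tibble::tibble(snp1 = snp1, snp2 = snp2, mode = mode), out)
}

#' @rdname comparator_tests
#' @export
threeway_interaction_test <- function(data, snp1, snp2, snp3,
                                      status = "status",
                                      mode = c("allelic", "genotypic")) {
  mode <- match.arg(mode)
  d <- comparator_frame(data, c(snp1, snp2, snp3), status)
  snps <- c(snp1, snp2, snp3)
  a <- d$g
  if (any(vapply(a, function(g) length(unique(g)) < 2L, TRUE))) {
    stop("monomorphic SNP in triple (", paste(snps, collapse = ", "), ")",
         call. = FALSE)
  }
  if (mode == "allelic") {
    null_terms <- setNames(a, snps)
    for (p in combn(3L, 2L, simplify = FALSE)) {
      null_terms[[paste0(snps[p[1L]], ".", snps[p[2L]], "_aa")]] <-
        a[[p[1L]]] * a[[p[2L]]]
    }
    int_terms <- setNames(list(a[[1L]] * a[[2L]] * a[[3L]]),
                          paste0(paste(snps, collapse = "."), "_aaa"))
  } else {
    dm <- lapply(a, function(g) as.numeric(round(g) == 1))
    null_terms <- list()
    for (i in 1:3) {
      null_terms[[snps[i]]] <- a[[i]]
      null_terms[[paste0("dom_", snps[i])]] <- dm[[i]]
    }
    for (p in combn(3L, 2L, simplify = FALSE)) {
      i <- p[1L]; j <- p[2L]
      base <- paste0(snps[i], ".", snps[j])
      null_terms[[paste0(base, "_aa")]] <- a[[i]] * a[[j]]
      null_terms[[paste0(base, "_ad")]] <- a[[i]] * dm[[j]]
      null_terms[[paste0(base, "_da")]] <- dm[[i]] * a[[j]]
      null_terms[[paste0(base, "_dd")]] <- dm[[i]] * dm[[j]]
    }
    base <- paste(snps, collapse = ".")
    int_terms <- list()
    for (k1 in c("a", "d")) for (k2 in c("a", "d")) for (k3 in c("a", "d")) {
      t1 <- if (k1 == "a") a[[1L]] else dm[[1L]]
      t2 <- if (k2 == "a") a[[2L]] else dm[[2L]]
      t3 <- if (k3 == "a") a[[3L]] else dm[[3L]]
      int_terms[[paste0(base, "_", k1, k2, k3)]] <- t1 * t2 * t3
    }
  }
  out <- lrt_block(d$y, null_terms, int_terms)
  dplyr::bind_cols(
    tibble::tibble(snp1 = snp1, snp2 = snp2, snp3 = snp3, mode = mode), out)
}

# Likelihood-ratio test of a term block over a lower-order model, with
# greedy rank repair: dependent columns (null first, then block) are dropped
# and the tested degrees of freedom reduced accordingly.
lrt_block <- function(y, null_terms, int_terms) {
  n <- length(y)
  keep_null <- greedy_independent(null_terms, n)
  Xnull <- design_matrix(null_terms[keep_null], n)
  keep_int <- greedy_independent(int_terms, n, base = Xnull)
  dropped <- (length(null_terms) - length(keep_null)) +
    (length(int_terms) - length(keep_int))
  df <- length(keep_int)
  if (df == 0L) {
    return(tibble::tibble(statistic = NA_real_, df = 0L, p_value = NA_real_,
                          dropped_terms = dropped, rank_adjusted = TRUE))
  }
  Xalt <- cbind(Xnull, do.call(cbind, int_terms[keep_int]))
  null_fit <- fit_logistic(Xnull, y)
  alt_fit <- fit_logistic(Xalt, y)
  res <- likelihood_ratio_test(null_fit, alt_fit, df = df)
  tibble::tibble(statistic = res$statistic, df = res$df,
                 p_value = res$p_value, dropped_terms = dropped,
                 rank_adjusted = dropped > 0L)
}

# Indices of terms that keep the design full rank, added greedily in order
# on top of `base` (or an intercept).
greedy_independent <- function(terms, n, base = NULL) {
  if (is.null(base)) {
    base <- matrix(1, n, 1L)
  }
  keep <- integer(0)
  X <- base
  r <- qr(X)$rank
  for (i in seq_along(terms)) {
    cand <- cbind(X, terms[[i]])
    rc <- qr(cand)$rank
    if (rc > r) {
      keep <- c(keep, i)
      X <- cand
      r <- rc
    }
  }
  keep
}

comparator_frame <- function(data, snps, status) {
  if (!status %in% names(data)) {
    stop("status column '", status, "' not found", call. = FALSE)
  }
  miss <- setdiff(snps, names(data))
  if (length(miss)) {
    stop("SNP column(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  y <- as.numeric(data[[status]])
  g <- lapply(snps, function(s) as.numeric(data[[s]]))
  keep <- !is.na(y) & Reduce(`&`, lapply(g, function(v) !is.na(v)))
  y <- y[keep]
  g <- lapply(g, function(v) v[keep])
  if (!all(y %in% c(0, 1)) || all(y == 0) || all(y == 1)) {
    stop("degenerate phenotype: both cases and controls are required",
         call. = FALSE)
  }
  list(y = y, g = g)
}

#' Most significant comparator test over a SNP set
#'
#' Enumerates every single marker, SNP pair or SNP triple of the set, runs
#' the chosen comparator test on each, and reports the minimum p-value with
#' a configurable decision rule: `"uncorrected"` compares the minimum
#' p-value against `alpha` directly (the convention used when quoting power
#' of the most significant pair without multiplicity correction), while
#' `"bonferroni"` compares it against `alpha / m`, where `m` is the number
#' of member tests.
#'
#' @inheritParams comparator_tests
#' @param test `"single_marker"`, `"pairwise"` or `"threeway"`.
#' @param snps SNP column names (default: all numeric columns except
#'   `sample_id`/`status`/`allele_load`).
#' @param alpha Optional significance level for the decision columns.
#' @param alpha_policy Decision rule (see above).
#' @return A one-row tibble with `test`, `mode`, `n_tests`, `min_p`, the
#'   identity of the most significant member, and, when `alpha` is given,
#'   `alpha`, `alpha_threshold` and `significant`.  The full enumeration is
#'   attached as attribute `"tests"`.
#' @examples
#' set.seed(42)
#' rep1 <- sample_case_control(rez_model("A"), 200, 200)
#' best_of_set(rep1$data, test = "pairwise")
#' @export
best_of_set <- function(data, test = c("single_marker", "pairwise",
                                       "threeway"),
                        snps = NULL, status = "status",
                        mode = c("allelic", "genotypic"), alpha = NULL,
                        alpha_policy = c("uncorrected", "bonferroni")) {
  test <- match.arg(test)
  mode <- match.arg(mode)
  alpha_policy <- match.arg(alpha_policy)
  snps <- resolve_snps(data, NULL, snps, status = status)
  order_needed <- switch(test, single_marker = 1L, pairwise = 2L,
                         threeway = 3L)
  if (length(snps) < order_needed) {
    stop("SNP set smaller than the order of the requested test",
         call. = FALSE)
  }
  members <- combn(snps, order_needed, simplify = FALSE)
  rows <- switch(test,
    single_marker = purrr::map(members, function(m) {
      single_marker_test(data, m[1L], status)
    }),
    pairwise = purrr::map(members, function(m) {
      pairwise_interaction_test(data, m[1L], m[2L], status, mode)
    }),
    threeway = purrr::map(members, function(m) {
      threeway_interaction_test(data, m[1L], m[2L], m[3L], status, mode)
    })
  )
  tests <- dplyr::bind_rows(rows)
  m <- nrow(tests)
  finite_p <- tests$p_value[!is.na(tests$p_value)]
  min_p <- if (length(finite_p)) min(finite_p) else NA_real_
  best_idx <- if (is.na(min_p)) NA_integer_ else {
    which(tests$p_value == min_p)[1L]
  }
  best_id <- if (is.na(best_idx)) NA_character_ else {
    paste(members[[best_idx]], collapse = ",")
  }
  out <- tibble::tibble(
    test = test,
    mode = if (test == "single_marker") NA_character_ else mode,
    n_tests = m,
    min_p = min_p,
    best = best_id
  )
  if (!is.null(alpha)) {
    thr <- if (alpha_policy == "bonferroni") alpha / m else alpha
    out$alpha <- alpha
    out$alpha_policy <- alpha_policy
    out$alpha_threshold <- thr
    out$significant <- !is.na(min_p) && min_p <= thr
  }
  attr(out, "tests") <- tests
  out
}
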