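#' Fit a binomial-logit regression by iteratively reweighted least squares
#'
#' The package's internal engine behind every test: a plain logistic
#' regression maximising the Bernoulli log-likelihood.  The design matrix
#' must carry the intercept as its first column.  Convergence is declared
#' when the relative change in log-likelihood falls below `tol`; complete or
#' quasi-complete separation is flagged when fitted probabilities saturate
#' (within 1e-10 of 0 or 1) alongside diverging coefficients.
#'
#' @param X Numeric design matrix, intercept as first column, finite values,
#'   unique column names.
#' @param y Binary phenotype vector (0 = control, 1 = case), both classes
#'   present, `length(y) == nrow(X)`.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param start Optional starting coefficient vector.
#'
#' @return An object of class `logistic_fit`: a list with `coefficients`,
#'   `std_errors` (both named), `log_likelihood`, `converged`, `separated`,
#'   `iterations`, `n`, `df`.
#' @examples
#' X <- cbind(intercept = 1, x = c(rep(0, 10), rep(1, 10)))
#' y <- rep(c(0, 1, 0, 0), 5)
#' fit_logistic(X, y)$coefficients
#' @export
fit_logistic <- function(X, y, max_iter = 100L, tol = 1e-10, start = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) {
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1L)))
  }
  if (anyDuplicated(colnames(X))) {
    stop("design matrix column labels must be unique", call. = FALSE)
  }
  if (!all(is.finite(X))) {
    stop("design matrix contains non-finite values", call. = FALSE)
  }
  y <- as.numeric(y)
  if (length(y) != nrow(X)) {
    stop("phenotype length does not match design matrix rows", call. = FALSE)
  }
  if (!all(y %in% c(0, 1))) {
    stop("phenotype must be coded 0/1", call. = FALSE)
  }
  if (all(y == 0) || all(y == 1)) {
    stop("degenerate phenotype: both cases and controls are required",
         call. = FALSE)
  }
  qrX <- qr(X, tol = 1e-9)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(start)) {
    start <- numeric(ncol(X))
    start[1L] <- log(mean(y) / (1 - mean(y)))
  }
  raw <- cpp_logistic_fit(X, y, start, as.integer(max_iter), tol)
  structure(
    list(
      coefficients   = setNames(drop(raw$coefficients), colnames(X)),
      std_errors     = setNames(drop(raw$std_errors), colnames(X)),
      log_likelihood = raw$log_likelihood,
      converged      = raw$converged && !raw$singular,
      separated      = raw$separated,
      iterations     = raw$iterations,
      n              = nrow(X),
      df             = ncol(X)
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit:", x$n, "individuals,", x$df, "parameters\n")
  cat("log-likelihood:", format(x$log_likelihood), "| converged:",
      x$converged, "| separated:", x$separated, "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Likelihood-ratio test between two nested logistic fits
#'
#' The statistic is `2 * (llik_alt - llik_null)`, clipped at zero, referred
#' to the upper tail of a chi-square distribution with `df` degrees of
#' freedom.
#'
#' @param null_fit,alt_fit `logistic_fit` objects for the nested (null) and
#'   encompassing (alternative) model.
#' @param df Positive integer: number of parameters tested.
#' @return A one-row tibble with `statistic`, `df`, `p_value`,
#'   `effect_estimate`, `effect_se` (the latter two `NA` for a block test).
#' @examples
#' # identical models: statistic 0, p = 1
#' X <- cbind(intercept = 1)
#' y <- rep(0:1, 10)
#' f <- fit_logistic(X, y)
#' likelihood_ratio_test(f, f, df = 1)
#' @export
likelihood_ratio_test <- function(null_fit, alt_fit, df) {
  df <- as.integer(df)
  if (length(df) != 1L || is.na(df) || df <= 0L) {
    stop("df must be a positive integer", call. = FALSE)
  }
  if (alt_fit$log_likelihood < null_fit$log_likelihood - 1e-8) {
    stop("models are not nested: alternative log-likelihood below null",
         call. = FALSE)
  }
  statistic <- max(0, 2 * (alt_fit$log_likelihood - null_fit$log_likelihood))
  tibble::tibble(
    statistic = statistic,
    df = df,
    p_value = pchisq(statistic, df = df, lower.tail = FALSE),
    effect_estimate = NA_real_,
    effect_se = NA_real_
  )
}

#' Wald test for a single coefficient of a logistic fit
#'
#' Reported alongside the likelihood-ratio scan because the per-threshold
#' effect estimate and its standard error are part of the threshold profile.
#'
#' @param fit A converged `logistic_fit`.
#' @param column_label Name of the coefficient to test.
#' @return A one-row tibble with `statistic` (`(coef/se)^2`), `df = 1`,
#'   `p_value`, `effect_estimate`, `effect_se`.
#' @export
wald_test <- function(fit, column_label) {
  if (!column_label %in% names(fit$coefficients)) {
    stop("no coefficient named '", column_label, "'", call. = FALSE)
  }
  if (fit$separated) {
    stop("unreliable Wald: fit is separated", call. = FALSE)
  }
  if (!fit$converged) {
    stop("unreliable Wald: fit did not converge", call. = FALSE)
  }
  est <- unname(fit$coefficients[column_label])
  se <- unname(fit$std_errors[column_label])
  statistic <- (est / se)^2
  tibble::tibble(
    statistic = statistic,
    df = 1L,
    p_value = pchisq(statistic, df = 1, lower.tail = FALSE),
    effect_estimate = est,
    effect_se = se
  )
}

# Build a design matrix from an intercept plus named term columns.
design_matrix <- function(terms, n) {
  if (length(terms) == 0L) {
    return(matrix(1, nrow = n, ncol = 1L, dimnames = list(NULL, "(Intercept)")))
  }
  X <- do.call(cbind, terms)
  cbind(`(Intercept)` = rep(1, n), X)
}
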