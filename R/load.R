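#' Per-individual risk-allele load
#'
#' Sums the (optionally weighted) risk-allele counts across the SNP set for
#' each individual.  Genotype columns must already be oriented so that values
#' count the externally designated risk allele (see [read_genotypes()] /
#' [orient_genotypes()]); with unit weights the load is an integer in
#' `[0, 2n]`.
#'
#' @param data A data frame with one row per individual and one numeric
#'   column per SNP (risk-allele counts in `[0, 2]`; fractional dosages
#'   allowed).
#' @param spec Optional risk-allele specification: a data frame with columns
#'   `snp_id` and (optionally) `weight`.  Every SNP used must appear exactly
#'   once; missing weights default to 1.  When `NULL`, unit weights are used.
#' @param snps Character vector of SNP column names; defaults to the spec's
#'   `snp_id` order, or to all numeric columns except `sample_id`/`status`.
#' @return The input data with an `allele_load` column appended (a tibble).
#' @examples
#' d <- tibble::tibble(snp1 = c(2, 1), snp2 = c(1, 0), snp3 = c(1, 1))
#' spec <- tibble::tibble(snp_id = c("snp1", "snp2", "snp3"),
#'                        weight = c(0.5, 1, 2))
#' compute_allele_load(d, spec)$allele_load # 4 and 2.5
#' @export
compute_allele_load <- function(data, spec = NULL, snps = NULL) {
  snps <- resolve_snps(data, spec, snps)
  w <- resolve_weights(spec, snps)
  G <- genotype_matrix(data, snps)
  out <- tibble::as_tibble(data)
  out$allele_load <- drop(G %*% w)
  out
}

#' Valid load thresholds for the indicator scan
#'
#' A cut-off `T` is valid when at least one individual has load `>= T` and at
#' least one has load `< T`; the count of valid cut-offs is the Bonferroni
#' factor of the supra-multiplicativity test.  For integer (unit-weight)
#' loads the grid is every integer in `{min(L)+1, ..., max(L)}`; for
#' real-valued weighted loads it is the distinct observed load values above
#' the minimum, so each achievable split is tested once.
#'
#' @param load Numeric vector of per-individual allele loads.
#' @return Strictly increasing numeric vector of valid thresholds (empty when
#'   all loads are identical).
#' @examples
#' valid_thresholds(c(0, 1, 2, 3, 4)) # 1 2 3 4
#' valid_thresholds(c(5, 5, 5))       # empty
#' @export
valid_thresholds <- function(load) {
  if (length(load) == 0L) stop("empty load vector", call. = FALSE)
  if (anyNA(load)) stop("load vector contains missing values", call. = FALSE)
  lo <- min(load)
  hi <- max(load)
  if (lo == hi) return(numeric(0))
  if (all(abs(load - round(load)) < 1e-8)) {
    seq(round(lo) + 1, round(hi))
  } else {
    sort(unique(load))[-1L]
  }
}

# ---- internal helpers shared across modules ---------------------------------

resolve_snps <- function(data, spec = NULL, snps = NULL,
                         status = "status", covariates = NULL) {
  if (is.null(snps)) {
    if (!is.null(spec)) {
      snps <- as.character(spec$snp_id)
    } else {
      numeric_cols <- names(data)[vapply(data, is.numeric, logical(1))]
      snps <- setdiff(numeric_cols,
                      c("sample_id", "allele_load", status, covariates))
    }
  }
  missing_cols <- setdiff(snps, names(data))
  if (length(missing_cols)) {
    stop("SNP column(s) not found in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.null(spec)) {
    uncovered <- setdiff(snps, as.character(spec$snp_id))
    if (length(uncovered)) {
      stop("SNP(s) absent from risk-allele spec: ",
           paste(uncovered, collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(spec$snp_id)) {
      stop("risk-allele spec lists SNP(s) more than once: ",
           paste(unique(spec$snp_id[duplicated(spec$snp_id)]), collapse = ", "),
           call. = FALSE)
    }
  }
  snps
}

resolve_weights <- function(spec, snps) {
  if (is.null(spec) || is.null(spec$weight)) {
    return(setNames(rep(1, length(snps)), snps))
  }
  w <- setNames(as.numeric(spec$weight), as.character(spec$snp_id))[snps]
  if (anyNA(w)) w[is.na(w)] <- 1
  if (any(w <= 0)) stop("risk-allele weights must be positive", call. = FALSE)
  w
}

genotype_matrix <- function(data, snps) {
  G <- as.matrix(data[snps])
  storage.mode(G) <- "double"
  ok <- is.na(G) | (G >= 0 & G <= 2)
  if (!all(ok)) {
    stop("genotype values must be risk-allele counts/dosages in [0, 2]",
         call. = FALSE)
  }
  G
}
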