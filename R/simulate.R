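#' Draw population genotypes under Hardy-Weinberg equilibrium
#'
#' Per SNP, risk-allele counts are Binomial(2, q), independent across SNPs
#' and individuals.
#'
#' @param q Risk-allele frequency vector.
#' @param n_individuals Number of individuals to draw.
#' @param seed Optional seed (the current RNG stream is used when `NULL`).
#' @param snp_ids Optional SNP column names.
#' @return A tibble with `sample_id` and one column of counts per SNP.
#' @export
draw_population_genotypes <- function(q, n_individuals, seed = NULL,
                                      snp_ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(q > 0), all(q < 1), n_individuals >= 1)
  n <- length(q)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%02d", seq_len(n))
  G <- matrix(rbinom(n_individuals * n, 2L, rep(q, each = n_individuals)),
              nrow = n_individuals, ncol = n, dimnames = list(NULL, snp_ids))
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("id%06d", seq_len(n_individuals))),
    tibble::as_tibble(G)
  )
}

#' Simulate a case-control data set under a penetrance model
#'
#' Draws population genotypes under Hardy-Weinberg equilibrium, assigns
#' disease status Bernoulli(penetrance), and fills the case and control
#' quotas exactly.  The sampling is exact with respect to the implied
#' case-control genotype distributions; depending on the model family it is
#' realised as plain vectorised rejection (liability models), tilted
#' proposals with an acceptance correction for the penetrance cap
#' (multiplicative family), or closed-form enumeration of the 27 genotype
#' combinations (three-SNP recessive models).
#'
#' @param model A `pen_model`.
#' @param n_cases,n_controls Requested sample sizes (met exactly).
#' @param seed Optional seed.
#' @return An object of class `sim_replicate`: a list with `data` (tibble:
#'   `sample_id`, `status`, one column per SNP of risk-allele counts),
#'   `spec` (risk-allele specification tibble with the model's weights),
#'   `model`, `seed`, `prevalence` (exact) and `acceptance_rate` (expected
#'   fraction of population draws retained by quota-rejection sampling).
#' @export
sample_case_control <- function(model, n_cases = 3000, n_controls = 3000,
                                seed = NULL) {
  stopifnot(inherits(model, "pen_model"), n_cases >= 1, n_controls >= 1)
  if (!is.null(seed)) set.seed(seed)
  prev <- prevalence(model)
  if (prev < 1e-4) {
    stop("population prevalence below 1e-4 under this model; enrich the ",
         "design (raise penetrances) before case-control sampling",
         call. = FALSE)
  }
  if (prev > 1 - 1e-4) {
    stop("population prevalence above 1 - 1e-4; controls cannot be sampled",
         call. = FALSE)
  }
  G <- sample_cc_impl(model, n_cases, n_controls, prev)
  data <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = sprintf("id%06d", seq_len(n_cases + n_controls)),
      status = rep(c(1L, 0L), c(n_cases, n_controls))
    ),
    tibble::as_tibble(G)
  )
  spec <- tibble::tibble(
    snp_id = model$snp_ids,
    risk_allele = "A",
    weight = if (is.null(model$weights)) 1 else model$weights
  )
  # expected retention of a population draw under plain quota rejection
  acc <- (n_cases + n_controls) /
    max(n_cases / prev, n_controls / (1 - prev))
  structure(
    list(data = data, spec = spec, model = model, seed = seed,
         prevalence = prev, acceptance_rate = acc),
    class = "sim_replicate"
  )
}

#' @export
print.sim_replicate <- function(x, ...) {
  cat("Simulated case-control replicate [", x$model$type, "]: ",
      sum(x$data$status == 1), " cases / ", sum(x$data$status == 0),
      " controls, ", x$model$n_snps, " SNPs\n", sep = "")
  cat("prevalence:", signif(x$prevalence, 4),
      "| expected rejection-sampling acceptance:",
      signif(x$acceptance_rate, 3), "\n")
  invisible(x)
}

sample_cc_impl <- function(model, n_cases, n_controls, prev) {
  UseMethod("sample_cc_impl")
}

#' @export
sample_cc_impl.recessive_model <- function(model, n_cases, n_controls, prev) {
  # exact enumeration of the 27 three-SNP genotype combinations
  combos <- as.matrix(expand.grid(g1 = 0:2, g2 = 0:2, g3 = 0:2))
  pop <- hwe_probs(model$q[1L])[combos[, 1L] + 1L] *
    hwe_probs(model$q[2L])[combos[, 2L] + 1L] *
    hwe_probs(model$q[3L])[combos[, 3L] + 1L]
  f <- ifelse(rowSums(combos == 2) == 3L, model$p_high, model$f0)
  case_counts <- drop(rmultinom(1L, n_cases, pop * f))
  ctrl_counts <- drop(rmultinom(1L, n_controls, pop * (1 - f)))
  G <- combos[rep(seq_len(27L), case_counts + 0L), , drop = FALSE]
  G <- rbind(G, combos[rep(seq_len(27L), ctrl_counts), , drop = FALSE])
  # shuffle within status blocks so row order carries no genotype structure
  G[c(shuffle_within(case_counts), n_cases + shuffle_within(ctrl_counts)), ,
    drop = FALSE] -> G
  colnames(G) <- model$snp_ids
  G
}

shuffle_within <- function(counts) {
  sample.int(sum(counts))
}

#' @export
sample_cc_impl.lplm_model <- function(model, n_cases, n_controls, prev) {
  n <- model$n_snps
  cases <- matrix(0, 0L, n)
  ctrls <- matrix(0, 0L, n)
  while (nrow(cases) < n_cases || nrow(ctrls) < n_controls) {
    need_c <- n_cases - nrow(cases)
    need_k <- n_controls - nrow(ctrls)
    B <- ceiling(max(need_c / prev, need_k / (1 - prev)) * 1.1) + 100
    B <- min(B, 400000L)
    G <- matrix(rbinom(B * n, 2L, rep(model$q, each = B)), B, n)
    f <- penetrance(model, G)
    is_case <- runif(B) < f
    if (need_c > 0L) {
      add <- G[is_case, , drop = FALSE]
      cases <- rbind(cases, add[seq_len(min(nrow(add), need_c)), ,
                                drop = FALSE])
    }
    if (need_k > 0L) {
      add <- G[!is_case, , drop = FALSE]
      ctrls <- rbind(ctrls, add[seq_len(min(nrow(add), need_k)), ,
                                drop = FALSE])
    }
  }
  G <- rbind(cases, ctrls)
  colnames(G) <- model$snp_ids
  G
}

#' @export
sample_cc_impl.mult_block_model <- function(model, n_cases, n_controls,
                                            prev) {
  n <- model$n_snps
  draw_block_genotypes <- function(m, tilted) {
    G <- matrix(0, m, n)
    logS <- numeric(m)
    for (b in model$blocks) {
      pr <- if (tilted) b$probs * b$mult else b$probs
      cat_idx <- sample.int(length(pr), m, replace = TRUE, prob = pr)
      if (length(b$snps) == 1L) {
        G[, b$snps] <- cat_idx - 1L
      } else {
        G[, b$snps[1L]] <- (cat_idx - 1L) %/% 3L
        G[, b$snps[2L]] <- (cat_idx - 1L) %% 3L
      }
      logS <- logS + log(b$mult)[cat_idx]
    }
    list(G = G, f_raw = model$f0 * exp(logS))
  }
  # cases: tilted proposal prop. to p(x) * f0 * prod(mult); accepting with
  # min(f, 1) / (f0 * prod(mult)) corrects exactly for the penetrance cap
  cases <- matrix(0, 0L, n)
  while (nrow(cases) < n_cases) {
    m <- ceiling((n_cases - nrow(cases)) * 1.02) + 20
    d <- draw_block_genotypes(m, tilted = TRUE)
    keep <- runif(m) < pmin(d$f_raw, 1) / d$f_raw
    add <- d$G[keep, , drop = FALSE]
    cases <- rbind(cases,
                   add[seq_len(min(nrow(add), n_cases - nrow(cases))), ,
                       drop = FALSE])
  }
  # controls: population draws thinned by 1 - f
  ctrls <- matrix(0, 0L, n)
  while (nrow(ctrls) < n_controls) {
    m <- ceiling((n_controls - nrow(ctrls)) / (1 - prev) * 1.05) + 20
    d <- draw_block_genotypes(m, tilted = FALSE)
    keep <- runif(m) >= pmin(d$f_raw, 1)
    add <- d$G[keep, , drop = FALSE]
    ctrls <- rbind(ctrls,
                   add[seq_len(min(nrow(add), n_controls - nrow(ctrls))), ,
                       drop = FALSE])
  }
  G <- rbind(cases, ctrls)
  colnames(G) <- model$snp_ids
  G
}

#' Replace causal genotypes by LD-tagged proxy markers
#'
#' For each SNP, builds the two-locus haplotype distribution between the
#' causal variant and a proxy marker with squared correlation `r2`
#' (correlation `sqrt(r2)` between allele indicators) and samples the two
#' proxy allele copies conditional on the individual's causal allele copies.
#' By default the proxy allele frequency equals the causal risk-allele
#' frequency, for which any `r2` in (0, 1] is achievable; `r2 = 1`
#' reproduces the causal genotypes exactly.  The proxy allele counted is the
#' one positively correlated with the causal risk allele.
#'
#' @param data Data frame with one numeric risk-allele-count column per SNP
#'   (other columns are passed through).
#' @param q Causal risk-allele frequencies, in SNP column order (taken from
#'   `model` when supplied).
#' @param r2 Target squared correlation in (0, 1].
#' @param model Optional `pen_model` supplying `q` and the SNP names.
#' @param proxy_freq Optional proxy allele frequencies (default `q`).
#' @param snps SNP column names (default: the model's SNPs, or all numeric
#'   columns except `sample_id`/`status`/`allele_load`).
#' @param seed Optional seed.
#' @return The input tibble with the SNP columns replaced by proxy counts.
#' @export
make_tagged_proxies <- function(data, r2, q = NULL, model = NULL,
                                proxy_freq = NULL, snps = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(r2 > 0, r2 <= 1)
  if (!is.null(model)) {
    q <- q %||% model$q
    snps <- snps %||% model$snp_ids
  }
  snps <- resolve_snps(data, NULL, snps)
  if (is.null(q)) stop("supply causal allele frequencies via q= or model=",
                       call. = FALSE)
  if (length(q) == 1L) q <- rep(q, length(snps))
  stopifnot(length(q) == length(snps))
  p <- proxy_freq %||% q
  if (length(p) == 1L) p <- rep(p, length(snps))
  r <- sqrt(r2)
  d_target <- r * sqrt(q * (1 - q) * p * (1 - p))
  d_max <- pmin(q * (1 - p), p * (1 - q))
  bad <- d_target > d_max + 1e-12
  if (any(bad)) {
    r2_max <- (d_max / sqrt(q * (1 - q) * p * (1 - p)))^2
    stop("requested r2 infeasible for SNP(s) ",
         paste(snps[bad], collapse = ", "), "; maximum achievable r2: ",
         paste(signif(r2_max[bad], 3), collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(data)
  m <- nrow(out)
  for (i in seq_along(snps)) {
    x <- as.integer(round(out[[snps[i]]]))
    p1 <- p[i] + d_target[i] / q[i]         # P(proxy allele | causal allele)
    p0 <- p[i] - d_target[i] / (1 - q[i])   # P(proxy allele | other allele)
    out[[snps[i]]] <- rbinom(m, x, min(p1, 1)) +
      rbinom(m, 2L - x, max(p0, 0))
  }
  out
}
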