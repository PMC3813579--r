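#' Penetrance models for case-control genotype simulation
#'
#' Constructors for the penetrance models used throughout the simulation
#' study:
#'
#' * [multiplicative_model()] — per-allele relative risks combined
#'   multiplicatively on the risk scale (the "no deviation from
#'   multiplicativity" null).
#' * [dominance_semi_null_model()] — a subset of SNPs is purely recessive
#'   (relative risk only for homozygote carriers), the rest multiplicative.
#' * [pairwise_semi_null_model()] — listed SNP pairs carry a
#'   double-recessive relative risk for the 4-risk-allele two-locus
#'   genotype, the rest multiplicative.
#' * [lplm_model()] / [weighted_lplm_model()] — limiting-pathway liability
#'   models: baseline penetrance `f0` below a (weighted) risk-allele-load
#'   threshold, elevated penetrance `p1` at or above it.
#' * [recessive_model()] / [rez_model()] — three-SNP completely recessive
#'   models: elevated penetrance only for individuals homozygous for the
#'   risk allele at all three SNPs.
#'
#' Multiplicative-family penetrances are capped below 1 (capped individuals
#' are flagged); a configuration in which more than 0.1% of the population
#' would be capped is rejected at construction.
#'
#' @param q Risk-allele frequency vector, values in (0, 1).
#' @param rr Per-allele relative risks (multiplicative family).
#' @param f0 Baseline penetrance.  For the multiplicative family the default
#'   (`NULL`) sets `f0` so the population prevalence equals
#'   `target_prevalence`.
#' @param target_prevalence Target population prevalence used to derive `f0`
#'   when `f0` is not given.
#' @param snp_ids Optional SNP identifiers (default `snp01`, `snp02`, ...).
#' @return An object of class `pen_model` (with a variant subclass).
#' @name penetrance_models
NULL

new_pen_model <- function(type, subclass, q, f0, snp_ids, extra = list()) {
  n <- length(q)
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.finite(f0) || f0 <= 0 || f0 >= 1) {
    stop("baseline penetrance must lie strictly in (0, 1)", call. = FALSE)
  }
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%02d", seq_len(n))
  if (length(snp_ids) != n || anyDuplicated(snp_ids)) {
    stop("snp_ids must be unique and match the number of SNPs", call. = FALSE)
  }
  structure(
    c(list(type = type, q = as.numeric(q), f0 = f0,
           snp_ids = as.character(snp_ids), n_snps = n), extra),
    class = c(subclass, "pen_model")
  )
}

hwe_probs <- function(q) c((1 - q)^2, 2 * q * (1 - q), q^2)

#' @rdname penetrance_models
#' @export
multiplicative_model <- function(q, rr, f0 = NULL, target_prevalence = 0.01,
                                 snp_ids = NULL) {
  stopifnot(length(q) == length(rr), all(rr > 0))
  blocks <- lapply(seq_along(q), function(i) {
    list(snps = i, probs = hwe_probs(q[i]), mult = rr[i]^(0:2))
  })
  finish_block_model("multiplicative", q, blocks, f0, target_prevalence,
                     snp_ids, rr = rr)
}

#' @rdname penetrance_models
#' @param rr_hom Homozygote relative risk of the recessive-type SNPs.
#' @param recessive_snps Integer indices of the recessive-type SNPs.
#' @export
dominance_semi_null_model <- function(q, rr, rr_hom, recessive_snps,
                                      f0 = NULL, target_prevalence = 0.01,
                                      snp_ids = NULL) {
  n <- length(q)
  stopifnot(length(rr) == n, rr_hom > 0,
            all(recessive_snps %in% seq_len(n)))
  rr_out <- rr
  rr_out[recessive_snps] <- NA_real_
  blocks <- lapply(seq_len(n), function(i) {
    mult <- if (i %in% recessive_snps) c(1, 1, rr_hom) else rr[i]^(0:2)
    list(snps = i, probs = hwe_probs(q[i]), mult = mult)
  })
  finish_block_model("dominance_semi_null", q, blocks, f0, target_prevalence,
                     snp_ids, rr = rr_out,
                     extra = list(rr_hom = rr_hom,
                                  recessive_snps = as.integer(recessive_snps)))
}

#' @rdname penetrance_models
#' @param rr_double Relative risk of the two-locus genotype carrying 4 risk
#'   alleles, for each listed pair.
#' @param pairs Two-column matrix of SNP indices; pairs must be disjoint.
#' @export
pairwise_semi_null_model <- function(q, rr, rr_double, pairs, f0 = NULL,
                                     target_prevalence = 0.01,
                                     snp_ids = NULL) {
  n <- length(q)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  paired <- as.vector(pairs)
  stopifnot(length(rr) == n, rr_double > 0, all(paired %in% seq_len(n)),
            !anyDuplicated(paired))
  rr_out <- rr
  rr_out[paired] <- NA_real_
  blocks <- lapply(setdiff(seq_len(n), paired), function(i) {
    list(snps = i, probs = hwe_probs(q[i]), mult = rr[i]^(0:2))
  })
  pair_blocks <- lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    probs <- as.vector(outer(hwe_probs(q[i]), hwe_probs(q[j])))
    mult <- rep(1, 9L)
    mult[9L] <- rr_double  # genotype (2, 2): all four risk alleles
    list(snps = c(i, j), probs = probs, mult = mult)
  })
  finish_block_model("pairwise_semi_null", q, c(blocks, pair_blocks), f0,
                     target_prevalence, snp_ids, rr = rr_out,
                     extra = list(rr_double = rr_double, pairs = pairs))
}

finish_block_model <- function(type, q, blocks, f0, target_prevalence,
                               snp_ids, rr, extra = list()) {
  e_mult <- prod(vapply(blocks, function(b) sum(b$probs * b$mult), 0))
  if (is.null(f0)) f0 <- target_prevalence / e_mult
  m <- new_pen_model(type, "mult_block_model", q, f0, snp_ids,
                     extra = c(list(blocks = blocks, rr = rr,
                                    e_mult = e_mult), extra))
  capped <- cap_probability(m)
  if (capped > 0.001) {
    stop(sprintf(paste0("penetrance capped at 1 for %.2f%% of the population ",
                        "(> 0.1%%); lower the relative risks or the target ",
                        "prevalence"), 100 * capped), call. = FALSE)
  }
  m$cap_prob <- capped
  m
}

#' @rdname penetrance_models
#' @param p1 Elevated penetrance at or above the load threshold (LPLM) —
#'   must be at least `f0`.
#' @param n_snps Number of SNPs (when `q` is a scalar to be recycled).
#' @param weights Positive per-SNP load weights (default unit).
#' @param threshold Load threshold; the default (`NULL`) calibrates it so
#'   that about `target_tail` of the general population has load at or above
#'   it.
#' @param target_tail Target upper-tail population fraction for calibration.
#' @export
lplm_model <- function(p1, n_snps = NULL, q = 0.5, f0 = 0.03, weights = NULL,
                       threshold = NULL, target_tail = 0.015,
                       snp_ids = NULL) {
  if (!is.null(n_snps) && length(q) == 1L) q <- rep(q, n_snps)
  n <- length(q)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0))
  if (!is.finite(p1) || p1 >= 1 || p1 < f0) {
    stop("elevated penetrance p1 must lie in [f0, 1)", call. = FALSE)
  }
  cal_tail <- NA_real_
  if (is.null(threshold)) {
    cal <- calibrate_lplm_threshold(q, weights, target_tail)
    threshold <- cal$threshold
    cal_tail <- cal$tail
  }
  type <- if (all(weights == 1)) "lplm" else "weighted_lplm"
  dist <- load_distribution(q, weights)
  if (is.na(cal_tail)) cal_tail <- sum(dist$prob[dist$load >= threshold])
  new_pen_model(type, "lplm_model", q, f0, snp_ids,
                extra = list(p1 = p1, weights = as.numeric(weights),
                             threshold = threshold, tail = cal_tail,
                             load_dist = dist))
}

#' @rdname penetrance_models
#' @export
weighted_lplm_model <- function(p1, n_snps, q = 0.5, f0 = 0.03,
                                target_tail = 0.015, snp_ids = NULL) {
  lplm_model(p1, n_snps = n_snps, q = q, f0 = f0,
             weights = assign_modified_weights(n_snps),
             target_tail = target_tail, snp_ids = snp_ids)
}

#' @rdname penetrance_models
#' @param p_high Penetrance of the triple-homozygous-risk genotype.
#' @export
recessive_model <- function(q, p_high, f0 = 0.03, snp_ids = NULL) {
  if (length(q) != 3L) {
    stop("completely recessive models are defined by exactly three SNPs",
         call. = FALSE)
  }
  if (!is.finite(p_high) || p_high <= f0 || p_high >= 1) {
    stop("triple-homozygote penetrance must lie in (f0, 1)", call. = FALSE)
  }
  new_pen_model("recessive", "recessive_model", q, f0, snp_ids,
                extra = list(p_high = p_high))
}

#' @rdname penetrance_models
#' @param which Which preset recessive scenario: `"A"` (frequencies
#'   0.2/0.5/0.8, triple-homozygote penetrance 0.20), `"B"` (0.2/0.3/0.4,
#'   0.70), `"C"` (0.4/0.5/0.6, 0.10) or `"D"` (0.6/0.7/0.8, 0.05); baseline
#'   penetrance 0.03 throughout.
#' @export
rez_model <- function(which = c("A", "B", "C", "D")) {
  which <- match.arg(which)
  preset <- switch(which,
    A = list(q = c(0.2, 0.5, 0.8), p = 0.20),
    B = list(q = c(0.2, 0.3, 0.4), p = 0.70),
    C = list(q = c(0.4, 0.5, 0.6), p = 0.10),
    D = list(q = c(0.6, 0.7, 0.8), p = 0.05)
  )
  recessive_model(preset$q, preset$p, f0 = 0.03)
}

#' Random multiplicative null model
#'
#' Draws a fresh multiplicative null model using the current RNG state:
#' per-SNP risk-allele frequencies uniform on `q_range` and per-allele
#' relative risks uniform on `rr_range`.  Intended to be passed per
#' replicate to the study runner, which redraws frequencies and effects for
#' every simulated data set.
#'
#' @inheritParams penetrance_models
#' @param n_snps Number of SNPs.
#' @param q_range,rr_range Ranges of the uniform draws.
#' @return A `pen_model`.
#' @export
multiplicative_null_draw <- function(n_snps, q_range = c(0.1, 0.9),
                                     rr_range = c(1.2, 1.5),
                                     target_prevalence = 0.01) {
  multiplicative_model(q = runif(n_snps, q_range[1L], q_range[2L]),
                       rr = runif(n_snps, rr_range[1L], rr_range[2L]),
                       target_prevalence = target_prevalence)
}

#' @rdname multiplicative_null_draw
#' @param n_recessive Number of leading SNPs made purely recessive (semi-null
#'   model with dominance deviation).
#' @param rr_hom Homozygote relative risk of the recessive-type SNPs.
#' @export
semi_null_b1_draw <- function(n_snps = 30, n_recessive = 15, rr_hom,
                              q_range = c(0.1, 0.9), rr_range = c(1.2, 1.5),
                              target_prevalence = 0.01) {
  dominance_semi_null_model(
    q = runif(n_snps, q_range[1L], q_range[2L]),
    rr = runif(n_snps, rr_range[1L], rr_range[2L]),
    rr_hom = rr_hom, recessive_snps = seq_len(n_recessive),
    target_prevalence = target_prevalence)
}

#' @rdname multiplicative_null_draw
#' @param n_pairs Number of leading disjoint SNP pairs made double-recessive
#'   (semi-null model with pairwise interaction).
#' @param rr_double Relative risk of the 4-risk-allele two-locus genotype.
#' @export
semi_null_b2_draw <- function(n_snps = 30, n_pairs = 7, rr_double,
                              q_range = c(0.1, 0.9), rr_range = c(1.2, 1.5),
                              target_prevalence = 0.01) {
  pairwise_semi_null_model(
    q = runif(n_snps, q_range[1L], q_range[2L]),
    rr = runif(n_snps, rr_range[1L], rr_range[2L]),
    rr_double = rr_double,
    pairs = matrix(seq_len(2 * n_pairs), ncol = 2L, byrow = TRUE),
    target_prevalence = target_prevalence)
}

#' @export
print.pen_model <- function(x, ...) {
  cat("Penetrance model [", x$type, "]: ", x$n_snps, " SNPs, f0 = ",
      signif(x$f0, 4), "\n", sep = "")
  cat("population prevalence:", signif(prevalence(x), 4), "\n")
  if (!is.null(x$threshold)) {
    cat("load threshold:", x$threshold, "(tail", signif(x$tail, 3), "), p1 =",
        x$p1, "\n")
  }
  if (!is.null(x$p_high)) {
    cat("triple-homozygote penetrance:", x$p_high, "\n")
  }
  invisible(x)
}

# ---- penetrance -------------------------------------------------------------

#' Penetrance of genotypes under a model
#'
#' @param model A `pen_model`.
#' @param genotypes A data frame or matrix of risk-allele counts, one row
#'   per individual, columns matching the model's SNPs (by name when named),
#'   or a single genotype vector.
#' @return Numeric vector of disease probabilities; for the multiplicative
#'   family, values are capped at 1 and the number of capped individuals is
#'   attached as attribute `"capped"`.
#' @examples
#' penetrance(rez_model("A"), c(2, 2, 2)) # 0.20
#' penetrance(rez_model("A"), c(2, 2, 1)) # 0.03
#' @export
penetrance <- function(model, genotypes) {
  UseMethod("penetrance")
}

model_geno_matrix <- function(model, genotypes) {
  if (is.null(dim(genotypes))) {
    genotypes <- matrix(as.numeric(genotypes), nrow = 1L)
    colnames(genotypes) <- model$snp_ids
  }
  if (is.data.frame(genotypes)) {
    nm <- intersect(model$snp_ids, names(genotypes))
    genotypes <- if (length(nm) == model$n_snps) {
      as.matrix(genotypes[model$snp_ids])
    } else {
      as.matrix(genotypes[vapply(genotypes, is.numeric, logical(1))])
    }
  }
  if (ncol(genotypes) != model$n_snps) {
    stop("genotype row length does not match the model's SNP count",
         call. = FALSE)
  }
  storage.mode(genotypes) <- "double"
  genotypes
}

#' @export
penetrance.mult_block_model <- function(model, genotypes) {
  G <- model_geno_matrix(model, genotypes)
  logS <- numeric(nrow(G))
  for (b in model$blocks) {
    idx <- if (length(b$snps) == 1L) {
      G[, b$snps] + 1
    } else {
      3 * G[, b$snps[1L]] + G[, b$snps[2L]] + 1
    }
    logS <- logS + log(b$mult)[idx]
  }
  f <- model$f0 * exp(logS)
  capped <- sum(f > 1)
  f <- pmin(f, 1)
  attr(f, "capped") <- capped
  f
}

#' @export
penetrance.lplm_model <- function(model, genotypes) {
  G <- model_geno_matrix(model, genotypes)
  L <- drop(G %*% model$weights)
  ifelse(L >= model$threshold, model$p1, model$f0)
}

#' @export
penetrance.recessive_model <- function(model, genotypes) {
  G <- model_geno_matrix(model, genotypes)
  ifelse(rowSums(G == 2) == 3L, model$p_high, model$f0)
}

# ---- prevalence and cap probability -----------------------------------------

#' Exact population prevalence of a penetrance model
#'
#' Computed by exact enumeration: a load-distribution convolution for
#' liability models, closed form for recessive models, and a
#' dynamic-programming convolution of the per-block log-risk lattice for the
#' multiplicative family (the penetrance cap is accounted for).
#'
#' @param model A `pen_model`.
#' @return Scalar prevalence.
#' @export
prevalence <- function(model) {
  UseMethod("prevalence")
}

#' @export
prevalence.lplm_model <- function(model) {
  d <- model$load_dist
  sum(d$prob * ifelse(d$load >= model$threshold, model$p1, model$f0))
}

#' @export
prevalence.recessive_model <- function(model) {
  p_triple <- prod(model$q^2)
  model$f0 + (model$p_high - model$f0) * p_triple
}

#' @export
prevalence.mult_block_model <- function(model) {
  raw <- model$f0 * model$e_mult
  # subtract the exact expectation of the part of f0 * prod(mult) above 1
  dp <- block_log_dp(model, h = 2e-4)
  s <- dp$base + (seq_along(dp$p) - 1)
  f <- model$f0 * exp(s * dp$h)
  raw - sum(dp$p[f > 1] * (f[f > 1] - 1))
}

cap_probability <- function(model) {
  # quick Chernoff screen first; exact DP only when the bound is not decisive
  cval <- -log(model$f0)
  ts <- seq(0.25, 40, by = 0.25)
  logmgf <- vapply(ts, function(t) {
    sum(vapply(model$blocks,
               function(b) log(sum(b$probs * b$mult^t)), 0))
  }, 0)
  bound <- exp(min(logmgf - ts * cval))
  if (bound <= 1e-3) return(bound)
  dp <- block_log_dp(model, h = 2e-4)
  s <- dp$base + (seq_along(dp$p) - 1)
  sum(dp$p[s * dp$h > cval])
}

block_log_dp <- function(model, h = 2e-4) {
  p <- 1
  base <- 0L
  for (b in model$blocks) {
    shifts <- as.integer(round(log(b$mult) / h))
    smin <- min(shifts)
    out <- numeric(length(p) + max(shifts) - smin)
    for (k in seq_along(shifts)) {
      idx <- (shifts[k] - smin) + seq_along(p)
      out[idx] <- out[idx] + b$probs[k] * p
    }
    p <- out
    base <- base + smin
  }
  list(p = p, base = base, h = h)
}

# ---- load distribution and threshold calibration ----------------------------

#' Exact distribution of the weighted risk-allele load
#'
#' Convolves the per-SNP Binomial(2, q) risk-allele-count distributions
#' (scaled by the load weights) into the exact population distribution of
#' the total load.
#'
#' @param q Risk-allele frequency vector.
#' @param weights Optional positive per-SNP weights (default unit).
#' @return A tibble with columns `load` and `prob`, sorted by load.
#' @export
load_distribution <- function(q, weights = NULL) {
  n <- length(q)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights > 0), all(q > 0), all(q < 1))
  vals <- 0
  probs <- 1
  for (i in seq_len(n)) {
    gp <- hwe_probs(q[i])
    nv <- as.vector(outer(vals, weights[i] * (0:2), `+`))
    np <- as.vector(outer(probs, gp, `*`))
    o <- order(nv)
    nv <- nv[o]
    np <- np[o]
    ends <- c(which(diff(nv) > 1e-9), length(nv))
    cs <- cumsum(np)
    probs <- cs[ends] - c(0, cs[head(ends, -1L)])
    vals <- nv[ends]
  }
  tibble::tibble(load = vals, prob = probs)
}

#' Calibrate the liability-threshold of an LPLM
#'
#' Chooses the load threshold `T` whose population upper-tail probability
#' `P(L >= T)` is closest to `target_tail` (about 1.5% by default), using
#' the exact load distribution.  Ties favour the smaller threshold.
#'
#' @inheritParams load_distribution
#' @param target_tail Target upper-tail fraction.
#' @return A list with `threshold`, the achieved `tail`, and the tibble of
#'   `candidates` (threshold, tail).
#' @examples
#' calibrate_lplm_threshold(rep(0.5, 10))$threshold # 15
#' @export
calibrate_lplm_threshold <- function(q, weights = NULL, target_tail = 0.015) {
  d <- load_distribution(q, weights)
  if (nrow(d) < 2L) {
    stop("degenerate load distribution: all loads equal", call. = FALSE)
  }
  cand <- d$load[-1L]
  tail_p <- rev(cumsum(rev(d$prob)))[-1L]
  best <- which.min(abs(tail_p - target_tail))
  list(threshold = cand[best], tail = tail_p[best],
       candidates = tibble::tibble(threshold = cand, tail = tail_p))
}

#' Weight pattern of the modified (weighted) threshold model
#'
#' The first third of the SNP set (rounded up) gets load weight 0.5, the
#' next third weight 1 and the remainder weight 2, in set order.
#'
#' @param n_snps Number of SNPs.
#' @return Numeric weight vector of length `n_snps`.
#' @examples
#' assign_modified_weights(3)            # 0.5 1 2
#' sum(assign_modified_weights(30))      # 35
#' @export
assign_modified_weights <- function(n_snps) {
  k <- ceiling(n_snps / 3)
  rep(c(0.5, 1, 2),
      times = c(k, min(k, n_snps - k), max(0L, n_snps - 2L * k)))
}

# ---- marginal allelic effects ----------------------------------------------

#' Marginal allelic effect of each SNP under a penetrance model
#'
#' Exact enumeration (under Hardy-Weinberg equilibrium and SNP independence)
#' of the disease probability given that a randomly chosen allele copy at
#' the SNP is the risk vs the non-risk allele.  Both the allele-exposure
#' relative risk and the allelic odds ratio are reported; for realistic
#' penetrances they bracket the marginal effect sizes quoted for the
#' recessive scenarios.  For the multiplicative family the penetrance cap is
#' ignored here (its population mass is below 0.1% by construction).
#'
#' @param model A `pen_model`.
#' @return A tibble with one row per SNP: `snp_id`, `p_case_risk`,
#'   `p_case_nonrisk`, `rr`, `or`.
#' @examples
#' marginal_allelic_effect(rez_model("B"))
#' @export
marginal_allelic_effect <- function(model) {
  UseMethod("marginal_allelic_effect")
}

mae_tibble <- function(model, pa, pu) {
  tibble::tibble(
    snp_id = model$snp_ids,
    p_case_risk = pa,
    p_case_nonrisk = pu,
    rr = pa / pu,
    or = (pa / (1 - pa)) / (pu / (1 - pu))
  )
}

#' @export
marginal_allelic_effect.recessive_model <- function(model) {
  q <- model$q
  p_rest <- vapply(1:3, function(i) prod(q[-i]^2), 0)
  pa <- model$f0 + (model$p_high - model$f0) * q * p_rest
  pu <- rep(model$f0, 3L)
  mae_tibble(model, pa, pu)
}

#' @export
marginal_allelic_effect.lplm_model <- function(model) {
  n <- model$n_snps
  pa <- pu <- numeric(n)
  for (i in seq_len(n)) {
    rest <- load_distribution(model$q[-i], model$weights[-i])
    qi <- model$q[i]
    wi <- model$weights[i]
    p_case <- function(allele) {
      # second allele copy at SNP i is Bernoulli(q_i)
      load0 <- rest$load + wi * allele
      load1 <- load0 + wi
      p_hi <- (1 - qi) * sum(rest$prob[load0 >= model$threshold]) +
        qi * sum(rest$prob[load1 >= model$threshold])
      model$f0 + (model$p1 - model$f0) * p_hi
    }
    pa[i] <- p_case(1)
    pu[i] <- p_case(0)
  }
  mae_tibble(model, pa, pu)
}

#' @export
marginal_allelic_effect.mult_block_model <- function(model) {
  block_e <- vapply(model$blocks, function(b) sum(b$probs * b$mult), 0)
  n <- model$n_snps
  pa <- pu <- numeric(n)
  for (i in seq_len(n)) {
    bidx <- which(vapply(model$blocks, function(b) i %in% b$snps, TRUE))
    b <- model$blocks[[bidx]]
    qi <- model$q[i]
    cond_e <- function(allele) {
      if (length(b$snps) == 1L) {
        # genotype = allele + Bernoulli(q_i)
        (1 - qi) * b$mult[allele + 1L] + qi * b$mult[allele + 2L]
      } else {
        pos <- match(i, b$snps)
        other <- b$snps[3L - pos]
        po <- hwe_probs(model$q[other])
        tot <- 0
        for (g_self in allele + 0:1) {
          w_self <- if (g_self == allele) 1 - qi else qi
          for (g_other in 0:2) {
            idx <- if (pos == 1L) 3L * g_self + g_other + 1L
                   else 3L * g_other + g_self + 1L
            tot <- tot + w_self * po[g_other + 1L] * b$mult[idx]
          }
        }
        tot
      }
    }
    rest <- prod(block_e[-bidx])
    pa[i] <- model$f0 * cond_e(1L) * rest
    pu[i] <- model$f0 * cond_e(0L) * rest
  }
  mae_tibble(model, pa, pu)
}
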