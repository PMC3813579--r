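#' Read a risk-allele specification
#'
#' Tab-separated file with columns `snp_id`, `risk_allele` and optionally
#' `weight` (default 1).  The externally designated risk allele per SNP is
#' the anchor of the whole analysis: allele loads must count the outside
#' source's risk alleles, never a data-derived direction.
#'
#' @param path File path.
#' @return A tibble with `snp_id`, `risk_allele`, `weight`.
#' @export
read_risk_spec <- function(path) {
  spec <- readr::read_tsv(path, show_col_types = FALSE,
                          progress = FALSE)
  need <- c("snp_id", "risk_allele")
  miss <- setdiff(need, names(spec))
  if (length(miss)) {
    stop("risk-allele spec lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(spec$snp_id)) {
    stop("risk-allele spec lists SNP(s) more than once", call. = FALSE)
  }
  if (is.null(spec$weight)) spec$weight <- 1
  if (any(!is.finite(spec$weight)) || any(spec$weight <= 0)) {
    stop("risk-allele weights must be positive", call. = FALSE)
  }
  spec[c("snp_id", "risk_allele", "weight")]
}

#' Read a phenotype table
#'
#' Tab-separated file with columns `sample_id` and `status` (0 = control,
#' 1 = case).
#'
#' @param path File path.
#' @return A tibble with `sample_id`, `status`.
#' @export
read_phenotypes <- function(path) {
  ph <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("sample_id", "status"), names(ph))
  if (length(miss)) {
    stop("phenotype file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ph$sample_id)) {
    stop("duplicate sample IDs in phenotype file", call. = FALSE)
  }
  if (!all(ph$status %in% c(0, 1), na.rm = TRUE)) {
    stop("phenotype status must be coded 0/1", call. = FALSE)
  }
  tibble::as_tibble(ph[c("sample_id", "status")])
}

#' Read genotypes and orient them to the designated risk alleles
#'
#' Dispatches on the file extension: `.vcf`/`.vcf.gz` files are parsed with
#' vcfR (GT field preferred, DS dosages used when GT is absent), anything
#' else is read as a dosage TSV whose first column is `sample_id` and whose
#' remaining columns are named `<snp_id>_<counted_allele>` with values in
#' `[0, 2]`.  Counts are then flipped (`2 - x`) wherever the file's counted
#' allele is not the spec's risk allele, so that the returned columns always
#' count risk alleles; per-SNP flip decisions are logged via `message()`.
#'
#' @param source Path to a VCF or dosage TSV file.
#' @param spec Risk-allele specification (see [read_risk_spec()]).
#' @return A tibble with `sample_id` and one risk-oriented count column per
#'   SNP in spec order, with attribute `counted_allele` recording the
#'   (post-orientation) counted allele per SNP.
#' @export
read_genotypes <- function(source, spec) {
  raw <- if (grepl("\\.vcf(\\.gz)?$", source, ignore.case = TRUE)) {
    read_vcf_genotypes(source)
  } else {
    read_dosage(source)
  }
  orient_genotypes(raw, spec)
}

#' @rdname read_genotypes
#' @param path File path.
#' @export
read_dosage <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(d)[1L] != "sample_id") {
    stop("dosage file must have 'sample_id' as its first column",
         call. = FALSE)
  }
  geno_cols <- names(d)[-1L]
  parts <- regmatches(geno_cols, regexpr("_[^_]+$", geno_cols))
  if (length(parts) != length(geno_cols) || any(nchar(parts) < 2L)) {
    stop("dosage columns must be named <snp_id>_<counted_allele>",
         call. = FALSE)
  }
  snp_ids <- sub("_[^_]+$", "", geno_cols)
  counted <- sub("^_", "", parts)
  if (anyDuplicated(snp_ids)) {
    stop("duplicate SNP(s) in dosage file", call. = FALSE)
  }
  vals <- d[geno_cols]
  ok <- vapply(vals, function(v) all(is.na(v) | (v >= 0 & v <= 2)),
               logical(1))
  if (!all(ok)) {
    stop("dosage values outside [0, 2] for SNP(s): ",
         paste(snp_ids[!ok], collapse = ", "), call. = FALSE)
  }
  names(vals) <- snp_ids
  out <- dplyr::bind_cols(tibble::tibble(sample_id = d$sample_id), vals)
  attr(out, "counted_allele") <- setNames(counted, snp_ids)
  attr(out, "other_allele") <- setNames(rep(NA_character_, length(snp_ids)),
                                        snp_ids)
  out
}

#' @rdname read_genotypes
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix   # always a matrix, even for a single record
  snp_ids <- fix[, "ID"]
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | nchar(ref) != 1L | nchar(alt) != 1L
  if (any(multi)) {
    stop("multi-allelic or non-SNP record(s): ",
         paste(snp_ids[multi], collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(snp_ids)) {
    stop("duplicate SNP IDs in VCF", call. = FALSE)
  }
  has_gt <- any(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"]))
  if (has_gt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    counts <- apply(gt, c(1, 2), function(x) {
      if (is.na(x)) return(NA_real_)
      sum(as.integer(strsplit(x, "[/|]")[[1L]]))
    })
  } else {
    ds <- vcfR::extract.gt(v, element = "DS")
    if (all(is.na(ds))) {
      stop("VCF carries neither GT nor DS genotype fields", call. = FALSE)
    }
    counts <- apply(ds, c(1, 2), as.numeric)
  }
  counts <- t(counts) # individuals x SNPs, counting ALT alleles
  colnames(counts) <- snp_ids
  out <- dplyr::bind_cols(tibble::tibble(sample_id = rownames(counts)),
                          tibble::as_tibble(counts))
  attr(out, "counted_allele") <- setNames(alt, snp_ids)
  attr(out, "other_allele") <- setNames(ref, snp_ids)
  out
}

#' @rdname read_genotypes
#' @param data Genotype tibble carrying `counted_allele` (and possibly
#'   `other_allele`) attributes, as returned by [read_dosage()] /
#'   [read_vcf_genotypes()].
#' @export
orient_genotypes <- function(data, spec) {
  counted <- attr(data, "counted_allele")
  other <- attr(data, "other_allele")
  if (is.null(counted)) {
    stop("genotype data carries no counted-allele metadata; read it with ",
         "read_dosage()/read_vcf_genotypes()", call. = FALSE)
  }
  snp_ids <- names(counted)
  missing_spec <- setdiff(snp_ids, spec$snp_id)
  if (length(missing_spec)) {
    stop("SNP(s) absent from risk-allele spec: ",
         paste(missing_spec, collapse = ", "), call. = FALSE)
  }
  risk <- setNames(spec$risk_allele, spec$snp_id)[snp_ids]
  known_other <- !is.na(other)
  bad <- known_other & risk != counted & risk != other
  if (any(bad)) {
    stop("risk allele not among the SNP's two alleles: ",
         paste(snp_ids[bad], collapse = ", "), call. = FALSE)
  }
  flip <- risk != counted
  out <- tibble::as_tibble(data)
  for (s in snp_ids[flip]) out[[s]] <- 2 - out[[s]]
  if (any(flip)) {
    message("flipped ", sum(flip), " SNP(s) to count the designated risk ",
            "allele: ", paste(snp_ids[flip], collapse = ", "))
  }
  new_counted <- ifelse(flip, risk, counted)
  new_other <- ifelse(flip, counted, other)
  attr(out, "counted_allele") <- setNames(new_counted, snp_ids)
  attr(out, "other_allele") <- setNames(new_other, snp_ids)
  out
}

#' Assemble an analysis data set from genotype, phenotype and spec files
#'
#' Inner-joins genotypes and phenotypes on `sample_id` (duplicates are an
#' error; an empty intersection is an error) and returns the joined data
#' together with the spec, ready for [smt_test()].
#'
#' @param geno Path to a VCF or dosage TSV.
#' @param pheno Path to a phenotype TSV.
#' @param spec Path to a risk-allele spec TSV, or a spec tibble.
#' @return A list with `data` (tibble: `sample_id`, `status`, SNP columns)
#'   and `spec`.
#' @export
load_dataset <- function(geno, pheno, spec) {
  if (is.character(spec)) spec <- read_risk_spec(spec)
  g <- read_genotypes(geno, spec)
  ph <- read_phenotypes(pheno)
  if (anyDuplicated(g$sample_id)) {
    stop("duplicate sample IDs in genotype data", call. = FALSE)
  }
  common <- intersect(ph$sample_id, g$sample_id)
  if (length(common) == 0L) {
    stop("no sample IDs shared between genotype and phenotype files",
         call. = FALSE)
  }
  dropped <- (nrow(g) - length(common)) + (nrow(ph) - length(common))
  if (dropped > 0L) {
    message("dropping ", dropped,
            " sample(s) absent from either genotypes or phenotypes")
  }
  data <- dplyr::inner_join(ph, g, by = "sample_id")
  list(data = tibble::as_tibble(data), spec = spec)
}

#' Write analysis results to TSV/JSON files
#'
#' `smt_fit` objects are written as `<prefix>_profile.tsv` (one row per
#' threshold, mirroring the threshold-profile columns) plus
#' `<prefix>_summary.json` (`v`, `best_threshold`, `min_p`, `p_final`,
#' sample counts, package version).  Study tibbles are written as
#' `<prefix>_study.tsv` plus `<prefix>_pvalues.tsv.gz` holding the
#' per-replicate p-values.  Column order is deterministic, so rerunning on
#' identical inputs reproduces the files byte for byte.
#'
#' @param result An `smt_fit` or a study result tibble.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, prefix) {
  if (inherits(result, "smt_fit")) {
    profile_path <- paste0(prefix, "_profile.tsv")
    json_path <- paste0(prefix, "_summary.json")
    readr::write_tsv(tidy(result), profile_path, progress = FALSE)
    summary <- c(as.list(glance(result)),
                 list(package = "supramult",
                      version = as.character(packageVersion("supramult"))))
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(c(profile_path, json_path)))
  }
  if (is.data.frame(result)) {
    study_path <- paste0(prefix, "_study.tsv")
    readr::write_tsv(result, study_path, progress = FALSE)
    paths <- study_path
    pv <- attr(result, "p_values")
    if (!is.null(pv)) {
      pv_path <- paste0(prefix, "_pvalues.tsv.gz")
      readr::write_tsv(pv, pv_path, progress = FALSE)
      paths <- c(paths, pv_path)
    }
    return(invisible(paths))
  }
  stop("unsupported result type", call. = FALSE)
}
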