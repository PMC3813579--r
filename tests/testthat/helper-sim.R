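# Shared fixture builders for the test suite.  Everything is generated in
# code; no binary fixtures.

# Small deterministic case-control tibble with independent SNPs and a given
# per-individual case probability function.
toy_dataset <- function(n = 200, q = c(0.3, 0.5), seed = 1,
                        p_case = function(G) rep(0.5, nrow(G))) {
  set.seed(seed)
  G <- sapply(q, function(qq) rbinom(n, 2, qq))
  colnames(G) <- paste0("s", seq_along(q))
  status <- rbinom(n, 1, p_case(G))
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("id%04d", seq_len(n)),
                   status = status),
    tibble::as_tibble(G)
  )
}

unit_spec <- function(snps, weight = 1) {
  tibble::tibble(snp_id = snps, risk_allele = "A",
                 weight = rep(weight, length.out = length(snps)))
}

# Minimal VCF written to a temp file; counts are ALT dosages.
write_toy_vcf <- function(path, with_gt = TRUE) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", "S4", sep = "\t")
  )
  if (with_gt) {
    rows <- c(
      paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "0/0", "0/1", "1/1", "0/1", sep = "\t"),
      paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
            "0/1", "1/1", "0/0", "0/0", sep = "\t"),
      paste("2", "300", "rs3", "G", "A", ".", "PASS", ".", "GT",
            "1/1", "0/1", "0/1", "0/0", sep = "\t")
    )
  } else {
    rows <- c(
      paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "DS",
            "0", "1", "2", "1", sep = "\t"),
      paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "DS",
            "1", "2", "0", "0", sep = "\t"),
      paste("2", "300", "rs3", "G", "A", ".", "PASS", ".", "DS",
            "2", "1", "1.37", "0", sep = "\t")
    )
  }
  writeLines(c(hdr, rows), path)
  path
}

# Dosage TSV equivalent to the GT VCF above (counted allele = ALT).
write_toy_dosage <- function(path) {
  lines <- c(
    paste("sample_id", "rs1_G", "rs2_T", "rs3_A", sep = "\t"),
    paste("S1", 0, 1, 2, sep = "\t"),
    paste("S2", 1, 2, 1, sep = "\t"),
    paste("S3", 2, 0, 1, sep = "\t"),
    paste("S4", 1, 0, 0, sep = "\t")
  )
  writeLines(lines, path)
  path
}

toy_risk_spec <- function() {
  # rs1: risk = ALT (no flip); rs2: risk = REF (flip); rs3: risk = ALT
  tibble::tibble(snp_id = c("rs1", "rs2", "rs3"),
                 risk_allele = c("G", "C", "A"),
                 weight = c(1, 1, 1))
}
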