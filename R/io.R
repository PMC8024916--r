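#' Read a phased haplotype panel from TSV
#'
#' Expects columns `sample`, `hap1`, `hap2` and optionally `population`
#' (residue-string haplotypes in canonical site order).
#'
#' @param path TSV file path.
#' @return Phased panel tibble.
#' @export
read_phased_tsv <- function(path) {
  if (!file.exists(path)) abort(paste("input file not found:", path))
  panel <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
  need <- c("sample", "hap1", "hap2")
  if (!all(need %in% names(panel))) {
    abort(paste("phased TSV must have columns:", paste(need, collapse = ", ")))
  }
  panel
}

#' Read a phased VCF into a haplotype panel
#'
#' Extracts phased GT fields (separator `|`; unphased `/` records are
#' rejected) for the sites listed in the annotation table, maps allele 0/1
#' to residues through the annotation's `allele0_residue`/`allele1_residue`
#' columns, and assembles per-chromosome residue strings in ascending
#' position order (the canonical site order). Sites are matched by ID
#' (rsid) when present, else by position.
#'
#' @param path VCF file path (plain text or gzipped).
#' @param annotation Site annotation tibble as from [site_annotation()].
#' @return Phased panel tibble: `sample`, `hap1`, `hap2`.
#' @export
read_phased_vcf <- function(path, annotation = site_annotation("ERAP1")) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("package 'vcfR' is required for VCF ingestion")
  }
  if (!file.exists(path)) abort(paste("input file not found:", path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")

  key <- if (all(annotation$rsid %in% fix$ID)) {
    match(annotation$rsid, fix$ID)
  } else {
    match(as.character(annotation$position), fix$POS)
  }
  if (anyNA(key)) abort("VCF is missing sites listed in the annotation")
  gt <- gt[key, , drop = FALSE]

  if (any(grepl("/", gt, fixed = TRUE))) {
    abort("VCF contains unphased genotypes ('/'); phased input required")
  }
  alleles <- str_split(gt, stringr::fixed("|"), simplify = FALSE)
  a1 <- matrix(map_chr(alleles, 1), nrow = nrow(gt))
  a2 <- matrix(map_chr(alleles, 2), nrow = nrow(gt))
  to_res <- function(a) {
    m <- matrix(NA_character_, nrow(a), ncol(a))
    m[a == "0"] <- rep(annotation$allele0_residue, ncol(a))[a == "0"]
    m[a == "1"] <- rep(annotation$allele1_residue, ncol(a))[a == "1"]
    if (anyNA(m)) abort("GT allele other than 0/1 encountered")
    apply(m, 2, paste, collapse = "")
  }
  tibble(sample = colnames(gt), hap1 = to_res(a1), hap2 = to_res(a2))
}

#' Write a frequency table with one-decimal display rounding
#'
#' Report writers are the only place display rounding happens; all internal
#' arithmetic stays at full precision.
#'
#' @param x Tibble containing `freq_pct` and/or `pct_*` columns.
#' @param path Output TSV path.
#' @return `x`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  x |>
    mutate(across(matches("^(freq_pct|pct_)"), ~ round(.x, 1))) |>
    readr::write_tsv(path)
  invisible(x)
}

#' Convert concentrations to molar
#' @param x Values.
#' @param unit One of `"M"`, `"mM"`, `"uM"`, `"nM"`.
#' @return Values in molar.
#' @export
to_molar <- function(x, unit = c("M", "mM", "uM", "nM")) {
  unit <- match.arg(unit)
  x * c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)[[unit]]
}

#' Convert times to seconds
#' @param x Values.
#' @param unit One of `"s"`, `"min"`, `"h"`.
#' @return Values in seconds.
#' @export
to_seconds <- function(x, unit = c("s", "min", "h")) {
  unit <- match.arg(unit)
  x * c(s = 1, min = 60, h = 3600)[[unit]]
}
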