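#' Polymorphic-site annotation for ERAP1 and ERAP2
#'
#' Returns the shipped site annotation table: the coding positions that are
#' polymorphic at the population level, the field-standard SNP identifiers,
#' and the residue (or nucleotide, for the intronic ERAP2 splice site)
#' attached to each of the two alleles. The allele0/allele1 orientation is
#' the one used by the package's phased-VCF reader and synthetic generators.
#'
#' @param gene `"ERAP1"` or `"ERAP2"`.
#' @return A tibble with columns `gene`, `position`, `rsid`,
#'   `allele0_residue`, `allele1_residue`.
#' @examples
#' site_annotation("ERAP1")
#' @export
site_annotation <- function(gene = c("ERAP1", "ERAP2")) {
  gene <- match.arg(gene)
  f <- if (gene == "ERAP1") "erap1_sites.tsv" else "erap2_sites.tsv"
  readr::read_tsv(ext_file(f), show_col_types = FALSE,
                  col_types = readr::cols(position = "i", .default = "c"))
}

#' Filter candidate positions down to a polymorphic site set
#'
#' Applies the population-frequency cutoff used to qualify a coding missense
#' variant as a polymorphism (default 1%) and drops explicitly excluded
#' positions such as signal-peptide residues that do not appear in the
#' mature protein.
#'
#' @param allele_freqs Data frame with columns `position` and `frequency`
#'   (minor-allele frequency as a fraction in \[0, 1\]); additional columns
#'   (e.g. allele annotations) are carried through.
#' @param cutoff Minimum minor-allele frequency, as a fraction. Default 0.01.
#' @param excluded_positions Integer vector of positions to drop regardless
#'   of frequency (default: none).
#' @return The retained rows, original order preserved, as a tibble.
#' @examples
#' freqs <- tibble::tibble(position = c(12, 56, 528), frequency = c(0.05, 0.03, 0.3))
#' filter_polymorphic_sites(freqs, cutoff = 0.01, excluded_positions = 12)
#' @export
filter_polymorphic_sites <- function(allele_freqs, cutoff = 0.01,
                                     excluded_positions = integer()) {
  stopifnot(is.data.frame(allele_freqs),
            all(c("position", "frequency") %in% names(allele_freqs)))
  if (any(allele_freqs$frequency < 0 | allele_freqs$frequency > 1)) {
    abort("frequencies must lie in [0, 1]")
  }
  out <- allele_freqs |>
    filter(.data$frequency >= cutoff,
           !.data$position %in% excluded_positions) |>
    as_tibble()
  if (nrow(out) == 0L) abort("no polymorphic sites")
  out
}

site_alphabets <- function(catalog) {
  haps <- str_split(catalog$haplotype, "")
  n <- length(haps[[1]])
  lapply(seq_len(n), function(i) unique(map_chr(haps, i)))
}
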