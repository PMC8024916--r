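#' Call ERAP2 allotypes and expression-null status
#'
#' ERAP2 haplotypes over the two sites (rs2549782, rs2248374) are labelled
#' `A` for \[G, A\] and `B` for \[T, G\]; any other combination (essentially
#' absent from real panels) is labelled `"other"`. The rs2248374 G allele
#' abolishes ERAP2 protein expression, so a sample is flagged
#' `expression_null` when both of its haplotypes carry G at that site.
#'
#' @param panel Tibble with columns `sample`, `hap1`, `hap2`; haplotypes are
#'   two-character nucleotide strings in site order (rs2549782, rs2248374),
#'   e.g. `"GA"` or `"TG"`.
#' @return Tibble with columns `sample`, `hap1_label`, `hap2_label`,
#'   `erap2_class` (unordered, e.g. `"A/B"`), `expression_null`.
#' @examples
#' call_erap2(tibble::tibble(sample = "s1", hap1 = "GA", hap2 = "TG"))
#' @export
call_erap2 <- function(panel) {
  check_panel(panel)
  ok <- grepl("^[GT][AG]$", panel$hap1) & grepl("^[GT][AG]$", panel$hap2)
  if (!all(ok)) {
    abort("ERAP2 haplotypes must be two characters over {G,T} x {A,G}")
  }
  lab <- function(h) dplyr::case_match(h, "GA" ~ "A", "TG" ~ "B",
                                       .default = "other")
  l1 <- lab(panel$hap1)
  l2 <- lab(panel$hap2)
  tibble(
    sample = panel$sample,
    hap1_label = l1,
    hap2_label = l2,
    erap2_class = paste(pmin(l1, l2), pmax(l1, l2), sep = "/"),
    expression_null = str_sub(panel$hap1, 2, 2) == "G" &
      str_sub(panel$hap2, 2, 2) == "G"
  )
}

#' Summarise ERAP2 calls
#'
#' Chromosome-level allotype frequencies and the fraction of samples with
#' no expected ERAP2 protein expression.
#'
#' @param calls Output of [call_erap2()].
#' @return List with `haplotype_freq` (tibble: `label`, `n_chrom`,
#'   `freq_pct`) and `null_fraction` (fraction of samples).
#' @export
erap2_frequencies <- function(calls) {
  hf <- tibble(label = c(calls$hap1_label, calls$hap2_label)) |>
    count(.data$label, name = "n_chrom") |>
    mutate(freq_pct = 100 * .data$n_chrom / sum(.data$n_chrom))
  list(haplotype_freq = hf, null_fraction = mean(calls$expression_null))
}
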