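#' Shipped catalog of common ERAP1 allotypes
#'
#' The 16 ERAP1 allotypes that reach appreciable population frequency,
#' each defined by its residues at the nine canonical polymorphic positions
#' (56, 127, 276, 346, 349, 528, 575, 725, 730) on one chromosome.
#' Haplotype strings not present in the catalog are labelled
#' `"unassigned"` by [classify_haplotype()].
#'
#' @return A tibble with columns `allotype` (character label `"1"`..`"16"`)
#'   and `haplotype` (9-residue string in canonical position order).
#' @examples
#' allotype_catalog()
#' @export
allotype_catalog <- function() {
  tab <- readr::read_tsv(ext_file("erap1_allotypes.tsv"),
                         show_col_types = FALSE,
                         col_types = readr::cols(allotype = "c",
                                                 haplotype = "c",
                                                 .default = "d"))
  out <- tab |> select("allotype", "haplotype")
  stopifnot(!anyDuplicated(out$haplotype), !anyDuplicated(out$allotype))
  out
}

#' Published population frequencies of the common ERAP1 allotypes
#'
#' Per-population frequencies (percent of chromosomes) of the 16 shipped
#' allotypes across the five continental population groups of a 2504-sample
#' phased reference panel, plus the pooled `ALL` column.
#'
#' @param long If `TRUE` (default) return one row per allotype x population;
#'   otherwise the wide table as shipped.
#' @return A tibble; long format has columns `allotype`, `haplotype`,
#'   `population`, `freq_pct`.
#' @export
table1_frequencies <- function(long = TRUE) {
  tab <- readr::read_tsv(ext_file("erap1_allotypes.tsv"),
                         show_col_types = FALSE,
                         col_types = readr::cols(allotype = "c",
                                                 haplotype = "c",
                                                 .default = "d"))
  if (!long) return(tab)
  tab |>
    pivot_longer(-c("allotype", "haplotype"),
                 names_to = "population", values_to = "freq_pct")
}

#' Classify phased haplotype strings into allotype labels
#'
#' Looks each residue string up in an allotype catalog; strings absent from
#' the catalog get the label `"unassigned"`. Strings whose length does not
#' match the catalog, or that carry a residue never seen at that position in
#' the catalog, are rejected.
#'
#' @param h Character vector of haplotype residue strings, canonical
#'   position order.
#' @param catalog Allotype catalog tibble (columns `allotype`, `haplotype`),
#'   default [allotype_catalog()].
#' @return Character vector of allotype labels, same length as `h`.
#' @examples
#' classify_haplotype(c("ERIGMKDRQ", "EPIGVRNQE"))
#' @export
classify_haplotype <- function(h, catalog = allotype_catalog()) {
  width <- nchar(catalog$haplotype[1])
  if (any(nchar(h) != width)) {
    abort(sprintf("haplotype length must be %d to match the catalog", width))
  }
  alph <- site_alphabets(catalog)
  chars <- str_split(h, "")
  ok <- vapply(chars, function(cc) all(mapply(`%in%`, cc, alph)), logical(1))
  if (!all(ok)) {
    abort(sprintf("residue outside site alphabet in haplotype(s): %s",
                  paste(unique(h[!ok]), collapse = ", ")))
  }
  lab <- catalog$allotype[match(h, catalog$haplotype)]
  lab[is.na(lab)] <- UNASSIGNED
  lab
}
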