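allotype_levels <- function(labels) {
  labs <- unique(labels)
  nums <- suppressWarnings(as.numeric(labs))
  labs[order(is.na(nums), nums, labs)]
}

check_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("sample", "hap1", "hap2") %in% names(panel)))
  if (nrow(panel) == 0L) abort("panel is empty")
  invisible(panel)
}

#' Allotype frequencies of a phased panel
#'
#' Counts chromosomes per allotype within each population and overall
#' (`ALL`), converting to percent of chromosomes. Optional label groups add
#' subtotal rows (e.g. the common allotypes 1-10 versus the rarer 11-16).
#' Frequencies are kept at full precision; round to one decimal for display.
#'
#' @param panel Phased panel tibble with columns `sample`, `hap1`, `hap2`
#'   and optionally `population`.
#' @param catalog Allotype catalog, default [allotype_catalog()].
#' @param groups Named list of allotype-label vectors for subtotal rows;
#'   `NULL` for none. Default: groups `1-10` and `11-16`.
#' @return Tibble with columns `allotype`, `population`, `n_chrom`,
#'   `freq_pct`, `is_subtotal`.
#' @examples
#' panel <- tibble::tibble(sample = "s1", population = "EUR",
#'                         hap1 = "ERIGMKDRQ", hap2 = "EPMGMRDRE")
#' allotype_frequencies(panel)
#' @export
allotype_frequencies <- function(panel, catalog = allotype_catalog(),
                                 groups = list(`1-10` = as.character(1:10),
                                               `11-16` = as.character(11:16))) {
  check_panel(panel)
  if (!"population" %in% names(panel)) panel$population <- "ALL"

  chrom <- tibble(
    population = rep(panel$population, 2L),
    allotype = classify_haplotype(c(panel$hap1, panel$hap2), catalog)
  )
  chrom_all <- bind_rows(chrom, chrom |> mutate(population = "ALL"))
  if (all(panel$population == "ALL")) chrom_all <- chrom

  counts <- chrom_all |>
    count(.data$population, .data$allotype, name = "n_chrom") |>
    group_by(.data$population) |>
    mutate(freq_pct = 100 * .data$n_chrom / sum(.data$n_chrom)) |>
    ungroup() |>
    mutate(is_subtotal = FALSE)

  if (!is.null(groups)) {
    subs <- purrr::imap(groups, function(labs, nm) {
      counts |>
        filter(.data$allotype %in% labs) |>
        group_by(.data$population) |>
        summarise(n_chrom = sum(.data$n_chrom),
                  freq_pct = sum(.data$freq_pct), .groups = "drop") |>
        mutate(allotype = paste0("subtotal:", nm), is_subtotal = TRUE)
    }) |> list_rbind()
    counts <- bind_rows(counts, subs)
  }

  lev <- allotype_levels(counts$allotype[!counts$is_subtotal])
  counts |>
    arrange(.data$population, .data$is_subtotal,
            match(.data$allotype, lev)) |>
    select("allotype", "population", "n_chrom", "freq_pct", "is_subtotal")
}

sort_pair <- function(a, b) {
  lev <- allotype_levels(c(a, b))
  swap <- match(a, lev) > match(b, lev)
  tibble(allotype_a = ifelse(swap, b, a), allotype_b = ifelse(swap, a, b))
}

#' Diplotype (allotype-combination) table of a phased panel
#'
#' Tabulates the unordered pair of allotypes each sample carries on its two
#' chromosomes. Pair keys are sorted so that (8, 2) and (2, 8) count under
#' the same key; frequencies are percent of samples.
#'
#' @inheritParams allotype_frequencies
#' @return Tibble with columns `allotype_a`, `allotype_b`, `n`, `freq_pct`.
#' @export
diplotype_table <- function(panel, catalog = allotype_catalog()) {
  check_panel(panel)
  pairs <- sort_pair(classify_haplotype(panel$hap1, catalog),
                     classify_haplotype(panel$hap2, catalog))
  pairs |>
    count(.data$allotype_a, .data$allotype_b, name = "n") |>
    mutate(freq_pct = 100 * .data$n / sum(.data$n)) |>
    arrange(desc(.data$n))
}

#' Expected co-occurrence frequency of two allotypes in one individual
#'
#' Under random pairing of chromosomes the expected frequency of an
#' unordered allotype pair is `2*p*q` for distinct allotypes and `p^2` for a
#' homozygous pair (`mode = "hwe"`, the default). `mode = "product"` returns
#' the plain product `p*q`, the arithmetic sometimes quoted for a "random
#' distribution" expectation; note that for distinct allotypes it is half
#' the Hardy-Weinberg value.
#'
#' @param p,q Haplotype frequencies as fractions in \[0, 1\].
#' @param mode `"hwe"` or `"product"`.
#' @param identical Logical; are p and q the same allotype? Only used in
#'   `"hwe"` mode. Default `FALSE`.
#' @return Expected pair frequency as a fraction.
#' @examples
#' expected_cooccurrence(0.256, 0.218, mode = "product") # 0.0558
#' expected_cooccurrence(0.256, 0.218)                   # 2pq = 0.1116
#' @export
expected_cooccurrence <- function(p, q, mode = c("hwe", "product"),
                                  identical = FALSE) {
  mode <- match.arg(mode)
  stopifnot(p >= 0, p <= 1, q >= 0, q <= 1)
  if (mode == "product") return(p * q)
  if (identical) p^2 else 2 * p * q
}

as_freq_vector <- function(freqs) {
  if (is.data.frame(freqs)) {
    val_col <- intersect(c("freq", "freq_pct"), names(freqs))[1]
    if (is.na(val_col)) abort("freqs needs a 'freq' or 'freq_pct' column")
    v <- setNames(freqs[[val_col]], freqs$allotype)
    if (val_col == "freq_pct") v <- v / 100
  } else {
    v <- freqs
  }
  if (is.null(names(v))) abort("freqs must be named by allotype")
  v / sum(v)
}

#' Simulate random pairing of haplotypes into diplotypes
#'
#' Draws `2 * n_samples` haplotypes i.i.d. from the given allotype frequency
#' vector, pairs consecutive draws into individuals, and tabulates the
#' unordered allotype pairs. Used to compare observed diplotype frequencies
#' against the random-pairing (Hardy-Weinberg) expectation.
#'
#' @param freqs Named numeric vector of allotype frequencies (fractions or
#'   percents; normalised internally), or a tibble with columns `allotype`
#'   and `freq`/`freq_pct`.
#' @param n_samples Number of individuals to simulate.
#' @param seed Integer seed; the simulation is reproducible given the seed.
#' @return Diplotype tibble as from [diplotype_table()].
#' @export
random_pairing_simulation <- function(freqs, n_samples, seed) {
  v <- as_freq_vector(freqs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  draws <- sample(names(v), 2L * n_samples, replace = TRUE, prob = v)
  h1 <- draws[seq_len(n_samples) * 2L - 1L]
  h2 <- draws[seq_len(n_samples) * 2L]
  sort_pair(h1, h2) |>
    count(.data$allotype_a, .data$allotype_b, name = "n") |>
    mutate(freq_pct = 100 * .data$n / sum(.data$n)) |>
    arrange(desc(.data$n))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Conditional distribution of ERAP1 diplotypes within ERAP2 classes
#'
#' For each group of individuals carrying a particular ERAP2 diplotype
#' class, computes the percentage distribution of ERAP1 allotype
#' combinations, next to the marginal (whole-population) percentages.
#'
#' @param erap1 Tibble with columns `sample`, `allotype_a`, `allotype_b`
#'   (per-sample unordered ERAP1 pair; see [diplotype_table()] keys).
#' @param erap2 Tibble with columns `sample` and `erap2_class` (e.g.
#'   `"A/A"`, `"A/B"`, `"B/B"`).
#' @return Tibble with columns `erap2_class`, `allotype_a`, `allotype_b`,
#'   `n`, `pct_within_class`, `pct_overall`.
#' @export
cross_tabulate <- function(erap1, erap2) {
  stopifnot(all(c("sample", "allotype_a", "allotype_b") %in% names(erap1)),
            all(c("sample", "erap2_class") %in% names(erap2)))
  if (!setequal(erap1$sample, erap2$sample) ||
      nrow(erap1) != nrow(erap2)) {
    abort("erap1 and erap2 must cover the same samples")
  }
  joined <- inner_join(erap1, erap2, by = "sample") |>
    mutate(sort_pair(.data$allotype_a, .data$allotype_b))

  marginal <- joined |>
    count(.data$allotype_a, .data$allotype_b, name = "n_all") |>
    mutate(pct_overall = 100 * .data$n_all / sum(.data$n_all))

  joined |>
    count(.data$erap2_class, .data$allotype_a, .data$allotype_b, name = "n") |>
    group_by(.data$erap2_class) |>
    mutate(pct_within_class = 100 * .data$n / sum(.data$n)) |>
    ungroup() |>
    left_join(select(marginal, -"n_all"),
              by = c("allotype_a", "allotype_b")) |>
    arrange(.data$erap2_class, desc(.data$n))
}
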