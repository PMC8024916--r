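largest_remainder <- function(x, total) {
  stopifnot(all(x >= 0), total >= 0)
  scaled <- x / sum(x) * total
  base <- floor(scaled)
  short <- total - sum(base)
  if (short > 0) {
    add <- order(scaled - base, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Specification for a synthetic phased panel
#'
#' Describes one population's worth of phased two-haplotype samples, either
#' by haplotype frequencies (converted to exact chromosome counts by
#' largest-remainder rounding, or sampled i.i.d.) or by exact counts, with
#' an optional joint diplotype distribution for non-random pairing.
#'
#' @param freqs Named vector (haplotype string -> frequency) or tibble with
#'   columns `allotype`/`haplotype` and `freq`/`freq_pct`. Ignored when
#'   `counts` is given.
#' @param n_samples Number of diploid samples.
#' @param counts Optional named integer vector of chromosome counts per
#'   haplotype; must total `2 * n_samples`.
#' @param population Population label attached to every sample.
#' @param mode `"exact"` (largest-remainder counts, default) or `"sample"`
#'   (i.i.d. draws).
#' @param joint Optional tibble (`hap1`, `hap2`, `n`) prescribing how
#'   chromosomes pair into samples; `n` must total `n_samples` and the
#'   implied haplotype counts must match the marginal counts.
#' @param seed Integer seed for pairing / sampling.
#' @return List of class `panel_spec`.
#' @export
panel_spec <- function(freqs = NULL, n_samples, counts = NULL,
                       population = "ALL", mode = c("exact", "sample"),
                       joint = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(freqs) && is.null(counts)) abort("give freqs or counts")
  structure(list(freqs = freqs, counts = counts, n_samples = n_samples,
                 population = population, mode = mode, joint = joint,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

freqs_to_named <- function(freqs) {
  if (is.data.frame(freqs)) {
    key <- intersect(c("haplotype", "allotype"), names(freqs))[1]
    val <- intersect(c("freq", "freq_pct"), names(freqs))[1]
    if (is.na(key) || is.na(val)) abort("freqs tibble needs haplotype/allotype and freq/freq_pct columns")
    v <- setNames(freqs[[val]], freqs[[key]])
    if (val == "freq_pct") v <- v / 100
    v
  } else {
    if (is.null(names(freqs))) abort("freqs must be named")
    freqs
  }
}

#' Generate a synthetic phased panel
#'
#' In exact-count mode, assigns each haplotype `round`-free largest-remainder
#' counts totalling exactly `2 * n_samples` chromosomes, then pairs
#' chromosomes into samples: at random (seeded) or following the spec's
#' joint diplotype distribution. In sampling mode chromosomes are drawn
#' i.i.d. from the frequency vector. Output is byte-identical for a fixed
#' spec and seed.
#'
#' @param spec A [panel_spec()].
#' @return Phased panel tibble: `sample`, `population`, `hap1`, `hap2`.
#' @export
gen_phased_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  n2 <- 2L * spec$n_samples
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)

  if (!is.null(spec$counts)) {
    counts <- spec$counts
    if (sum(counts) != n2) abort("counts must total 2 * n_samples")
  } else {
    v <- freqs_to_named(spec$freqs)
    if (spec$mode == "sample") {
      draws <- sample(names(v), n2, replace = TRUE, prob = v / sum(v))
      counts <- table(draws)
      counts <- setNames(as.integer(counts), names(counts))
    } else {
      counts <- setNames(largest_remainder(v, n2), names(v))
    }
  }

  if (!is.null(spec$joint)) {
    j <- spec$joint
    stopifnot(all(c("hap1", "hap2", "n") %in% names(j)))
    if (sum(j$n) != spec$n_samples) abort("joint counts must total n_samples")
    implied <- table(c(rep(j$hap1, j$n), rep(j$hap2, j$n)))
    tol <- max(2L, round(0.005 * n2))
    for (h in union(names(counts), names(implied))) {
      a <- if (h %in% names(counts)) counts[[h]] else 0L
      b <- if (h %in% names(implied)) implied[[h]] else 0L
      if (abs(a - b) > tol) {
        abort(sprintf("joint distribution inconsistent with marginals for haplotype %s (%d vs %d)",
                      h, b, a))
      }
    }
    hap1 <- rep(j$hap1, j$n)
    hap2 <- rep(j$hap2, j$n)
    ord <- sample.int(length(hap1))
    hap1 <- hap1[ord]; hap2 <- hap2[ord]
  } else {
    pool <- rep(names(counts), counts)
    pool <- sample(pool)
    hap1 <- pool[seq_len(spec$n_samples) * 2L - 1L]
    hap2 <- pool[seq_len(spec$n_samples) * 2L]
  }

  tibble(sample = sprintf("S%05d", seq_len(spec$n_samples)),
         population = spec$population,
         hap1 = hap1, hap2 = hap2)
}

POP_SIZES <- c(ALL = 2504L, AFR = 661L, AMR = 347L, EAS = 504L,
               EUR = 503L, SAS = 489L)

#' Fixture panel reconstructed from the shipped allotype frequency table
#'
#' Builds an exact-count phased panel whose chromosome counts reproduce the
#' shipped per-population allotype frequencies. For the pooled `ALL` panel
#' (2504 samples, 5008 chromosomes) the counts are
#' `round(freq_pct / 100 * 5008)` per catalog haplotype, with the remaining
#' chromosomes filled by an off-catalog haplotype so they classify as
#' `"unassigned"`; per-population panels use largest-remainder counts at
#' that population's frequencies and sample size.
#'
#' @param population One of `"ALL"`, `"AFR"`, `"AMR"`, `"EAS"`, `"EUR"`,
#'   `"SAS"`.
#' @param seed Pairing seed.
#' @param pad_haplotype Off-catalog haplotype used for the unassigned
#'   remainder of the `ALL` panel.
#' @return Phased panel tibble.
#' @export
table1_panel <- function(population = "ALL", seed = 1L,
                         pad_haplotype = "EPIGMKDRE") {
  population <- match.arg(population, names(POP_SIZES))
  tab <- table1_frequencies(long = FALSE)
  n <- POP_SIZES[[population]]
  n2 <- 2L * n
  pct <- setNames(tab[[population]], tab$haplotype)
  if (population == "ALL") {
    counts <- round(pct / 100 * n2)
    pad <- n2 - sum(counts)
    stopifnot(pad >= 0)
    counts <- c(counts, setNames(pad, pad_haplotype))
  } else {
    pct <- pct[pct > 0]
    counts <- setNames(largest_remainder(pct, n2), names(pct))
  }
  counts <- counts[counts > 0]
  gen_phased_panel(panel_spec(counts = setNames(as.integer(counts),
                                                names(counts)),
                              n_samples = n, population = population,
                              seed = seed))
}

#' Fixture ERAP2 panel at the observed haplotype split
#'
#' Exact-count two-haplotype ERAP2 panel: `round(a_pct/100 * 2n)`
#' chromosomes carry the expressed \[G, A\] haplotype (allotype A) and the
#' remainder the expression-null \[T, G\] haplotype (allotype B), paired at
#' random.
#'
#' @param n_samples Number of samples (default 2504).
#' @param a_pct Percent of chromosomes carrying allotype A (default 44.7).
#' @param seed Pairing seed.
#' @return Phased panel tibble with two-site nucleotide haplotypes.
#' @export
erap2_panel <- function(n_samples = 2504L, a_pct = 44.7, seed = 1L) {
  n2 <- 2L * n_samples
  n_a <- as.integer(round(a_pct / 100 * n2))
  gen_phased_panel(panel_spec(
    counts = c(GA = n_a, TG = n2 - n_a),
    n_samples = n_samples, population = "ALL", seed = seed))
}
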