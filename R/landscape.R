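#' Expected total activity of an allotype pair
#'
#' Assuming no interaction between the two alleles and equal expression,
#' the expected total enzymatic activity of an individual is the sum of the
#' catalytic efficiencies of the two allotypes carried.
#'
#' @param pair Character vector of length 2 (allotype labels).
#' @param profile Activity profile tibble (`allotype`, `substrate`, value
#'   column).
#' @param substrate Substrate label.
#' @param value Value column name (default `"efficiency"`).
#' @return Summed activity (same units as the profile values).
#' @export
diplotype_activity <- function(pair, profile, substrate,
                               value = "efficiency") {
  stopifnot(length(pair) == 2L)
  sub <- profile |>
    filter(.data$substrate == !!substrate, !is.na(.data[[value]]))
  missing <- setdiff(pair, sub$allotype)
  if (length(missing)) {
    abort(paste("no activity value for allotype(s):",
                paste(unique(missing), collapse = ", ")))
  }
  sum(sub[[value]][match(pair, sub$allotype)])
}

#' Genotype-activity landscape table
#'
#' Joins a diplotype frequency table with a per-allotype activity profile:
#' each allotype combination gets its population frequency and its expected
#' total activity (sum of the two allelic efficiencies, equal-expression
#' assumption), ranked from most to least active. Pairs involving an
#' allotype absent from the profile are dropped with a message.
#'
#' @param diplo Diplotype tibble (`allotype_a`, `allotype_b`, `freq_pct`),
#'   as from [diplotype_table()].
#' @param profile Activity profile tibble.
#' @param substrate Substrate label (the 9mer epitope profile in the
#'   default generators).
#' @param value Value column name (default `"efficiency"`).
#' @return Tibble: `allotype_a`, `allotype_b`, `freq_pct`, `activity`,
#'   `rank` (1 = highest activity), with attribute `spread`
#'   (max/min activity over retained pairs).
#' @export
landscape_table <- function(diplo, profile, substrate,
                            value = "efficiency") {
  stopifnot(all(c("allotype_a", "allotype_b", "freq_pct") %in% names(diplo)))
  sub <- profile |>
    filter(.data$substrate == !!substrate, !is.na(.data[[value]]))
  keep <- diplo$allotype_a %in% sub$allotype &
    diplo$allotype_b %in% sub$allotype
  if (!any(keep)) abort("no diplotype is covered by the activity profile")
  if (any(!keep)) {
    inform(sprintf("landscape_table: dropping %d pair(s) not covered by the profile",
                   sum(!keep)))
  }
  val <- setNames(sub[[value]], sub$allotype)
  out <- diplo[keep, ] |>
    mutate(activity = val[.data$allotype_a] + val[.data$allotype_b]) |>
    arrange(desc(.data$activity)) |>
    mutate(rank = row_number())
  attr(out, "spread") <- max(out$activity) / min(out$activity)
  out
}
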