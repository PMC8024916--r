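#' The ovalbumin sequential-trimming species vocabulary
#'
#' The seven peptide species tracked in the sequential digestion of the
#' 14mer ovalbumin epitope precursor down to the mature 8mer epitope
#' (one N-terminal residue removed per cleavage step).
#'
#' @return Tibble with columns `species`, `length`, `sequence`, ordered
#'   longest (precursor) to shortest (terminal product).
#' @export
ovalbumin_species <- function() {
  readr::read_tsv(ext_file("ovalbumin_species.tsv"), show_col_types = FALSE,
                  col_types = "cic")
}

species_order <- function(series) {
  sp <- unique(series$species)
  len <- suppressWarnings(as.integer(sub("mer$", "", sp)))
  if (anyNA(len)) sp else sp[order(-len)]
}

#' Quantify trimming species from internal-standard-normalised signals
#'
#' Divides each species' mass-spectrometric signal by the co-measured
#' internal-standard signal at the same time point, then converts the
#' normalised value to concentration through that species' calibration
#' curve.
#'
#' @param raw Tibble with columns `time`, `species`, `signal`, `is_signal`.
#' @param curves Either a single `standard_curve` applied to all species or
#'   a named list of curves, one per species.
#' @return Trimming series tibble: `time`, `species`, `conc`.
#' @export
quantify_species <- function(raw, curves) {
  stopifnot(is.data.frame(raw),
            all(c("time", "species", "signal", "is_signal") %in% names(raw)))
  bad <- raw$is_signal <= 0
  if (any(bad)) {
    abort(sprintf("internal-standard signal <= 0 at time point(s): %s",
                  paste(unique(raw$time[bad]), collapse = ", ")))
  }
  curve_for <- function(sp) {
    if (inherits(curves, "standard_curve")) return(curves)
    cv <- curves[[sp]]
    if (is.null(cv)) abort(paste("no calibration curve for species", sp))
    cv
  }
  raw |>
    mutate(norm = .data$signal / .data$is_signal) |>
    group_by(.data$species) |>
    mutate(conc = invert_curve(curve_for(.data$species[1]), .data$norm)) |>
    ungroup() |>
    select("time", "species", "conc")
}

#' Fraction-of-total trajectories of a trimming series
#'
#' At each time point, expresses each species' concentration as a fraction
#' of the total peptide present, the quantity displayed in
#' intermediate-accumulation heat maps.
#'
#' @param series Trimming series tibble (`time`, `species`, `conc`).
#' @return The series with an added `fraction` column.
#' @export
fraction_of_total <- function(series) {
  stopifnot(all(c("time", "species", "conc") %in% names(series)))
  out <- series |>
    group_by(.data$time) |>
    mutate(total = sum(.data$conc)) |>
    ungroup()
  if (any(out$total <= 0)) {
    abort(sprintf("total peptide is zero at time point(s): %s",
                  paste(unique(out$time[out$total <= 0]), collapse = ", ")))
  }
  out |>
    mutate(fraction = .data$conc / .data$total) |>
    select(-"total")
}

#' Maximal accumulation of each trimming intermediate
#'
#' Per-species maximum over the sampled time grid (no interpolation), in
#' both concentration and fraction-of-total units, with the times at which
#' the maxima occur.
#'
#' @param series Trimming series tibble (`time`, `species`, `conc`).
#' @return Tibble: `species`, `max_conc`, `t_max_conc`, `max_fraction`,
#'   `t_max_fraction`.
#' @export
max_accumulation <- function(series) {
  if (length(unique(series$time)) < 2L) abort("need >= 2 time points")
  frac <- fraction_of_total(series)
  frac |>
    group_by(.data$species) |>
    summarise(max_conc = max(.data$conc),
              t_max_conc = .data$time[which.max(.data$conc)],
              max_fraction = max(.data$fraction),
              t_max_fraction = .data$time[which.max(.data$fraction)],
              .groups = "drop") |>
    arrange(match(.data$species, species_order(series)))
}

#' Locally weighted scatterplot smoothing (display aid)
#'
#' Standard tricube-weighted local linear smoother (no robustness
#' iterations), used only as a visual aid for plotting noisy time courses.
#' Smoothed values never feed any downstream statistic.
#'
#' @param series Data frame with columns `time` and `conc` (>= 5 points).
#' @param span Fraction of points in each local neighbourhood (default 2/3).
#' @return Tibble with `time` and `smoothed`, sorted by time.
#' @export
lowess_smooth <- function(series, span = 2/3) {
  stopifnot(is.data.frame(series), all(c("time", "conc") %in% names(series)))
  if (nrow(series) < 5L) abort("need >= 5 points to smooth")
  sm <- lowess(series$time, series$conc, f = span, iter = 0, delta = 0)
  tibble(time = sm$x, smoothed = sm$y)
}
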