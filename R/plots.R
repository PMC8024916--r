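#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_tile
#'   scale_x_log10 scale_y_log10 scale_size_area labs theme_minimal
#'   facet_wrap scale_fill_viridis_c
#' @export
ggplot2::autoplot

fit_curve_data <- function(x, n = 200) {
  S <- seq(min(x$data$S), max(x$data$S), length.out = n)
  v <- predict(x$fit, newdata = data.frame(S = S))
  tibble(S = S, v = v)
}

#' @describeIn fit_mm Plot data points with the fitted rate curve.
#' @param object An `mm_fit`.
#' @param ... Unused.
#' @export
autoplot.mm_fit <- function(object, ...) {
  stopifnot(object$converged)
  ggplot(object$data, aes(.data$S * 1e6, .data$v)) +
    geom_point() +
    geom_line(data = fit_curve_data(object),
              aes(.data$S * 1e6, .data$v), colour = "steelblue") +
    labs(x = "[S] (uM)", y = "v (M/s)",
         title = sprintf("Michaelis-Menten fit: kcat/KM = %.3g /M/s",
                         object$efficiency)) +
    theme_minimal()
}

#' @describeIn fit_hill Plot data points with the fitted Hill curve.
#' @param object A `hill_fit`.
#' @param ... Unused.
#' @export
autoplot.hill_fit <- function(object, ...) {
  stopifnot(object$converged)
  ggplot(object$data, aes(.data$S * 1e6, .data$v)) +
    geom_point() +
    geom_line(data = fit_curve_data(object),
              aes(.data$S * 1e6, .data$v), colour = "steelblue") +
    labs(x = "[S] (uM)", y = "v (M/s)",
         title = sprintf("Allosteric fit: h = %.2f", object$h)) +
    theme_minimal()
}

#' @describeIn fit_4pl Plot the titration with the fitted logistic curve.
#' @param object A `pl4_fit`.
#' @param ... Unused.
#' @export
autoplot.pl4_fit <- function(object, ...) {
  stopifnot(object$converged)
  doses <- 10^seq(log10(min(object$data$dose)),
                  log10(max(object$data$dose)), length.out = 200)
  ggplot(object$data, aes(.data$dose, .data$response)) +
    geom_point() +
    geom_line(data = tibble(dose = doses,
                            response = predict(object, doses)),
              colour = "steelblue") +
    scale_x_log10() +
    labs(x = "dose (M)", y = "% activity",
         title = sprintf("4PL fit (%s): p%s50 = %.2f", object$direction,
                         if (object$direction == "inhibition") "IC" else "XC",
                         object$pXC50)) +
    theme_minimal()
}

#' Bubble chart of diplotype prevalence
#'
#' @param diplo Diplotype tibble from [diplotype_table()].
#' @return A ggplot.
#' @export
plot_diplotype_bubble <- function(diplo) {
  lev <- allotype_levels(c(diplo$allotype_a, diplo$allotype_b))
  ggplot(diplo, aes(factor(.data$allotype_a, lev),
                    factor(.data$allotype_b, lev),
                    size = .data$freq_pct)) +
    geom_point(colour = "steelblue", alpha = 0.8) +
    scale_size_area(max_size = 12) +
    labs(x = "allotype", y = "allotype", size = "% of samples") +
    theme_minimal()
}

#' Scatter and bubble views of the genotype-activity landscape
#'
#' @param landscape Tibble from [landscape_table()].
#' @param type `"scatter"` (activity vs frequency) or `"bubble"` (pair grid
#'   coloured by activity).
#' @return A ggplot.
#' @export
plot_landscape <- function(landscape, type = c("scatter", "bubble")) {
  type <- match.arg(type)
  if (type == "scatter") {
    return(ggplot(landscape, aes(.data$activity, .data$freq_pct)) +
             geom_point(colour = "steelblue") +
             scale_x_log10() +
             labs(x = "expected total activity (1/M/s)",
                  y = "% of samples") +
             theme_minimal())
  }
  lev <- allotype_levels(c(landscape$allotype_a, landscape$allotype_b))
  ggplot(landscape, aes(factor(.data$allotype_a, lev),
                        factor(.data$allotype_b, lev),
                        size = .data$freq_pct, colour = log10(.data$activity))) +
    geom_point(alpha = 0.9) +
    scale_size_area(max_size = 12) +
    labs(x = "allotype", y = "allotype",
         size = "% of samples", colour = "log10 activity") +
    theme_minimal()
}

#' Trimming time courses with LOWESS display smoothing
#'
#' Points are the measured concentrations; lines are the tricube local
#' smoother and serve only as a visual aid.
#'
#' @param series Trimming series tibble (`time`, `species`, `conc`).
#' @param span LOWESS span (default 2/3).
#' @return A ggplot.
#' @export
plot_trimming <- function(series, span = 2/3) {
  sm <- series |>
    group_by(.data$species) |>
    group_modify(~ lowess_smooth(.x, span)) |>
    ungroup()
  lev <- species_order(series)
  ggplot(series, aes(.data$time / 60, .data$conc * 1e6)) +
    geom_point(size = 0.8) +
    geom_line(data = sm, aes(.data$time / 60, .data$smoothed * 1e6),
              colour = "steelblue") +
    facet_wrap(~ factor(species, lev)) +
    labs(x = "time (min)", y = "peptide (uM)") +
    theme_minimal()
}

#' Heat map of intermediate accumulation
#'
#' @param series Trimming series tibble.
#' @param what `"fraction"` (fraction-of-total trajectory) or `"max"`
#'   (per-species maxima).
#' @return A ggplot.
#' @export
plot_accumulation_heatmap <- function(series, what = c("fraction", "max")) {
  what <- match.arg(what)
  lev <- rev(species_order(series))
  if (what == "fraction") {
    frac <- fraction_of_total(series)
    return(ggplot(frac, aes(.data$time / 60, factor(.data$species, lev),
                            fill = .data$fraction)) +
             geom_tile() +
             scale_fill_viridis_c(limits = c(0, 1)) +
             labs(x = "time (min)", y = NULL, fill = "fraction") +
             theme_minimal())
  }
  mx <- max_accumulation(series)
  ggplot(mx, aes("max", factor(.data$species, lev),
                 fill = .data$max_fraction)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, fill = "max fraction") +
    theme_minimal()
}
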