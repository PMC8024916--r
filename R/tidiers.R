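#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Michaelis-Menten fit
#'
#' @param x An `mm_fit`.
#' @param ... Unused.
#' @return One row per parameter (`kcat`, `KM`, `efficiency`) with
#'   `estimate` and `std.error`.
#' @export
tidy.mm_fit <- function(x, ...) {
  tibble(term = c("kcat", "KM", "efficiency"),
         estimate = c(x$kcat, x$KM, x$efficiency),
         std.error = c(x$kcat_se, x$KM_se, x$efficiency_se))
}

#' Tidy an allosteric (Hill) fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return One row per parameter (`Vmax`, `K_half`, `h`).
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("Vmax", "K_half", "h"),
         estimate = c(x$Vmax, x$K_half, x$h),
         std.error = c(x$Vmax_se, x$K_half_se, x$h_se))
}

#' Tidy a four-parameter logistic fit
#'
#' @param x A `pl4_fit`.
#' @param ... Unused.
#' @return One row per parameter (`top`, `bottom`, `pXC50`, `slope`);
#'   the fit's direction tag is carried in the `direction` column.
#' @export
tidy.pl4_fit <- function(x, ...) {
  tibble(term = c("top", "bottom", "pXC50", "slope"),
         estimate = c(x$top, x$bottom, x$pXC50, x$slope),
         std.error = c(x$top_se, x$bottom_se, x$pXC50_se, x$slope_se),
         direction = x$direction)
}

#' One-row fit summary
#'
#' @param x Any kinetic fit object (`mm_fit`, `hill_fit`, `pl4_fit`).
#' @param ... Unused.
#' @return Tibble with `converged`, `n`, `sigma`, `aic`.
#' @export
glance.kinetic_fit <- function(x, ...) {
  n <- nrow(x$data)
  if (is.null(x$fit) || !x$converged) {
    return(tibble(converged = FALSE, n = n,
                  sigma = NA_real_, aic = NA_real_))
  }
  if (inherits(x$fit, "nls")) {
    return(tibble(converged = x$converged, n = n,
                  sigma = summary(x$fit)$sigma, aic = AIC(x$fit)))
  }
  # nls.lm-backed fits: gaussian log-likelihood from the residual sum of
  # squares (AIC counts the error variance as a parameter)
  sigma <- sqrt(x$rss / max(n - x$n_par, 1))
  ll <- -n / 2 * (log(2 * pi) + log(x$rss / n) + 1)
  tibble(converged = x$converged, n = n, sigma = sigma,
         aic = 2 * (x$n_par + 1) - 2 * ll)
}
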