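#' Percent turnover from substrate and product signals
#'
#' Converts raw substrate and product signals to concentrations through
#' their respective calibration curves (correcting for the difference in
#' detection sensitivity between the two analytes) and computes
#' `100 * [P] / ([P] + [S])`. Values above `flag_above` (default 35%) are
#' flagged as exceeding the assay's quality-control bound; they are flagged,
#' not removed.
#'
#' @param sub_signal,prod_signal Raw signals (same arbitrary units).
#' @param sub_curve,prod_curve `standard_curve` objects for substrate and
#'   product.
#' @param flag_above QC bound in percent (default 35).
#' @return Tibble with `turnover` (percent) and `flagged`.
#' @export
percent_turnover <- function(sub_signal, prod_signal, sub_curve, prod_curve,
                             flag_above = 35) {
  stopifnot(all(sub_signal >= 0), all(prod_signal >= 0))
  s <- invert_curve(sub_curve, sub_signal)
  p <- invert_curve(prod_curve, prod_signal)
  if (any(s + p <= 0)) abort("substrate and product both zero")
  turnover <- 100 * p / (p + s)
  tibble(turnover = turnover, flagged = turnover > flag_above)
}

#' Normalise raw responses to percent activity between controls
#'
#' `100 * (raw - low) / (high - low)`, with the uninhibited reaction as the
#' high control and the fully inhibited reaction as the low control. Values
#' above 100 are legitimate for activators.
#'
#' @param raw Raw response(s).
#' @param high_ctrl,low_ctrl Control responses (scalars or vectors).
#' @return Percent activity.
#' @export
normalize_activity <- function(raw, high_ctrl, low_ctrl) {
  if (any(high_ctrl == low_ctrl)) abort("high and low controls are equal")
  100 * (raw - low_ctrl) / (high_ctrl - low_ctrl)
}

#' Four-parameter logistic fit of a titration curve
#'
#' Fits `response = A0 + (Ainf - A0) / (1 + (XC50 / x)^slope)` on a log10 dose
#' scale, where `A0` and `Ainf` are the zero-dose and saturating-dose
#' plateaus. Reported `top`/`bottom` are the larger/smaller plateau; the
#' direction tag is `"inhibition"` when the saturating plateau lies below
#' the zero-dose plateau and `"activation"` otherwise, so pIC50 (inhibition)
#' and pXC50 (activation) keep the vocabulary of the underlying assay.
#' A fit whose midpoint falls outside the dosed range, or that does not
#' converge, is flagged.
#'
#' @param curve Data frame with columns `dose` (molar, > 0) and `response`
#'   (percent activity); at least 6 doses spanning the transition.
#' @return Object of class `pl4_fit`: `top`, `bottom`, `pXC50`, `slope`,
#'   standard errors, `direction`, `converged`, `in_range`.
#' @export
fit_4pl <- function(curve) {
  stopifnot(is.data.frame(curve),
            all(c("dose", "response") %in% names(curve)))
  if (any(curve$dose <= 0)) abort("doses must be positive")
  if (length(unique(curve$dose)) < 6L) abort("need >= 6 doses")
  l <- log10(curve$dose)
  y <- curve$response
  o <- order(l)
  model <- function(par, l) {
    par[1] + (par[2] - par[1]) / (1 + 10^(par[4] * (-par[3] - l)))
  }
  start <- c(a0 = mean(y[o][1:2]), ainf = mean(y[rev(o)][1:2]),
             p = -median(l), h = 1)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = function(p) model(p, l) - y,
                       control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) {
      warn(paste("4PL fit failed:", conditionMessage(e)))
      NULL
    })
  if (is.null(fit) || !fit$info %in% 1:4) {
    if (!is.null(fit)) warn("4PL fit did not converge")
    return(structure(
      list(fit = fit, data = curve, converged = FALSE,
           top = NA_real_, bottom = NA_real_, pXC50 = NA_real_,
           slope = NA_real_, top_se = NA_real_, bottom_se = NA_real_,
           pXC50_se = NA_real_, slope_se = NA_real_,
           direction = NA_character_, in_range = NA,
           rss = NA_real_, n_par = 4L),
      class = c("pl4_fit", "kinetic_fit")))
  }
  cf <- fit$par
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  names(se) <- names(cf)
  # normalise so the slope is positive and plateaus keep their meaning
  a0 <- cf[["a0"]]; ainf <- cf[["ainf"]]; p <- cf[["p"]]; h <- cf[["h"]]
  a0_se <- se[["a0"]]; ainf_se <- se[["ainf"]]
  if (h < 0) {
    tmp <- a0; a0 <- ainf; ainf <- tmp
    tmp <- a0_se; a0_se <- ainf_se; ainf_se <- tmp
    h <- -h
  }
  direction <- if (ainf < a0) "inhibition" else "activation"
  in_range <- -p >= min(l) && -p <= max(l)
  if (!in_range) warn("4PL midpoint falls outside the dosed range")
  structure(
    list(fit = fit, data = curve, converged = TRUE,
         par = c(a0 = a0, ainf = ainf, p = p, h = h),
         top = max(a0, ainf), bottom = min(a0, ainf),
         pXC50 = p, slope = h,
         top_se = if (a0 > ainf) a0_se else ainf_se,
         bottom_se = if (a0 > ainf) ainf_se else a0_se,
         pXC50_se = se[["p"]], slope_se = se[["h"]],
         direction = direction, in_range = in_range,
         rss = fit$deviance, n_par = 4L),
    class = c("pl4_fit", "kinetic_fit"))
}

#' Predicted 4PL response at given doses
#' @param object A `pl4_fit`.
#' @param dose Doses (molar).
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.pl4_fit <- function(object, dose, ...) {
  stopifnot(object$converged)
  p <- object$par
  p[["a0"]] + (p[["ainf"]] - p[["a0"]]) /
    (1 + 10^(p[["h"]] * (-p[["p"]] - log10(dose))))
}

#' Correlation between paired per-allotype quantities
#'
#' Pearson and Spearman correlation (both reported) with two-sided
#' p-values, for relating e.g. allotype specific activity to inhibitor
#' potency.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @return Tibble with columns `method`, `estimate`, `p_value`, `n`.
#' @export
correlate <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector has no correlation")
  res <- lapply(c("pearson", "spearman"), function(m) {
    ct <- suppressWarnings(cor.test(x, y, method = m, exact = FALSE))
    tibble(method = m, estimate = unname(ct$estimate),
           p_value = ct$p.value, n = length(x))
  })
  list_rbind(res)
}
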