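mm_start <- function(S, v, E) {
  list(kcat = max(v) / E, KM = median(S))
}

new_kinetic_fit <- function(class, fit, params, data, extra = list()) {
  structure(c(list(fit = fit, data = data, converged = !is.null(fit) &&
                     isTRUE(fit$convInfo$isConv)),
              params, extra),
            class = c(class, "kinetic_fit"))
}

safe_nls <- function(expr) {
  tryCatch(expr, error = function(e) {
    warn(paste("nonlinear fit did not converge:", conditionMessage(e)))
    NULL
  })
}

#' Michaelis-Menten fit of rate versus substrate data
#'
#' Nonlinear least-squares fit of `v = kcat * E * S / (KM + S)`.
#' Reports the turnover number kcat (1/s), the Michaelis constant KM
#' (molar), and the derived catalytic efficiency kcat/KM (1/M/s) with a
#' delta-method standard error. A fit that fails to converge returns a
#' flagged result (all parameters `NA`, `converged = FALSE`) rather than
#' raising, so screening pipelines can carry non-results forward explicitly.
#'
#' @param data Data frame with columns `S` (molar) and `v` (molar/s);
#'   at least 5 substrate levels spanning the anticipated KM.
#' @param E Enzyme concentration (molar).
#' @param weights `"none"` (default) or `"1/v"` for inverse-response
#'   weighting.
#' @return An object of class `mm_fit`; see [tidy.mm_fit()],
#'   [glance.kinetic_fit()].
#' @examples
#' S <- c(5, 10, 25, 50, 100, 200) * 1e-6
#' v <- 10 * 25e-9 * S / (50e-6 + S)
#' fit_mm(data.frame(S = S, v = v), E = 25e-9)
#' @export
fit_mm <- function(data, E, weights = c("none", "1/v")) {
  stopifnot(is.data.frame(data), all(c("S", "v") %in% names(data)), E > 0)
  weights <- match.arg(weights)
  if (length(unique(data$S)) < 5L) abort("need >= 5 substrate levels")
  args <- list(v ~ kcat * E * S / (KM + S), data = data,
               start = mm_start(data$S, data$v, E),
               lower = c(kcat = 0, KM = 0),
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (weights == "1/v") {
    args$weights <- 1 / pmax(data$v, .Machine$double.eps)
  }
  E # force so the formula environment carries the enzyme concentration
  fit <- safe_nls(do.call(minpack.lm::nlsLM, args))
  if (is.null(fit)) {
    return(new_kinetic_fit("mm_fit", NULL,
                           list(kcat = NA_real_, KM = NA_real_,
                                kcat_se = NA_real_, KM_se = NA_real_,
                                efficiency = NA_real_,
                                efficiency_se = NA_real_, E = E),
                           data))
  }
  cf <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  V <- vcov(fit)
  kcat <- cf[["kcat"]]; KM <- cf[["KM"]]
  grad <- c(1 / KM, -kcat / KM^2)
  eff_se <- sqrt(drop(t(grad) %*% V %*% grad))
  new_kinetic_fit("mm_fit", fit,
                  list(kcat = kcat, KM = KM,
                       kcat_se = se[["kcat"]], KM_se = se[["KM"]],
                       efficiency = kcat / KM, efficiency_se = eff_se,
                       E = E),
                  data)
}

#' Allosteric (Hill) fit of rate versus substrate data
#'
#' Nonlinear least-squares fit of `v = Vmax * S^h / (K_half^h + S^h)`,
#' the cooperative generalisation of Michaelis-Menten kinetics. With
#' `fix_h = 1` the model reduces exactly to Michaelis-Menten (with
#' `Vmax = kcat * E`).
#'
#' @param data Data frame with columns `S` (molar) and `v` (molar/s);
#'   at least 6 substrate levels.
#' @param fix_h Optionally pin the Hill coefficient (e.g. `1`).
#' @param weights As in [fit_mm()].
#' @return An object of class `hill_fit` with `Vmax`, `K_half`, `h` and
#'   standard errors.
#' @export
fit_hill <- function(data, fix_h = NULL, weights = c("none", "1/v")) {
  stopifnot(is.data.frame(data), all(c("S", "v") %in% names(data)))
  weights <- match.arg(weights)
  min_levels <- if (is.null(fix_h)) 6L else 5L
  if (length(unique(data$S)) < min_levels) {
    abort(sprintf("need >= %d substrate levels", min_levels))
  }
  if (is.null(fix_h)) {
    args <- list(v ~ Vmax * S^h / (K_half^h + S^h), data = data,
                 start = list(Vmax = max(data$v), K_half = median(data$S),
                              h = 1),
                 lower = c(Vmax = 0, K_half = 0, h = 1e-3),
                 control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    h0 <- fix_h
    args <- list(v ~ Vmax * S^h0 / (K_half^h0 + S^h0), data = data,
                 start = list(Vmax = max(data$v), K_half = median(data$S)),
                 lower = c(Vmax = 0, K_half = 0),
                 control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  if (weights == "1/v") {
    args$weights <- 1 / pmax(data$v, .Machine$double.eps)
  }
  fit <- safe_nls(do.call(minpack.lm::nlsLM, args))
  if (is.null(fit)) {
    return(new_kinetic_fit("hill_fit", NULL,
                           list(Vmax = NA_real_, K_half = NA_real_,
                                h = NA_real_, Vmax_se = NA_real_,
                                K_half_se = NA_real_, h_se = NA_real_),
                           data))
  }
  cf <- coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  new_kinetic_fit("hill_fit", fit,
                  list(Vmax = cf[["Vmax"]], K_half = cf[["K_half"]],
                       h = if (is.null(fix_h)) cf[["h"]] else fix_h,
                       Vmax_se = se[["Vmax"]], K_half_se = se[["K_half"]],
                       h_se = if (is.null(fix_h)) se[["h"]] else 0),
                  data)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<%s> converged: %s\n", class(x)[1], x$converged))
  print(generics::tidy(x))
  invisible(x)
}

#' Select between Michaelis-Menten and allosteric (Hill) models
#'
#' Compares AIC of the two fits on identical data. The model with more
#' parameters (Hill) is chosen only when it improves AIC by more than
#' `parsimony_delta`; ties go to Michaelis-Menten.
#'
#' @param mm An `mm_fit`.
#' @param hill A `hill_fit` on the same data.
#' @param parsimony_delta AIC margin the richer model must beat (default 2).
#' @return List with `chosen` (`"mm"` or `"hill"`), `delta_aic`
#'   (AIC(mm) - AIC(hill)) and `aic` (tibble per model).
#' @export
model_select <- function(mm, hill, parsimony_delta = 2) {
  stopifnot(inherits(mm, "mm_fit"), inherits(hill, "hill_fit"))
  if (!isTRUE(all.equal(mm$data$S, hill$data$S)) ||
      !isTRUE(all.equal(mm$data$v, hill$data$v))) {
    abort("model_select requires fits on identical data")
  }
  if (!mm$converged || !hill$converged) {
    abort("both fits must have converged for model selection")
  }
  aics <- c(mm = AIC(mm$fit), hill = AIC(hill$fit))
  delta <- unname(aics["mm"] - aics["hill"])
  list(chosen = if (delta > parsimony_delta) "hill" else "mm",
       delta_aic = delta,
       aic = tibble(model = names(aics), aic = unname(aics)))
}

#' Pairwise fold ratios of an activity profile
#'
#' For one substrate, forms the matrix of pairwise ratios of a per-allotype
#' activity measure (catalytic efficiency by default) and the overall
#' spread (max/min). Allotypes with a missing value for that substrate are
#' excluded with a message — a flagged non-result never turns into a number.
#'
#' @param profile Activity profile tibble with columns `allotype`,
#'   `substrate` and the value column.
#' @param substrate Substrate label to subset on.
#' @param value Name of the value column (default `"efficiency"`).
#' @return List with `ratios` (tibble: `allotype_num`, `allotype_den`,
#'   `ratio`) and `spread` (max/min).
#' @export
fold_ratios <- function(profile, substrate, value = "efficiency") {
  stopifnot(all(c("allotype", "substrate", value) %in% names(profile)))
  sub <- profile |>
    filter(.data$substrate == !!substrate) |>
    select("allotype", value = all_of(value))
  dropped <- sub$allotype[is.na(sub$value)]
  if (length(dropped)) {
    inform(paste("fold_ratios: excluding allotype(s) with missing values:",
                 paste(dropped, collapse = ", ")))
    sub <- filter(sub, !is.na(.data$value))
  }
  if (nrow(sub) < 2L) abort("need >= 2 allotypes with values")
  ratios <- expand_grid(allotype_num = sub$allotype,
                        allotype_den = sub$allotype) |>
    mutate(ratio = sub$value[match(.data$allotype_num, sub$allotype)] /
             sub$value[match(.data$allotype_den, sub$allotype)])
  list(ratios = ratios, spread = max(sub$value) / min(sub$value))
}
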