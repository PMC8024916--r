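apply_noise <- function(x, cv, seed, model = c("lognormal", "additive")) {
  if (cv <= 0) return(x)
  model <- match.arg(model)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  if (model == "lognormal") {
    sdlog <- sqrt(log(1 + cv^2))
    x * rlnorm(length(x), -sdlog^2 / 2, sdlog)
  } else {
    x + rnorm(length(x), 0, cv * mean(abs(x)))
  }
}

#' Default ground-truth activity profile for the synthetic generators
#'
#' Per-allotype catalytic parameters used by the generators. The absolute
#' values are package defaults chosen in the ranges typical of ERAP1
#' in-vitro assays; what they are anchored to are the published fold
#' relationships: for the 9mer epitope substrate, a roughly twofold kcat
#' spread across allotypes 1-9 with allotype 10 about tenfold below the
#' median, a KM spread below sixfold with allotypes 1 and 2 binding
#' tightest, and a 60-fold efficiency ratio between allotypes 2 and 10;
#' for the dipeptide Leu-AMC, an 18-fold efficiency ratio between
#' allotype 3 (most active) and allotype 10, with the response linear in
#' substrate well past 150 uM (KM far above the assayed range).
#'
#' @return Tibble: `allotype`, `substrate` (`"9mer"`, `"Leu-AMC"`),
#'   `kcat` (1/s), `KM` (molar), `efficiency` (1/M/s).
#' @export
default_activity_profile <- function() {
  nine <- tibble(
    allotype = as.character(1:10),
    substrate = "9mer",
    kcat = c(0.55, 0.60, 0.50, 0.40, 0.45, 0.42, 0.38, 0.50, 0.30, 0.045),
    KM = c(22, 20, 35, 60, 50, 55, 70, 45, 80, 90) * 1e-6
  )
  amc <- tibble(
    allotype = as.character(1:10),
    substrate = "Leu-AMC",
    efficiency = c(2600, 2800, 3000, 1800, 2000, 1900, 1700, 2200, 1500,
                   3000 / 18),
    KM = 1.5e-3
  ) |> mutate(kcat = .data$efficiency * .data$KM)
  bind_rows(mutate(nine, efficiency = .data$kcat / .data$KM), amc) |>
    select("allotype", "substrate", "kcat", "KM", "efficiency")
}

#' Default allosteric (Hill) ground truths for the chromogenic dipeptide
#'
#' Hill-model parameters per allotype for Leu-pNA-style assays. Allotype 10
#' hydrolyses this substrate too slowly for reliable parameter estimation,
#' so its entry is an explicit missing value - downstream code must carry
#' it as a flagged non-result, never extrapolate one.
#'
#' @return Tibble: `allotype`, `Vmax_over_E` (1/s), `K_half` (molar), `h`.
#' @export
default_hill_params <- function() {
  tibble(
    allotype = as.character(1:10),
    Vmax_over_E = c(2.0, 2.2, 1.9, 1.4, 1.6, 1.5, 1.3, 1.8, 1.2, NA),
    K_half = c(350, 320, 400, 520, 480, 500, 560, 420, 600, NA) * 1e-6,
    h = c(rep(1.5, 9), NA)
  )
}

model_rate <- function(params, S, E) {
  if (params$model == "mm") {
    params$kcat * E * S / (params$KM + S)
  } else if (params$model == "hill") {
    params$Vmax_over_E * E * S^params$h / (params$K_half^params$h + S^params$h)
  } else {
    abort("params$model must be 'mm' or 'hill'")
  }
}

#' Generate a rate-versus-substrate dataset from kinetic ground truth
#'
#' Evaluates the Michaelis-Menten or Hill rate law on a substrate grid and
#' applies seeded multiplicative noise - the (S, v) input that the fitting
#' operations consume.
#'
#' @param params List with `model = "mm"` (`kcat`, `KM`) or
#'   `model = "hill"` (`Vmax_over_E`, `K_half`, `h`).
#' @param S Substrate concentrations (molar).
#' @param E Enzyme concentration (molar).
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   noise (0 = noiseless).
#' @param seed Integer seed.
#' @param noise_model `"lognormal"` (default) or `"additive"`.
#' @return Tibble with columns `S`, `v` (molar/s).
#' @export
gen_rate_dataset <- function(params, S, E, noise_cv = 0, seed = 1L,
                             noise_model = "lognormal") {
  v <- model_rate(params, S, E)
  tibble(S = S, v = apply_noise(v, noise_cv, seed, noise_model))
}

#' Generate assay progress curves from kinetic ground truth
#'
#' Integrates substrate depletion under the chosen rate law for each level
#' of a substrate design grid, yielding product-concentration time courses
#' like those read off a plate reader after standard-curve conversion.
#' Optionally re-encodes concentrations as raw signal through a supplied
#' standard curve plus internal-standard signal (mass-spectrometry style).
#'
#' @inheritParams gen_rate_dataset
#' @param times Time grid (s).
#' @param curve Optional `standard_curve` used to emit a `signal` column.
#' @param is_signal Optional internal-standard signal (scalar or per time
#'   point); when given, `signal` is multiplied by it and an `is_signal`
#'   column is emitted.
#' @return Tibble: `S` (initial substrate, molar), `time`, `conc` (product,
#'   molar), plus `signal`/`is_signal` when requested.
#' @export
gen_assay_timecourses <- function(params, S, E, times, noise_cv = 0,
                                  seed = 1L, curve = NULL, is_signal = NULL) {
  sim_one <- function(s0) {
    sol <- deSolve::ode(
      y = c(P = 0), times = times,
      func = function(t, y, p) {
        list(model_rate(params, pmax(s0 - y[1], 0), E))
      },
      parms = NULL, rtol = 1e-10, atol = 1e-16)
    tibble(S = s0, time = times, conc = pmax(sol[, "P"], 0))
  }
  out <- list_rbind(map(S, sim_one))
  out$conc <- apply_noise(out$conc, noise_cv, seed)
  if (!is.null(curve)) {
    out$signal <- apply_curve(curve, out$conc)
    if (!is.null(is_signal)) {
      isv <- rep_len(is_signal, nrow(out))
      out$signal <- out$signal * isv
      out$is_signal <- isv
    }
  }
  out
}

#' Generate inhibitor/activator titration curves with control wells
#'
#' Four-parameter logistic responses on a dose series (threefold dilution
#' by default), emitted as raw plate signals together with replicated
#' uninhibited (high) and fully-inhibited (low) control wells, so the
#' normalisation step can be exercised end to end.
#'
#' @param params List with `top` (percent-activity plateau at zero dose),
#'   `bottom` (plateau at saturating dose; may exceed `top` for
#'   activators), `pXC50` (-log10 molar midpoint) and `slope`.
#' @param doses Dose series (molar); default ten threefold dilutions from
#'   100 uM.
#' @param noise_cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @param n_ctrl Control wells per side (default 8).
#' @param raw_high,raw_low Raw signals corresponding to 100% and 0%
#'   activity.
#' @return Tibble: `well` (`"sample"`, `"high"`, `"low"`), `dose` (NA for
#'   controls), `raw_signal`; the percent-activity truth is attribute
#'   `truth`.
#' @export
gen_titration <- function(params, doses = 100e-6 / 3^(0:9), noise_cv = 0,
                          seed = 1L, n_ctrl = 8L,
                          raw_high = 1000, raw_low = 50) {
  stopifnot(all(c("top", "bottom", "pXC50", "slope") %in% names(params)))
  xc50 <- 10^(-params$pXC50)
  pct <- params$bottom + (params$top - params$bottom) /
    (1 + (doses / xc50)^params$slope)
  raw <- raw_low + pct / 100 * (raw_high - raw_low)
  out <- bind_rows(
    tibble(well = "sample", dose = doses, raw_signal = raw),
    tibble(well = "high", dose = NA_real_,
           raw_signal = rep(raw_high, n_ctrl)),
    tibble(well = "low", dose = NA_real_, raw_signal = rep(raw_low, n_ctrl))
  )
  out$raw_signal <- apply_noise(out$raw_signal, noise_cv, seed)
  attr(out, "truth") <- params
  out
}

#' Normalise a generated titration to percent activity
#'
#' Applies [normalize_activity()] with the mean high/low control signals
#' and returns the dose-response table ready for [fit_4pl()].
#'
#' @param titration Output of [gen_titration()] (columns `well`, `dose`,
#'   `raw_signal`).
#' @return Tibble with `dose` and `response` (percent activity).
#' @export
normalize_titration <- function(titration) {
  hi <- mean(titration$raw_signal[titration$well == "high"])
  lo <- mean(titration$raw_signal[titration$well == "low"])
  titration |>
    filter(.data$well == "sample") |>
    mutate(response = normalize_activity(.data$raw_signal, hi, lo)) |>
    select("dose", "response")
}
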