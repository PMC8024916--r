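test_that("exact-count panels reproduce their frequency spec", {
  tab <- table1_frequencies(long = FALSE)
  spec <- panel_spec(freqs = setNames(tab$ALL / 100, tab$haplotype),
                     n_samples = 2504, seed = 2)
  panel <- gen_phased_panel(spec)
  expect_equal(nrow(panel), 2504L)
  got <- allotype_frequencies(panel, groups = NULL)
  for (i in seq_len(nrow(tab))) {
    g <- got$freq_pct[got$allotype == tab$allotype[i]]
    expect_lte(abs(g - tab$ALL[i]), 0.1)
  }
})

test_that("panel generation is byte-identical under a fixed seed", {
  spec <- panel_spec(freqs = c(ERIGMKDRQ = 0.5, EPMGMRDRE = 0.5),
                     n_samples = 100, seed = 9)
  expect_identical(gen_phased_panel(spec), gen_phased_panel(spec))
})

test_that("sampling mode converges to the spec frequencies at large n", {
  spec <- panel_spec(freqs = c(ERIGMKDRQ = 0.3, EPMGMRDRE = 0.7),
                     n_samples = 20000, mode = "sample", seed = 5)
  got <- allotype_frequencies(gen_phased_panel(spec), groups = NULL)
  expect_lt(abs(got$freq_pct[got$allotype == "2"] - 30), 1)
})

test_that("joint diplotype distributions are honoured and validated", {
  joint <- tibble::tibble(hap1 = c("ERIGMKDRQ", "ERIGMKDRQ"),
                          hap2 = c("ERIGMKDRQ", "EPMGMRDRE"),
                          n = c(30L, 70L))
  spec <- panel_spec(counts = c(ERIGMKDRQ = 130L, EPMGMRDRE = 70L),
                     n_samples = 100, joint = joint, seed = 1)
  panel <- gen_phased_panel(spec)
  dt <- diplotype_table(panel)
  expect_equal(dt$n[dt$allotype_a == "2" & dt$allotype_b == "2"], 30L)
  expect_equal(dt$n[dt$allotype_a == "2" & dt$allotype_b == "8"], 70L)

  clash <- panel_spec(counts = c(ERIGMKDRQ = 100L, EPMGMRDRE = 100L),
                      n_samples = 100, joint = joint, seed = 1)
  expect_error(gen_phased_panel(clash), "inconsistent")
})

test_that("largest-remainder counts always total 2n", {
  for (n in c(3L, 17L, 503L)) {
    x <- c(0.21, 0.33, 0.46)
    cnt <- allokin:::largest_remainder(x, 2L * n)
    expect_equal(sum(cnt), 2L * n)
  }
})

test_that("rate generator is exact at zero noise and feeds fits round-trip", {
  S <- c(5, 10, 25, 50, 100, 200, 400) * 1e-6
  d <- gen_rate_dataset(list(model = "mm", kcat = 0.5, KM = 45e-6),
                        S = S, E = 1e-9)
  expect_equal(d$v, 0.5 * 1e-9 * S / (45e-6 + S))
  f <- fit_mm(d, E = 1e-9)
  expect_equal(f$kcat, 0.5, tolerance = 1e-6)
})

test_that("time courses re-encode as MS-style signals losslessly", {
  sc <- fit_standard_curve(data.frame(conc = c(0, 1e-6),
                                      signal = c(0.2, 0.2 + 1e-6 * 2e5)))
  tc <- gen_assay_timecourses(list(model = "mm", kcat = 1, KM = 50e-6),
                              S = c(10, 50) * 1e-6, E = 1e-9,
                              times = seq(0, 600, 60),
                              curve = sc, is_signal = 3)
  expect_equal(tc$signal, apply_curve(sc, tc$conc) * 3)
  expect_equal(invert_curve(sc, tc$signal / tc$is_signal), tc$conc,
               tolerance = 1e-9)
})

test_that("generated time courses stay linear in S at low substrate", {
  prof <- default_activity_profile()
  amc <- prof[prof$allotype == "3" & prof$substrate == "Leu-AMC", ]
  S <- c(10, 25, 50, 100, 150) * 1e-6 # the assayed sub-KM range
  tc <- gen_assay_timecourses(list(model = "mm", kcat = amc$kcat,
                                   KM = amc$KM),
                              S = S, E = 25e-9, times = seq(0, 60, 10))
  rates <- tc |>
    dplyr::group_by(S) |>
    dplyr::group_modify(~ initial_rate(.x, s0 = .y$S)) |>
    dplyr::ungroup()
  est <- efficiency_from_linear_regime(
    data.frame(S = rates$S, v_over_E = rates$rate / 25e-9))
  expect_false(est$nonlinear)
  # closed-form oracle for the 1/S^2-weighted through-origin slope on
  # mild-saturation data (equals the mean of v/(E*S) over the grid); the
  # top of the assayed range (S/KM = 0.1) pulls it slightly low
  v_over_E_true <- amc$kcat * S / (amc$KM + S)
  slope_oracle <- mean(v_over_E_true / S)
  expect_equal(est$efficiency, slope_oracle, tolerance = 0.02)
  expect_lt(abs(est$efficiency - amc$efficiency) / amc$efficiency, 0.06)
})

test_that("titration generator round-trips through normalisation and fitting", {
  tt <- gen_titration(list(top = 100, bottom = 5, pXC50 = 7.0, slope = 1.1))
  # control wells anchor the normalisation at 100 and 0
  expect_equal(mean(normalize_activity(
    tt$raw_signal[tt$well == "high"], 1000, 50)), 100)
  f <- fit_4pl(normalize_titration(tt))
  expect_equal(f$pXC50, 7.0, tolerance = 1e-4)
  expect_equal(f$top, 100, tolerance = 1e-4)
  expect_equal(f$bottom, 5, tolerance = 1e-3)
})

test_that("default ground truths encode the published fold relations", {
  prof <- default_activity_profile()
  nine <- prof[prof$substrate == "9mer", ]
  e <- setNames(nine$efficiency, nine$allotype)
  expect_equal(e[["2"]] / e[["10"]], 60)
  expect_equal(max(e) / min(e), 60)
  k <- setNames(nine$kcat, nine$allotype)
  expect_lte(max(k[as.character(1:9)]) / min(k[as.character(1:9)]), 2)
  expect_equal(median(k[as.character(1:9)]) / k[["10"]], 10)
  km <- setNames(nine$KM, nine$allotype)
  expect_lte(max(km) / min(km), 6)

  amc <- prof[prof$substrate == "Leu-AMC", ]
  ea <- setNames(amc$efficiency, amc$allotype)
  expect_equal(ea[["3"]] / ea[["10"]], 18)
  expect_true(all(ea[["3"]] >= ea))

  # the sluggish allotype's dipeptide Hill parameters are explicit NAs
  hp <- default_hill_params()
  expect_true(is.na(hp$K_half[hp$allotype == "10"]))
  expect_false(anyNA(hp$K_half[hp$allotype != "10"]))
})
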