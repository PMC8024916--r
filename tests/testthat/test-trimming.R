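test_that("internal-standard normalisation and calibration invert the generator", {
  # unit calibration, signal equal to IS -> concentration 1
  raw <- tibble::tibble(time = 0, species = "14mer", signal = 5,
                        is_signal = 5)
  q <- quantify_species(raw, unit_curve())
  expect_equal(q$conc, 1)

  # doubling the IS halves the normalised value
  raw2 <- dplyr::mutate(raw, is_signal = 10)
  expect_equal(quantify_species(raw2, unit_curve())$conc, 0.5)

  # round-trip: encode a simulated series as signals, then recover it
  series <- simulate_cascade()
  curves <- setNames(
    lapply(seq_len(7), function(i) {
      fit_standard_curve(data.frame(conc = c(0, 30e-6),
                                    signal = c(0.1, 0.1 + 30e-6 * (1e5 + i))))
    }),
    ovalbumin_species()$species)
  is_sig <- 2.5
  encoded <- series |>
    dplyr::group_by(species) |>
    dplyr::mutate(signal = apply_curve(curves[[species[1]]], conc) * is_sig,
                  is_signal = is_sig) |>
    dplyr::ungroup()
  rec <- quantify_species(encoded, curves)
  expect_equal(rec$conc, series$conc, tolerance = 1e-6)

  bad <- dplyr::mutate(raw, is_signal = 0)
  expect_error(quantify_species(bad, unit_curve()), "time point")
})

test_that("fraction-of-total divides per time point", {
  one <- tibble::tibble(time = c(0, 0), species = c("a", "b"),
                        conc = c(2e-6, 0))
  expect_equal(fraction_of_total(one)$fraction, c(1, 0))

  eq <- tidyr::expand_grid(time = c(0, 60), species = letters[1:7]) |>
    dplyr::mutate(conc = 3e-6)
  expect_true(all(abs(fraction_of_total(eq)$fraction - 1 / 7) < 1e-12))

  sim <- fraction_of_total(simulate_cascade())
  byhand <- sim |>
    dplyr::group_by(time) |>
    dplyr::mutate(f2 = conc / sum(conc)) |>
    dplyr::ungroup()
  expect_equal(sim$fraction, byhand$f2)
  # noiseless rows sum to exactly 1
  sums <- sim |> dplyr::summarise(s = sum(fraction), .by = time)
  expect_equal(sums$s, rep(1, nrow(sums)))

  zero <- tibble::tibble(time = c(0, 0), species = c("a", "b"), conc = 0)
  expect_error(fraction_of_total(zero), "zero")
})

test_that("maximal accumulation is the grid maximum, no interpolation", {
  s <- simulate_cascade()
  mx <- max_accumulation(s)
  grid_max <- s |> dplyr::summarise(m = max(conc), .by = species)
  expect_equal(mx$max_conc,
               grid_max$m[match(mx$species, grid_max$species)])
  # terminal product accumulates monotonically: maximum at final time
  expect_equal(mx$t_max_conc[mx$species == "8mer"], max(s$time))
  # precursor maximal at t = 0
  expect_equal(mx$t_max_conc[mx$species == "14mer"], 0)
})

test_that("a fast-then-slow two-step cascade parks almost everything in the intermediate", {
  # A -> B -> C with k1 >> k2 in the sub-saturating regime:
  # B transiently holds nearly all of A's initial amount
  spec <- cascade_spec(species = c("A", "B", "C"),
                       kcat = c(5, 0.05), KM = c(50e-6, 50e-6),
                       E = 10e-9, s0 = 10e-6,
                       times = seq(0, 40000, 500))
  mx <- max_accumulation(simulate_cascade(spec))
  expect_gt(mx$max_conc[mx$species == "B"], 0.95 * 10e-6)
})

test_that("noiseless cascade trajectories are monotone at the ends", {
  wide <- tidyr::pivot_wider(simulate_cascade(), names_from = species,
                             values_from = conc) |> dplyr::arrange(time)
  expect_true(all(diff(wide$`14mer`) <= 1e-12))
  expect_true(all(diff(wide$`8mer`) >= -1e-12))
})

test_that("the display smoother matches a textbook tricube local-linear oracle", {
  const <- tibble::tibble(time = 1:10, conc = 4)
  expect_equal(lowess_smooth(const)$smoothed, rep(4, 10))

  lin <- tibble::tibble(time = 1:20, conc = 2 * (1:20) + 1)
  expect_equal(lowess_smooth(lin, span = 1)$smoothed, lin$conc,
               tolerance = 1e-9)

  set.seed(9)
  x <- sort(runif(40, 0, 10))
  y <- sin(x) + rnorm(40, 0, 0.2)
  for (span in c(0.3, 0.5, 0.75)) {
    got <- lowess_smooth(tibble::tibble(time = x, conc = y), span = span)
    oracle <- tricube_lowess(x, y, span)
    expect_equal(got$smoothed, oracle$y, tolerance = 1e-6)
  }

  expect_error(lowess_smooth(tibble::tibble(time = 1:4, conc = 1:4)),
               ">= 5")
})
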