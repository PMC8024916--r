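mm_grid <- c(2, 5, 10, 20, 40, 60, 100, 150, 220, 320, 450, 600) * 1e-6

test_that("Michaelis-Menten fit recovers noiseless parameters exactly", {
  d <- gen_rate_dataset(list(model = "mm", kcat = 10, KM = 50e-6),
                        S = mm_grid, E = 25e-9)
  f <- fit_mm(d, E = 25e-9)
  expect_true(f$converged)
  expect_equal(f$kcat, 10, tolerance = 1e-6)
  expect_equal(f$KM, 50e-6, tolerance = 1e-6)
  expect_equal(f$efficiency, 2e5, tolerance = 1e-6)
})

test_that("MM fit stays within 15% of truth at 5% noise", {
  d <- gen_rate_dataset(list(model = "mm", kcat = 10, KM = 50e-6),
                        S = mm_grid, E = 25e-9, noise_cv = 0.05, seed = 101)
  f <- fit_mm(d, E = 25e-9)
  expect_lt(abs(f$kcat - 10) / 10, 0.15)
  expect_lt(abs(f$KM - 50e-6) / 50e-6, 0.15)
})

test_that("median parameter recovery bias is below 5% over 100 seeds", {
  # duplicate wells per substrate level, as plates are laid out
  bias <- vapply(1:100, function(s) {
    d <- gen_rate_dataset(list(model = "mm", kcat = 10, KM = 50e-6),
                          S = rep(mm_grid, 2), E = 25e-9,
                          noise_cv = 0.05, seed = s)
    f <- fit_mm(d, E = 25e-9)
    c(abs(f$kcat - 10) / 10, abs(f$KM - 50e-6) / 50e-6)
  }, numeric(2))
  expect_lt(median(bias[1, ]), 0.05)
  expect_lt(median(bias[2, ]), 0.05)
})

test_that("Hill fit with h constrained to 1 equals the MM fit", {
  d <- gen_rate_dataset(list(model = "mm", kcat = 8, KM = 80e-6),
                        S = mm_grid, E = 10e-9, noise_cv = 0.04, seed = 7)
  mm <- fit_mm(d, E = 10e-9)
  hill <- fit_hill(d, fix_h = 1)
  # agreement to 4 significant figures
  expect_equal(hill$Vmax, mm$kcat * 10e-9, tolerance = 1e-4)
  expect_equal(hill$K_half, mm$KM, tolerance = 1e-4)
})

test_that("Hill fit recovers noiseless and noisy cooperative data", {
  hg <- c(10, 25, 50, 100, 200, 350, 600, 1000, 1600) * 1e-6
  d0 <- gen_rate_dataset(list(model = "hill", Vmax_over_E = 2,
                              K_half = 300e-6, h = 1.5),
                         S = hg, E = 5e-9)
  f0 <- fit_hill(d0)
  expect_equal(f0$Vmax, 2 * 5e-9, tolerance = 1e-6)
  expect_equal(f0$K_half, 300e-6, tolerance = 1e-6)
  expect_equal(f0$h, 1.5, tolerance = 1e-6)

  d2 <- gen_rate_dataset(list(model = "hill", Vmax_over_E = 2,
                              K_half = 300e-6, h = 2),
                         S = hg, E = 5e-9, noise_cv = 0.05, seed = 13)
  f2 <- fit_hill(d2)
  expect_gte(f2$h, 1.6)
  expect_lte(f2$h, 2.4)
})

test_that("AIC model selection prefers the generating model", {
  hg <- c(10, 25, 50, 100, 200, 350, 600, 1000, 1600) * 1e-6
  # cooperative data: Hill wins
  d2 <- gen_rate_dataset(list(model = "hill", Vmax_over_E = 2,
                              K_half = 300e-6, h = 2),
                         S = hg, E = 5e-9, noise_cv = 0.03, seed = 5)
  sel2 <- model_select(fit_mm(d2, E = 5e-9), fit_hill(d2))
  expect_identical(sel2$chosen, "hill")
  expect_gt(sel2$delta_aic, 2)

  # hyperbolic data: parsimony keeps MM
  d1 <- gen_rate_dataset(list(model = "mm", kcat = 2, KM = 300e-6),
                         S = hg, E = 5e-9, noise_cv = 0.03, seed = 5)
  sel1 <- model_select(fit_mm(d1, E = 5e-9), fit_hill(d1))
  expect_identical(sel1$chosen, "mm")
})

test_that("non-converging fits come back flagged, never silent numbers", {
  # pathological: negative-trend garbage cannot satisfy the MM form
  bad <- data.frame(S = mm_grid[1:6], v = c(5, 4, 3, 2, 1, 0.5) * NA_real_)
  f <- suppressWarnings(fit_mm(bad, E = 1e-9))
  expect_false(f$converged)
  expect_true(is.na(f$kcat))
  expect_true(is.na(tidy(f)$estimate[1]))
  expect_false(glance(f)$converged)
})

test_that("fold ratios report pairwise spread and skip missing values", {
  profile <- tibble::tibble(
    allotype = c("2", "3", "10"),
    substrate = "9mer",
    efficiency = c(60, 30, 1))
  fr <- fold_ratios(profile, "9mer")
  r <- fr$ratios
  expect_equal(r$ratio[r$allotype_num == "2" & r$allotype_den == "10"], 60)
  expect_equal(r$ratio[r$allotype_num == "3" & r$allotype_den == "2"], 0.5)
  expect_equal(fr$spread, 60)

  uniform <- dplyr::mutate(profile, efficiency = 5)
  expect_true(all(fold_ratios(uniform, "9mer")$ratios$ratio == 1))

  with_na <- dplyr::mutate(profile,
                           efficiency = replace(efficiency, 3, NA))
  expect_message(fr2 <- fold_ratios(with_na, "9mer"), "excluding")
  expect_false("10" %in% fr2$ratios$allotype_num)
})
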