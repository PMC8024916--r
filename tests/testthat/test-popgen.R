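test_that("allotype frequencies match a hand count on a toy panel", {
  ft <- allotype_frequencies(toy_panel())
  get <- function(a, p) ft$freq_pct[ft$allotype == a & ft$population == p]
  # 20 chromosomes overall: 8x allotype 2, 7x 8, 4x 10, 1 unassigned
  expect_equal(get("2", "ALL"), 40)
  expect_equal(get("8", "ALL"), 35)
  expect_equal(get("10", "ALL"), 20)
  expect_equal(get("unassigned", "ALL"), 5)
  expect_equal(get("2", "EUR"), 30)
  expect_equal(get("8", "EAS"), 30)
})

test_that("a single homozygous sample gives 100% for its allotype", {
  p <- tibble::tibble(sample = "s", hap1 = "ERIGMKDRQ", hap2 = "ERIGMKDRQ")
  ft <- allotype_frequencies(p, groups = NULL)
  expect_equal(ft$freq_pct[ft$allotype == "2"], 100)
})

test_that("population frequency columns sum to 100 within rounding", {
  for (panel in list(toy_panel(), table1_panel("ALL"), table1_panel("AFR"))) {
    ft <- allotype_frequencies(panel)
    sums <- ft |>
      dplyr::filter(!is_subtotal) |>
      dplyr::summarise(s = sum(round(freq_pct, 1)), .by = population)
    expect_true(all(abs(sums$s - 100) <= 0.3))
  }
})

test_that("diplotype table uses unordered keys and exact counts", {
  # (8,2) and (2,8) samples fall under one key
  p <- tibble::tibble(sample = c("a", "b"),
                      hap1 = c("EPMGMRDRE", "ERIGMKDRQ"),
                      hap2 = c("ERIGMKDRQ", "EPMGMRDRE"))
  dt <- diplotype_table(p)
  expect_equal(nrow(dt), 1L)
  expect_identical(dt$allotype_a, "2")
  expect_identical(dt$allotype_b, "8")
  expect_equal(dt$n, 2L)

  # all-homozygous panel: only diagonal keys
  ph <- tibble::tibble(sample = c("a", "b"),
                       hap1 = c("ERIGMKDRQ", "EPIGVRNQE"),
                       hap2 = c("ERIGMKDRQ", "EPIGVRNQE"))
  dth <- diplotype_table(ph)
  expect_true(all(dth$allotype_a == dth$allotype_b))

  # toy panel matches brute-force hand enumeration; counts sum to samples
  dt2 <- diplotype_table(toy_panel())
  expect_equal(sum(dt2$n), 10L)
  expect_equal(sum(dt2$freq_pct), 100)
  key <- paste(dt2$allotype_a, dt2$allotype_b)
  expect_equal(dt2$n[key == "2 8"], 3L)
  expect_equal(dt2$n[key == "2 2"], 2L)
  expect_equal(dt2$n[key == "8 10"], 2L)
  expect_equal(dt2$n[key == "2 unassigned"], 1L)
})

test_that("expected co-occurrence reproduces product and HWE arithmetic", {
  expect_equal(round(expected_cooccurrence(0.256, 0.218, mode = "product"), 4),
               0.0558)
  expect_equal(expected_cooccurrence(0.256, 0.218, mode = "hwe"),
               2 * 0.256 * 0.218)
  expect_equal(expected_cooccurrence(0.3, 0.3, mode = "hwe", identical = TRUE),
               0.09)
  expect_equal(expected_cooccurrence(0, 0.5, mode = "product"), 0)
})

test_that("random pairing is seeded, degenerate-safe, and matches HWE in the mean", {
  freqs <- c(`2` = 0.256, `8` = 0.218, other = 1 - 0.256 - 0.218)

  expect_identical(random_pairing_simulation(freqs, 100, seed = 11),
                   random_pairing_simulation(freqs, 100, seed = 11))

  one <- random_pairing_simulation(c(only = 1), 50, seed = 3)
  expect_equal(nrow(one), 1L)
  expect_identical(one$allotype_a, one$allotype_b)

  n <- 500
  seeds <- 1:200
  get_pair <- function(dt, a, b) {
    i <- dt$allotype_a == a & dt$allotype_b == b
    if (any(i)) dt$freq_pct[i] / 100 else 0
  }
  sims <- vapply(seeds, function(s) {
    dt <- random_pairing_simulation(freqs, n, seed = s)
    c(het = get_pair(dt, "2", "8"), hom = get_pair(dt, "2", "2"))
  }, numeric(2))
  p <- 0.256; q <- 0.218
  for (case in list(list(obs = mean(sims["het", ]), expct = 2 * p * q),
                    list(obs = mean(sims["hom", ]), expct = p^2))) {
    mc_se <- sqrt(case$expct * (1 - case$expct) / n) / sqrt(length(seeds))
    expect_lt(abs(case$obs - case$expct), 3 * mc_se)
  }
})

test_that("cross-tabulation conditions ERAP1 diplotypes on ERAP2 class", {
  erap1 <- tibble::tibble(
    sample = sprintf("s%d", 1:6),
    allotype_a = c("8", "8", "2", "2", "8", "2"),
    allotype_b = c("8", "2", "2", "8", "8", "2"))
  erap2 <- tibble::tibble(sample = sprintf("s%d", 1:6),
                          erap2_class = c("A/A", "A/A", "A/A",
                                          "B/B", "B/B", "B/B"))
  ct <- cross_tabulate(erap1, erap2)
  cell <- function(cls, a, b) {
    i <- ct$erap2_class == cls & ct$allotype_a == a & ct$allotype_b == b
    ct$pct_within_class[i]
  }
  expect_equal(cell("A/A", "8", "8"), 100 / 3)
  expect_equal(cell("B/B", "8", "8"), 100 / 3)
  expect_equal(unique(ct$pct_overall[ct$allotype_a == "8" &
                                       ct$allotype_b == "8"]), 100 / 3)
  sums <- ct |> dplyr::summarise(s = sum(pct_within_class),
                                 .by = erap2_class)
  expect_true(all(abs(sums$s - 100) < 1e-9))

  # single-class input: conditional equals marginal
  ct1 <- cross_tabulate(erap1, dplyr::mutate(erap2, erap2_class = "A/B"))
  expect_equal(ct1$pct_within_class, ct1$pct_overall)

  expect_error(cross_tabulate(erap1, erap2[1:5, ]), "same samples")
})
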