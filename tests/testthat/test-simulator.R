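# The acquisition simulator: panel structure, mass-error physics, seeded
# determinism, ion-count conservation and the dilution/condition designs.

test_that("panel has 21 label-matched pairs over the 8 UPR proteins", {
  panel <- build_upr_panel(seed = 1)
  expect_equal(nrow(panel), 42L)
  expect_setequal(unique(panel$protein),
                  c("IRE1", "PERK", "ATF6", "ATF3", "ATF4", "CHOP",
                    "GADD34", "XBP1"))
  pairs <- dplyr::count(panel, peptide)
  expect_equal(nrow(pairs), 21L)
  expect_true(all(pairs$n == 2L))
  # light/heavy partners share RT, fragments and response factor
  wide <- panel |>
    dplyr::group_by(peptide) |>
    dplyr::summarise(rt_ok = dplyr::n_distinct(rt_true) == 1,
                     rf_ok = dplyr::n_distinct(response_factor) == 1,
                     nfrag_ok = dplyr::n_distinct(purrr::map_int(fragments, nrow)) == 1)
  expect_true(all(wide$rt_ok & wide$rf_ok & wide$nfrag_ok))
  # documented sequences present with their protein assignments
  expect_equal(unique(panel$protein[panel$peptide == "GGFGVVFEAK"]), "PERK")
  expect_equal(unique(panel$protein[panel$peptide == "YLTDFEPIQCLGR"]), "PERK")
  expect_equal(unique(panel$protein[panel$peptide == "AEPQPLSPASSSYSVSSPR"]),
               "ATF6")
  expect_equal(unique(panel$protein[panel$peptide == "APLSPSLLIR"]), "GADD34")
  expect_true(all(panel$ambiguous_protein[panel$peptide == "APLSPSLLIR"]))
  # RTs spread over the 75-min gradient
  expect_gt(diff(range(panel$rt_true)), 50)
  # library intensities normalized
  expect_true(all(abs(purrr::map_dbl(panel$fragments,
                                     ~ sum(.x$rel_intensity)) - 1) < 1e-12))
})

test_that("mass error sigma follows the resolution and ion-count scaling", {
  # arithmetic oracle: sigma_ppm = 1e6 * 9.6 * sqrt(mz) / (R*sqrt(200)*sqrt(N))
  oracle <- 1e6 * 9.6 * sqrt(500) / (240000 * sqrt(200) * sqrt(1000))
  expect_equal(mass_error_sigma(240000, 500, 1000), oracle, tolerance = 1e-12)
  # doubling resolution halves sigma
  expect_equal(mass_error_sigma(120000, 433.3, 777) /
                 mass_error_sigma(240000, 433.3, 777), 2, tolerance = 1e-9)
  # monotone in resolution and ion count
  for (m in c(300, 700, 1100)) {
    for (n in c(50, 5000)) {
      expect_lt(mass_error_sigma(240000, m, n), mass_error_sigma(60000, m, n))
    }
  }
  expect_lt(mass_error_sigma(60000, 500, 4000),
            mass_error_sigma(60000, 500, 1000))
  # calibration anchors: mean |error| (= sigma*sqrt(2/pi)) above 5 ppm at
  # 60k, at or below 2 ppm at 240k, for the reference point
  mean_abs <- function(r) mass_error_sigma(r, 500, 1000) * sqrt(2 / pi)
  expect_gt(mean_abs(60000), 5)
  expect_lte(mean_abs(240000), 2)
  expect_error(mass_error_sigma(-1, 500, 100), "positive")
})

test_that("simulation is bit-identical under the same seed", {
  panel <- tiny_panel(n = 2)
  truth <- simulation_truth(panel, seed = 42)
  a1 <- simulate_acquisition(panel, acquisition_settings(), truth)
  a2 <- simulate_acquisition(panel, acquisition_settings(), truth)
  expect_identical(a1$scans, a2$scans)
  expect_identical(a1$scan_times, a2$scan_times)
})

test_that("zero analyte amount leaves only baseline and interference", {
  panel <- tiny_panel(n = 1)
  amounts <- tibble::tibble(peptide = panel$peptide, label = panel$label,
                            amol = c(0, 0))
  acq <- simulate_acquisition(panel, acquisition_settings(),
                              simulation_truth(panel, amounts, seed = 5))
  # baseline is a flat low Poisson floor: no centroid anywhere near the
  # expected analyte apex intensity
  expect_lt(max(acq$scans$intensity),
            10 * qpois(0.999, 0.05 * 500))
})

test_that("missing truth entries are a configuration error", {
  panel <- tiny_panel(n = 2)
  amounts <- tibble::tibble(peptide = panel$peptide[1], label = "light",
                            amol = 10)
  expect_error(
    simulate_acquisition(panel, acquisition_settings(),
                         simulation_truth(panel, amounts, seed = 1)),
    "missing amounts")
})

test_that("per-scan fragment counts conserve the drawn total", {
  set.seed(7)
  rel <- c(0.4, 0.3, 0.2, 0.1)
  totals <- c(0L, 1L, 17L, 1000L, 250000L)
  counts <- draw_fragment_counts(totals, rel)
  expect_equal(colSums(counts), totals)
  expect_true(all(counts >= 0))
})

test_that("scan spacing equals the implied duty cycle", {
  panel <- tiny_panel(n = 1)  # no window overlap: concurrency 1 pair
  st <- acquisition_settings()
  acq <- simulate_acquisition(panel, st, simulation_truth(panel, seed = 2))
  per_scan_ms <- max(st$injection_time, transient_time(st$resolution)) +
    st$scan_overhead
  expected_cycle <- 2 * per_scan_ms / 60000  # 2 precursors active
  gaps <- acq$scan_times |>
    dplyr::group_by(peptide, label) |>
    dplyr::summarise(gap = list(diff(sort(rt))), .groups = "drop") |>
    tidyr::unnest(gap)
  expect_true(all(abs(gaps$gap - expected_cycle) < 1e-9))
  # RTs strictly increasing per precursor is implied by positive gaps
  expect_true(all(gaps$gap > 0))
})

test_that("doubling the amount doubles the expected summed signal", {
  panel <- tiny_panel(n = 1)
  areas <- sapply(1:20, function(s) {
    sapply(c(50, 100), function(a) {
      amounts <- tibble::tibble(peptide = panel$peptide, label = panel$label,
                                amol = ifelse(panel$label == "light", a, 100))
      acq <- simulate_acquisition(panel, acquisition_settings(),
                                  simulation_truth(panel, amounts, seed = s))
      sc <- acq$scans[acq$scans$label == "light", ]
      sum(sc$intensity)
    })
  })
  ratio <- mean(areas[2, ] / areas[1, ])
  se <- sd(areas[2, ] / areas[1, ]) / sqrt(ncol(areas))
  expect_lt(abs(ratio - 2), 3 * se + 0.05)
})

test_that("narrow isolation rejects the co-isolating interferent", {
  panel <- tiny_panel(n = 1)
  snr <- sapply(1:20, function(s) {
    truth <- simulation_truth(panel,
                              interferents = default_interferents(panel),
                              seed = s)
    sapply(c(0.4, 1.6), function(w) {
      acq <- simulate_acquisition(
        panel, acquisition_settings(isolation_width = w), truth)
      ev <- evaluate_acquisition(acq, panel)
      ev$snr_light
    })
  })
  expect_gt(mean(snr[1, ]), mean(snr[2, ]))  # S/N(0.4) > S/N(1.6)
})

test_that("dilution series reproduces the published endpoint arithmetic", {
  pair <- tiny_panel(n = 1)
  s1 <- simulate_dilution_series(pair, 980.8, 2, 7, seed = 1)
  expect_equal(nrow(s1), 8L)  # steps + 1 levels
  expect_equal(min(s1$nominal_amol), 7.6625)
  expect_equal(round(min(s1$nominal_amol), 1), 7.7)
  s2 <- simulate_dilution_series(pair, 59, 2, 7, seed = 1)
  expect_equal(round(min(s2$nominal_amol), 1), 0.5)
  expect_error(simulate_dilution_series(pair, 59, 1, 7, seed = 1),
               "factor")
  # heavy standard constant across levels
  hv <- purrr::map_dbl(s1$acquisition, function(a) {
    a$truth$amounts$amol[a$truth$amounts$label == "heavy"]
  })
  expect_equal(length(unique(hv)), 1L)
})

test_that("condition experiment scales light amounts by the programmed fold", {
  panel <- tiny_panel(n = 2)
  sim <- simulate_condition_experiment(
    panel, c(IRE1 = 17), replicates = 3, seed = 3, cv = 0)
  for (r in 1:3) {
    tr <- sim$acquisition[[r]]$truth$amounts
    base <- panel$endog_amol[match(paste(tr$peptide, tr$label),
                                   paste(panel$peptide, panel$label))]
    light <- tr$label == "light"
    targ <- panel$protein[match(tr$peptide, panel$peptide)] == "IRE1"
    expect_equal(tr$amol[light & targ], base[light & targ] * 17)
    expect_equal(tr$amol[light & !targ], base[light & !targ])
  }
  expect_error(
    simulate_condition_experiment(panel, c(NOPE = 2), seed = 1),
    "unknown protein")
})
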