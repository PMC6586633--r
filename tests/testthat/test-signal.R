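# XIC extraction, peak integration, dot product, shape scoring and pair
# acceptance.

test_that("XIC keeps centroids inside and drops centroids outside tolerance", {
  rts <- c(1, 2, 3)
  cent <- tibble::tibble(
    rt = c(1, 2, 3), peptide = "PEP", label = "light", fragment = "y4",
    true_mz = 500,
    measured_mz = c(500, 500 * (1 + 15e-6), 500 * (1 - 9e-6)),
    intensity = c(100, 200, 300)
  )
  acq <- manual_acquisition(cent, rts)
  tr <- extract_xic(acq, "PEP", "light", "y4", 500, tol = 10)
  expect_equal(tr$intensity, c(100, 0, 300))
  expect_equal(tr$measured_mz[1], 500)
  expect_equal(tr$measured_mz[2], 0)
})

test_that("XIC equals the brute-force oracle on random instances", {
  set.seed(11)
  for (case in 1:100) {
    n <- sample(5:15, 1)
    rts <- sort(runif(n, 0, 10))
    ncent <- sample(10:40, 1)
    cent <- tibble::tibble(
      rt = sample(rts, ncent, replace = TRUE),
      peptide = "PEP", label = "light",
      fragment = sample(c("y3", "y4"), ncent, replace = TRUE),
      true_mz = 500,
      measured_mz = 500 * (1 + runif(ncent, -25e-6, 25e-6)),
      intensity = rpois(ncent, 50)
    )
    acq <- manual_acquisition(cent, rts)
    tol <- runif(1, 2, 20)
    tr <- extract_xic(acq, "PEP", "light", "y4", 500, tol = tol)
    expect_equal(tr$intensity, xic_oracle(acq, "PEP", "light", 500, tol))
  }
})

test_that("XIC on an unknown precursor is a lookup error", {
  acq <- manual_acquisition(gaussian_trace(1:3)[0, ], 1:3)
  expect_error(extract_xic(acq, "NOPE", "light", "y4", 500), "unknown")
  expect_error(extract_xic(acq, "PEP", "light", "y4", 500, tol = 0), "tol")
})

test_that("dot product matches the published identities and hand arithmetic", {
  v <- c(3, 4, 5)
  expect_equal(dot_product(v, v), 1.00)
  expect_equal(dot_product(c(1, 0), c(0, 1)), 0.00)
  expect_equal(dot_product(c(3, 4), c(4, 3)), 0.96)
  expect_error(dot_product(c(0, 0), c(1, 2)), "zero vector")
  expect_error(dot_product(c(1, 2, 3), c(1, 2)), "equal length")
  expect_error(dot_product(c(-1, 2), c(1, 2)), "nonnegative")
})

test_that("dot product is symmetric and scale invariant", {
  set.seed(4)
  for (i in 1:50) {
    a <- rgamma(6, 1); b <- rgamma(6, 1); c <- runif(1, 0.01, 100)
    expect_equal(dot_product(a, b), dot_product(b, a), tolerance = 1e-12)
    expect_equal(dot_product(a, c * b), dot_product(a, b), tolerance = 1e-12)
  }
})

test_that("integration recovers the closed-form Gaussian area", {
  rts <- seq(8, 12, by = 0.02)
  tr <- gaussian_trace(rts, apex_rt = 10, sigma = 0.11, height = 5000)
  pk <- detect_and_integrate(tr, expected_rt = 10, window = 2)
  analytic <- 5000 * 0.11 * sqrt(2 * pi)
  expect_equal(pk$apex_rt, 10, tolerance = 0.03)
  expect_equal(pk$per_fragment$area, analytic, tolerance = 0.01 * analytic)
  expect_gte(pk$shape_r2, 0.999)
})

test_that("all-zero traces yield zero area and a not-detected flag", {
  tr <- gaussian_trace(seq(8, 12, 0.1), height = 0)
  tr$intensity <- 0
  pk <- detect_and_integrate(tr, 10, 2)
  expect_equal(pk$per_fragment$area, 0)
  expect_false(pk$detected)
  expect_equal(pk$n_detected, 0L)
  expect_error(detect_and_integrate(tr[0, ], 10, 2), "trace")
})

test_that("integration targets the peak nearest the expected RT", {
  rts <- seq(0, 20, by = 0.05)
  two <- gaussian_trace(rts, apex_rt = 5, sigma = 0.1, height = 1000)
  two$intensity <- two$intensity +
    3000 * exp(-(rts - 15)^2 / (2 * 0.1^2))
  pk <- detect_and_integrate(two, expected_rt = 5, window = 2)
  expect_equal(pk$apex_rt, 5, tolerance = 0.1)
  # area of the first peak only, not the larger distant one
  expect_equal(pk$per_fragment$area, 1000 * 0.1 * sqrt(2 * pi),
               tolerance = 0.02 * 1000 * 0.1 * sqrt(2 * pi))
})

test_that("area is additive across fragments over shared boundaries", {
  rts <- seq(8, 12, by = 0.05)
  f1 <- gaussian_trace(rts, height = 1000, fragment = "y3")
  f2 <- gaussian_trace(rts, height = 400, fragment = "y5")
  pk <- detect_and_integrate(dplyr::bind_rows(f1, f2), 10, 2)
  summed <- gaussian_trace(rts, height = 1400, fragment = "sum")
  pk_sum <- detect_and_integrate(summed, 10, 2)
  expect_equal(sum(pk$per_fragment$area), pk_sum$per_fragment$area,
               tolerance = 1e-9)
})

test_that("shape score separates Gaussian peaks from noise and flats", {
  rts <- seq(9, 11, by = 0.05)
  y <- 800 * exp(-(rts - 10)^2 / (2 * 0.15^2))
  expect_gte(gaussian_shape_score(rts, y), 0.999)
  # flat nonzero trace: no curvature explained
  expect_lte(gaussian_shape_score(rts, rep(100, length(rts))), 0.05)
  # uniform random noise scores low on average
  set.seed(21)
  scores <- replicate(20, gaussian_shape_score(seq_len(50), runif(50, 1, 100)))
  expect_lt(mean(scores), 0.5)
  # too few points is not evaluable
  expect_true(is.na(gaussian_shape_score(1:4, c(1, 5, 4, 1))))
})

test_that("clean simulated pairs are accepted with all criteria reported", {
  panel <- tiny_panel(n = 2)
  acq <- simulate_acquisition(panel, acquisition_settings(),
                              simulation_truth(panel, seed = 9))
  ev <- evaluate_acquisition(acq, panel)
  expect_true(all(ev$accepted))
  expect_true(all(lengths(ev$rejection_reasons) == 0))
  expect_true(all(ev$mean_abs_ppm_light < 5))
  expect_true(all(ev$n_detected_light >= 2))
})

test_that("violated criteria produce named rejection reasons", {
  rts <- seq(8, 12, by = 0.05)
  mk <- function(apex, ppm = 0) {
    tr <- dplyr::bind_rows(
      gaussian_trace(rts, apex_rt = apex, height = 1000, fragment = "y3"),
      gaussian_trace(rts, apex_rt = apex, height = 500, fragment = "y4")
    )
    tr$measured_mz <- tr$theoretical_mz * (1 + ppm * 1e-6)
    detect_and_integrate(tr, 10, 4)
  }
  lib <- c(2 / 3, 1 / 3)
  # heavy apex shifted +0.5 min -> co-elution failure
  ev <- evaluate_pair(mk(10), mk(10.5), lib)
  expect_false(ev$accepted)
  expect_true("rt-coelution" %in% ev$rejection_reasons[[1]])
  # mass errors at 8 ppm -> mass-error failure
  ev2 <- evaluate_pair(mk(10, ppm = 8), mk(10, ppm = 8), lib)
  expect_false(ev2$accepted)
  expect_true("mass-error" %in% ev2$rejection_reasons[[1]])
  # clean pair accepted
  ev3 <- evaluate_pair(mk(10), mk(10), lib)
  expect_true(ev3$accepted)
})

test_that("acceptance degrades monotonically with shot noise", {
  panel <- tiny_panel(n = 2)
  acc <- sapply(1:20, function(s) {
    truth <- simulation_truth(panel, seed = s)
    sapply(c(500, 10), function(it) {
      acq <- simulate_acquisition(
        panel, acquisition_settings(injection_time = it), truth)
      sum(evaluate_acquisition(acq, panel)$accepted)
    })
  })
  # more noise (short fill) never helps on average
  expect_gte(mean(acc[1, ]), mean(acc[2, ]))
})

test_that("parameter sweep summarises each grid point", {
  panel <- tiny_panel(n = 2)
  truth <- simulation_truth(panel, seed = 5)
  grid <- tibble::tibble(injection_time = c(30, 500))
  sw <- parameter_sweep(panel, truth, grid)
  expect_equal(nrow(sw), 2L)
  expect_true(all(c("mean_abs_ppm", "mean_dotp", "mean_snr") %in% names(sw)))
  expect_lte(sw$mean_dotp[1], sw$mean_dotp[2] + 1e-9)
  sw1 <- parameter_sweep(panel, truth, tibble::tibble(resolution = 240000))
  expect_equal(nrow(sw1), 1L)
  expect_error(parameter_sweep(panel, truth, tibble::tibble()[0, ]),
               "nonempty")
})
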