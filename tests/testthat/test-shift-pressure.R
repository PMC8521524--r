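pressures <- c(1, 500, 1000, 1500, 2000)

series_tbl <- function(delta0, B1, B2, p = pressures, p0 = 1,
                       residue_index = 5L, residue_name = "ARG",
                       nucleus = "N") {
  x <- (p - p0) / 1000
  tibble::tibble(
    residue_index = residue_index, residue_name = residue_name,
    nucleus = nucleus, pressure_bar = p,
    shift_ppm = delta0 + B1 * x + B2 * x^2
  )
}

test_that("quadratic fit recovers generating coefficients exactly", {
  # constant series
  const <- series_tbl(8.3, 0, 0)
  fit <- fit_pressure_coefficients(const)
  expect_equal(fit$delta0, 8.3, tolerance = 1e-10)
  expect_equal(fit$B1, 0, tolerance = 1e-10)
  expect_equal(fit$B2, 0, tolerance = 1e-10)

  # exact quadratic round trip to >= 6 decimals
  fit <- fit_pressure_coefficients(series_tbl(8.0, 0.20, -0.05))
  expect_equal(fit$delta0, 8.0, tolerance = 1e-7)
  expect_equal(fit$B1, 0.20, tolerance = 1e-7)
  expect_equal(fit$B2, -0.05, tolerance = 1e-7)
  expect_lt(fit$fit_rss, 1e-12)

  # property: random coefficient triples round-trip through >= 3 exact points
  set.seed(41)
  for (i in 1:20) {
    tru <- c(runif(1, 5, 12), runif(1, -1, 1), runif(1, -0.3, 0.3))
    fit <- fit_pressure_coefficients(series_tbl(tru[1], tru[2], tru[3]))
    expect_equal(c(fit$delta0, fit$B1, fit$B2), tru, tolerance = 1e-8)
  }
})

test_that("exact interpolation when point count equals parameter count", {
  fit <- fit_pressure_coefficients(series_tbl(8, 0.3, -0.1, p = c(1, 1000, 2000)))
  expect_equal(fit$n_points, 3L)
  expect_lt(fit$fit_rss, 1e-18)
  expect_true(is.na(fit$B1_se))
})

test_that("insufficient data and duplicate pressures are handled", {
  two <- series_tbl(8, 0.2, 0, p = c(1, 2000))
  expect_error(fit_pressure_coefficients(two), "insufficient data")
  # linear-only mode accepts 2 points and fixes B2 = 0
  fit <- fit_pressure_coefficients(two, order = 1)
  expect_equal(fit$B1, 0.2, tolerance = 1e-10)
  expect_identical(fit$B2, 0)

  dup <- dplyr::bind_rows(series_tbl(8, 0.2, -0.05),
                          series_tbl(8, 0.2, -0.05, p = 1000))
  expect_warning(fitd <- fit_pressure_coefficients(dup), "duplicate pressures")
  expect_equal(fitd$B1, 0.2, tolerance = 1e-8)

  expect_error(fit_pressure_coefficients(series_tbl(8, 0, 0, p = c(0, 1000, 2000))),
               "> 0 bar")
})

test_that("shift invariance: constant offset moves only delta0", {
  base <- series_tbl(8.0, 0.35, -0.08)
  shifted <- dplyr::mutate(base, shift_ppm = shift_ppm + 2.5)
  f1 <- fit_pressure_coefficients(base)
  f2 <- fit_pressure_coefficients(shifted)
  expect_equal(f2$delta0, f1$delta0 + 2.5, tolerance = 1e-9)
  expect_equal(f2$B1, f1$B1, tolerance = 1e-9)
  expect_equal(f2$B2, f1$B2, tolerance = 1e-9)
})

test_that("B1 recovery is unbiased under Gaussian noise", {
  set.seed(7)
  sigma <- 0.01
  n_rep <- 500
  errs <- vapply(seq_len(n_rep), function(i) {
    noisy <- series_tbl(8.0, 0.20, -0.05) |>
      dplyr::mutate(shift_ppm = shift_ppm + rnorm(dplyr::n(), 0, sigma))
    fit_pressure_coefficients(noisy)$B1 - 0.20
  }, numeric(1))
  sem <- sd(errs) / sqrt(n_rep)
  expect_lt(abs(mean(errs)), 3 * sem)
})

test_that("random-coil correction subtracts reference and flags missing pairs", {
  fit <- fit_pressure_coefficients(series_tbl(8, 0.50, -0.10))
  ref <- tibble::tibble(residue_name = "ARG", nucleus = "N",
                        B1_rc = 0.20, B2_rc = -0.04)
  corr <- apply_random_coil_correction(fit, ref)
  expect_equal(corr$B1_corrected, 0.30, tolerance = 1e-9)
  expect_equal(corr$B2_corrected, -0.06, tolerance = 1e-9)
  expect_false(corr$rc_missing)

  # self-subtraction
  ref$B1_rc <- fit$B1; ref$B2_rc <- fit$B2
  corr <- apply_random_coil_correction(fit, ref)
  expect_equal(corr$B1_corrected, 0, tolerance = 1e-12)

  # absent pair: zero subtraction, flagged (shipped default table is empty)
  corr <- apply_random_coil_correction(fit)
  expect_equal(corr$B1_corrected, corr$B1)
  expect_true(corr$rc_missing)
})

test_that("response classification matches the threshold rule on a grid", {
  rule <- function(b1, thr) {
    if (b1 > thr) "positive" else if (b1 < -thr) "negative" else "near_zero"
  }
  grid <- expand.grid(b1 = seq(-1, 1, by = 0.1), thr = c(0.05, 0.2, 0.5))
  coeffs <- tibble::tibble(residue_index = seq_len(nrow(grid)),
                           residue_name = "ALA", nucleus = "N",
                           B1 = grid$b1, B1_corrected = grid$b1)
  for (thr in unique(grid$thr)) {
    got <- classify_response(coeffs, threshold = thr)$response
    want <- vapply(coeffs$B1_corrected, rule, character(1), thr = thr)
    expect_identical(as.character(got), want)
  }
  expect_identical(
    as.character(classify_response(coeffs[1, ] |>
                                     dplyr::mutate(B1_corrected = 0),
                                   threshold = 0.2)$response),
    "near_zero"
  )
  expect_error(classify_response(coeffs, threshold = 0), "positive")
  expect_error(classify_response(coeffs, threshold = -1), "positive")
})

test_that("units: pressures in bar with the fixed kbar conversion are self-consistent", {
  # expressing the same physical series on a doubled pressure scale while
  # doubling p0 halves the per-kbar coefficients accordingly; the fit must
  # track the algebra exactly
  f1 <- fit_pressure_coefficients(series_tbl(8, 0.4, -0.1), p0 = 1)
  doubled <- series_tbl(8, 0.4, -0.1) |>
    dplyr::mutate(pressure_bar = pressure_bar * 2)
  f2 <- fit_pressure_coefficients(doubled, p0 = 2)
  expect_equal(f2$B1, f1$B1 / 2, tolerance = 1e-9)
  expect_equal(f2$B2, f1$B2 / 4, tolerance = 1e-9)
  expect_equal(f2$delta0, f1$delta0, tolerance = 1e-9)
})

test_that("intensity trend slope and labels", {
  itab <- function(p, int) {
    tibble::tibble(residue_index = 5L, residue_name = "ARG", nucleus = "NE",
                   pressure_bar = p, intensity = int)
  }
  flat <- fit_intensity_trend(itab(c(1, 2000), c(1, 1)))
  expect_equal(flat$slope_kbar, 0, tolerance = 1e-12)
  expect_identical(flat$trend, "flat")

  up <- fit_intensity_trend(itab(c(1, 2000), 1 + 0.5 * (c(1, 2000) - 1) / 1000))
  expect_equal(up$slope_kbar, 0.5, tolerance = 1e-9)
  expect_identical(up$trend, "increasing")

  expect_error(fit_intensity_trend(itab(1000, 1)), "no intensity data")
  expect_error(
    fit_intensity_trend(itab(c(1, 2000), c(NA_real_, NA_real_))),
    "no intensity data"
  )
})
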