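#' Fit pressure coefficients of chemical shifts
#'
#' Fits the pressure dependence of each (residue, nucleus) chemical-shift
#' series to a second-order Taylor expansion about a reference pressure `p0`:
#'
#' \deqn{\delta(p) = \delta_0 + B_1 (p - p_0)/1000 + B_2 ((p - p_0)/1000)^2}
#'
#' with pressures in bar, so that `B1` is in ppm/kbar and `B2` in ppm/kbar^2.
#' An ordinary least-squares fit is used; when the number of distinct
#' pressures equals the number of parameters the fit interpolates exactly.
#'
#' @param shifts Data frame with columns `residue_index`, `residue_name`,
#'   `nucleus`, `pressure_bar`, `shift_ppm`. One series per
#'   (residue_index, residue_name, nucleus) combination.
#' @param p0 Expansion (reference) pressure in bar. Default 1 bar (ambient).
#' @param order 2 for the full quadratic fit (default), 1 for a linear-only
#'   fit in which `B2` is fixed at 0.
#'
#' @return A tibble with one row per series: `residue_index`, `residue_name`,
#'   `nucleus`, `n_points`, `delta0`, `B1`, `B2`, their standard errors
#'   (`delta0_se`, `B1_se`, `B2_se`; `NA` where not estimable) and `fit_rss`
#'   (residual sum of squares, ppm^2). Carries attributes `p0` and `order`.
#'
#' @details Duplicate pressures within a series are collapsed to their mean
#'   shift with a warning. A series with fewer distinct pressures than fitted
#'   parameters raises an "insufficient data" error.
#'
#' @examples
#' tbl <- gen_shift_table(seed = 1)
#' fit_pressure_coefficients(tbl)
#' @export
fit_pressure_coefficients <- function(shifts, p0 = 1, order = 2) {
  stopifnot(is.data.frame(shifts))
  req <- c("residue_index", "residue_name", "nucleus", "pressure_bar", "shift_ppm")
  miss <- setdiff(req, names(shifts))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  if (!order %in% c(1L, 2L)) abort("`order` must be 1 or 2")
  if (any(shifts$pressure_bar <= 0)) abort("all pressures must be > 0 bar")

  out <- shifts |>
    dplyr::group_by(.data$residue_index, .data$residue_name, .data$nucleus) |>
    dplyr::group_modify(function(df, key) {
      .fit_one_series(df, p0 = p0, order = order,
                      label = paste0(key$residue_name, key$residue_index,
                                     "/", key$nucleus))
    }) |>
    dplyr::ungroup()
  attr(out, "p0") <- p0
  attr(out, "order") <- order
  class(out) <- c("absalt_pressure_fit", class(out))
  out
}

.fit_one_series <- function(df, p0, order, label) {
  df <- dplyr::arrange(df, .data$pressure_bar)
  if (anyDuplicated(df$pressure_bar)) {
    warn(paste0("duplicate pressures in series ", label,
                "; collapsing to mean shift"))
    df <- df |>
      dplyr::group_by(.data$pressure_bar) |>
      dplyr::summarise(shift_ppm = mean(.data$shift_ppm), .groups = "drop")
  }
  n <- nrow(df)
  npar <- order + 1L
  if (n < npar) {
    abort(paste0("insufficient data for series ", label, ": ", n,
                 " distinct pressure(s), need >= ", npar))
  }
  x <- (df$pressure_bar - p0) / 1000 # kbar
  fit <- if (order == 2L) {
    lm(shift_ppm ~ x + I(x^2), data = data.frame(shift_ppm = df$shift_ppm, x = x))
  } else {
    lm(shift_ppm ~ x, data = data.frame(shift_ppm = df$shift_ppm, x = x))
  }
  cf <- coef(fit)
  se <- rep(NA_real_, npar)
  if (n > npar) {
    # avoids summary.lm's perfect-fit warning on noiseless series
    s2 <- sum(fit$residuals^2) / (n - npar)
    se <- sqrt(diag(chol2inv(qr.R(fit$qr))) * s2)
  }
  tibble(
    n_points = n,
    delta0 = unname(cf[1]),
    B1 = unname(cf[2]),
    B2 = if (order == 2L) unname(cf[3]) else 0,
    delta0_se = se[1],
    B1_se = se[2],
    B2_se = if (order == 2L) se[3] else NA_real_,
    fit_rss = sum(fit$residuals^2)
  )
}

#' Subtract random-coil reference pressure coefficients
#'
#' Isolates structure-specific pressure response by subtracting, per
#' (residue type, nucleus), the coefficients observed in unstructured
#' random-coil reference peptides. The correction acts on fitted
#' coefficients, which for a polynomial model is equivalent to correcting
#' the raw shifts.
#'
#' @param coeffs Tibble from [fit_pressure_coefficients()] (or any data frame
#'   with `residue_name`, `nucleus`, `B1`, `B2` columns).
#' @param reference Data frame with columns `residue_name`, `nucleus`,
#'   `B1_rc`, `B2_rc` (ppm/kbar, ppm/kbar^2), or `NULL` for the shipped
#'   default (all zeros, i.e. no correction; every row is then flagged).
#'
#' @return `coeffs` with added columns `B1_corrected`, `B2_corrected` and
#'   `rc_missing` (`TRUE` when no reference row exists for that residue
#'   type and nucleus; zero is subtracted in that case).
#' @export
apply_random_coil_correction <- function(coeffs, reference = NULL) {
  stopifnot(is.data.frame(coeffs))
  reference <- reference %||% random_coil_reference()
  req <- c("residue_name", "nucleus", "B1_rc", "B2_rc")
  miss <- setdiff(req, names(reference))
  if (length(miss) > 0) {
    abort(paste0("reference table missing column(s): ", paste(miss, collapse = ", ")))
  }
  at <- attributes(coeffs)
  out <- coeffs |>
    dplyr::left_join(
      dplyr::select(reference, dplyr::all_of(req)),
      by = c("residue_name", "nucleus")
    ) |>
    dplyr::mutate(
      rc_missing = is.na(.data$B1_rc),
      B1_rc = dplyr::coalesce(.data$B1_rc, 0),
      B2_rc = dplyr::coalesce(.data$B2_rc, 0),
      B1_corrected = .data$B1 - .data$B1_rc,
      B2_corrected = .data$B2 - .data$B2_rc
    )
  for (a in c("p0", "order")) attr(out, a) <- at[[a]]
  class(out) <- unique(c("absalt_pressure_fit", class(out)))
  out
}

#' Random-coil reference pressure coefficients
#'
#' Loads a per-(residue type, nucleus) table of random-coil pressure
#' coefficients used by [apply_random_coil_correction()]. The shipped
#' default table is empty, so every lookup falls back to a zero correction
#' and is flagged `rc_missing`: corrected coefficients then equal the raw
#' ones, and downstream results should be read as *uncorrected* until a
#' measured reference table is supplied. Users with reference-peptide data
#' should edit the CSV (columns `residue_name,nucleus,B1_rc,B2_rc`).
#'
#' @param path Path to a reference CSV, or `NULL` for the shipped default.
#' @return Tibble with columns `residue_name`, `nucleus`, `B1_rc`, `B2_rc`.
#' @export
random_coil_reference <- function(path = NULL) {
  path <- path %||% system.file("extdata", "random_coil_reference.csv",
                                package = "absalt", mustWork = TRUE)
  ref <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           residue_name = "c", nucleus = "c",
                           B1_rc = "d", B2_rc = "d"
                         ))
  miss <- setdiff(c("residue_name", "nucleus", "B1_rc", "B2_rc"), names(ref))
  if (length(miss) > 0) {
    abort(paste0("reference table missing column(s): ", paste(miss, collapse = ", ")))
  }
  ref
}

#' Classify per-residue pressure response
#'
#' Labels each series by the sign of its corrected first-order pressure
#' coefficient: `positive` if `B1_corrected > threshold`, `negative` if
#' `< -threshold`, else `near_zero` (pressure response indistinguishable
#' from random coil at the chosen threshold).
#'
#' @param coeffs Tibble from [apply_random_coil_correction()]; if
#'   `B1_corrected` is absent, raw `B1` is used.
#' @param threshold Magnitude cutoff in ppm/kbar, must be > 0. Default 0.2,
#'   a practical choice for backbone 15N coefficients.
#' @return `coeffs` with an added `response` column
#'   (factor: `negative`, `near_zero`, `positive`).
#' @export
classify_response <- function(coeffs, threshold = 0.2) {
  stopifnot(is.data.frame(coeffs))
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold) ||
      threshold <= 0) {
    abort("`threshold` must be a single positive number (ppm/kbar)")
  }
  b1 <- if ("B1_corrected" %in% names(coeffs)) coeffs$B1_corrected else coeffs$B1
  at <- attributes(coeffs)
  out <- dplyr::mutate(
    coeffs,
    response = factor(
      dplyr::case_when(
        b1 > threshold ~ "positive",
        b1 < -threshold ~ "negative",
        TRUE ~ "near_zero"
      ),
      levels = c("negative", "near_zero", "positive")
    )
  )
  for (a in c("p0", "order")) attr(out, a) <- at[[a]]
  attr(out, "threshold") <- threshold
  class(out) <- unique(c("absalt_pressure_fit", class(out)))
  out
}

#' Fit a linear pressure trend to peak intensities
#'
#' Least-squares linear slope of peak intensity versus pressure (per kbar),
#' with a sign label, per (residue, nucleus) series. Used e.g. to quantify
#' the pressure-induced intensity gain of the arginine Neta-Heta side-chain
#' peak when a salt bridge is disrupted by pressure.
#'
#' @param intensities Data frame with columns `residue_index`,
#'   `residue_name`, `nucleus`, `pressure_bar`, `intensity` (arbitrary
#'   units, >= 0).
#' @param flat_tol Slopes with absolute value `<= flat_tol` (intensity units
#'   per kbar) are labelled `flat`. Default `1e-8`, which treats only
#'   numerically constant series as flat.
#' @return Tibble with one row per series: slope per kbar (`slope_kbar`),
#'   its standard error, and `trend` (`increasing`/`decreasing`/`flat`).
#' @export
fit_intensity_trend <- function(intensities, flat_tol = 1e-8) {
  stopifnot(is.data.frame(intensities))
  req <- c("residue_index", "residue_name", "nucleus", "pressure_bar", "intensity")
  miss <- setdiff(req, names(intensities))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  intensities <- dplyr::filter(intensities, !is.na(.data$intensity))
  if (nrow(intensities) == 0) abort("no intensity data")
  if (flat_tol < 0) abort("`flat_tol` must be >= 0")

  intensities |>
    dplyr::group_by(.data$residue_index, .data$residue_name, .data$nucleus) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 2) abort("no intensity data: need >= 2 intensity points")
      x <- df$pressure_bar / 1000
      fit <- lm(y ~ x, data = data.frame(y = df$intensity, x = x))
      slope <- unname(coef(fit)[2])
      se <- if (nrow(df) > 2) sqrt(diag(vcov(fit)))[2] else NA_real_
      tibble(
        n_points = nrow(df),
        slope_kbar = slope,
        slope_se = unname(se),
        trend = dplyr::case_when(
          abs(slope) <= flat_tol ~ "flat",
          slope > 0 ~ "increasing",
          TRUE ~ "decreasing"
        )
      )
    }) |>
    dplyr::ungroup()
}
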