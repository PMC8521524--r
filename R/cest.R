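# Two-site symmetric-exchange CEST: Bloch-McConnell simulation, nonlinear
# least-squares fitting with a multi-start grid, and dip detection.
#
# Physical picture: the two N-eta nuclei of an arginine guanidinium group
# interconvert by rotation about the CZ-NE bond. With equal populations
# (0.5/0.5) this is a symmetric two-site exchange characterised by the total
# rate k_ex (sum of forward and backward rates; each direction runs at
# k_ex/2) and the shift difference delta_omega (rad/s) between the sites.

#' Construct a two-site symmetric exchange model
#'
#' Parameter container for the CEST simulator/fitter. Site populations are
#' fixed at 0.5/0.5 (rotational exchange swaps two chemically equivalent
#' nitrogens). `k_ex` follows the *sum* convention: it is the sum of the
#' forward and backward rates, each direction exchanging at `k_ex/2`.
#'
#' @param k_ex Total exchange rate, 1/s (>= 0).
#' @param delta_omega Shift difference between the two sites, rad/s.
#' @param center_ppm Mean chemical shift of the two sites, ppm. Default 71,
#'   the typical arginine N-eta position.
#' @param R1,R2 Longitudinal / transverse relaxation rates, 1/s (> 0).
#' @param B1_sat Saturation field strength, Hz.
#' @param T_sat Saturation duration, s (> 0).
#' @param freq_MHz Nitrogen Larmor frequency in MHz, used for all
#'   ppm to rad/s conversions. Default 81.1 (800 MHz proton field).
#' @return An object of class `exchange_model` (a named list).
#' @examples
#' m <- exchange_model(k_ex = 356, delta_omega = 1214)
#' simulate_cest_profile(m, seq(60, 82, by = 0.5))
#' @export
exchange_model <- function(k_ex, delta_omega, center_ppm = 71,
                           R1 = 1.5, R2 = 30, B1_sat = 25, T_sat = 0.4,
                           freq_MHz = 81.1) {
  if (k_ex < 0) abort("`k_ex` must be >= 0")
  if (R1 <= 0 || R2 <= 0) abort("`R1` and `R2` must be > 0")
  if (T_sat <= 0) abort("`T_sat` must be > 0")
  if (freq_MHz <= 0) abort("`freq_MHz` must be > 0")
  structure(
    list(k_ex = k_ex, delta_omega = delta_omega, center_ppm = center_ppm,
         R1 = R1, R2 = R2, B1_sat = B1_sat, T_sat = T_sat,
         freq_MHz = freq_MHz, populations = c(0.5, 0.5)),
    class = "exchange_model"
  )
}

#' @export
print.exchange_model <- function(x, ...) {
  cat("Two-site symmetric exchange model (populations 0.5/0.5)\n")
  cat(sprintf("  k_ex        %.4g 1/s (sum of both directions)\n", x$k_ex))
  cat(sprintf("  delta_omega %.4g rad/s (%.3f ppm at %.1f MHz)\n",
              x$delta_omega, x$delta_omega / (2 * pi * x$freq_MHz), x$freq_MHz))
  cat(sprintf("  center      %.3f ppm\n", x$center_ppm))
  cat(sprintf("  R1 %.3g 1/s, R2 %.3g 1/s, B1_sat %.3g Hz, T_sat %.3g s\n",
              x$R1, x$R2, x$B1_sat, x$T_sat))
  invisible(x)
}

#' Convert between ppm and rad/s at a given Larmor frequency
#'
#' @param x Value(s) to convert.
#' @param freq_MHz Larmor frequency in MHz.
#' @return Converted value(s).
#' @export
ppm_to_rads <- function(x, freq_MHz) x * 2 * pi * freq_MHz

#' @rdname ppm_to_rads
#' @export
rads_to_ppm <- function(x, freq_MHz) x / (2 * pi * freq_MHz)

# Bloch-McConnell generator for one saturation offset, augmented to 7x7 so
# the inhomogeneous R1*M0 term rides along as a constant. State:
# (Mx_a, My_a, Mz_a, Mx_b, My_b, Mz_b, 1).
.bm_matrix <- function(model, offset_ppm) {
  w1 <- 2 * pi * model$B1_sat
  k <- model$k_ex / 2
  half <- rads_to_ppm(model$delta_omega, model$freq_MHz) / 2
  site_ppm <- model$center_ppm + c(half, -half)
  om <- ppm_to_rads(site_ppm - offset_ppm, model$freq_MHz)
  A <- matrix(0, 7, 7)
  for (s in 1:2) {
    i <- (s - 1) * 3
    A[i + 1, i + 1] <- -model$R2 - k
    A[i + 1, i + 2] <- -om[s]
    A[i + 2, i + 1] <- om[s]
    A[i + 2, i + 2] <- -model$R2 - k
    A[i + 2, i + 3] <- -w1
    A[i + 3, i + 2] <- w1
    A[i + 3, i + 3] <- -model$R1 - k
    A[i + 3, 7] <- model$R1 * model$populations[s]
    j <- (2 - s) * 3 # other site block
    A[i + 1, j + 1] <- k
    A[i + 2, j + 2] <- k
    A[i + 3, j + 3] <- k
  }
  A
}

# expm(A*t) %*% m0 through eigendecomposition (fast; the Bloch-McConnell
# generator is generically diagonalizable), falling back to a
# scaling-and-squaring matrix exponential when the eigenbasis is
# ill-conditioned.
.bm_propagate <- function(A, t, m0) {
  e <- tryCatch(eigen(A), error = function(err) NULL)
  if (!is.null(e)) {
    co <- tryCatch(solve(e$vectors, m0), error = function(err) NULL)
    if (!is.null(co)) {
      out <- Re(e$vectors %*% (exp(e$values * t) * co))
      if (all(is.finite(out))) return(drop(out))
    }
  }
  drop(as.matrix(Matrix::expm(Matrix::Matrix(A * t))) %*% m0)
}

#' Simulate a CEST profile under two-site symmetric exchange
#'
#' Propagates the six-component magnetisation (x, y, z per site) under the
#' Bloch-McConnell evolution matrix - relaxation, saturation-field nutation,
#' resonance-offset precession and symmetric exchange at `k_ex/2` per
#' direction - for the saturation time `T_sat` via a matrix exponential, at
#' each requested saturation offset. Intensities are total z-magnetisation
#' normalised to the no-saturation (`T_sat` = 0) reference; since the spins
#' start at thermal equilibrium and relax toward it, the far-off-resonance
#' baseline sits near 1.
#'
#' @param model An [exchange_model()].
#' @param offsets_ppm Saturation offsets, ppm (strictly monotone).
#' @return Tibble with columns `offset_ppm`, `intensity`; attribute `model`
#'   holds the generating model.
#' @export
simulate_cest_profile <- function(model, offsets_ppm) {
  stopifnot(inherits(model, "exchange_model"))
  if (length(offsets_ppm) < 1) abort("need at least one offset")
  if (length(offsets_ppm) > 1 && !(all(diff(offsets_ppm) > 0) ||
                                   all(diff(offsets_ppm) < 0))) {
    abort("`offsets_ppm` must be strictly monotone")
  }
  m0 <- c(0, 0, model$populations[1], 0, 0, model$populations[2], 1)
  intensity <- vapply(offsets_ppm, function(off) {
    A <- .bm_matrix(model, off)
    mt <- .bm_propagate(A, model$T_sat, m0)
    if (any(!is.finite(mt))) {
      abort(paste0("non-finite Bloch-McConnell propagator at offset ",
                   off, " ppm"))
    }
    (mt[3] + mt[6]) / sum(model$populations)
  }, numeric(1))
  out <- tibble(offset_ppm = offsets_ppm, intensity = intensity)
  attr(out, "model") <- model
  class(out) <- c("absalt_cest_profile", class(out))
  out
}

.check_profile <- function(profile) {
  miss <- setdiff(c("offset_ppm", "intensity"), names(profile))
  if (length(miss) > 0) {
    abort(paste0("profile missing column(s): ", paste(miss, collapse = ", ")))
  }
  d <- diff(profile$offset_ppm)
  if (length(d) > 0 && !(all(d > 0) || all(d < 0))) {
    abort("profile offsets must be strictly monotone")
  }
  invisible(profile)
}

#' Fit a CEST profile with the two-site symmetric exchange model
#'
#' Nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nls.lm()]) over
#' `(k_ex, delta_omega, center_ppm)` with fixed relaxation/acquisition
#' parameters and a multi-start grid over exchange parameters; the best
#' converged start (lowest residual sum of squares) is returned with
#' covariance-based standard errors.
#'
#' @param profile Data frame with columns `offset_ppm`, `intensity`
#'   (>= 8 points).
#' @param fixed Named list overriding the fixed model parameters
#'   `R1`, `R2`, `B1_sat`, `T_sat`, `freq_MHz` (defaults as in
#'   [exchange_model()]).
#' @param starts Data frame of starting values with columns `k_ex`,
#'   `delta_omega`; default grid k_ex in \{50, 200, 500, 1000\} 1/s crossed
#'   with delta_omega in \{500, 1000, 2000\} rad/s.
#' @param center_start Starting value for `center_ppm`; default the offset
#'   of the profile minimum.
#' @return Object of class `cest_fit`: a list with `estimates` (tibble of
#'   term/estimate/std.error), the fitted `model`, `rss`, `converged`,
#'   `multi_start` log (one row per start), the `fixed` parameters, and the
#'   input `profile` with fitted values. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
fit_cest_profile <- function(profile, fixed = list(), starts = NULL,
                             center_start = NULL) {
  .check_profile(profile)
  if (nrow(profile) < 8) abort("need >= 8 profile points to fit")
  rng <- diff(range(profile$intensity))
  if (rng < 0.02) abort("no exchange information: profile is flat")
  fx <- utils::modifyList(
    list(R1 = 1.5, R2 = 30, B1_sat = 25, T_sat = 0.4, freq_MHz = 81.1), fixed
  )
  starts <- starts %||% expand.grid(k_ex = c(50, 200, 500, 1000),
                                    delta_omega = c(500, 1000, 2000))
  center_start <- center_start %||%
    profile$offset_ppm[which.min(profile$intensity)]

  resid_fun <- function(par) {
    m <- exchange_model(k_ex = max(par[1], 0), delta_omega = par[2],
                        center_ppm = par[3], R1 = fx$R1, R2 = fx$R2,
                        B1_sat = fx$B1_sat, T_sat = fx$T_sat,
                        freq_MHz = fx$freq_MHz)
    simulate_cest_profile(m, profile$offset_ppm)$intensity - profile$intensity
  }

  log_rows <- vector("list", nrow(starts))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    par0 <- c(k_ex = starts$k_ex[i], delta_omega = starts$delta_omega[i],
              center_ppm = center_start)
    res <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fun,
                         lower = c(0, 1e-6, min(profile$offset_ppm)),
                         upper = c(Inf, Inf, max(profile$offset_ppm)),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    ok <- !is.null(res) && res$info %in% 1:4
    log_rows[[i]] <- tibble(
      start_k_ex = par0[1], start_delta_omega = par0[2],
      converged = ok,
      rss = if (!is.null(res)) res$deviance else NA_real_,
      k_ex = if (!is.null(res)) unname(res$par[1]) else NA_real_,
      delta_omega = if (!is.null(res)) unname(res$par[2]) else NA_real_,
      center_ppm = if (!is.null(res)) unname(res$par[3]) else NA_real_
    )
    if (ok && (is.null(best) || res$deviance < best$deviance)) best <- res
  }
  multi_start <- dplyr::bind_rows(log_rows)
  if (is.null(best)) {
    abort(paste0("no start converged; inspect the start grid and fixed ",
                 "parameters (", nrow(starts), " starts tried)"))
  }
  par <- best$par
  se <- tryCatch({
    s2 <- best$deviance / (nrow(profile) - length(par))
    sqrt(pmax(diag(solve(best$hessian)) * s2, 0))
  }, error = function(e) rep(NA_real_, length(par)))
  model <- exchange_model(k_ex = unname(par[1]), delta_omega = unname(par[2]),
                          center_ppm = unname(par[3]), R1 = fx$R1, R2 = fx$R2,
                          B1_sat = fx$B1_sat, T_sat = fx$T_sat,
                          freq_MHz = fx$freq_MHz)
  fitted_profile <- dplyr::mutate(
    as_tibble(profile),
    fitted = simulate_cest_profile(model, profile$offset_ppm)$intensity
  )
  structure(
    list(
      estimates = tibble(
        term = c("k_ex", "delta_omega", "center_ppm"),
        estimate = unname(par),
        std.error = unname(se)
      ),
      model = model,
      rss = best$deviance,
      converged = TRUE,
      n_points = nrow(profile),
      multi_start = multi_start,
      fixed = fx,
      convention = "k_ex is the sum of forward and backward rates; delta_omega in rad/s",
      profile = fitted_profile
    ),
    class = "cest_fit"
  )
}

#' @export
print.cest_fit <- function(x, ...) {
  cat("Two-site symmetric-exchange CEST fit\n")
  cat(sprintf("  k_ex        %.4g +/- %.2g 1/s\n",
              x$estimates$estimate[1], x$estimates$std.error[1]))
  cat(sprintf("  delta_omega %.4g +/- %.2g rad/s\n",
              x$estimates$estimate[2], x$estimates$std.error[2]))
  cat(sprintf("  center      %.4f ppm\n", x$estimates$estimate[3]))
  cat(sprintf("  rss %.3g over %d points; %d/%d starts converged\n",
              x$rss, x$n_points, sum(x$multi_start$converged),
              nrow(x$multi_start)))
  cat(" ", x$convention, "\n")
  invisible(x)
}

#' Detect saturation-transfer dips in a CEST profile
#'
#' Finds local minima of the (optionally smoothed) profile that are deeper
#' than `depth_threshold` below the local baseline, where the local baseline
#' of a minimum is the lower of the two maxima flanking it. The deepest dip
#' is labelled `major`, remaining dips `minor`; output is ordered by depth.
#'
#' @param profile Data frame with `offset_ppm`, `intensity` (>= 5 points).
#' @param depth_threshold Minimum dip depth (intensity units, relative to
#'   local baseline). Default 0.05.
#' @param smooth_window Odd window length for moving-average smoothing;
#'   1 (default) disables smoothing. Must not exceed the profile length.
#' @return Tibble with columns `position_ppm`, `depth`, `label`.
#' @export
detect_dips <- function(profile, depth_threshold = 0.05, smooth_window = 1) {
  .check_profile(profile)
  if (nrow(profile) < 5) abort("need >= 5 points for dip detection")
  n <- nrow(profile)
  if (smooth_window > n) abort("`smooth_window` larger than profile")
  if (smooth_window %% 2 == 0) abort("`smooth_window` must be odd")
  ord <- order(profile$offset_ppm)
  off <- profile$offset_ppm[ord]
  y <- profile$intensity[ord]
  if (smooth_window > 1) {
    sm <- stats::filter(y, rep(1 / smooth_window, smooth_window), sides = 2)
    y <- ifelse(is.na(sm), y, as.numeric(sm))
  }
  is_min <- vapply(seq_len(n), function(i) {
    if (i == 1 || i == n) return(FALSE)
    y[i] <= y[i - 1] && y[i] <= y[i + 1] && (y[i] < y[i - 1] || y[i] < y[i + 1])
  }, logical(1))
  idx <- which(is_min)
  if (length(idx) == 0) {
    return(tibble(position_ppm = numeric(0), depth = numeric(0),
                  label = character(0)))
  }
  depth <- vapply(idx, function(i) {
    left_max <- max(y[1:i])
    right_max <- max(y[i:n])
    min(left_max, right_max) - y[i]
  }, numeric(1))
  keep <- depth > depth_threshold
  out <- tibble(position_ppm = off[idx[keep]], depth = depth[keep]) |>
    dplyr::arrange(dplyr::desc(.data$depth))
  out$label <- if (nrow(out) > 0) c("major", rep("minor", nrow(out) - 1)) else character(0)
  out
}
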