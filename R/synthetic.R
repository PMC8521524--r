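# Synthetic-data generators with machine-readable ground truth. These stand
# in for the study's unreleased inputs (pressure-series NMR shift tables, the
# MD conformer ensemble, CEST profiles, DFT energy tables) so that every
# estimator in the package can be validated by planted-truth recovery.
#
# Generator defaults encode the study conditions: bridge occupancies 14% / 10%
# / 6% / 2% for Arg5 with Asp7 / Glu3 / Glu11 / Asp1, a 0.3% double-bridge
# fraction, and bridge-conditional Glu3-Ser8 C-alpha distance laws
# N(1.25, 0.05) nm (bridged) vs N(1.39, 0.05) nm (unbridged).

.with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

.res3 <- function(sequence) unname(AA_1TO3[strsplit(sequence, "")[[1]]])

#' Generate a synthetic pressure-series chemical-shift table
#'
#' Evaluates the quadratic pressure model
#' `delta(p) = delta0 + B1 (p-p0)/1000 + B2 ((p-p0)/1000)^2` for each truth
#' row at the given pressures and adds Gaussian noise. Where the truth table
#' carries an `intensity_slope` column, a matching `intensity` column
#' (linear in pressure, baseline 1 at `p0`) is generated too.
#'
#' @param truths Data frame with columns `residue_index`, `residue_name`,
#'   `nucleus`, `delta0`, `B1` (ppm/kbar), `B2` (ppm/kbar^2) and optionally
#'   `intensity_slope` (per kbar). Default: a small amide-nitrogen set
#'   emulating the mixed positive/negative/near-zero pressure response of
#'   the amyloid-beta N-terminus.
#' @param pressures Pressure points in bar; default `c(1, 500, 1000, 1500,
#'   2000)`.
#' @param noise_sd Gaussian noise on shifts, ppm. Default 0.
#' @param p0 Expansion pressure, bar.
#' @param seed Optional integer seed; the same seed reproduces the table
#'   exactly.
#' @return Tibble in the long shift-table layout accepted by
#'   [fit_pressure_coefficients()], with a `truth` attribute (list holding
#'   the truth table, seed, and generation parameters).
#' @export
gen_shift_table <- function(truths = NULL, pressures = c(1, 500, 1000, 1500, 2000),
                            noise_sd = 0, p0 = 1, seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  truths <- truths %||% tibble(
    residue_index = c(3L, 5L, 6L, 7L, 8L, 13L, 14L, 20L),
    residue_name = c("GLU", "ARG", "HIS", "ASP", "SER", "HIS", "HIS", "PHE"),
    nucleus = "N",
    delta0 = c(120.3, 121.8, 119.2, 120.9, 117.1, 119.8, 120.2, 121.5),
    B1 = c(0.45, -0.80, -0.65, 0.55, 0.60, -0.50, -0.45, 0.05),
    B2 = c(-0.10, 0.15, 0.12, -0.12, -0.14, 0.10, 0.09, 0.00)
  )
  .with_seed(seed, {
    out <- tidyr::crossing(truths, pressure_bar = pressures) |>
      dplyr::mutate(
        x = (.data$pressure_bar - p0) / 1000,
        shift_ppm = .data$delta0 + .data$B1 * .data$x + .data$B2 * .data$x^2 +
          rnorm(dplyr::n(), 0, noise_sd)
      )
    if ("intensity_slope" %in% names(truths)) {
      out <- dplyr::mutate(out, intensity = 1 + .data$intensity_slope * .data$x)
    }
    out <- out |>
      dplyr::select(-dplyr::any_of(c("x", "delta0", "B1", "B2",
                                     "intensity_slope"))) |>
      dplyr::arrange(.data$residue_index, .data$nucleus, .data$pressure_bar)
    attr(out, "truth") <- list(kind = "shift_table", seed = seed, p0 = p0,
                               noise_sd = noise_sd, truths = truths)
    out
  })
}

# Local-frame templates for planted groups. The guanidinium sits in the z = 0
# plane with CZ at (4,0,0) relative to the donor C-alpha, NE pointing back
# toward the backbone and NH1/NH2 at +/-60 degrees.
.gdm_local <- function() {
  cz <- c(4, 0, 0)
  rbind(
    CZ = cz,
    NE = cz + 1.33 * c(-1, 0, 0),
    NH1 = cz + 1.33 * c(cos(pi / 3), sin(pi / 3), 0),
    NH2 = cz + 1.33 * c(cos(pi / 3), -sin(pi / 3), 0)
  )
}

# Carboxylate (C, O1, O2) in the guanidinium local frame realising the
# requested interaction mode at N...O contact distance d (angstrom).
.carb_local <- function(mode, d) {
  if (mode %in% c("side_on", "end_on")) {
    y_o <- 1.10
    nh_y <- 1.33 * sin(pi / 3)
    x_o <- 1.33 * cos(pi / 3) + sqrt(d^2 - (nh_y - y_o)^2)
    m <- rbind(
      C = c(x_o + sqrt(1.25^2 - y_o^2), 0, 0),
      O1 = c(x_o, y_o, 0),
      O2 = c(x_o, -y_o, 0)
    )
    if (mode == "end_on") {
      # rotate by +120 deg about z: the contacted nitrogens become NE and NH1
      th <- 2 * pi / 3
      R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
      m <- m %*% t(R)
      rownames(m) <- c("C", "O1", "O2")
    }
  } else if (mode == "backside") {
    o1 <- c(-(1.33 + d), 0, 0)
    cc <- o1 + 1.25 * c(-1, 0, 0)
    o2 <- cc + 1.25 * c(cos(126 * pi / 180), sin(126 * pi / 180), 0)
    m <- rbind(C = cc, O1 = o1, O2 = o2)
  } else {
    abort(paste0("unknown interaction mode: ", mode))
  }
  sweep(m, 2, c(4, 0, 0), "+") # shift into the CZ-at-(4,0,0) frame
}

.random_rotation <- function() {
  # uniform rotation from a normalised quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

.rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# C-alpha random walk with approximate self-avoidance: fixed step length,
# non-neighbour (|i-j| >= 2) pairs kept >= min_sep apart by per-step
# rejection, restarting the walk when the retry budget is exhausted.
.self_avoiding_walk <- function(n, step = 3.8, min_sep = 4, max_retries = 1000) {
  for (attempt in 1:100) {
    pos <- matrix(0, n, 3)
    pos[2, ] <- step * .rand_unit()
    retries <- 0L
    ok <- TRUE
    i <- 3L
    while (i <= n) {
      cand <- pos[i - 1, ] + step * .rand_unit()
      prev <- pos[1:(i - 2), , drop = FALSE]
      d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
        (prev[, 3] - cand[3])^2
      if (min(d2) >= min_sep^2) {
        pos[i, ] <- cand
        i <- i + 1L
      } else {
        retries <- retries + 1L
        if (retries > max_retries) { ok <- FALSE; break }
      }
    }
    if (ok) return(pos)
  }
  abort("self-avoiding walk failed repeatedly; relax `min_sep` or `step`")
}

#' Generate a reduced-atom conformer ensemble with planted salt bridges
#'
#' Builds `n_conformers` conformers of a 40-residue peptide as C-alpha
#' random walks (3.8 angstrom steps, approximate self-avoidance) decorated
#' with idealised functional groups: one arginine guanidinium (CZ, NE, NH1,
#' NH2) on the donor residue and side-chain carboxylates on every Asp/Glu.
#' For conformers drawn (independent Bernoulli) to carry a bridge, the
#' acceptor carboxylate is placed so the requested mode's contact pattern is
#' met at an N...O distance drawn uniformly from `contact_range`; unbridged
#' carboxylates are kept clear of the guanidinium. The C-alpha distance of
#' `ca_pair` is then adjusted to a draw from the bridged or unbridged
#' conditional law, emulating bridge-coupled N-terminal compaction.
#'
#' @param n_conformers Number of conformers (>= 1).
#' @param seed Optional integer seed.
#' @param sequence 1-letter peptide sequence; default the amyloid-beta(1-40)
#'   sequence.
#' @param donor Donor (Arg) residue index; default 5.
#' @param bridges Data frame with columns `acceptor`, `mode`, `occupancy`;
#'   default plants side-on bridges on Asp7/Glu3/Glu11/Asp1 at occupancies
#'   0.14/0.10/0.06/0.02.
#' @param double_bridge List with `acceptors` (length 2), `fraction`, and
#'   `modes` (modes used when both bridges are present); default Glu3+Asp7
#'   at 0.003 with a backside Glu3 and side-on Asp7 contact. Set
#'   `fraction = 0` to disable. The double-bridge draw is taken first and
#'   the marginal occupancies are preserved by rescaling the single-bridge
#'   probabilities.
#' @param ca_pair Residue pair whose conditional C-alpha distance is
#'   planted; default `c(3, 8)`.
#' @param ca_condition_acceptors Acceptor residues whose bridges define the
#'   "bridged" state for the compaction law; default `c(3, 7)`.
#' @param ca_bridged,ca_unbridged `c(mean, sd)` in nm of the conditional
#'   distance law given that any `donor`-Glu3 or `donor`-Asp7 bridge is
#'   present / absent; defaults `c(1.25, 0.05)` and `c(1.39, 0.05)`.
#' @param contact_range Range (angstrom) from which planted N...O contact
#'   distances are drawn; default `c(2.8, 3.2)`, inside the 3.5 angstrom
#'   detection cutoff.
#' @param step,min_sep C-alpha step length and non-neighbour minimum
#'   distance (angstrom) of the random walk.
#' @param max_retries Per-conformer step-retry budget before the walk is
#'   restarted.
#' @return Tidy atom tibble (`conformer_id`, `residue_index`,
#'   `residue_name`, `atom_name`, `x`, `y`, `z`) with attribute `truth`, a
#'   list holding the per-conformer planted bridge table (`bridges`:
#'   `conformer_id`, `acceptor`, `mode`), the per-conformer compaction table
#'   (`ca`: `conformer_id`, `bridged`, `target_nm`), the seed and the
#'   configuration.
#' @export
gen_ensemble <- function(n_conformers, seed = NULL, sequence = AB40_SEQUENCE,
                         donor = 5,
                         bridges = NULL,
                         double_bridge = list(acceptors = c(3, 7),
                                              fraction = 0.003,
                                              modes = c("backside", "side_on")),
                         ca_pair = c(3, 8),
                         ca_condition_acceptors = c(3, 7),
                         ca_bridged = c(1.25, 0.05),
                         ca_unbridged = c(1.39, 0.05),
                         contact_range = c(2.8, 3.2),
                         step = 3.8, min_sep = 4, max_retries = 1000) {
  if (n_conformers < 1) abort("`n_conformers` must be >= 1")
  res3 <- .res3(sequence)
  n_res <- length(res3)
  if (res3[donor] != "ARG") abort(paste0("donor residue ", donor, " is not ARG"))
  bridges <- bridges %||% tibble(
    acceptor = c(7L, 3L, 11L, 1L),
    mode = "side_on",
    occupancy = c(0.14, 0.10, 0.06, 0.02)
  )
  if (any(bridges$occupancy < 0 | bridges$occupancy > 1)) {
    abort("bridge occupancies must be in [0, 1]")
  }
  acc_names <- res3[bridges$acceptor]
  if (!all(acc_names %in% c("ASP", "GLU"))) {
    abort("all bridge acceptors must be ASP or GLU residues")
  }
  p_both <- 0
  if (!is.null(double_bridge) && double_bridge$fraction > 0) {
    p_both <- double_bridge$fraction
    if (length(double_bridge$acceptors) != 2 ||
        !all(double_bridge$acceptors %in% bridges$acceptor)) {
      abort("`double_bridge$acceptors` must name two acceptors listed in `bridges`")
    }
    in_double <- bridges$acceptor %in% double_bridge$acceptors
    if (any(bridges$occupancy[in_double] < p_both)) {
      abort(paste0("infeasible joint constraint: double-bridge fraction ",
                   p_both, " exceeds a marginal occupancy of an acceptor in ",
                   paste(double_bridge$acceptors, collapse = "/")))
    }
  }

  # side-chain carboxylates only; the backbone C-terminal carboxylate is not
  # part of the reduced-atom representation
  carb_res <- which(res3 %in% c("ASP", "GLU"))
  # roster metadata (identical across conformers)
  atom_res <- c(seq_len(n_res), rep(donor, 4L),
                rep(carb_res, each = 3L))
  atom_name <- c(rep("CA", n_res), c("CZ", "NE", "NH1", "NH2"),
                 unlist(lapply(res3[carb_res],
                               function(rn) unname(.carboxylate_atoms(rn)))))
  atom_resname <- res3[atom_res]
  n_atoms <- length(atom_res)
  gdm_tpl <- .gdm_local()

  .with_seed(seed, {
    coords <- vector("list", n_conformers)
    truth_bridges <- vector("list", n_conformers)
    ca_bridged_flag <- logical(n_conformers)
    ca_target <- numeric(n_conformers)

    for (cf in seq_len(n_conformers)) {
      ca <- .self_avoiding_walk(n_res, step, min_sep, max_retries)

      # planted-bridge draw. The two double-bridge acceptors follow a joint
      # law realising P(both) = fraction exactly while preserving the
      # marginal occupancies (the paper's joint fraction is smaller than the
      # independence product, so the coupling is anti-correlated); all other
      # acceptors are independent Bernoulli draws.
      planted_mode <- rep(NA_character_, nrow(bridges))
      joint_idx <- integer(0)
      if (p_both > 0) {
        joint_idx <- match(double_bridge$acceptors, bridges$acceptor)
        p1 <- bridges$occupancy[joint_idx[1]]
        p2 <- bridges$occupancy[joint_idx[2]]
        if (p1 + p2 - p_both > 1) {
          abort("infeasible joint constraint: marginal occupancies and double-bridge fraction exceed 1")
        }
        u <- runif(1)
        if (u < p_both) {
          planted_mode[joint_idx] <- double_bridge$modes
        } else if (u < p1) {
          planted_mode[joint_idx[1]] <- bridges$mode[joint_idx[1]]
        } else if (u < p1 + p2 - p_both) {
          planted_mode[joint_idx[2]] <- bridges$mode[joint_idx[2]]
        }
      }
      for (b in setdiff(seq_len(nrow(bridges)), joint_idx)) {
        if (runif(1) < bridges$occupancy[b]) planted_mode[b] <- bridges$mode[b]
      }

      rot <- .random_rotation()
      ca_d <- ca[donor, ]
      gdm_world <- gdm_tpl %*% t(rot) + matrix(ca_d, 4, 3, byrow = TRUE)

      carb_world <- matrix(NA_real_, 3 * length(carb_res), 3)
      for (ci in seq_along(carb_res)) {
        rr <- carb_res[ci]
        b <- match(rr, bridges$acceptor)
        mode_here <- if (!is.na(b)) planted_mode[b] else NA_character_
        rows <- (ci - 1) * 3 + 1:3
        if (!is.na(mode_here)) {
          d <- runif(1, contact_range[1], contact_range[2])
          loc <- .carb_local(mode_here, d)
          carb_world[rows, ] <- loc %*% t(rot) +
            matrix(ca_d, 3, 3, byrow = TRUE)
        } else {
          cz <- gdm_world[1, ]
          placed <- FALSE
          for (try in 1:50) {
            cc <- ca[rr, ] + 3 * .rand_unit()
            oo <- .carb_oxygens(cc)
            dmin <- min(.min_no_dist(gdm_world[2:4, ], oo))
            if (dmin > 4.0) {
              carb_world[rows, ] <- rbind(cc, oo)
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            cc <- cz + 8 * .rand_unit()
            carb_world[rows, ] <- rbind(cc, .carb_oxygens(cc))
          }
        }
      }

      # bridge-coupled compaction of the ca_pair distance, conditioned on a
      # bridge to either residue named in `ca_condition_acceptors`
      bridged <- any(!is.na(
        planted_mode[bridges$acceptor %in% ca_condition_acceptors]
      ))
      law <- if (bridged) ca_bridged else ca_unbridged
      tgt_nm <- max(rnorm(1, law[1], law[2]), 0.3)
      v <- ca[ca_pair[2], ] - ca[ca_pair[1], ]
      ca[ca_pair[2], ] <- ca[ca_pair[1], ] + v / sqrt(sum(v^2)) * (10 * tgt_nm)

      coords[[cf]] <- rbind(ca, gdm_world, carb_world)
      ca_bridged_flag[cf] <- bridged
      ca_target[cf] <- tgt_nm
      keep <- !is.na(planted_mode)
      truth_bridges[[cf]] <- if (any(keep)) {
        tibble(conformer_id = cf, acceptor = bridges$acceptor[keep],
               mode = planted_mode[keep])
      } else NULL
    }

    xyz <- do.call(rbind, coords)
    dimnames(xyz) <- NULL
    out <- tibble(
      conformer_id = rep(seq_len(n_conformers), each = n_atoms),
      residue_index = rep(as.integer(atom_res), n_conformers),
      residue_name = rep(atom_resname, n_conformers),
      atom_name = rep(atom_name, n_conformers),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
    )
    attr(out, "truth") <- list(
      kind = "ensemble", seed = seed,
      donor = donor,
      bridges = {
        tb <- dplyr::bind_rows(truth_bridges)
        if (nrow(tb) == 0) {
          tb <- tibble(conformer_id = integer(0), acceptor = integer(0),
                       mode = character(0))
        }
        tb
      },
      ca = tibble(conformer_id = seq_len(n_conformers),
                  bridged = ca_bridged_flag, target_nm = ca_target),
      config = list(n_conformers = n_conformers, bridge_spec = bridges,
                    double_bridge = double_bridge, ca_pair = ca_pair,
                    ca_bridged = ca_bridged, ca_unbridged = ca_unbridged,
                    contact_range = contact_range, step = step,
                    min_sep = min_sep)
    )
    out
  })
}

# idealised oxygens around a carboxylate carbon in a random plane, 126 deg apart
.carb_oxygens <- function(cc) {
  u <- .rand_unit()
  w <- .rand_unit()
  w <- w - sum(w * u) * u
  w <- w / sqrt(sum(w^2))
  half <- 63 * pi / 180
  rbind(cc + 1.25 * (cos(half) * u + sin(half) * w),
        cc + 1.25 * (cos(half) * u - sin(half) * w))
}

.min_no_dist <- function(nmat, omat) {
  d <- numeric(nrow(nmat) * nrow(omat))
  k <- 1L
  for (i in seq_len(nrow(nmat))) for (j in seq_len(nrow(omat))) {
    d[k] <- sqrt(sum((nmat[i, ] - omat[j, ])^2))
    k <- k + 1L
  }
  d
}

#' Generate a synthetic CEST profile with known exchange truth
#'
#' Simulates the two-site symmetric-exchange profile for `model` at the
#' given offsets and adds Gaussian intensity noise.
#'
#' @param model An [exchange_model()]; default the free-arginine reference
#'   truth (`k_ex` 356 1/s, `delta_omega` 1214 rad/s, centred at 71 ppm).
#' @param offsets_ppm Saturation offset grid; default 60 to 90 ppm in
#'   0.25 ppm steps.
#' @param noise_sd Gaussian noise on normalised intensities; default 0.
#' @param seed Optional integer seed.
#' @return Tibble `offset_ppm`, `intensity` with attribute `truth`.
#' @export
gen_cest_profile <- function(model = exchange_model(k_ex = 356, delta_omega = 1214),
                             offsets_ppm = seq(60, 90, by = 0.25),
                             noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  clean <- simulate_cest_profile(model, offsets_ppm)
  .with_seed(seed, {
    out <- dplyr::mutate(
      as_tibble(clean),
      intensity = .data$intensity + rnorm(dplyr::n(), 0, noise_sd)
    )
    attr(out, "truth") <- list(kind = "cest_profile", seed = seed,
                               noise_sd = noise_sd,
                               model = unclass(model))
    out
  })
}

#' Generate a synthetic per-conformer phosphorylation energy table
#'
#' Draws per-conformer phosphorylation energy differences
#' `dE = E_phos - E_nonphos` from Gaussian group laws and attaches them to a
#' common baseline energy, producing the input layout of [group_stats()].
#'
#' @param groups Data frame with columns `group`, `n`, `mean_dE`, `sd_dE`
#'   (hartrees). Default: three groups shaped like a
#'   both-bridges/one-bridge/control comparison (means -567.268, -567.291,
#'   -567.303; sds 0.065, 0.026, 0.023; n 7, 8, 12).
#' @param base_energy Mean nonphosphorylated total energy, hartrees
#'   (arbitrary; cancels in all statistics). Default -9000.
#' @param base_sd Spread of the nonphosphorylated energies, hartrees.
#' @param seed Optional integer seed.
#' @return Tibble `conformer_id`, `group`, `E_phos`, `E_nonphos` with
#'   attribute `truth`.
#' @export
gen_energy_table <- function(groups = NULL, base_energy = -9000, base_sd = 0.5,
                             seed = NULL) {
  groups <- groups %||% tibble(
    group = c("test_both_bridges", "test_d7_only", "control"),
    n = c(7L, 8L, 12L),
    mean_dE = c(-567.268, -567.291, -567.303),
    sd_dE = c(0.065, 0.026, 0.023)
  )
  .with_seed(seed, {
    out <- groups |>
      dplyr::rowwise() |>
      dplyr::mutate(dE = list(rnorm(.data$n, .data$mean_dE, .data$sd_dE))) |>
      dplyr::ungroup() |>
      dplyr::select("group", "dE") |>
      tidyr::unnest("dE") |>
      dplyr::mutate(
        conformer_id = dplyr::row_number(),
        E_nonphos = rnorm(dplyr::n(), base_energy, base_sd),
        E_phos = .data$E_nonphos + .data$dE
      ) |>
      dplyr::select("conformer_id", "group", "E_phos", "E_nonphos")
    attr(out, "truth") <- list(kind = "energy_table", seed = seed,
                               groups = groups, base_energy = base_energy,
                               base_sd = base_sd)
    out
  })
}
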