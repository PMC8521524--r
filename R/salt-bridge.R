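# Salt-bridge geometry: guanidinium/carboxylate group extraction, interaction
# mode classification, and ensemble-level occupancy statistics.
#
# An ensemble is a tidy atom table: one row per atom per conformer, columns
# conformer_id, residue_index, residue_name, atom_name, x, y, z (angstrom).

GDM_ATOMS <- c("CZ", "NE", "NH1", "NH2")

.carboxylate_atoms <- function(residue_name) {
  switch(residue_name,
    ASP = c(C = "CG", O1 = "OD1", O2 = "OD2"),
    GLU = c(C = "CD", O1 = "OE1", O2 = "OE2"),
    abort(paste0("residue ", residue_name, " carries no side-chain carboxylate"))
  )
}

.check_ensemble <- function(ensemble) {
  req <- c("conformer_id", "residue_index", "residue_name", "atom_name",
           "x", "y", "z")
  miss <- setdiff(req, names(ensemble))
  if (length(miss) > 0) {
    abort(paste0("ensemble missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(ensemble) == 0) abort("empty ensemble")
  rosters <- ensemble |>
    dplyr::group_by(.data$conformer_id) |>
    dplyr::summarise(
      roster = paste(.data$residue_index, .data$atom_name, collapse = ";"),
      .groups = "drop"
    )
  if (dplyr::n_distinct(rosters$roster) != 1) {
    bad <- rosters$conformer_id[which(rosters$roster != rosters$roster[1])[1]]
    abort(paste0("atom roster differs across conformers (first mismatch: ",
                 "conformer ", bad, ")"))
  }
  invisible(ensemble)
}

#' Extract guanidinium and carboxylate groups from one conformer
#'
#' Locates the arginine guanidinium group (CZ, NE, NH1, NH2) and the
#' side-chain carboxylate groups of aspartate (CG, OD1, OD2) and glutamate
#' (CD, OE1, OE2) in a single conformer, checking that bonded heavy-atom
#' distances within each group are below 1.6 angstrom. Residues with missing
#' or mis-bonded group atoms are skipped with a warning. The C-terminal
#' backbone carboxylate is not considered (side-chain groups only).
#'
#' @param conformer Atom table for one conformer (columns `residue_index`,
#'   `residue_name`, `atom_name`, `x`, `y`, `z`).
#' @return A list with tibbles `guanidinium` (one row per arginine; columns
#'   `residue_index` and `<atom>_x/_y/_z` for CZ, NE, NH1, NH2) and
#'   `carboxylate` (one row per Asp/Glu; `residue_index`, `residue_name`,
#'   `C_/O1_/O2_` coordinates).
#' @export
extract_groups <- function(conformer) {
  stopifnot(is.data.frame(conformer))
  gdm <- .collect_groups(conformer, "ARG",
                         c(CZ = "CZ", NE = "NE", NH1 = "NH1", NH2 = "NH2"),
                         bond_pairs = list(c("NE", "CZ"), c("NH1", "CZ"),
                                           c("NH2", "CZ")))
  carb <- dplyr::bind_rows(
    .collect_groups(conformer, "ASP", .carboxylate_atoms("ASP"),
                    bond_pairs = list(c("O1", "C"), c("O2", "C"))),
    .collect_groups(conformer, "GLU", .carboxylate_atoms("GLU"),
                    bond_pairs = list(c("O1", "C"), c("O2", "C")))
  )
  if (nrow(carb) > 0) carb <- dplyr::arrange(carb, .data$residue_index)
  list(guanidinium = gdm, carboxylate = carb)
}

# One row per residue of `resname` having all atoms in `atom_map`
# (names = roles, values = PDB atom names); bonded roles must be < 1.6 A apart.
.collect_groups <- function(conformer, resname, atom_map, bond_pairs) {
  res <- conformer |>
    dplyr::filter(.data$residue_name == resname,
                  .data$atom_name %in% atom_map)
  empty <- tibble(residue_index = integer(0), residue_name = character(0))
  for (role in names(atom_map)) {
    empty[[paste0(role, "_x")]] <- numeric(0)
    empty[[paste0(role, "_y")]] <- numeric(0)
    empty[[paste0(role, "_z")]] <- numeric(0)
  }
  if (nrow(res) == 0) return(empty)
  role_of <- setNames(names(atom_map), unname(atom_map))
  res$role <- role_of[res$atom_name]
  wide <- res |>
    dplyr::select("residue_index", "residue_name", "role", "x", "y", "z") |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("x", "y", "z"),
                       names_glue = "{role}_{.value}")
  keep_cols <- as.vector(outer(names(atom_map), c("x", "y", "z"), paste, sep = "_"))
  complete <- stats::complete.cases(wide[, intersect(keep_cols, names(wide))]) &
    all(keep_cols %in% names(wide))
  if (!all(keep_cols %in% names(wide))) complete <- rep(FALSE, nrow(wide))
  bad <- wide$residue_index[!complete]
  wide <- wide[complete, , drop = FALSE]
  # bonded sanity
  if (nrow(wide) > 0) {
    ok <- rep(TRUE, nrow(wide))
    for (bp in bond_pairs) {
      d <- sqrt((wide[[paste0(bp[1], "_x")]] - wide[[paste0(bp[2], "_x")]])^2 +
                (wide[[paste0(bp[1], "_y")]] - wide[[paste0(bp[2], "_y")]])^2 +
                (wide[[paste0(bp[1], "_z")]] - wide[[paste0(bp[2], "_z")]])^2)
      ok <- ok & d < 1.6
    }
    bad <- c(bad, wide$residue_index[!ok])
    wide <- wide[ok, , drop = FALSE]
  }
  if (length(bad) > 0) {
    warn(paste0("skipping ", resname, " residue(s) with incomplete or ",
                "mis-bonded side-chain group: ", paste(sort(bad), collapse = ", ")))
  }
  dplyr::select(wide, "residue_index", "residue_name",
                dplyr::all_of(intersect(keep_cols, names(wide))))
}

# Mode from the six N...O contact booleans. Bidentate requires two nitrogens
# on DISTINCT oxygens; any remaining contact pattern is monodentate toward a
# single oxygen (or a single nitrogen), hence backside.
# Precedence: side_on > end_on > backside.
.mode_from_contacts <- function(ne_o1, ne_o2, nh1_o1, nh1_o2, nh2_o1, nh2_o2) {
  side_on <- (nh1_o1 & nh2_o2) | (nh1_o2 & nh2_o1)
  end_on <- (ne_o1 & (nh1_o2 | nh2_o2)) | (ne_o2 & (nh1_o1 | nh2_o1))
  any_contact <- ne_o1 | ne_o2 | nh1_o1 | nh1_o2 | nh2_o1 | nh2_o2
  dplyr::case_when(
    side_on ~ "side_on",
    end_on ~ "end_on",
    any_contact ~ "backside",
    TRUE ~ "none"
  )
}

#' Classify the interaction mode of a guanidinium/carboxylate pair
#'
#' Evaluates the six heavy-atom N...O distances between the guanidinium
#' nitrogens (NE, NH1, NH2) and the two carboxylate oxygens, and assigns an
#' interaction mode:
#'
#' * `side_on` - bidentate: NH1 and NH2 each contact a distinct oxygen;
#' * `end_on` - bidentate: NE and one NH each contact a distinct oxygen;
#' * `backside` - monodentate: contacts exist but no two nitrogens reach
#'   distinct oxygens (including two nitrogens sharing one oxygen);
#' * `none` - no N...O distance within the cutoff.
#'
#' Precedence is side_on > end_on > backside, reporting the
#' highest-denticity interpretation when several patterns hold at once.
#'
#' @param gdm One-row guanidinium tibble as returned by [extract_groups()].
#' @param carb One-row carboxylate tibble as returned by [extract_groups()].
#' @param cutoff Heavy-atom N...O contact cutoff in angstrom; default 3.5,
#'   a standard salt-bridge criterion. Must be > 0.
#' @return A list with `mode` (character scalar) and `contacts`, a tibble of
#'   the qualifying (nitrogen, oxygen, distance) contacts.
#' @export
classify_mode <- function(gdm, carb, cutoff = 3.5) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 || !is.finite(cutoff) ||
      cutoff <= 0) {
    abort("`cutoff` must be a single positive distance in angstrom")
  }
  stopifnot(nrow(gdm) == 1, nrow(carb) == 1)
  d <- matrix(NA_real_, 3, 2, dimnames = list(c("NE", "NH1", "NH2"), c("O1", "O2")))
  for (n in rownames(d)) for (o in colnames(d)) {
    d[n, o] <- sqrt((gdm[[paste0(n, "_x")]] - carb[[paste0(o, "_x")]])^2 +
                    (gdm[[paste0(n, "_y")]] - carb[[paste0(o, "_y")]])^2 +
                    (gdm[[paste0(n, "_z")]] - carb[[paste0(o, "_z")]])^2)
  }
  ct <- d <= cutoff
  mode <- .mode_from_contacts(ct["NE", "O1"], ct["NE", "O2"],
                              ct["NH1", "O1"], ct["NH1", "O2"],
                              ct["NH2", "O1"], ct["NH2", "O2"])
  idx <- which(ct, arr.ind = TRUE)
  contacts <- tibble(
    donor_atom = rownames(d)[idx[, 1]],
    acceptor_atom = colnames(d)[idx[, 2]],
    distance = d[idx]
  ) |> dplyr::arrange(.data$distance)
  list(mode = mode, contacts = contacts)
}

# Wide per-conformer coordinate matrix for one atom of one residue,
# rows ordered by conformer_id. Returns n_conformer x 3 matrix.
.atom_matrix <- function(ensemble, res_index, atom) {
  sub <- ensemble[ensemble$residue_index == res_index &
                    ensemble$atom_name == atom, ]
  sub <- sub[order(sub$conformer_id), ]
  cbind(sub$x, sub$y, sub$z)
}

.dist2 <- function(a, b) (a[, 1] - b[, 1])^2 + (a[, 2] - b[, 2])^2 + (a[, 3] - b[, 3])^2

#' Scan a conformer ensemble for arginine salt bridges
#'
#' Classifies, in every conformer, the interaction mode of each
#' (arginine donor, Asp/Glu acceptor) pair using [classify_mode()]'s
#' geometric rules, vectorised across the ensemble.
#'
#' @param ensemble Tidy atom table (columns `conformer_id`, `residue_index`,
#'   `residue_name`, `atom_name`, `x`, `y`, `z`) with an identical atom
#'   roster in every conformer, e.g. from [read_ensemble_pdb()] or
#'   [gen_ensemble()].
#' @param cutoff Heavy-atom N...O contact cutoff in angstrom (default 3.5).
#' @param donors Optional integer vector restricting donor (Arg) residue
#'   indices; default all arginines.
#' @param acceptors Optional integer vector restricting acceptor (Asp/Glu)
#'   residue indices; default all aspartates/glutamates.
#' @return A tibble with one row per (conformer, donor, acceptor):
#'   `conformer_id`, `donor`, `acceptor`, `acceptor_name`, `mode`
#'   (`side_on`/`end_on`/`backside`/`none`) and `min_no_dist` (the smallest
#'   of the six N...O distances, angstrom). Attributes `n_conformers` and
#'   `cutoff` are set; class `absalt_bridge_scan`.
#' @examples
#' ens <- gen_ensemble(50, seed = 1)
#' scan_ensemble(ens) |> bridge_occupancy()
#' @export
scan_ensemble <- function(ensemble, cutoff = 3.5, donors = NULL, acceptors = NULL) {
  .check_ensemble(ensemble)
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    abort("`cutoff` must be a single positive distance in angstrom")
  }
  first <- ensemble[ensemble$conformer_id == ensemble$conformer_id[1], ]
  groups <- extract_groups(first)
  gd <- groups$guanidinium
  cb <- groups$carboxylate
  if (!is.null(donors)) gd <- gd[gd$residue_index %in% donors, , drop = FALSE]
  if (!is.null(acceptors)) cb <- cb[cb$residue_index %in% acceptors, , drop = FALSE]
  conformers <- sort(unique(ensemble$conformer_id))
  n <- length(conformers)
  if (nrow(gd) == 0 || nrow(cb) == 0) {
    out <- tibble(conformer_id = integer(0), donor = integer(0),
                  acceptor = integer(0), acceptor_name = character(0),
                  mode = character(0), min_no_dist = numeric(0))
  } else {
    res <- vector("list", nrow(gd) * nrow(cb))
    k <- 1L
    for (i in seq_len(nrow(gd))) {
      di <- gd$residue_index[i]
      NE <- .atom_matrix(ensemble, di, "NE")
      NH1 <- .atom_matrix(ensemble, di, "NH1")
      NH2 <- .atom_matrix(ensemble, di, "NH2")
      for (j in seq_len(nrow(cb))) {
        aj <- cb$residue_index[j]
        an <- cb$residue_name[j]
        amap <- .carboxylate_atoms(an)
        O1 <- .atom_matrix(ensemble, aj, amap[["O1"]])
        O2 <- .atom_matrix(ensemble, aj, amap[["O2"]])
        c2 <- cutoff^2
        d2 <- cbind(.dist2(NE, O1), .dist2(NE, O2),
                    .dist2(NH1, O1), .dist2(NH1, O2),
                    .dist2(NH2, O1), .dist2(NH2, O2))
        ct <- d2 <= c2
        res[[k]] <- tibble(
          conformer_id = conformers,
          donor = di,
          acceptor = aj,
          acceptor_name = an,
          mode = .mode_from_contacts(ct[, 1], ct[, 2], ct[, 3],
                                     ct[, 4], ct[, 5], ct[, 6]),
          min_no_dist = sqrt(pmin(d2[, 1], d2[, 2], d2[, 3],
                                  d2[, 4], d2[, 5], d2[, 6]))
        )
        k <- k + 1L
      }
    }
    out <- dplyr::bind_rows(res) |>
      dplyr::arrange(.data$conformer_id, .data$donor, .data$acceptor)
  }
  attr(out, "n_conformers") <- n
  attr(out, "cutoff") <- cutoff
  class(out) <- c("absalt_bridge_scan", class(out))
  out
}

#' Salt-bridge occupancy and mode breakdown per donor-acceptor pair
#'
#' @param scan Per-conformer assignment tibble from [scan_ensemble()].
#' @return Tibble with one row per (donor, acceptor) pair: `occupancy`
#'   (fraction of conformers with any mode) and per-mode fractions
#'   `f_side_on`, `f_end_on`, `f_backside` (which sum to `occupancy`),
#'   plus `n_conformers`.
#' @export
bridge_occupancy <- function(scan) {
  n <- attr(scan, "n_conformers")
  if (is.null(n)) abort("`scan` must come from scan_ensemble()")
  scan |>
    dplyr::group_by(.data$donor, .data$acceptor, .data$acceptor_name) |>
    dplyr::summarise(
      n_conformers = n,
      occupancy = sum(.data$mode != "none") / n,
      f_side_on = sum(.data$mode == "side_on") / n,
      f_end_on = sum(.data$mode == "end_on") / n,
      f_backside = sum(.data$mode == "backside") / n,
      .groups = "drop"
    )
}

#' Fraction of conformers in which one arginine bridges several acceptors
#'
#' A conformer counts when the donor simultaneously shows a qualifying
#' interaction (any mode) with *every* listed acceptor, e.g. the arginine
#' side chain bridging two carboxylates at once.
#'
#' @param scan Assignment tibble from [scan_ensemble()].
#' @param donor Donor (Arg) residue index.
#' @param acceptors Integer vector of two or more acceptor residue indices.
#' @return One-row tibble: `donor`, `acceptors` (comma-joined), `n_bridging`,
#'   `n_conformers`, `fraction`.
#' @export
simultaneous_bridging <- function(scan, donor, acceptors) {
  n <- attr(scan, "n_conformers")
  if (is.null(n)) abort("`scan` must come from scan_ensemble()")
  if (length(acceptors) < 2) abort("need at least 2 acceptor residues")
  known <- unique(scan$acceptor[scan$donor == donor])
  missing_acc <- setdiff(acceptors, known)
  if (length(missing_acc) > 0) {
    abort(paste0("acceptor residue(s) not scanned as Asp/Glu partners of ",
                 "donor ", donor, ": ", paste(missing_acc, collapse = ", ")))
  }
  hits <- scan |>
    dplyr::filter(.data$donor == !!donor, .data$acceptor %in% acceptors,
                  .data$mode != "none") |>
    dplyr::count(.data$conformer_id) |>
    dplyr::filter(.data$n == length(acceptors))
  tibble(
    donor = donor,
    acceptors = paste(sort(acceptors), collapse = ","),
    n_bridging = nrow(hits),
    n_conformers = n,
    fraction = nrow(hits) / n
  )
}

#' Bridge-conditional C-alpha distance statistics
#'
#' Splits the ensemble into conformers that do / do not carry any of the
#' specified salt bridges and summarises the C-alpha to C-alpha distance of a
#' residue pair in each partition, in nanometres. Used to quantify
#' bridge-coupled N-terminal compaction (e.g. the Glu3-Ser8 distance
#' contracting when an Arg5-based bridge is present).
#'
#' @param ensemble Tidy atom table (must contain `CA` atoms for both
#'   residues in every conformer).
#' @param scan Assignment tibble from [scan_ensemble()] over the same
#'   ensemble.
#' @param bridge_spec Data frame with columns `donor`, `acceptor`: a
#'   conformer is "bridged" when any listed pair has mode != "none".
#' @param residue_pair Integer vector of length 2: the residues whose
#'   C-alpha distance is summarised.
#' @return One-row tibble: `mean_with`, `sd_with`, `n_with`, `mean_without`,
#'   `sd_without`, `n_without` (distances in nm; an empty partition reports
#'   `n = 0` with `NA` mean/sd).
#' @export
conditional_ca_distance <- function(ensemble, scan, bridge_spec, residue_pair) {
  .check_ensemble(ensemble)
  n <- attr(scan, "n_conformers")
  if (is.null(n)) abort("`scan` must come from scan_ensemble()")
  stopifnot(length(residue_pair) == 2)
  if (!all(c("donor", "acceptor") %in% names(bridge_spec))) {
    abort("`bridge_spec` needs columns donor, acceptor")
  }
  ca1 <- .atom_matrix(ensemble, residue_pair[1], "CA")
  ca2 <- .atom_matrix(ensemble, residue_pair[2], "CA")
  if (nrow(ca1) != n || nrow(ca2) != n) {
    abort(paste0("both residues ", residue_pair[1], " and ", residue_pair[2],
                 " must have a CA atom in every conformer"))
  }
  dist_nm <- sqrt(.dist2(ca1, ca2)) / 10
  conformers <- sort(unique(scan$conformer_id))
  bridged_ids <- scan |>
    dplyr::inner_join(dplyr::mutate(as_tibble(bridge_spec),
                                    donor = as.integer(.data$donor),
                                    acceptor = as.integer(.data$acceptor)),
                      by = c("donor", "acceptor")) |>
    dplyr::filter(.data$mode != "none") |>
    dplyr::pull(.data$conformer_id) |>
    unique()
  bridged <- conformers %in% bridged_ids
  summ <- function(v) {
    if (length(v) == 0) return(c(NA_real_, NA_real_, 0))
    c(mean(v), if (length(v) > 1) sd(v) else NA_real_, length(v))
  }
  w <- summ(dist_nm[bridged])
  wo <- summ(dist_nm[!bridged])
  tibble(
    residue_a = residue_pair[1], residue_b = residue_pair[2],
    mean_with = w[1], sd_with = w[2], n_with = as.integer(w[3]),
    mean_without = wo[1], sd_without = wo[2], n_without = as.integer(wo[3])
  )
}
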