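# Shared fixtures: hand-built guanidinium/carboxylate geometries, tiny
# ensembles, and an independent brute-force oracle for the interaction-mode
# precedence rules.

# guanidinium in the z = 0 plane, CZ at origin, NE toward -x, NH1/NH2 at
# +/- 60 degrees
make_gdm <- function(residue_index = 5L) {
  tibble::tibble(
    residue_index = residue_index, residue_name = "ARG",
    CZ_x = 0, CZ_y = 0, CZ_z = 0,
    NE_x = -1.33, NE_y = 0, NE_z = 0,
    NH1_x = 1.33 * cos(pi / 3), NH1_y = 1.33 * sin(pi / 3), NH1_z = 0,
    NH2_x = 1.33 * cos(pi / 3), NH2_y = -1.33 * sin(pi / 3), NH2_z = 0
  )
}

# carboxylate with oxygens at arbitrary positions (carbon placed 1.25 A from
# O1 on the O1->O2 axis' perpendicular is unnecessary for classification, so
# the carbon simply sits between the oxygens, within bonding distance)
make_carb <- function(o1, o2, residue_index = 7L, residue_name = "ASP") {
  cc <- (o1 + o2) / 2
  tibble::tibble(
    residue_index = residue_index, residue_name = residue_name,
    C_x = cc[1], C_y = cc[2], C_z = cc[3],
    O1_x = o1[1], O1_y = o1[2], O1_z = o1[3],
    O2_x = o2[1], O2_y = o2[2], O2_z = o2[3]
  )
}

# Independent oracle for the mode rules: enumerates nitrogen-pair ->
# distinct-oxygen assignments by brute force instead of using boolean
# shortcuts. `ct` is a named logical vector over the six N-O combinations.
oracle_mode <- function(ct) {
  has <- function(n, o) ct[[paste(n, o, sep = "_")]]
  pair_distinct <- function(na, nb) {
    (has(na, "O1") && has(nb, "O2")) || (has(na, "O2") && has(nb, "O1"))
  }
  if (pair_distinct("NH1", "NH2")) return("side_on")
  if (pair_distinct("NE", "NH1") || pair_distinct("NE", "NH2")) return("end_on")
  if (any(unlist(ct))) return("backside")
  "none"
}

# coordinates realising a given contact pattern: contacted oxygens sit 2.9 A
# from their nitrogen along +z (stacked so one oxygen can touch several
# nitrogens only when asked); non-contacted stay 10 A away. Not all 64
# patterns are geometrically realisable with 2 oxygens, so tests that need
# geometry use realisable ones and the full 64 go through the boolean rule.
apply_rigid <- function(df, R, t) {
  out <- df
  for (role in c("CZ", "NE", "NH1", "NH2", "C", "O1", "O2")) {
    cx <- paste0(role, "_x")
    if (!cx %in% names(df)) next
    xyz <- as.matrix(df[, paste0(role, c("_x", "_y", "_z"))])
    new <- xyz %*% t(R) + matrix(t, nrow(df), 3, byrow = TRUE)
    out[, paste0(role, c("_x", "_y", "_z"))] <- new
  }
  out
}

random_rotation_matrix <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# minimal hand-built ensemble: n conformers of a 10-residue chain carrying
# one Arg (residue 5) and one Asp (residue 7); conformers listed in
# `bridged` get a side-on carboxylate, the rest a distant one
make_tiny_ensemble <- function(n, bridged = integer(0)) {
  rows <- lapply(seq_len(n), function(cf) {
    ca <- tibble::tibble(
      conformer_id = cf,
      residue_index = 1:10,
      residue_name = c("ASP", "ALA", "GLU", "PHE", "ARG",
                       "HIS", "ASP", "SER", "GLY", "TYR"),
      atom_name = "CA",
      x = (0:9) * 3.8, y = 0, z = 0
    )
    gdm <- tibble::tibble(
      conformer_id = cf, residue_index = 5L, residue_name = "ARG",
      atom_name = c("CZ", "NE", "NH1", "NH2"),
      x = c(0, -1.33, 1.33 * cos(pi / 3), 1.33 * cos(pi / 3)),
      y = c(0, 0, 1.33 * sin(pi / 3), -1.33 * sin(pi / 3)),
      z = 20
    )
    ox <- if (cf %in% bridged) {
      list(o1 = c(3.56, 1.10, 20), o2 = c(3.56, -1.10, 20), cc = c(4.15, 0, 20))
    } else {
      list(o1 = c(30, 1.1, 0), o2 = c(30, -1.1, 0), cc = c(30.6, 0, 0))
    }
    carb <- tibble::tibble(
      conformer_id = cf, residue_index = 7L, residue_name = "ASP",
      atom_name = c("CG", "OD1", "OD2"),
      x = c(ox$cc[1], ox$o1[1], ox$o2[1]),
      y = c(ox$cc[2], ox$o1[2], ox$o2[2]),
      z = c(ox$cc[3], ox$o1[3], ox$o2[3])
    )
    dplyr::bind_rows(ca, gdm, carb)
  })
  dplyr::bind_rows(rows)
}
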