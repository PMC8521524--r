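# Readers/writers: header-driven CSV for tabular data, multi-model PDB for
# conformer ensembles, JSON sidecars for generator ground truth.

.read_typed_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  miss <- setdiff(required, names(out))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s) in ", basename(path), ": ",
                 paste(miss, collapse = ", ")))
  }
  if (nrow(out) == 0) {
    warn(paste0("empty data section in ", basename(path)))
    for (cc in numeric_cols) out[[cc]] <- as.numeric(out[[cc]])
    return(out)
  }
  for (cc in numeric_cols) {
    v <- out[[cc]]
    if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      if (anyNA(conv) && !all(is.na(v[is.na(conv)]))) {
        bad <- which(is.na(conv) & !is.na(v))[1]
        abort(paste0("non-numeric value in column '", cc, "' at data row ",
                     bad, " of ", basename(path)))
      }
      out[[cc]] <- conv
    }
  }
  out
}

#' Read a pressure-series chemical-shift CSV
#'
#' Expects columns `residue_index`, `residue_name`, `nucleus`,
#' `pressure_bar`, `shift_ppm` and optionally `intensity`; column order is
#' irrelevant and unknown columns are preserved.
#'
#' @param path CSV path.
#' @return Tibble in the layout accepted by [fit_pressure_coefficients()].
#' @export
read_shift_csv <- function(path) {
  .read_typed_csv(
    path,
    required = c("residue_index", "residue_name", "nucleus",
                 "pressure_bar", "shift_ppm"),
    numeric_cols = c("residue_index", "pressure_bar", "shift_ppm")
  )
}

#' Read a CEST profile CSV
#'
#' Expects columns `offset_ppm` and `intensity` (normalised to the
#' no-saturation reference).
#'
#' @param path CSV path.
#' @return Tibble in the layout accepted by [fit_cest_profile()].
#' @export
read_cest_csv <- function(path) {
  .read_typed_csv(path, required = c("offset_ppm", "intensity"),
                  numeric_cols = c("offset_ppm", "intensity"))
}

#' Read a per-conformer energy CSV
#'
#' Expects columns `conformer_id`, `group`, `E_phos`, `E_nonphos`
#' (hartrees).
#'
#' @param path CSV path.
#' @return Tibble in the layout accepted by [group_stats()].
#' @export
read_energy_csv <- function(path) {
  .read_typed_csv(path, required = c("conformer_id", "group",
                                     "E_phos", "E_nonphos"),
                  numeric_cols = c("E_phos", "E_nonphos"))
}

#' Write a synthetic table with its ground-truth sidecar
#'
#' Writes `x` as CSV and, when `x` carries a generator `truth` attribute,
#' a machine-readable JSON sidecar at `<path>.truth.json` recording the
#' seed and configuration, so downstream validation never has to re-derive
#' the planted truth.
#'
#' @param x Tibble from one of the `gen_*` generators (or any data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_synthetic_csv <- function(x, path) {
  readr::write_csv(as_tibble(x), path)
  truth <- attr(x, "truth")
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
  }
  invisible(path)
}

#' Read a multi-model PDB file as a tidy conformer ensemble
#'
#' Parses a (v3-format) PDB file via [bio3d::read.pdb()] with multi-model
#' support; MODEL order defines `conformer_id` (a single-model file yields
#' an ensemble of one). The atom roster must be identical across models.
#'
#' @param path PDB path.
#' @return Tidy atom tibble (`conformer_id`, `residue_index`,
#'   `residue_name`, `atom_name`, `x`, `y`, `z`) as consumed by
#'   [scan_ensemble()].
#' @export
read_ensemble_pdb <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  # roster check before handing to bio3d (which assumes consistency)
  atom_key <- function(ls) {
    paste(trimws(substr(ls, 13, 16)), trimws(substr(ls, 18, 20)),
          trimws(substr(ls, 23, 26)), sep = "|")
  }
  if (length(model_starts) > 1) {
    model_id <- cumsum(startsWith(lines, "MODEL"))
    rosters <- tapply(atom_key(lines[is_atom]), model_id[is_atom],
                      paste, collapse = ";")
    if (length(unique(rosters)) != 1) {
      bad <- names(rosters)[which(rosters != rosters[[1]])[1]]
      abort(paste0("atom roster differs across models (first mismatch: ",
                   "MODEL block ", bad, ")"))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  xyz <- pdb$xyz # nmodels x 3*natoms
  n_models <- nrow(xyz)
  n_atoms <- nrow(atom)
  tibble(
    conformer_id = rep(seq_len(n_models), each = n_atoms),
    residue_index = rep(as.integer(atom$resno), n_models),
    residue_name = rep(atom$resid, n_models),
    atom_name = rep(atom$elety, n_models),
    x = as.vector(t(xyz[, seq(1, 3 * n_atoms, by = 3), drop = FALSE])),
    y = as.vector(t(xyz[, seq(2, 3 * n_atoms, by = 3), drop = FALSE])),
    z = as.vector(t(xyz[, seq(3, 3 * n_atoms, by = 3), drop = FALSE]))
  )
}

#' Write a tidy conformer ensemble as a multi-model PDB file
#'
#' Emits standard v3 ATOM records wrapped in MODEL/ENDMDL blocks, one block
#' per conformer, with a `truth` JSON sidecar when the ensemble carries
#' generator ground truth (see [write_synthetic_csv()]).
#'
#' @param ensemble Tidy atom tibble (see [read_ensemble_pdb()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  .check_ensemble(ensemble)
  con <- file(path, "w")
  on.exit(close(con))
  truth <- attr(ensemble, "truth")
  seed <- truth$seed
  writeLines(c(
    "REMARK   6 REDUCED-ATOM CONFORMER ENSEMBLE",
    if (!is.null(seed)) sprintf("REMARK   6 GENERATOR SEED %d", seed)
  ), con)
  split_cf <- split(seq_len(nrow(ensemble)), ensemble$conformer_id)
  for (cf in names(split_cf)) {
    idx <- split_cf[[cf]]
    sub <- ensemble[idx, ]
    writeLines(sprintf("MODEL %8d", as.integer(cf)), con)
    el <- substr(trimws(sub$atom_name), 1, 1)
    name4 <- ifelse(nchar(sub$atom_name) < 4,
                    sprintf(" %-3s", sub$atom_name),
                    sprintf("%-4s", sub$atom_name))
    writeLines(sprintf(
      "ATOM  %5d %s %-3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_along(idx), name4, sub$residue_name, sub$residue_index,
      sub$x, sub$y, sub$z, 1.00, 0.00, el
    ), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  if (!is.null(truth)) {
    jsonlite::write_json(truth, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "columns")
  }
  invisible(path)
}
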