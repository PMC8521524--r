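# Phosphorylation energetics: per-conformer energy differences and group
# comparisons for conformer sets with / without salt bridges.

#' Convert hartrees to kJ/mol
#'
#' Uses the CODATA conversion 1 hartree = 2625.4996 kJ/mol. Note that group
#' tables rounded to 3 decimals in hartrees will not reproduce a kJ/mol
#' column computed from unrounded values (e.g. 0.035 x 2625.5 is 91.9, while
#' the unrounded difference may print as 90.96); this is rounding, not a
#' discrepancy.
#'
#' @param x Energy in hartrees.
#' @return Energy in kJ/mol.
#' @examples
#' hartree_to_kjmol(0.035)
#' @export
hartree_to_kjmol <- function(x) {
  if (!is.numeric(x)) abort("`x` must be numeric (hartrees)")
  x * HARTREE_KJMOL
}

#' Group statistics of per-conformer phosphorylation energy differences
#'
#' For each conformer the phosphorylation energy difference is
#' `dE = E_phos - E_nonphos` (hartrees). Conformer groups (e.g. conformers
#' carrying both Arg5-based salt bridges, carrying one, or none) are
#' summarised as mean +/- sd, and each group's destabilisation relative to
#' the control group is reported as `ddE = mean(dE_group) - mean(dE_control)`
#' in hartrees and kJ/mol. A positive `ddE` means the group is relatively
#' destabilised by phosphorylation compared with the control.
#'
#' @param energies Data frame with columns `conformer_id`, `group`,
#'   `E_phos`, `E_nonphos` (hartrees).
#' @param control Name of the control (reference) group. Default
#'   `"control"`. Must be present and non-empty.
#' @return Tibble with one row per group: `n`, `mean_dE`, `sd_dE`
#'   (hartrees; `sd_dE` is `NA` for n = 1), `ddE_hartree`, `ddE_kjmol`.
#'   The control row has `ddE` exactly 0.
#' @examples
#' tab <- gen_energy_table(seed = 1)
#' group_stats(tab)
#' @export
group_stats <- function(energies, control = "control") {
  stopifnot(is.data.frame(energies))
  req <- c("conformer_id", "group", "E_phos", "E_nonphos")
  miss <- setdiff(req, names(energies))
  if (length(miss) > 0) {
    abort(paste0("missing required column(s): ", paste(miss, collapse = ", ")))
  }
  if (!all(is.finite(energies$E_phos)) || !all(is.finite(energies$E_nonphos))) {
    abort("all energies must be finite")
  }
  if (!any(energies$group == control)) {
    abort(paste0("control group '", control, "' is empty or absent"))
  }
  per_group <- energies |>
    dplyr::mutate(dE = .data$E_phos - .data$E_nonphos) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_dE = mean(.data$dE),
      sd_dE = if (dplyr::n() > 1) sd(.data$dE) else NA_real_,
      .groups = "drop"
    )
  ctrl_mean <- per_group$mean_dE[per_group$group == control]
  per_group |>
    dplyr::mutate(
      ddE_hartree = .data$mean_dE - ctrl_mean,
      ddE_kjmol = hartree_to_kjmol(.data$mean_dE - ctrl_mean),
      is_control = .data$group == control
    ) |>
    dplyr::arrange(dplyr::desc(.data$ddE_hartree))
}
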