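# broom-style tidiers for fitted objects.

#' Tidy a CEST exchange fit
#'
#' @param x A `cest_fit` from [fit_cest_profile()].
#' @param ... Unused.
#' @return Tibble with columns `term`, `estimate`, `std.error`.
#' @method tidy cest_fit
#' @export
tidy.cest_fit <- function(x, ...) x$estimates

#' One-row summary of a CEST exchange fit
#'
#' @param x A `cest_fit` from [fit_cest_profile()].
#' @param ... Unused.
#' @return One-row tibble: `rss`, `n_points`, `converged`,
#'   `n_starts_converged`, `n_starts`, and the fixed acquisition parameters.
#' @method glance cest_fit
#' @export
glance.cest_fit <- function(x, ...) {
  tibble(
    rss = x$rss,
    n_points = x$n_points,
    converged = x$converged,
    n_starts_converged = sum(x$multi_start$converged),
    n_starts = nrow(x$multi_start),
    R1 = x$fixed$R1, R2 = x$fixed$R2,
    B1_sat = x$fixed$B1_sat, T_sat = x$fixed$T_sat,
    freq_MHz = x$fixed$freq_MHz
  )
}
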