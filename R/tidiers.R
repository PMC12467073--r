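#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an energy budget
#'
#' @param x An [energy_budget()].
#' @param ... Unused.
#' @return `tidy()`: one row per work component (`component`, `energy`,
#'   `fraction` of total). `glance()`: a one-row tibble with `w_el`,
#'   `w_visc`, `w_adh`, `w_total`, `dissipation_ratio`
#'   (`w_visc / w_el`, `NA` when nothing is stored) and `method`.
#' @examples
#' b <- ramp_budget(kv_params(1000, 50), D = 0.10, T = 1.0)
#' tidy(b)
#' glance(b)
#' @method tidy energy_budget
#' @export
tidy.energy_budget <- function(x, ...) {
  e <- c(x$w_el, x$w_visc, x$w_adh)
  tibble::tibble(
    component = c("elastic", "viscous", "adhesive"),
    energy = e,
    fraction = if (x$w_total > 0) e / x$w_total else rep(NA_real_, 3))
}

#' @rdname tidy.energy_budget
#' @method glance energy_budget
#' @export
glance.energy_budget <- function(x, ...) {
  tibble::tibble(
    w_el = x$w_el, w_visc = x$w_visc, w_adh = x$w_adh,
    w_total = x$w_total,
    dissipation_ratio = if (x$w_el > 0) x$w_visc / x$w_el else NA_real_,
    method = x$method)
}
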