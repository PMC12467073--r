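#' Linear displacement ramp protocol
#'
#' Samples the kinematics of a constant-velocity loading protocol
#' `x(t) = D t / T` on a uniform time grid: the indenter (or stretch
#' actuator) moves from 0 to the total displacement `D` over the loading
#' duration `T`. The ramp velocity is `D / T` at every sample; at `t = 0`
#' the velocity is taken as its right limit, so a viscoelastic force trace
#' starts with the finite jump `eta * D / T` rather than zero.
#'
#' @param D Total imposed displacement, m (non-negative).
#' @param T Loading duration, s (strictly positive).
#' @param n Number of samples on `[0, T]`, integer >= 2. The default
#'   10001 keeps trapezoidal work integrals on the resulting grid accurate
#'   to better than 1e-8 relative for these affine force laws.
#'
#' @return A tibble of class `ramp_protocol` with columns `t` (s), `x` (m),
#'   `v` (m/s) and attributes `D`, `T`.
#' @examples
#' linear_ramp(D = 1e-7, T = 0.1)$v[1]  # 1e-6 m/s: slow nanoparticle entry
#' linear_ramp(D = 0.02, T = 2)         # slow tendon stretch
#' @export
linear_ramp <- function(D, T, n = 10001L) {
  stopifnot(is.numeric(D), length(D) == 1L, is.numeric(T), length(T) == 1L,
            is.numeric(n), length(n) == 1L)
  if (!is.finite(D) || D < 0) {
    stop("`D` must be a finite non-negative displacement (m)", call. = FALSE)
  }
  if (!is.finite(T) || T <= 0) {
    stop("`T` must be a finite positive duration (s)", call. = FALSE)
  }
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("`n` must be an integer >= 2", call. = FALSE)
  t <- seq(0, T, length.out = n)
  out <- tibble::tibble(t = t, x = D * t / T, v = rep(D / T, n))
  attr(out, "D") <- D
  attr(out, "T") <- T
  class(out) <- c("ramp_protocol", class(out))
  out
}

#' Sample a force/power/work trace for a viscoelastic loading protocol
#'
#' Evaluates the Kelvin-Voigt force law (with optional adhesion) along a
#' sampled displacement protocol and fills in instantaneous power and the
#' cumulative work components by trapezoidal integration. This is the
#' numerical route to the energy budget; [elastic_work()] and
#' [viscous_work_ramp()] give the matching closed forms for linear ramps.
#'
#' @param protocol A [linear_ramp()] protocol, or any tibble with columns
#'   `t`, `x`, `v` describing a monotone loading history.
#' @param params A [kv_params()] object.
#' @param adh An [adhesion()] model; default none.
#'
#' @return A tibble of class `kv_trace` with columns `t`, `x`, `v`, `F`
#'   (N), `P` (W) and cumulative works `w_el`, `w_visc`, `w_adh`,
#'   `w_total` (J). The terminal [energy_budget()] is attached as
#'   attribute `"budget"` and retrievable with [trace_budget()].
#' @examples
#' p <- kv_params(k = 1000, eta = 50)
#' tr <- linear_ramp(D = 0.02, T = 0.5) |> sample_trace(p)
#' dplyr::last(tr$F)  # 22 N terminal force for the fast ramp
#' trace_budget(tr)
#' @export
sample_trace <- function(protocol, params, adh = adhesion("none")) {
  stopifnot(is.data.frame(protocol),
            all(c("t", "x", "v") %in% names(protocol)))
  tr <- tibble::as_tibble(protocol[c("t", "x", "v")])
  check_loading_grid(tr)
  tr$F <- kv_force(params, tr$x, tr$v, adh)
  tr$P <- tr$F * tr$v
  partition_trace(tr, params, adh)
}

# shared validation for loading histories: strictly increasing time from 0,
# non-decreasing one-sided displacement (unloading is not modeled)
check_loading_grid <- function(tr) {
  if (length(tr$t) < 2L) stop("a trace needs at least 2 samples", call. = FALSE)
  if (tr$t[1] != 0 || any(diff(tr$t) <= 0)) {
    stop("time grid must start at 0 and be strictly increasing",
         call. = FALSE)
  }
  if (tr$x[1] != 0) stop("loading must start from x = 0", call. = FALSE)
  if (any(tr$x < 0)) stop("indentation `x` must be non-negative", call. = FALSE)
  if (any(diff(tr$x) < 0)) {
    stop("displacement must be non-decreasing: unloading is not modeled",
         call. = FALSE)
  }
  invisible(tr)
}
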