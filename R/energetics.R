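#' Energy budget of one loading event
#'
#' Container splitting the total mechanical work done on a viscoelastic
#' element into recoverable elastic storage, irreversible viscous
#' dissipation and (optional) adhesive work: `W_total = W_el + W_visc +
#' W_adh`. The `method` field records whether the budget came from the
#' closed-form expressions for a linear ramp or from trapezoidal
#' integration of a sampled trace.
#'
#' @param w_el Elastic (recoverable) work, J.
#' @param w_visc Viscous (dissipated) work, J.
#' @param w_adh Adhesive work, J (default 0).
#' @param method `"analytic"` or `"numerical"`.
#'
#' @return An object of class `energy_budget`.
#' @examples
#' energy_budget(w_el = 5, w_visc = 0.5, method = "analytic")
#' @export
energy_budget <- function(w_el, w_visc, w_adh = 0,
                          method = c("analytic", "numerical")) {
  method <- match.arg(method)
  stopifnot(is.numeric(w_el), is.numeric(w_visc), is.numeric(w_adh))
  if (w_el < 0 || w_visc < 0) {
    stop("elastic and viscous works must be non-negative", call. = FALSE)
  }
  structure(list(w_el = as.numeric(w_el), w_visc = as.numeric(w_visc),
                 w_adh = as.numeric(w_adh),
                 w_total = as.numeric(w_el + w_visc + w_adh),
                 method = method),
            class = "energy_budget")
}

#' @export
print.energy_budget <- function(x, ...) {
  cat("<energy budget> (", x$method, ")\n", sep = "")
  cat("  W_el    =", format(x$w_el, digits = 6), "J\n")
  cat("  W_visc  =", format(x$w_visc, digits = 6), "J\n")
  if (x$w_adh != 0) cat("  W_adh   =", format(x$w_adh, digits = 6), "J\n")
  cat("  W_total =", format(x$w_total, digits = 6), "J\n")
  invisible(x)
}

#' Closed-form elastic stored energy of a linear spring
#'
#' The recoverable part of the work done loading a linear spring of
#' stiffness `k` to displacement `D`: `W_el = k D^2 / 2`. Independent of
#' loading duration — elastic storage is rate-invariant.
#'
#' @param k Stiffness, N/m (non-negative, vectorized).
#' @param D Displacement, m (non-negative, vectorized).
#' @return Energy, J.
#' @examples
#' elastic_work(k = 1000, D = 0.10)     # 5 J, tendon-like stretch
#' elastic_work(k = 0.010, D = 1e-7)    # 5e-17 J, membrane indentation
#' @export
elastic_work <- function(k, D) {
  stopifnot(is.numeric(k), is.numeric(D))
  if (any(!is.finite(k)) || any(k < 0)) {
    stop("`k` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(D)) || any(D < 0)) {
    stop("`D` must be finite and non-negative", call. = FALSE)
  }
  0.5 * k * D^2
}

#' Closed-form viscous dissipation for a linear ramp
#'
#' For a constant-velocity ramp `x(t) = D t / T` the dashpot dissipates
#' `W_visc = eta * integral(v^2 dt) = eta D^2 / T`: inversely proportional
#' to the loading duration, so halving `T` doubles the dissipated energy
#' at identical peak displacement.
#'
#' @param eta Damping coefficient, N s/m (non-negative, vectorized).
#' @param D Displacement, m (non-negative, vectorized).
#' @param T Loading duration, s (positive, vectorized).
#' @return Energy, J.
#' @examples
#' viscous_work_ramp(eta = 50, D = 0.10, T = 1.0)    # 0.5 J  (slow)
#' viscous_work_ramp(eta = 50, D = 0.10, T = 0.01)   # 50 J   (fast)
#' @export
viscous_work_ramp <- function(eta, D, T) {
  stopifnot(is.numeric(eta), is.numeric(D), is.numeric(T))
  if (any(!is.finite(eta)) || any(eta < 0)) {
    stop("`eta` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(D)) || any(D < 0)) {
    stop("`D` must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(T)) || any(T <= 0)) {
    stop("`T` must be finite and positive", call. = FALSE)
  }
  eta * D^2 / T
}

#' Analytic energy budget for a Kelvin-Voigt linear ramp
#'
#' Convenience wrapper combining [elastic_work()] and
#' [viscous_work_ramp()] into one [energy_budget()].
#'
#' @param params A [kv_params()] object.
#' @param D Displacement, m.
#' @param T Loading duration, s.
#' @return An [energy_budget()] with `method = "analytic"`.
#' @examples
#' ramp_budget(kv_params(1000, 50), D = 0.10, T = 1.0)
#' @export
ramp_budget <- function(params, D, T) {
  stopifnot(inherits(params, "kv_params"))
  energy_budget(w_el = elastic_work(params$k, D),
                w_visc = viscous_work_ramp(params$eta, D, T),
                method = "analytic")
}

#' Numerical work partition of a sampled trace
#'
#' Fills the cumulative work columns of a loading trace by trapezoidal
#' quadrature and attaches the terminal [energy_budget()]:
#' `w_el = integral(k x dx)`, `w_visc = integral(eta v^2 dt)`,
#' `w_adh = integral(F_adh dx)`, `w_total = integral(F dx)`. The
#' trapezoidal rule is exact (to float rounding) for the affine integrands
#' a linear ramp produces, and converges as `O(n^-2)` in general.
#'
#' @param trace A tibble with columns `t`, `x`, `v` (and optionally `F`);
#'   `x` must be a non-decreasing pure-loading history.
#' @param params A [kv_params()] object.
#' @param adh An [adhesion()] model; default none.
#' @return The trace as a `kv_trace` tibble with columns `F`, `P`,
#'   `w_el`, `w_visc`, `w_adh`, `w_total` filled and the terminal budget
#'   in attribute `"budget"` (see [trace_budget()]).
#' @examples
#' p <- kv_params(k = 1000, eta = 50)
#' tr <- linear_ramp(D = 0.10, T = 1.0) |> partition_trace(p)
#' trace_budget(tr)  # ~ 5 J elastic + 0.5 J viscous
#' @export
partition_trace <- function(trace, params, adh = adhesion("none")) {
  stopifnot(is.data.frame(trace), inherits(params, "kv_params"),
            all(c("t", "x", "v") %in% names(trace)))
  tr <- tibble::as_tibble(trace)
  check_loading_grid(tr)
  if (!"F" %in% names(tr)) tr$F <- kv_force(params, tr$x, tr$v, adh)
  tr$P <- tr$F * tr$v
  f_adh <- adhesion_force(adh, tr$x)

  tr$w_el <- cum_integral(tr$x, params$k * tr$x)
  tr$w_visc <- cum_integral(tr$t, params$eta * tr$v^2)
  tr$w_adh <- cum_integral(tr$x, f_adh)
  tr$w_total <- cum_integral(tr$x, tr$F)

  budget <- structure(list(w_el = last_of(tr$w_el),
                           w_visc = last_of(tr$w_visc),
                           w_adh = last_of(tr$w_adh),
                           w_total = last_of(tr$w_total),
                           method = "numerical"),
                      class = "energy_budget")
  attr(tr, "budget") <- budget
  if (!inherits(tr, "kv_trace")) class(tr) <- c("kv_trace", class(tr))
  tr
}

# cumulative trapezoid that tolerates a degenerate all-equal abscissa
# (zero-displacement protocols integrate to exactly zero work)
cum_integral <- function(s, y) {
  if (length(s) < 2L) return(rep(0, length(s)))
  pracma::cumtrapz(s, y)[, 1]
}

last_of <- function(x) x[[length(x)]]

#' Extract the terminal energy budget of a trace
#'
#' @param trace A `kv_trace` produced by [sample_trace()] or
#'   [partition_trace()].
#' @return The attached [energy_budget()].
#' @export
trace_budget <- function(trace) {
  b <- attr(trace, "budget")
  if (is.null(b)) {
    stop("no energy budget attached; run partition_trace() first",
         call. = FALSE)
  }
  b
}

#' Hill-muscle mechanical work per contraction
#'
#' Work done by a muscle shortening a distance `D` at constant velocity
#' `v` under the Hill force-velocity relation: `W(v) = F(v) * D`. Because
#' Hill force falls hyperbolically with velocity, faster contractions do
#' strictly less mechanical work per contraction, from `W(0) = F_max * D`
#' down to zero at `vmax`.
#'
#' @param params A [hill_params()] object.
#' @param D Shortening distance, m (non-negative).
#' @param v Shortening velocity, m/s (vectorized, in `[0, vmax]`).
#' @return Work, J.
#' @examples
#' p <- hill_params(fmax = 100, a = 10, b = 0.5)
#' hill_work(p, D = 0.05, v = 0.10)  # 4.0833 J (slow)
#' hill_work(p, D = 0.05, v = 0.50)  # 2.25 J   (fast)
#' @export
hill_work <- function(params, D, v) {
  stopifnot(is.numeric(D), length(D) == 1L)
  if (!is.finite(D) || D < 0) {
    stop("`D` must be finite and non-negative", call. = FALSE)
  }
  hill_force(params, v) * D
}

#' Elastic/viscous crossover time of a Kelvin-Voigt element
#'
#' The ramp duration at which viscous dissipation equals elastic storage.
#' Setting `eta D^2 / T = k D^2 / 2` gives `T* = 2 eta / k`, independent
#' of `D`. Ramps faster than `T*` are viscous-dominated; slower ramps are
#' elastic-dominated.
#'
#' @param params A [kv_params()] object with `k > 0`.
#' @return Duration, s.
#' @examples
#' crossover_time(kv_params(k = 1000, eta = 50))  # 0.1 s
#' @export
crossover_time <- function(params) {
  stopifnot(inherits(params, "kv_params"))
  if (params$k <= 0) {
    stop("crossover time is undefined for k = 0 (no elastic storage)",
         call. = FALSE)
  }
  2 * params$eta / params$k
}
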