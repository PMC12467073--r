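#' Kelvin-Voigt force law
#'
#' Force exerted by a Kelvin-Voigt element (plus optional adhesion) at
#' indentation `x` and indentation velocity `v`:
#' `F = k x + eta v + F_adh(x)`. The indentation coordinate is one-sided:
#' negative `x` is rejected rather than extrapolated.
#'
#' @param params A [kv_params()] object.
#' @param x Displacement / indentation, m. Vectorized; all values must be
#'   non-negative.
#' @param v Velocity, m/s. Vectorized (recycled against `x`).
#' @param adh An [adhesion()] model; default none.
#'
#' @return Numeric vector of forces, N.
#' @examples
#' p <- kv_params(k = 1000, eta = 50)
#' kv_force(p, x = 0.02, v = 0.01)  # 20.5 N: slow-ramp terminal force
#' kv_force(p, x = 0.02, v = 0.04)  # 22.0 N: fast-ramp terminal force
#' @export
kv_force <- function(params, x, v, adh = adhesion("none")) {
  stopifnot(inherits(params, "kv_params"), inherits(adh, "adhesion_model"),
            is.numeric(x), is.numeric(v))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("indentation `x` must be finite and non-negative ",
         "(the indentation coordinate is one-sided)", call. = FALSE)
  }
  params$k * x + params$eta * v + adhesion_force(adh, x)
}

#' Adhesion force
#'
#' Evaluates the adhesive contribution `F_adh(x)` of an [adhesion()] model.
#' `"none"` is identically zero; `"constant"` returns `f0` for `x > 0` and
#' 0 at contact (`x = 0`); `"exponential"` returns `f0 * exp(-x / lam)`.
#'
#' @param adh An [adhesion()] model.
#' @param x Indentation, m (non-negative, vectorized).
#' @return Numeric vector of forces, N.
#' @examples
#' adhesion_force(adhesion("constant", f0 = 1e-9), x = 5e-8)
#' adhesion_force(adhesion("exponential", f0 = 1e-9, lam = 5e-8), x = 0)
#' @export
adhesion_force <- function(adh, x) {
  stopifnot(inherits(adh, "adhesion_model"), is.numeric(x))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("indentation `x` must be finite and non-negative", call. = FALSE)
  }
  switch(adh$kind,
    none = rep(0, length(x)),
    constant = ifelse(x > 0, adh$f0, 0),
    exponential = adh$f0 * exp(-x / adh$lam),
    stop("unknown adhesion kind: ", adh$kind, call. = FALSE)
  )
}

#' Hill force at a given shortening velocity
#'
#' Solves the Hill relation `(F + a)(v + b) = (F_max + a) b` for force:
#' `F(v) = (F_max + a) b / (v + b) - a`. Valid only for concentric
#' shortening, `0 <= v <= vmax`; eccentric lengthening (`v < 0`) and
#' super-maximal shortening are outside the model and rejected.
#'
#' @param params A [hill_params()] object.
#' @param v Shortening velocity, m/s (vectorized).
#' @return Numeric vector of forces, N. `F(0) = fmax`, strictly decreasing
#'   in `v`, `F(vmax) = 0`.
#' @examples
#' p <- hill_params(fmax = 100, a = 10, b = 0.5)
#' hill_force(p, 0)      # isometric: 100 N
#' hill_force(p, 0.10)   # 81.67 N
#' hill_force(p, 0.50)   # 45 N
#' @export
hill_force <- function(params, v) {
  stopifnot(inherits(params, "hill_params"), is.numeric(v))
  vmax <- hill_vmax(params)
  # small relative guard so v = vmax computed in floating point is accepted
  tol <- vmax * 1e-12
  if (any(!is.finite(v)) || any(v < 0) || any(v > vmax + tol)) {
    stop("shortening velocity must lie in [0, vmax = ", format(vmax),
         " m/s]: outside the concentric Hill regime", call. = FALSE)
  }
  f <- (params$fmax + params$a) * params$b / (v + params$b) - params$a
  pmax(f, 0)
}

#' Maximum shortening velocity of a Hill muscle
#'
#' The velocity at which Hill force vanishes, obtained from the force-zero
#' root of the hyperbola: `vmax = b * F_max / a`.
#'
#' @param params A [hill_params()] object.
#' @return Velocity, m/s.
#' @examples
#' hill_vmax(hill_params(fmax = 100, a = 10, b = 0.5))  # 5 m/s
#' @export
hill_vmax <- function(params) {
  stopifnot(inherits(params, "hill_params"))
  params$b * params$fmax / params$a
}
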