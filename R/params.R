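#' Kelvin-Voigt element parameters
#'
#' A Kelvin-Voigt element is a linear spring and a dashpot in parallel, the
#' simplest analogue for soft-tissue viscoelasticity: the force resisting an
#' imposed indentation `x` moving at velocity `v` is `k*x + eta*v`, so
#' resistance grows with deformation rate.
#'
#' @param k Elastic stiffness, N/m. Must be non-negative.
#' @param eta Viscous damping coefficient, N s/m. Must be non-negative.
#'
#' @return An object of class `kv_params`: a named list with elements `k`
#'   and `eta` in SI units.
#' @examples
#' kv_params(k = 1000, eta = 50)  # tendon-like specimen
#' kv_params(k = 0.010, eta = 1e-6)  # cell membrane + cortex
#' @seealso [kv_force()], [sample_trace()], [crossover_time()]
#' @export
kv_params <- function(k, eta) {
  stopifnot(is.numeric(k), length(k) == 1L, is.numeric(eta), length(eta) == 1L)
  if (!is.finite(k) || k < 0) {
    stop("`k` must be a finite non-negative stiffness (N/m), got ", k,
         call. = FALSE)
  }
  if (!is.finite(eta) || eta < 0) {
    stop("`eta` must be a finite non-negative damping coefficient (N s/m), ",
         "got ", eta, call. = FALSE)
  }
  structure(list(k = as.numeric(k), eta = as.numeric(eta)),
            class = "kv_params")
}

#' @export
print.kv_params <- function(x, ...) {
  cat("<Kelvin-Voigt element>  k =", format(x$k), "N/m,  eta =",
      format(x$eta), "N s/m\n")
  invisible(x)
}

#' Adhesion force model for membrane indentation
#'
#' Optional adhesive contribution `F_adh(x)` added to the Kelvin-Voigt force
#' during nanoparticle-membrane indentation. The functional form of membrane
#' adhesion is not pinned down by first principles at this level of
#' description, so two simple plug-in forms are offered alongside the
#' default of no adhesion:
#'
#' * `"none"`: identically zero (the default).
#' * `"constant"`: a constant pull of `f0` for any positive indentation,
#'   zero at `x = 0`.
#' * `"exponential"`: `f0 * exp(-x / lam)`, a contact force decaying over a
#'   length scale `lam`.
#'
#' @param kind One of `"none"`, `"constant"`, `"exponential"`.
#' @param f0 Force amplitude, N (non-negative). Ignored for `"none"`.
#' @param lam Decay length, m (strictly positive). Required for
#'   `"exponential"` only.
#'
#' @return An object of class `adhesion_model`.
#' @examples
#' adhesion()                                     # no adhesion
#' adhesion("constant", f0 = 1e-9)
#' adhesion("exponential", f0 = 1e-9, lam = 5e-8)
#' @export
adhesion <- function(kind = c("none", "constant", "exponential"),
                     f0 = 0, lam = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(f0), length(f0) == 1L)
  if (!is.finite(f0) || f0 < 0) {
    stop("`f0` must be a finite non-negative force (N)", call. = FALSE)
  }
  if (kind == "exponential") {
    if (is.null(lam) || !is.numeric(lam) || length(lam) != 1L ||
        !is.finite(lam) || lam <= 0) {
      stop("exponential adhesion needs a positive decay length `lam` (m)",
           call. = FALSE)
    }
    lam <- as.numeric(lam)
  } else {
    lam <- NA_real_
  }
  structure(list(kind = kind, f0 = as.numeric(f0), lam = lam),
            class = "adhesion_model")
}

#' @export
print.adhesion_model <- function(x, ...) {
  cat("<adhesion model>", x$kind)
  if (x$kind != "none") cat("  f0 =", format(x$f0), "N")
  if (x$kind == "exponential") cat(",  lam =", format(x$lam), "m")
  cat("\n")
  invisible(x)
}

#' Hill force-velocity parameters
#'
#' The Hill relation for concentric muscle shortening,
#' `(F + a)(v + b) = (F_max + a) b`, links the force `F` a muscle can
#' produce to its shortening velocity `v` through the maximum isometric
#' force `F_max` and two empirical constants `a` (force units) and `b`
#' (velocity units). Force is maximal at zero velocity and falls
#' hyperbolically to zero at `vmax = b * F_max / a`.
#'
#' @param fmax Maximum isometric force, N (strictly positive; `fmax = 0`
#'   is accepted as the degenerate zero-force muscle).
#' @param a Hill constant, N (strictly positive).
#' @param b Hill constant, m/s (strictly positive).
#'
#' @return An object of class `hill_params`.
#' @examples
#' hill_params(fmax = 100, a = 10, b = 0.5)
#' @seealso [hill_force()], [hill_vmax()], [hill_work()]
#' @export
hill_params <- function(fmax, a, b) {
  stopifnot(is.numeric(fmax), length(fmax) == 1L,
            is.numeric(a), length(a) == 1L,
            is.numeric(b), length(b) == 1L)
  if (!is.finite(fmax) || fmax < 0) {
    stop("`fmax` must be a finite non-negative force (N)", call. = FALSE)
  }
  if (!is.finite(a) || a <= 0) {
    stop("`a` must be a finite positive Hill constant (N); a = 0 gives an ",
         "unbounded vmax", call. = FALSE)
  }
  if (!is.finite(b) || b <= 0) {
    stop("`b` must be a finite positive Hill constant (m/s)", call. = FALSE)
  }
  structure(list(fmax = as.numeric(fmax), a = as.numeric(a),
                 b = as.numeric(b)),
            class = "hill_params")
}

#' @export
print.hill_params <- function(x, ...) {
  cat("<Hill muscle>  Fmax =", format(x$fmax), "N,  a =", format(x$a),
      "N,  b =", format(x$b), "m/s,  vmax =", format(hill_vmax(x)), "m/s\n")
  invisible(x)
}

#' Unit helpers: nanometres and milliseconds to SI
#'
#' All computation inside the package is in SI units (m, s, N, J).
#' Parameter tables for nanoscale scenarios are usually quoted in nm and
#' ms; these helpers make the conversion explicit at the call site.
#'
#' @param x Numeric vector in nm (`from_nm`) or ms (`from_ms`).
#' @return Numeric vector in metres / seconds.
#' @examples
#' from_nm(100)   # 1e-7 m
#' from_ms(0.1)   # 1e-4 s
#' @export
from_nm <- function(x) x * 1e-9

#' @rdname from_nm
#' @export
from_ms <- function(x) x * 1e-3
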