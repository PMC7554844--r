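#' Transversely isotropic hyperelastic parameter set
#'
#' Container for the seven deviatoric coefficients of the Weiss-type
#' transversely isotropic (TI) law plus the bulk modulus. The deviatoric
#' strain energy is a Mooney--Rivlin matrix, `C1*(I1t - 3) + C2*(I2t - 3)`,
#' plus a multi-regime fiber term whose stress measure
#' `lambda * dF2/dlambda` is zero for deviatoric fiber stretch
#' `lambda <= 1`, exponential `C3*(exp(C4*(lambda - 1)) - 1)` in the toe
#' (uncrimping) regime `1 < lambda <= lambda_star`, and linear
#' `C5*lambda + C6` for straightened fibers `lambda > lambda_star`. The
#' volumetric energy is `K/2 * (log J)^2`.
#'
#' @param C1,C2 matrix (isotropic) stiffnesses, Pa. Non-negative.
#' @param C3 fiber toe-region scale, Pa. Non-negative.
#' @param C4 fiber toe-region exponent, dimensionless. Positive.
#' @param C5 straightened-fiber modulus, Pa. Non-negative.
#' @param C6 linear-regime offset, Pa. If `NA` (default) it is computed
#'   from the other coefficients so the exponential and linear branches
#'   agree at `lambda_star` (C0 continuity), via [c6_from_c0()].
#' @param lambda_star critical deviatoric fiber stretch at which fibers
#'   straighten, dimensionless, `>= 1`.
#' @param K bulk modulus, Pa, positive. Defaults to 1.464e8.
#' @param enforce_c0 if `TRUE` and `C6` is supplied, error unless the two
#'   fiber branches agree at `lambda_star` to within 1e-9 relative.
#'
#' @return An object of class `"ti_params"`: a named list with fields
#'   `C1, C2, C3, C4, C5, C6, lambda_star, K`.
#' @examples
#' pm <- ti_params(C1 = 0.30e4, C2 = 0, C3 = 0.50e2, C4 = 28.5,
#'                 C5 = 1.024e5, lambda_star = 1.15)
#' pm$C6
#' discontinuity_index(pm)
#' @export
ti_params <- function(C1, C2 = 0, C3 = 0, C4 = 1, C5 = 0, C6 = NA,
                      lambda_star = 1, K = 1.464e8, enforce_c0 = FALSE) {
  vals <- c(C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5,
            lambda_star = lambda_star, K = K)
  if (any(!is.finite(vals)))
    stop("ti_params: all coefficients must be finite")
  if (C1 < 0 || C2 < 0 || C3 < 0 || C5 < 0)
    stop("ti_params: C1, C2, C3, C5 must be non-negative")
  if (C4 <= 0) stop("ti_params: C4 must be positive")
  if (lambda_star < 1) stop("ti_params: lambda_star must be >= 1")
  if (K <= 0) stop("ti_params: K must be positive")

  p <- structure(list(C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5,
                      C6 = NA_real_, lambda_star = lambda_star, K = K),
                 class = "ti_params")
  if (is.na(C6)) {
    p$C6 <- c6_from_c0(p)
  } else {
    p$C6 <- C6
    if (enforce_c0) {
      exp_val <- C3 * (exp(C4 * (lambda_star - 1)) - 1)
      lin_val <- C5 * lambda_star + C6
      ref <- max(abs(exp_val), abs(lin_val), 1)
      if (abs(exp_val - lin_val) > 1e-9 * ref)
        stop("ti_params: fiber branches disagree at lambda_star (C0 violated)")
    }
  }
  p
}

#' @export
print.ti_params <- function(x, ...) {
  cat("Transversely isotropic hyperelastic parameters\n")
  cat(sprintf("  matrix:  C1 = %.4g Pa, C2 = %.4g Pa\n", x$C1, x$C2))
  cat(sprintf("  fiber:   C3 = %.4g Pa, C4 = %.4g, C5 = %.4g Pa, C6 = %.4g Pa\n",
              x$C3, x$C4, x$C5, x$C6))
  cat(sprintf("  lambda* = %.4g, K = %.4g Pa\n", x$lambda_star, x$K))
  invisible(x)
}

#' C5 implied by slope (C1) continuity at the regime change
#'
#' Returns the straightened-fiber modulus that makes the fiber stress
#' measure C1-continuous at `lambda_star`:
#' `C5 = C3 * C4 * exp(C4 * (lambda_star - 1))`.
#'
#' @param p a [ti_params()] object (only `C3`, `C4`, `lambda_star` used).
#' @return C5 in Pa.
#' @examples
#' p <- ti_params(C1 = 3e3, C3 = 50, C4 = 28.5, C5 = 1, lambda_star = 1.15)
#' c5_c1_continuity(p)  # ~1.024e5
#' @export
c5_c1_continuity <- function(p) {
  stopifnot(p$C3 > 0, p$C4 > 0, p$lambda_star >= 1)
  p$C3 * p$C4 * exp(p$C4 * (p$lambda_star - 1))
}

#' C6 enforcing value (C0) continuity at the regime change
#'
#' `C6 = C3 * (exp(C4 * (lambda_star - 1)) - 1) - C5 * lambda_star`, so that
#' the exponential and linear branches of the fiber stress measure agree at
#' `lambda_star`.
#'
#' @param p a [ti_params()] object.
#' @return C6 in Pa.
#' @export
c6_from_c0 <- function(p) {
  p$C3 * (exp(p$C4 * (p$lambda_star - 1)) - 1) - p$C5 * p$lambda_star
}

#' Discontinuity index of the fiber stress slope
#'
#' Ratio of the fitted straightened-fiber modulus C5 to the slope of the
#' exponential toe branch at the critical stretch:
#' `f = C5 / (C3 * C4 * exp(C4 * (lambda_star - 1)))`.
#' `f = 1` means the two regimes join with a continuous slope (C1
#' continuity); `f != 1` quantifies the slope jump.
#'
#' @param p a [ti_params()] object. `C3` and `C4` must be positive; an
#'   isotropic material (no fiber term) has no defined index and errors --
#'   callers grading against an isotropic terminal use the convention
#'   `f = 1` (see [generate_fgm()]).
#' @return dimensionless index.
#' @export
discontinuity_index <- function(p) {
  if (p$C3 <= 0 || p$C4 <= 0)
    stop("discontinuity_index: undefined for C3 = 0 or C4 = 0 (isotropic terminal)")
  p$C5 / (p$C3 * p$C4 * exp(p$C4 * (p$lambda_star - 1)))
}

#' Terminal material fit
#'
#' Bundles a fitted TI parameter set with the maximum deviatoric fiber
#' stretch reached by the underlying experiment, which the grading
#' algorithm uses to decide whether the fitted C5 is trustworthy (fibers
#' reached the linear extension regime) or must be replaced by the
#' C1-continuity value (fibers still uncrimping at the end of the test).
#'
#' @param params a [ti_params()] object.
#' @param lambda_max maximum deviatoric fiber stretch in the fit, `>= 1`.
#' @param is_isotropic flag: terminal has no fiber component (requires
#'   `C3 = C5 = 0`).
#' @return An object of class `"terminal_fit"`.
#' @export
terminal_fit <- function(params, lambda_max = Inf, is_isotropic = FALSE) {
  stopifnot(inherits(params, "ti_params"), lambda_max >= 1)
  if (is_isotropic && (params$C3 != 0 || params$C5 != 0))
    stop("terminal_fit: isotropic terminal requires C3 = C5 = 0")
  structure(list(params = params, lambda_max = lambda_max,
                 is_isotropic = is_isotropic),
            class = "terminal_fit")
}

#' Fitted TI parameters for porcine tricuspid and mitral valve tissues
#'
#' Published uniaxial-tension fits for the "pure" chordae tendineae (CT),
#' leaflet (LL) and papillary muscle (PM) of porcine tricuspid (TV) and
#' mitral (MV) valves, with a common bulk modulus K = 1.464e8 Pa. C6 is
#' completed by C0 continuity at `lambda_star`; slope continuity is not
#' assumed, so each tissue carries its own discontinuity index.
#'
#' @param valve `"TV"` or `"MV"`.
#' @return Named list of [ti_params()] objects with elements `CT`, `LL`,
#'   `PM`.
#' @examples
#' tv <- valve_presets("TV")
#' discontinuity_index(tv$LL)  # ~0.81: a genuine slope jump in the LL fit
#' @export
valve_presets <- function(valve = c("TV", "MV")) {
  valve <- match.arg(valve)
  K <- 1.464e8
  if (valve == "TV") {
    list(
      CT = ti_params(C1 = 3.00e7, C2 = 0, C3 = 0.70e4, C4 = 80.00,
                     C5 = 5.441e8, lambda_star = 1.086, K = K),
      LL = ti_params(C1 = 1.95e4, C2 = 0, C3 = 1.00e5, C4 = 13.50,
                     C5 = 4.80e7, lambda_star = 1.28, K = K),
      PM = ti_params(C1 = 0.30e4, C2 = 0, C3 = 0.50e2, C4 = 28.50,
                     C5 = 1.024e5, lambda_star = 1.15, K = K)
    )
  } else {
    list(
      CT = ti_params(C1 = 3.37e6, C2 = 0, C3 = 8.82e3, C4 = 60.00,
                     C5 = 9.21e7, lambda_star = 1.086, K = K),
      LL = ti_params(C1 = 3.00e5, C2 = 0, C3 = 9.00e4, C4 = 40.00,
                     C5 = 5.38e6, lambda_star = 1.010, K = K),
      PM = ti_params(C1 = 1.05e4, C2 = 0, C3 = 0.50e3, C4 = 24.50,
                     C5 = 1.111e5, lambda_star = 1.09, K = K)
    )
  }
}
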