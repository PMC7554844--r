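#' Multi-regime fiber stress measure
#'
#' Evaluates `lambda * dF2/dlambda`, the fiber contribution to the stress
#' expressed in the deviatoric fiber stretch: zero in compression
#' (`lambda_t <= 1`), `C3 * (exp(C4*(lambda_t - 1)) - 1)` while fibers
#' uncrimp (`1 < lambda_t <= lambda_star`) and `C5*lambda_t + C6` once
#' straightened (`lambda_t > lambda_star`). The tie at `lambda_star`
#' resolves to the exponential branch; when C6 comes from [c6_from_c0()]
#' both branches give the same value there.
#'
#' @param lambda_t deviatoric fiber stretch(es), positive; vectorized.
#' @param p a [ti_params()] object.
#' @return fiber stress measure in Pa, same length as `lambda_t`.
#' @export
fiber_stress_term <- function(lambda_t, p) {
  stopifnot(all(lambda_t > 0))
  out <- numeric(length(lambda_t))
  toe <- lambda_t > 1 & lambda_t <= p$lambda_star
  lin <- lambda_t > p$lambda_star
  out[toe] <- p$C3 * (exp(p$C4 * (lambda_t[toe] - 1)) - 1)
  out[lin] <- p$C5 * lambda_t[lin] + p$C6
  out
}

# d/dlambda of fiber_stress_term; lower-regime tie-break at both boundaries.
fiber_stress_term_slope <- function(lambda_t, p) {
  out <- numeric(length(lambda_t))
  toe <- lambda_t > 1 & lambda_t <= p$lambda_star
  lin <- lambda_t > p$lambda_star
  out[toe] <- p$C3 * p$C4 * exp(p$C4 * (lambda_t[toe] - 1))
  out[lin] <- p$C5
  out
}

#' Cauchy stress of the transversely isotropic law
#'
#' Full compressible evaluation: hydrostatic pressure `K * log(J) / J`
#' from the volumetric energy plus the deviatoric matrix and fiber terms,
#'
#' `sigma = p*I + (2/J) * ((W1 + W2*I1t)*Bt - W2*Bt^2 + W4*I4t*(a ox a)
#'          - (W1*I1t + 2*W2*I2t + W4*I4t)/3 * I)`
#'
#' with `W1 = C1`, `W2 = C2`, `W4*I4t` equal to half the fiber stress
#' measure, `Bt = J^(-2/3) * F %*% t(F)` and `a` the deformed unit fiber
#' direction. Vanishes identically at `F = I` and is objective:
#' `cauchy_stress` of `Q %*% F` equals `Q %*% sigma %*% t(Q)`.
#'
#' @param kin a [kinematics()] object.
#' @param p a [ti_params()] object.
#' @return 3x3 symmetric stress tensor, Pa.
#' @export
cauchy_stress <- function(kin, p) {
  stopifnot(inherits(kin, "kinematics"), inherits(p, "ti_params"))
  inv <- deviatoric_invariants(kin)
  J <- kin$J
  Bt <- J^(-2 / 3) * tcrossprod(kin$F)
  fib <- affine_fiber_update(kin$F, kin$a0)
  a <- fib$a
  W1 <- p$C1
  W2 <- p$C2
  W4I4 <- 0.5 * fiber_stress_term(inv$lambda_t, p)
  press <- p$K * log(J) / J
  dev <- (W1 + W2 * inv$I1t) * Bt - W2 * (Bt %*% Bt) +
    W4I4 * tcrossprod(a) -
    (W1 * inv$I1t + 2 * W2 * inv$I2t + W4I4) / 3 * diag(3)
  sig <- press * diag(3) + (2 / J) * dev
  (sig + t(sig)) / 2
}

#' Strain energy density of the TI law
#'
#' `W = C1*(I1t - 3) + C2*(I2t - 3) + F2(lambda_t) + K/2 * log(J)^2`.
#' The fiber energy `F2` has no elementary closed form in the toe regime
#' (its stress measure divided by the stretch must be integrated), so it
#' is evaluated by adaptive quadrature from `lambda = 1`.
#'
#' @param kin a [kinematics()] object.
#' @param p a [ti_params()] object.
#' @return scalar energy per unit reference volume, Pa.
#' @export
strain_energy <- function(kin, p) {
  inv <- deviatoric_invariants(kin)
  iso <- p$C1 * (inv$I1t - 3) + p$C2 * (inv$I2t - 3)
  fib <- 0
  if (inv$lambda_t > 1) {
    # integrate piecewise so the regime change at lambda_star never sits
    # inside an adaptive panel
    brk <- sort(unique(c(1, min(inv$lambda_t, p$lambda_star), inv$lambda_t)))
    for (j in seq_len(length(brk) - 1)) {
      fib <- fib + stats::integrate(function(s) fiber_stress_term(s, p) / s,
                                    lower = brk[j], upper = brk[j + 1],
                                    rel.tol = 1e-12)$value
    }
  }
  iso + fib + p$K / 2 * log(kin$J)^2
}

#' Grading stiffness along the fiber direction
#'
#' The scalar metric used to steer functional grading: the rate of change
#' of the fiber-direction traction stress `t(a) %*% sigma %*% a` with the
#' deviatoric fiber stretch, evaluated on the incompressible uniaxial
#' path along the fiber (`J = 1`, transverse stretches
#' `lambda_t^(-1/2)`). Under near-incompressibility it reduces to
#'
#' `kg = C1*g1(lambda) + C2*g2(lambda) + (2/3) * d/dlambda(fiber stress measure)`
#'
#' with path factors `g1 = (8/3)*lambda + (4/3)/lambda^2` and
#' `g2 = 4/3 + (8/3)/lambda^3` (both equal 4 at `lambda = 1`). In the
#' straightened-fiber regime of a fiber-dominated material
#' (`C1, C2 << C5`) this tends to `(2/3)*C5`.
#'
#' @param p a [ti_params()] object.
#' @param lambda_t deviatoric fiber stretch, positive; vectorized in
#'   `"analytic"` mode.
#' @param mode `"analytic"` (closed form above; regime ties resolve to
#'   the lower regime) or `"finite_difference"` (central difference of
#'   the traction stress computed from [cauchy_stress()] on the same
#'   path; warns if the stencil straddles a regime boundary).
#' @param h finite-difference step (default 1e-6).
#' @return kg in Pa.
#' @examples
#' ct <- valve_presets("TV")$CT
#' fib <- ti_params(C1 = 0, C3 = ct$C3, C4 = ct$C4, C5 = ct$C5,
#'                  lambda_star = ct$lambda_star)
#' grading_stiffness(fib, 1.15) / fib$C5  # 2/3
#' @export
grading_stiffness <- function(p, lambda_t, mode = c("analytic", "finite_difference"),
                              h = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(all(lambda_t > 0))
  if (mode == "analytic") {
    g1 <- (8 / 3) * lambda_t + (4 / 3) / lambda_t^2
    g2 <- 4 / 3 + (8 / 3) / lambda_t^3
    return(p$C1 * g1 + p$C2 * g2 +
             (2 / 3) * fiber_stress_term_slope(lambda_t, p))
  }
  vapply(lambda_t, function(lt) {
    lo <- lt - h
    hi <- lt + h
    for (b in c(1, p$lambda_star)) {
      if (lo < b && hi > b)
        warning("grading_stiffness: finite-difference stencil straddles a regime boundary at lambda = ",
                b)
    }
    traction <- function(l) {
      kin <- kinematics(diag(c(l, 1 / sqrt(l), 1 / sqrt(l))), c(1, 0, 0))
      sig <- cauchy_stress(kin, p)
      sig[1, 1]
    }
    (traction(hi) - traction(lo)) / (2 * h)
  }, numeric(1))
}
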