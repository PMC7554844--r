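#' Finite-deformation kinematics with a reference fiber direction
#'
#' Pairs a deformation gradient with the unit fiber direction of the
#' undeformed configuration. Deviatoric invariants, the deviatoric fiber
#' stretch and the deformed (affinely convected) fiber direction are
#' derived on demand.
#'
#' @param F 3x3 deformation gradient with positive determinant.
#' @param a0 reference fiber direction; normalized internally, must be
#'   unit length within 1e-12 if `normalize = FALSE`.
#' @param normalize rescale `a0` to unit length (default `TRUE`).
#' @return An object of class `"kinematics"`: list with `F`, `a0`, `J`.
#' @examples
#' k <- kinematics(diag(c(1.2, 1/sqrt(1.2), 1/sqrt(1.2))), c(1, 0, 0))
#' deviatoric_invariants(k)
#' @export
kinematics <- function(F, a0, normalize = TRUE) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L)) || any(!is.finite(F)))
    stop("kinematics: F must be a finite 3x3 matrix")
  J <- det(F)
  if (!is.finite(J) || J <= 0)
    stop("kinematics: det(F) must be positive")
  a0 <- as.numeric(a0)
  if (length(a0) != 3L || any(!is.finite(a0)))
    stop("kinematics: a0 must be a finite length-3 vector")
  n <- sqrt(sum(a0^2))
  if (n == 0) stop("kinematics: a0 must be nonzero")
  if (normalize) {
    a0 <- a0 / n
  } else if (abs(n - 1) > 1e-12) {
    stop("kinematics: a0 must be unit length")
  }
  structure(list(F = F, a0 = a0, J = J), class = "kinematics")
}

#' Deviatoric invariants of the right Cauchy--Green tensor
#'
#' For `C = t(F) %*% F` and its deviatoric part `Ct = J^(-2/3) * C`:
#' `I1t = tr(Ct)`, `I2t = (tr(Ct)^2 - tr(Ct %*% Ct)) / 2`,
#' `I4t = t(a0) %*% Ct %*% a0`, and the deviatoric fiber stretch
#' `lambda_t = sqrt(I4t)`. All are invariant under uniform rescaling of
#' `F` (the `J^(-2/3)` factor removes volume change).
#'
#' @param kin a [kinematics()] object.
#' @return Named list `I1t`, `I2t`, `I4t`, `lambda_t`, `J`.
#' @export
deviatoric_invariants <- function(kin) {
  stopifnot(inherits(kin, "kinematics"))
  C <- crossprod(kin$F)
  Ct <- kin$J^(-2 / 3) * C
  tr1 <- sum(diag(Ct))
  tr2 <- sum(Ct * Ct)  # tr(Ct %*% Ct) for symmetric Ct
  I4t <- as.numeric(kin$a0 %*% Ct %*% kin$a0)
  list(I1t = tr1,
       I2t = 0.5 * (tr1^2 - tr2),
       I4t = I4t,
       lambda_t = sqrt(I4t),
       J = kin$J)
}

#' Affine (convected) fiber-direction update
#'
#' The fiber kinematics are affine: the deformed fiber vector is
#' `F %*% a0`, whose magnitude is the fiber stretch `lambda` and whose
#' direction is the deformed unit fiber direction `a`.
#'
#' @param F 3x3 deformation gradient (nonsingular).
#' @param a0 unit reference fiber direction.
#' @return List with `a` (deformed unit direction) and `lambda` (stretch).
#' @examples
#' affine_fiber_update(diag(c(1.15, 1, 1)), c(1, 0, 0))
#' @export
affine_fiber_update <- function(F, a0) {
  F <- as.matrix(F)
  if (!all(dim(F) == c(3L, 3L)) || any(!is.finite(F)) || abs(det(F)) < 1e-300)
    stop("affine_fiber_update: F must be a nonsingular 3x3 matrix")
  a0 <- as.numeric(a0)
  if (abs(sqrt(sum(a0^2)) - 1) > 1e-10)
    stop("affine_fiber_update: a0 must be unit length")
  v <- as.numeric(F %*% a0)
  lambda <- sqrt(sum(v^2))
  list(a = v / lambda, lambda = lambda)
}
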