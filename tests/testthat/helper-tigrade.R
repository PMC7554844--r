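# shared test utilities: random parameter draws and rotations

random_ti_params <- function(linear_regime_ok = TRUE) {
  # tissue-plausible ranges spanning the valve presets
  ls <- runif(1, 1.02, 1.3)
  C3 <- 10^runif(1, 1, 5)
  C4 <- runif(1, 5, 60)
  f <- runif(1, 0.5, 1.5)
  ti_params(C1 = 10^runif(1, 3, 7),
            C2 = if (runif(1) < 0.5) 0 else 10^runif(1, 2, 4),
            C3 = C3, C4 = C4,
            C5 = f * C3 * C4 * exp(C4 * (ls - 1)),
            lambda_star = ls)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to det +1
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# energy per reference volume on the strict-incompressible uniaxial path
uniaxial_energy <- function(p, stretch) {
  kin <- kinematics(diag(c(stretch, 1 / sqrt(stretch), 1 / sqrt(stretch))),
                    c(1, 0, 0))
  strain_energy(kin, p)
}
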