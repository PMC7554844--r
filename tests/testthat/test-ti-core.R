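test_that("deviatoric invariants: identity, uniaxial closed form, scale invariance", {
  k <- kinematics(diag(3), c(0, 0, 1))
  inv <- deviatoric_invariants(k)
  expect_equal(unlist(inv[c("I1t", "I2t", "I4t", "lambda_t")]),
               c(I1t = 3, I2t = 3, I4t = 1, lambda_t = 1))

  # isochoric uniaxial stretch 1.2 along axis 2
  k <- kinematics(diag(c(1 / sqrt(1.2), 1.2, 1 / sqrt(1.2))), c(0, 1, 0))
  inv <- deviatoric_invariants(k)
  expect_equal(inv$I4t, 1.44, tolerance = 1e-12)
  expect_equal(inv$lambda_t, 1.2, tolerance = 1e-12)
  expect_equal(inv$I1t, 1.44 + 2 / 1.2, tolerance = 1e-12)
  expect_identical(inv$lambda_t, sqrt(inv$I4t))

  # deviatoric projection removes uniform rescaling of F
  set.seed(11)
  for (i in 1:10) {
    F <- diag(3) + 0.3 * matrix(rnorm(9), 3, 3)
    if (det(F) <= 0.1) next
    a0 <- random_unit_vector()
    i1 <- deviatoric_invariants(kinematics(F, a0))
    i2 <- deviatoric_invariants(kinematics(2.7 * F, a0))
    expect_equal(i1[c("I1t", "I2t", "I4t")], i2[c("I1t", "I2t", "I4t")],
                 tolerance = 1e-12)
  }

  expect_error(kinematics(matrix(0, 3, 3), c(1, 0, 0)), "det")
  expect_error(kinematics(matrix(NA_real_, 3, 3), c(1, 0, 0)), "finite")
})

test_that("fiber stress measure: regimes, continuity, Table-style values", {
  ll <- valve_presets("TV")$LL
  expect_identical(fiber_stress_term(0.95, ll), 0)   # compression inactive
  expect_identical(fiber_stress_term(1, ll), 0)      # tie at 1 -> zero branch
  # exponential branch, direct arithmetic
  expect_equal(fiber_stress_term(1.1, ll), 1e5 * (exp(1.35) - 1),
               tolerance = 1e-12)

  # C0 continuity at lambda_star by construction of C6
  for (i in 1:20) {
    p <- random_ti_params()
    ls <- p$lambda_star
    exp_val <- p$C3 * (exp(p$C4 * (ls - 1)) - 1)
    lin_val <- p$C5 * ls + p$C6
    expect_equal(exp_val, lin_val, tolerance = 1e-9)
    # continuity of the evaluated function across the boundary
    eps <- 1e-9
    expect_equal(fiber_stress_term(ls - eps, p), fiber_stress_term(ls + eps, p),
                 tolerance = 1e-6 * max(abs(exp_val), 1))
    expect_lt(fiber_stress_term(1 + 1e-12, p), 1e-3 * p$C3)
  }
})

test_that("slope-continuity relations reproduce the published coincidences", {
  tv <- valve_presets("TV")
  mv <- valve_presets("MV")
  # three of the six fits are numerically slope-continuous
  expect_equal(c5_c1_continuity(tv$PM), tv$PM$C5, tolerance = 5e-3)
  expect_equal(c5_c1_continuity(mv$PM), mv$PM$C5, tolerance = 5e-3)
  expect_equal(c5_c1_continuity(mv$CT), mv$CT$C5, tolerance = 5e-3)
  # lambda_star = 1 degenerate case
  p <- ti_params(C1 = 1, C3 = 10, C4 = 3, C5 = 1, lambda_star = 1)
  expect_identical(c5_c1_continuity(p), 30)

  # C6 arithmetic for the leaflet row
  ll <- tv$LL
  expect_equal(ll$C6, 1e5 * (exp(13.5 * 0.28) - 1) - 4.80e7 * 1.28,
               tolerance = 1e-12)

  # joint C5 + C6 construction implies slope agreement at lambda_star
  for (i in 1:10) {
    base <- random_ti_params()
    c5 <- c5_c1_continuity(base)
    p <- ti_params(C1 = base$C1, C3 = base$C3, C4 = base$C4, C5 = c5,
                   lambda_star = base$lambda_star)
    slope_exp <- p$C3 * p$C4 * exp(p$C4 * (p$lambda_star - 1))
    expect_equal(slope_exp, p$C5, tolerance = 1e-9)
  }
})

test_that("discontinuity index: unity under slope continuity, LL value, linearity", {
  tv <- valve_presets("TV")
  p <- ti_params(C1 = 1e4, C3 = 200, C4 = 20, C5 = 1, lambda_star = 1.12)
  p$C5 <- c5_c1_continuity(p)
  expect_equal(discontinuity_index(p), 1, tolerance = 1e-14)

  expect_equal(discontinuity_index(tv$LL), 0.81, tolerance = 0.01)

  p2 <- p
  p2$C5 <- 2 * p$C5
  expect_equal(discontinuity_index(p2), 2 * discontinuity_index(p),
               tolerance = 1e-14)
  iso <- ti_params(C1 = 1e4, C3 = 0, C4 = 1, C5 = 0, lambda_star = 1)
  expect_error(discontinuity_index(iso), "undefined")
})

test_that("Cauchy stress: zero at identity, neo-Hookean uniaxial, objectivity", {
  set.seed(21)
  for (i in 1:10) {
    p <- random_ti_params()
    sig <- cauchy_stress(kinematics(diag(3), random_unit_vector()), p)
    expect_lt(max(abs(sig)), 1e-9 * max(p$C1, p$C3))
  }

  # incompressible neo-Hookean uniaxial: normal stress difference
  p <- ti_params(C1 = 1e4, C2 = 0, C3 = 0, C4 = 1, C5 = 0, lambda_star = 1)
  l <- 1.2
  kin <- kinematics(diag(c(l, 1 / sqrt(l), 1 / sqrt(l))), c(1, 0, 0))
  sig <- cauchy_stress(kin, p)
  expect_equal(sig[1, 1] - sig[2, 2], 2 * 1e4 * (l^2 - 1 / l),
               tolerance = 1e-10)

  # objectivity under random rotations
  for (i in 1:10) {
    p <- random_ti_params()
    F <- diag(3) + 0.2 * matrix(rnorm(9), 3, 3)
    if (det(F) <= 0.2) next
    a0 <- random_unit_vector()
    Q <- random_rotation()
    s1 <- cauchy_stress(kinematics(Q %*% F, a0), p)
    s2 <- Q %*% cauchy_stress(kinematics(F, a0), p) %*% t(Q)
    expect_equal(s1, s2, tolerance = 1e-8)
  }
})

test_that("energy consistency on the incompressible uniaxial path", {
  set.seed(31)
  h <- 1e-5
  for (i in 1:100) {
    p <- random_ti_params()
    l <- runif(1, 1.02, 1.4)
    if (min(abs(l - c(1, p$lambda_star))) < 5 * h) next  # regime kinks
    dW <- (uniaxial_energy(p, l + h) - uniaxial_energy(p, l - h)) / (2 * h)
    P <- uniaxial_response(p, l)
    expect_equal(P, dW, tolerance = 1e-4)
  }
})

test_that("grading stiffness: closed forms, fiber-only limit, oracle agreement", {
  # path factors equal 4 at lambda = 1: matrix-only kg = 4 (C1 + C2)
  p <- ti_params(C1 = 3e3, C2 = 2e3, C3 = 0, C4 = 1, C5 = 0, lambda_star = 1)
  expect_equal(grading_stiffness(p, 1), 4 * (3e3 + 2e3), tolerance = 1e-12)

  # fiber-only straightened regime: kg = (2/3) C5
  ct <- valve_presets("TV")$CT
  fib <- ti_params(C1 = 0, C3 = ct$C3, C4 = ct$C4, C5 = ct$C5,
                   lambda_star = ct$lambda_star)
  expect_equal(grading_stiffness(fib, 1.15), (2 / 3) * fib$C5,
               tolerance = 1e-14)

  # compression: no fiber contribution
  p <- random_ti_params()
  expect_equal(grading_stiffness(p, 0.95),
               p$C1 * ((8 / 3) * 0.95 + (4 / 3) / 0.95^2) +
                 p$C2 * (4 / 3 + (8 / 3) / 0.95^3),
               tolerance = 1e-12)

  # analytic vs central finite difference of the traction stress
  set.seed(41)
  n_ok <- 0
  while (n_ok < 50) {
    p <- random_ti_params()
    lt <- runif(1, 0.9, 1.45)
    if (min(abs(lt - c(1, p$lambda_star))) < 1e-3) next
    kga <- grading_stiffness(p, lt, "analytic")
    kgf <- grading_stiffness(p, lt, "finite_difference")
    expect_equal(kgf, kga, tolerance = 1e-4)
    n_ok <- n_ok + 1
  }

  # boundary-straddling stencil warns
  expect_warning(grading_stiffness(p, p$lambda_star, "finite_difference"),
                 "straddles")
})
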