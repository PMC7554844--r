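test_that("scalar interpolation endpoints, midpoint, degenerate case", {
  expect_identical(interpolate_scalar(2, 10, 0), 2)
  expect_identical(interpolate_scalar(2, 10, 0.5), 6)
  expect_identical(interpolate_scalar(7, 7, 0.3), 7)
  expect_error(interpolate_scalar(0, 1, 1.2), "\\[0, 1\\]")
})

test_that("C4 solve: published row, closed form, bisection oracle round trip", {
  # slope-continuous papillary-muscle row recovers its printed exponent
  expect_equal(solve_C4(1, 0.50e2, 1.024e5, 1.15), 28.5, tolerance = 1e-3)
  # lambda_star = 1 closed form
  expect_identical(solve_C4(2, 10, 100, 1), 5)
  expect_error(solve_C4(-1, 1, 1, 1.1), "positive")

  # independent oracle: plain bisection on a wide bracket
  bisect_C4 <- function(f, C3, C5, ls, lo = 1e-8, hi = 1e4) {
    g <- function(C4) f * C3 * C4 * exp(C4 * (ls - 1)) - C5
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (g(mid) > 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  set.seed(51)
  for (i in 1:200) {
    p <- random_ti_params()
    f <- discontinuity_index(p)
    c4 <- solve_C4(f, p$C3, p$C5, p$lambda_star)
    expect_equal(c4, p$C4, tolerance = 1e-8)
    expect_equal(c4, bisect_C4(f, p$C3, p$C5, p$lambda_star), tolerance = 1e-8)
  }
})

test_that("grading endpoints reproduce terminals and f stays bounded", {
  set.seed(61)
  phi <- dist_spec("symmetric_sigmoid", c(2, 2), domain = list(X2 = c(0, 1)))
  for (i in 1:20) {
    p1 <- random_ti_params()
    pT <- random_ti_params()
    stk <- generate_fgm(terminal_fit(p1, 1.5), terminal_fit(pT, 1.5),
                        T = 8, phi_fn = phi)
    for (nm in c("C1", "C2", "C3", "C5", "lambda_star", "K", "C4")) {
      expect_equal(stk$layers[[1]][[nm]], p1[[nm]], tolerance = 1e-9)
      expect_equal(stk$layers[[8]][[nm]], pT[[nm]], tolerance = 1e-9)
    }
    f1 <- discontinuity_index(p1)
    fT <- discontinuity_index(pT)
    expect_true(all(stk$f >= min(f1, fT) - 1e-12 &
                    stk$f <= max(f1, fT) + 1e-12))
    # every layer C0-continuous at its own lambda_star
    for (l in stk$layers) {
      expect_equal(l$C3 * (exp(l$C4 * (l$lambda_star - 1)) - 1),
                   l$C5 * l$lambda_star + l$C6,
                   tolerance = 1e-9 * max(l$C5, 1))
    }
    # monotone terminal ordering + monotone psi -> monotone lambda_star
    ls <- vapply(stk$layers, `[[`, numeric(1), "lambda_star")
    expect_true(all(diff(ls) * sign(pT$lambda_star - p1$lambda_star) >= -1e-12))
  }
})

test_that("degenerate phi and special terminal handling", {
  tv <- valve_presets("TV")
  # phi = 0 everywhere -> every layer equals terminal 1
  stk <- generate_fgm(terminal_fit(tv$LL, 1.5), terminal_fit(tv$CT, 1.5),
                      T = 5, phi_fn = rep(0, 5), psi_fn = rep(0, 5))
  for (t in 1:4)
    expect_equal(stk$layers[[t]]$C5, tv$LL$C5, tolerance = 1e-9)

  # uncrimped terminal (lambda_max < lambda_star): C5 replaced, f = 1
  stk2 <- generate_fgm(terminal_fit(tv$LL, lambda_max = 1.05),
                       terminal_fit(tv$CT, 1.5),
                       T = 6, phi_fn = function(x) x, coords = seq(0, 1, length.out = 6))
  expect_equal(stk2$layers[[1]]$C5, c5_c1_continuity(tv$LL), tolerance = 1e-12)
  expect_equal(stk2$f[1], 1, tolerance = 1e-12)
  expect_equal(discontinuity_index(stk2$layers[[1]]), 1, tolerance = 1e-9)

  # isotropic terminal: f and lambda_star graded from 1 under phi
  iso <- terminal_fit(ti_params(C1 = 1e4, C3 = 0, C4 = 1, C5 = 0,
                                lambda_star = 1),
                      lambda_max = 1.5, is_isotropic = TRUE)
  stk3 <- generate_fgm(iso, terminal_fit(tv$CT, 1.5), T = 6,
                       phi_fn = function(x) x,
                       coords = seq(0, 1, length.out = 6))
  expect_equal(stk3$layers[[1]]$C3, 0)
  expect_equal(stk3$layers[[1]]$C5, 0)
  expect_equal(stk3$f[1], 1)
  expect_equal(stk3$layers[[1]]$lambda_star, 1)
  expect_equal(stk3$layers[[6]]$C4, tv$CT$C4, tolerance = 1e-9)
  # C3, C5 blend up linearly from zero
  expect_equal(stk3$layers[[4]]$C3, 0.6 * tv$CT$C3, tolerance = 1e-12)

  # non-monotone psi rejected
  expect_error(generate_fgm(terminal_fit(tv$LL, 1.5), terminal_fit(tv$CT, 1.5),
                            T = 5, phi_fn = rep(0.5, 5),
                            psi_fn = c(0, 0.6, 0.4, 0.8, 1)),
               "monotone")
})

test_that("grading-stiffness profile is linear in phi beyond both critical stretches", {
  tv <- valve_presets("TV")
  phi <- dist_spec("symmetric_sigmoid", c(2, 3), domain = list(X2 = c(0, 1)))
  stk <- generate_fgm(terminal_fit(tv$LL, 1.5), terminal_fit(tv$CT, 1.5),
                      T = 8, phi_fn = phi)
  kg <- grading_stiffness_profile(stk, 1.30)  # > max lambda_star = 1.28
  expect_equal((kg - kg[1]) / (kg[8] - kg[1]), stk$phi, tolerance = 1e-6)

  # compression: matrix-only, also linear in phi
  kgc <- grading_stiffness_profile(stk, 0.95)
  expect_equal((kgc - kgc[1]) / (kgc[8] - kgc[1]), stk$phi, tolerance = 1e-6)

  # identical terminals -> constant profile
  stk2 <- generate_fgm(terminal_fit(tv$CT, 1.5), terminal_fit(tv$CT, 1.5),
                       T = 5, phi_fn = phi)
  kg2 <- grading_stiffness_profile(stk2, 1.2)
  expect_equal(max(kg2) - min(kg2), 0, tolerance = 1e-9 * max(kg2))
})

test_that("the three grading schemes behave as the unit-cell study shows", {
  res <- run_demo_case3()
  # full law: inside the terminal envelope at every grid stretch
  expect_true(res$case3$bounded)
  # slope-continuity-forced scheme: overshoots the envelope
  expect_false(res$case1$bounded)
  # independent blending: amplified slope discontinuity at lambda_star
  expect_false(res$case2$bounded)
  expect_gt(res$case2$slope_jump, 2 * res$case3$slope_jump)

  # variant 3 delegates to generate_fgm
  tv <- valve_presets("TV")
  phi <- dist_spec("symmetric_sigmoid", c(2, 2), domain = list(X2 = c(0, 1)))
  s3 <- case_study(3, terminal_fit(tv$LL, 1.5), terminal_fit(tv$CT, 1.5), 8, phi)
  sg <- generate_fgm(terminal_fit(tv$LL, 1.5), terminal_fit(tv$CT, 1.5), 8, phi)
  expect_equal(as.data.frame(s3), as.data.frame(sg), tolerance = 1e-12)
})
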