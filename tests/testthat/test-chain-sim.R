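test_that("uniaxial unit-cell response: rest state, closed forms, material ordering", {
  tv <- valve_presets("TV")
  expect_identical(uniaxial_response(tv$LL, 1), 0)

  # neo-Hookean limit: nominal stress 2*C1*(l^2 - 1/l)/l
  p <- ti_params(C1 = 1e4, C3 = 0, C4 = 1, C5 = 0, lambda_star = 1)
  l <- seq(1, 1.5, 0.1)
  expect_equal(uniaxial_response(p, l), 2e4 * (l^2 - 1 / l) / l,
               tolerance = 1e-12)

  # chordae stiffer than leaflet at 10% stretch
  expect_gt(uniaxial_response(tv$CT, 1.1), uniaxial_response(tv$LL, 1.1))

  # strictly increasing in stretch for all published fits
  grid <- seq(1, 1.5, length.out = 200)
  for (p in c(valve_presets("TV"), valve_presets("MV")))
    expect_true(all(diff(uniaxial_response(p, grid)) > 0))
})

test_that("chain equilibrium invariants: single layer, symmetry, random chains", {
  tv <- valve_presets("TV")
  g1 <- chain_geometry(2, 1.5)
  s1 <- chain_equilibrium(g1, list(tv$PM), 1.07)
  expect_equal(s1$layer_stretches, 1.07, tolerance = 1e-10)

  # identical layers, equal areas: uniform stretch
  g4 <- chain_geometry(rep(1, 4))
  s4 <- chain_equilibrium(g4, rep(list(tv$PM), 4), 1.05)
  expect_equal(s4$layer_stretches, rep(1.05, 4), tolerance = 1e-8)

  # force uniformity + elongation consistency on random graded chains
  set.seed(71)
  phi <- dist_spec("symmetric_sigmoid", c(2, 2), domain = list(X2 = c(0, 1)))
  for (i in 1:50) {
    T <- sample(3:8, 1)
    stk <- generate_fgm(terminal_fit(random_ti_params(), 1.5),
                        terminal_fit(random_ti_params(), 1.5),
                        T = T, phi_fn = phi)
    geom <- chain_geometry(runif(T, 0.5, 2), runif(T, 0.5, 3))
    lam <- runif(1, 1.01, 1.12)
    st <- chain_equilibrium(geom, stk, lam)
    expect_equal(sum(geom$layer_lengths * st$layer_stretches),
                 geom$total_length * lam, tolerance = 1e-8)
    forces <- vapply(seq_len(T), function(j)
      uniaxial_response(stk$layers[[j]], st$layer_stretches[j]) *
        geom$layer_areas[j], numeric(1))
    expect_lt(max(forces) - min(forces), 1e-8 * max(forces))
  }
})

test_that("strain localizes on the compliant muscle side of a graded CT-PM chain", {
  mats <- valve_presets("TV")
  geom <- ct_pm_geometry()
  spec <- dist_spec("asymmetric_sigmoid", c(0.301, 1.084),
                    domain = list(X2 = c(0, geom$total_length)))
  coords <- cumsum(geom$layer_lengths) - geom$layer_lengths / 2
  stk <- generate_fgm(terminal_fit(mats$PM, 1.5), terminal_fit(mats$CT, 1.5),
                      T = 10, phi_fn = spec, coords = coords)
  st <- chain_equilibrium(geom, stk, 1.10)
  eps <- fiducial_strains(st, geom)
  # muscle (layer-1) side carries most of the deformation
  expect_gt(eps[1], 10 * eps[10])
  expect_equal(which.max(eps), 1L)
})

test_that("fiducial strains: zero load, homogeneous chain, normalization invariance", {
  tv <- valve_presets("TV")
  geom <- chain_geometry(rep(1, 5))
  s0 <- chain_equilibrium(geom, rep(list(tv$PM), 5), 1)
  expect_identical(fiducial_strains(s0, geom), rep(0, 5))

  s <- chain_equilibrium(geom, rep(list(tv$PM), 5), 1.06)
  expect_equal(fiducial_strains(s, geom, normalize = TRUE), rep(1, 5),
               tolerance = 1e-8)

  # scaling raw strains leaves the normalized profile unchanged
  raw <- fiducial_strains(s, geom)
  expect_equal(0.4 * raw / max(0.4 * raw), raw / max(raw), tolerance = 1e-14)

  bad <- chain_geometry(rep(1, 5), fiducials = c(0.5, 4.9))
  bad$fiducials <- c(0.5, 7)  # outside after construction
  expect_error(fiducial_strains(s, bad), "outside")
})

test_that("affine fiber update: identity, axial stretch, simple shear", {
  up <- affine_fiber_update(diag(3), c(0, 1, 0))
  expect_equal(up$a, c(0, 1, 0))
  expect_identical(up$lambda, 1)

  up <- affine_fiber_update(diag(c(1.15, 1 / sqrt(1.15), 1 / sqrt(1.15))),
                            c(1, 0, 0))
  expect_equal(up$a, c(1, 0, 0))
  expect_equal(up$lambda, 1.15, tolerance = 1e-14)

  # simple shear gamma = 0.5, fiber transverse to shear plane
  F <- diag(3)
  F[1, 2] <- 0.5
  up <- affine_fiber_update(F, c(0, 1, 0))
  expect_equal(up$lambda, sqrt(1.25), tolerance = 1e-14)
  expect_equal(up$a, c(0.5, 1, 0) / sqrt(1.25), tolerance = 1e-14)
  expect_gt(up$a[1], 0)  # rotated toward the shear direction

  expect_error(affine_fiber_update(matrix(0, 3, 3), c(1, 0, 0)), "nonsingular")
})

test_that("orientation mapping agrees with a brute-force scan and handles edge cases", {
  spec <- dist_spec("symmetric_sigmoid", c(2, 2), domain = list(X2 = c(0, 1)))
  field <- make_orientation_field(spec, n = 60, angle_sd = 5, seed = 9)

  # targets on the samples: identity assignment
  out <- map_orientations(field, field$points)
  expect_identical(attr(out, "index"), seq_len(60))

  # single-sample field: everything inherits it
  single <- list(points = field$points[1, , drop = FALSE],
                 vectors = field$vectors[1, , drop = FALSE])
  out1 <- map_orientations(single, matrix(runif(20), ncol = 2))
  expect_true(all(out1[, 1] == field$vectors[1, 1]))

  # brute-force scalar oracle on 500 random targets
  set.seed(13)
  targets <- cbind(runif(500), runif(500))
  out <- map_orientations(field, targets)
  oracle <- integer(500)
  for (i in 1:500) {
    best <- Inf
    for (j in 1:60) {
      d <- (targets[i, 1] - field$points[j, 1])^2 +
        (targets[i, 2] - field$points[j, 2])^2
      if (d < best) {
        best <- d
        oracle[i] <- j
      }
    }
  }
  expect_identical(attr(out, "index"), oracle)

  expect_error(map_orientations(list(points = matrix(0, 0, 2),
                                     vectors = matrix(0, 0, 2)),
                                cbind(0, 0)), "empty")
})
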