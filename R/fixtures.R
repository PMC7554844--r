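#' Synthetic normalized intensity grid
#'
#' Emulates the normalized collagen diffraction intensity measured over
#' a two-dimensional transition region: the true distribution function
#' evaluated on a seeded random grid of coordinates with additive
#' Gaussian noise, clamped back into `[0, 1]`.
#'
#' @param true_dist a [dist_spec()] giving the ground-truth distribution.
#' @param n number of grid points.
#' @param sd additive intensity noise standard deviation (0 for exact).
#' @param seed integer seed (mandatory for reproducibility).
#' @param X1_range span of the transverse coordinate (only used by
#'   bidirectional / tanh families).
#' @return data frame with columns `X1`, `X2`, `intensity`.
#' @export
make_intensity_grid <- function(true_dist, n = 200, sd = 0.05, seed = 1,
                                X1_range = c(0, 1)) {
  stopifnot(inherits(true_dist, "dist_spec"), sd >= 0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  span <- true_dist$domain$X2
  X2 <- stats::runif(n, span[1], span[2])
  X1 <- stats::runif(n, X1_range[1], X1_range[2])
  phi <- dist_eval(true_dist, X1 = X1, X2 = X2)
  intensity <- pmin(1, pmax(0, phi + stats::rnorm(n, 0, sd)))
  data.frame(X1 = X1, X2 = X2, intensity = intensity)
}

#' Synthetic normalized fiducial strain profile
#'
#' Runs the forward pipeline that the shape-parameter inverse problem
#' assumes -- constrained asymmetric sigmoid, graded chain, serial-chain
#' equilibrium at each load step -- and returns the fiducial strain
#' matrix with optional multiplicative noise, max-normalized at the top
#' load step (so the profile is scale-free, mirroring how molecular
#' strains from diffraction are compared to macroscopic strains only in
#' normalized form).
#'
#' @param true_p length-2 shape parameters `(p1, p2)` of the asymmetric
#'   sigmoid.
#' @param geom a [chain_geometry()]; default [ct_pm_geometry()].
#' @param terminals list of two [terminal_fit()]; default the
#'   papillary-muscle (material 1) and chordae (material T) fits of the
#'   chosen valve preset.
#' @param preset `"TV"` or `"MV"`, used when `terminals` is `NULL`.
#' @param steps applied engineering strains; default 0 to 10% by 2%.
#' @param noise_sd multiplicative strain noise sd (0 for exact).
#' @param seed integer seed.
#' @return List of class `"strain_profile"`: `fiducials`, `steps`,
#'   `strains` (fiducial x step matrix), `p_true`.
#' @export
make_strain_profile <- function(true_p, geom = ct_pm_geometry(),
                                terminals = NULL, preset = c("TV", "MV"),
                                steps = seq(0, 0.10, by = 0.02),
                                noise_sd = 0, seed = 1) {
  preset <- match.arg(preset)
  stopifnot(noise_sd >= 0)
  if (is.null(terminals)) {
    mats <- valve_presets(preset)
    terminals <- list(terminal_fit(mats$PM, lambda_max = 1.5),
                      terminal_fit(mats$CT, lambda_max = 1.5))
  }
  T <- length(geom$layer_lengths)
  coords <- cumsum(geom$layer_lengths) - geom$layer_lengths / 2
  spec <- dist_spec("asymmetric_sigmoid", true_p,
                    domain = list(X2 = c(0, geom$total_length)))
  stack <- generate_fgm(terminals[[1]], terminals[[2]], T, spec,
                        coords = coords)
  raw <- vapply(steps, function(s) {
    if (s == 0) return(rep(0, length(geom$fiducials)))
    state <- chain_equilibrium(geom, stack, 1 + s)
    fiducial_strains(state, geom, normalize = FALSE)
  }, numeric(length(geom$fiducials)))
  raw <- matrix(raw, nrow = length(geom$fiducials))
  if (noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    raw <- raw * matrix(1 + stats::rnorm(length(raw), 0, noise_sd),
                        nrow = nrow(raw))
  }
  top <- which.max(steps)
  m <- max(raw[, top])
  if (m > 0) raw <- raw / m
  structure(list(fiducials = geom$fiducials, steps = steps, strains = raw,
                 p_true = true_p),
            class = "strain_profile")
}

#' Synthetic force--displacement curve
#'
#' Samples the incompressible uniaxial response of a known TI parameter
#' set on a displacement grid and converts to force with the given
#' reference geometry, adding seeded relative Gaussian noise.
#'
#' @param true_params a [ti_params()] object.
#' @param gauge_length reference gauge length, mm.
#' @param area reference cross-section area, mm^2.
#' @param max_strain maximum engineering strain of the sweep.
#' @param n number of points including the origin.
#' @param noise_rel relative force noise sd (0 for exact; the origin is
#'   never perturbed).
#' @param seed integer seed.
#' @return an [fd_curve()] with attribute `"p_true"`.
#' @export
make_fd_curve <- function(true_params, gauge_length = 10, area = 1,
                          max_strain = 0.15, n = 30, noise_rel = 0,
                          seed = 1) {
  stopifnot(inherits(true_params, "ti_params"), noise_rel >= 0)
  disp <- seq(0, gauge_length * max_strain, length.out = n)
  stretch <- 1 + disp / gauge_length
  force <- uniaxial_response(true_params, stretch) * area * 1e-6
  if (noise_rel > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    noise <- 1 + stats::rnorm(n, 0, noise_rel)
    noise[1] <- 1
    force <- force * noise
  }
  curve <- fd_curve(disp, force, gauge_length, area)
  attr(curve, "p_true") <- true_params
  curve
}

#' Synthetic in-plane fiber orientation field
#'
#' Emulates diffraction-derived collagen orientations across a
#' transition: the in-plane fiber angle rotates from 0 degrees (along
#' the loading axis) where the constituent fraction is 0 to 90 degrees
#' (transverse) where it is 1, plus wrapped-normal angular noise.
#'
#' @param true_dist a [dist_spec()] driving the angle interpolation.
#' @param n number of sample points.
#' @param angle_sd angular noise standard deviation in degrees
#'   (default 5).
#' @param seed integer seed.
#' @param X1_range transverse coordinate span.
#' @return List with `points` (n x 2), `vectors` (n x 2 unit vectors)
#'   and `angles` (degrees).
#' @export
make_orientation_field <- function(true_dist, n = 100, angle_sd = 5,
                                   seed = 1, X1_range = c(0, 1)) {
  stopifnot(inherits(true_dist, "dist_spec"), angle_sd >= 0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  span <- true_dist$domain$X2
  X2 <- stats::runif(n, span[1], span[2])
  X1 <- stats::runif(n, X1_range[1], X1_range[2])
  phi <- dist_eval(true_dist, X1 = X1, X2 = X2)
  ang <- 90 * phi + stats::rnorm(n, 0, angle_sd)
  rad <- ang * pi / 180
  list(points = cbind(X1 = X1, X2 = X2),
       vectors = cbind(vx = cos(rad), vy = sin(rad)),
       angles = ang)
}
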