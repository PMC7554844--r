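#' Incompressible uniaxial tension response of a TI unit cell
#'
#' Nominal (first Piola--Kirchhoff) axial stress of a unit cell stretched
#' along its fiber direction under strict incompressibility (`J = 1`,
#' transverse stretches `stretch^(-1/2)`), with the hydrostatic pressure
#' eliminated by the traction-free lateral faces. Closed form:
#'
#' `sigma_axial = 2*(C1 + C2*I1t)*(l^2 - 1/l) - 2*C2*(l^4 - 1/l^2)
#'                + fiber stress measure(l)`
#'
#' and nominal stress `= sigma_axial / l`. For a neo-Hookean matrix
#' (`C2 = C3 = 0`) this reduces to the textbook
#' `2*C1*(l^2 - 1/l) / l`.
#'
#' @param p a [ti_params()] object.
#' @param stretch axial stretch(es), positive; vectorized.
#' @return nominal axial stress in Pa (0 at `stretch = 1`).
#' @examples
#' tv <- valve_presets("TV")
#' uniaxial_response(tv$CT, 1.1) > uniaxial_response(tv$LL, 1.1)
#' @export
uniaxial_response <- function(p, stretch) {
  stopifnot(inherits(p, "ti_params"), all(stretch > 0))
  l <- stretch
  I1t <- l^2 + 2 / l
  sig <- 2 * (p$C1 + p$C2 * I1t) * (l^2 - 1 / l) -
    2 * p$C2 * (l^4 - 1 / l^2) +
    fiber_stress_term(l, p)
  sig / l
}

#' Serial-chain geometry
#'
#' Reference geometry of a one-dimensional chain of material layers used
#' as a stand-in for a tensile specimen spanning a tissue transition:
#' per-layer reference lengths and cross-section areas plus fiducial
#' marker coordinates along the chain axis where strains are read out.
#'
#' @param layer_lengths reference lengths, mm, all positive.
#' @param layer_areas reference cross-section areas, mm^2, all positive;
#'   recycled to the number of layers.
#' @param fiducials reference axial coordinates of the strain read-out
#'   points, mm, within `[0, sum(layer_lengths)]`. Default: layer
#'   midpoints.
#' @return An object of class `"chain_geometry"`.
#' @export
chain_geometry <- function(layer_lengths, layer_areas = 1, fiducials = NULL) {
  layer_lengths <- as.numeric(layer_lengths)
  layer_areas <- rep_len(as.numeric(layer_areas), length(layer_lengths))
  if (any(layer_lengths <= 0) || any(layer_areas <= 0))
    stop("chain_geometry: lengths and areas must be positive")
  total <- sum(layer_lengths)
  if (is.null(fiducials)) {
    ends <- cumsum(layer_lengths)
    fiducials <- ends - layer_lengths / 2
  }
  if (any(fiducials < 0) || any(fiducials > total))
    stop("chain_geometry: fiducials must lie within the chain span")
  structure(list(layer_lengths = layer_lengths, layer_areas = layer_areas,
                 fiducials = as.numeric(fiducials), total_length = total),
            class = "chain_geometry")
}

#' Tapered chordae--papillary-muscle chain preset
#'
#' A chain emulating a tensile specimen across the chordae tendineae to
#' papillary muscle transition: total reference length 2.7 mm split into
#' equal layers, cross-section tapering linearly from the broad muscle
#' side (3 mm^2) down to the slender chordae side (0.6 mm^2), ten
#' fiducials at the layer midpoints.
#'
#' @param T number of layers (default 10).
#' @param total_length total reference length, mm (default 2.7).
#' @param area_pm,area_ct terminal cross-section areas, mm^2.
#' @return a [chain_geometry()].
#' @export
ct_pm_geometry <- function(T = 10, total_length = 2.7,
                           area_pm = 3, area_ct = 0.6) {
  chain_geometry(rep(total_length / T, T),
                 seq(area_pm, area_ct, length.out = T))
}

#' Equilibrium of a graded serial chain under tension
#'
#' Finds the per-layer stretches of a serial chain of TI unit cells
#' loaded to a prescribed overall stretch: in series, the nominal axial
#' force `uniaxial_response(layer) * area` must be identical in every
#' layer while the layer elongations sum to the applied elongation. The
#' force level is found by monotone bracketing + `uniroot` on the total
#' elongation; each residual evaluation inverts every layer's uniaxial
#' response for the candidate force (again monotone, again `uniroot`).
#'
#' @param geom a [chain_geometry()] with as many layers as the stack.
#' @param stack a [generate_fgm()] / [case_study()] result, or a plain
#'   list of [ti_params()].
#' @param applied_stretch overall engineering stretch, `>= 1`.
#' @param tol relative convergence tolerance on both invariants
#'   (default 1e-10).
#' @return An object of class `"chain_state"`: list with
#'   `applied_stretch`, `axial_force` (N, using mm^2 areas and Pa
#'   stresses via a 1e-6 factor), `layer_stretches`, `layer_strains`,
#'   and the geometry.
#' @export
chain_equilibrium <- function(geom, stack, applied_stretch, tol = 1e-10) {
  stopifnot(inherits(geom, "chain_geometry"), applied_stretch >= 1)
  layers <- if (inherits(stack, "graded_stack")) stack$layers else stack
  nlay <- length(layers)
  if (nlay != length(geom$layer_lengths))
    stop("chain_equilibrium: geometry and stack layer counts differ")

  if (applied_stretch == 1) {
    lam <- rep(1, nlay)
    return(new_chain_state(geom, applied_stretch, 0, lam))
  }

  # per-layer coefficients as vectors so the inner inversion is one
  # vectorized Newton iteration across all layers at once
  M <- list(C1 = vapply(layers, `[[`, numeric(1), "C1"),
            C2 = vapply(layers, `[[`, numeric(1), "C2"),
            C3 = vapply(layers, `[[`, numeric(1), "C3"),
            C4 = vapply(layers, `[[`, numeric(1), "C4"),
            C5 = vapply(layers, `[[`, numeric(1), "C5"),
            C6 = vapply(layers, `[[`, numeric(1), "C6"),
            ls = vapply(layers, `[[`, numeric(1), "lambda_star"))
  resp <- function(l) {
    toe <- l > 1 & l <= M$ls
    lin <- l > M$ls
    fst <- numeric(nlay)
    fst[toe] <- M$C3[toe] * (exp(M$C4[toe] * (l[toe] - 1)) - 1)
    fst[lin] <- M$C5[lin] * l[lin] + M$C6[lin]
    I1 <- l^2 + 2 / l
    (2 * (M$C1 + M$C2 * I1) * (l^2 - 1 / l) -
       2 * M$C2 * (l^4 - 1 / l^2) + fst) / l
  }
  dresp <- function(l) {
    toe <- l > 1 & l <= M$ls
    lin <- l > M$ls
    fst <- numeric(nlay)
    dfst <- numeric(nlay)
    fst[toe] <- M$C3[toe] * (exp(M$C4[toe] * (l[toe] - 1)) - 1)
    fst[lin] <- M$C5[lin] * l[lin] + M$C6[lin]
    dfst[toe] <- M$C3[toe] * M$C4[toe] * exp(M$C4[toe] * (l[toe] - 1))
    dfst[lin] <- M$C5[lin]
    I1 <- l^2 + 2 / l
    dI1 <- 2 * l - 2 / l^2
    sig <- 2 * (M$C1 + M$C2 * I1) * (l^2 - 1 / l) -
      2 * M$C2 * (l^4 - 1 / l^2) + fst
    dsig <- 2 * M$C2 * dI1 * (l^2 - 1 / l) +
      2 * (M$C1 + M$C2 * I1) * (2 * l + 1 / l^2) -
      2 * M$C2 * (4 * l^3 + 2 / l^3) + dfst
    (dsig * l - sig) / l^2
  }

  # invert every layer's nominal stress at force N (Pa * mm^2) by
  # bracketed Newton; warm-started from the previous force level
  lam_warm <- rep(applied_stretch, nlay)
  layer_stretch_at <- function(N) {
    target <- N / geom$layer_areas
    lam <- pmax(1 + 1e-9, lam_warm)
    lo <- rep(1, nlay)
    hi <- pmax(lam, applied_stretch)
    while (any(grow <- resp(hi) < target)) hi[grow] <- 1 + (hi[grow] - 1) * 2
    for (it in 1:100) {
      f <- resp(lam) - target
      lo[f < 0] <- lam[f < 0]
      hi[f > 0] <- lam[f > 0]
      step <- f / dresp(lam)
      cand <- lam - step
      bad <- !is.finite(cand) | cand <= lo | cand >= hi
      cand[bad] <- (lo[bad] + hi[bad]) / 2
      done <- max(abs(cand - lam)) < 1e-14 * max(lam)
      lam <- cand
      if (done) break
    }
    lam_warm <<- lam
    lam
  }
  elong <- function(N) sum(geom$layer_lengths * layer_stretch_at(N)) -
    geom$total_length * applied_stretch

  # bracket the force: all layers at the applied stretch overshoots
  N_hi <- min(resp(rep(applied_stretch, nlay)) * geom$layer_areas)
  if (N_hi <= 0) stop("chain_equilibrium: degenerate stack (no stiffness)")
  while (elong(N_hi) < 0) N_hi <- N_hi * 2
  N <- stats::uniroot(elong, c(0, N_hi), tol = N_hi * 1e-14)$root
  lam <- layer_stretch_at(N)

  state <- new_chain_state(geom, applied_stretch, N, lam)
  forces <- resp(lam) * geom$layer_areas
  if (abs(sum(geom$layer_lengths * lam) / (geom$total_length * applied_stretch) - 1) > 1e-8 ||
      (max(forces) - min(forces)) > 1e-8 * max(max(forces), 1e-12))
    stop("chain_equilibrium: failed to converge (elongation or force residual too large)")
  state
}

new_chain_state <- function(geom, applied_stretch, N, lam) {
  structure(list(applied_stretch = applied_stretch,
                 axial_force = N * 1e-6,  # Pa * mm^2 -> N
                 layer_stretches = lam,
                 layer_strains = lam - 1,
                 geom = geom),
            class = "chain_state")
}

#' Engineering strain at the fiducial markers
#'
#' Reads the engineering strain of the layer containing each fiducial
#' coordinate. A fiducial on a layer boundary belongs to the lower
#' layer.
#'
#' @param state a [chain_equilibrium()] result.
#' @param geom a [chain_geometry()]; defaults to the one in `state`.
#' @param normalize divide by the maximum fiducial strain (used when
#'   comparing scale-free profiles across load steps; see
#'   [make_strain_profile()] for the multi-step convention).
#' @return numeric vector of strains, one per fiducial.
#' @export
fiducial_strains <- function(state, geom = state$geom, normalize = FALSE) {
  stopifnot(inherits(state, "chain_state"), inherits(geom, "chain_geometry"))
  ends <- cumsum(geom$layer_lengths)
  idx <- vapply(geom$fiducials, function(x) {
    i <- which(x <= ends + 1e-12)[1]
    if (is.na(i)) stop("fiducial_strains: fiducial outside the chain")
    i
  }, integer(1))
  eps <- state$layer_strains[idx]
  if (normalize) {
    m <- max(eps)
    if (m > 0) eps <- eps / m
  }
  eps
}

#' Map sampled fiber orientations onto target points
#'
#' Assigns to each target point (e.g. an element centroid) the fiber
#' orientation of its nearest sample point in the plane (Euclidean
#' distance, ties broken toward the lowest sample index). With a single
#' sample the whole field inherits that orientation.
#'
#' @param field an orientation field: list with `points` (n x 2 matrix of
#'   sample coordinates) and `vectors` (n x 2 matrix of unit in-plane
#'   fiber vectors), as produced by [make_orientation_field()].
#' @param targets m x 2 matrix of target coordinates.
#' @return m x 2 matrix of assigned unit vectors, with attribute
#'   `"index"` giving the chosen sample per target.
#' @export
map_orientations <- function(field, targets) {
  pts <- as.matrix(field$points)
  vecs <- as.matrix(field$vectors)
  if (nrow(pts) == 0) stop("map_orientations: empty orientation field")
  targets <- matrix(as.numeric(targets), ncol = 2)
  # all-pairs squared distances; min index is the first minimum (ties ->
  # lowest sample index by max.col on the negated transpose)
  d2 <- outer(targets[, 1], pts[, 1], "-")^2 +
    outer(targets[, 2], pts[, 2], "-")^2
  idx <- max.col(-d2, ties.method = "first")
  out <- vecs[idx, , drop = FALSE]
  attr(out, "index") <- idx
  out
}
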