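#' Linear blend of a scalar between two terminal values
#'
#' `v1 + (vT - v1) * frac` -- the interpolation pattern used for every
#' individually graded TI coefficient.
#'
#' @param v1,vT terminal values; @param frac fraction(s) in `[0, 1]`.
#' @return blended value(s).
#' @export
interpolate_scalar <- function(v1, vT, frac) {
  if (any(frac < 0 | frac > 1))
    stop("interpolate_scalar: frac must lie in [0, 1]")
  v1 + (vT - v1) * frac
}

#' Solve for the toe-region exponent from the discontinuity index
#'
#' Inverts `g(C4) = f * C3 * C4 * exp(C4 * (lambda_star - 1)) - C5 = 0`
#' for its unique positive root. `g` is strictly increasing in `C4` when
#' `lambda_star >= 1`, so a bracketing search (bracket doubled until it
#' straddles the root) followed by `uniroot` and a Newton polish is
#' globally convergent; for `lambda_star = 1` the closed form
#' `C4 = C5 / (f * C3)` is returned directly.
#'
#' @param f_t target discontinuity index (> 0).
#' @param C3_t toe-region scale, Pa (> 0).
#' @param C5_t straightened-fiber modulus, Pa (> 0).
#' @param lambda_star_t critical stretch (`>= 1`).
#' @return C4 (dimensionless), accurate to ~1e-12 relative.
#' @examples
#' solve_C4(1, 0.50e2, 1.024e5, 1.15)  # ~28.5, the papillary-muscle exponent
#' @export
solve_C4 <- function(f_t, C3_t, C5_t, lambda_star_t) {
  if (f_t <= 0 || C3_t <= 0 || C5_t <= 0 || lambda_star_t < 1)
    stop("solve_C4: f, C3, C5 must be positive and lambda_star >= 1")
  if (lambda_star_t == 1) return(C5_t / (f_t * C3_t))
  g <- function(C4) f_t * C3_t * C4 * exp(C4 * (lambda_star_t - 1)) - C5_t
  hi <- 1
  while (g(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e6) stop("solve_C4: failed to bracket the root")
  }
  root <- stats::uniroot(g, c(0, hi), tol = 1e-12)$root
  # Newton polish: g'(C4) = f*C3*(1 + C4*(ls-1))*exp(C4*(ls-1))
  for (i in 1:5) {
    gp <- f_t * C3_t * (1 + root * (lambda_star_t - 1)) *
      exp(root * (lambda_star_t - 1))
    step <- g(root) / gp
    root <- root - step
    if (abs(step) <= 1e-14 * root) break
  }
  root
}

#' Grade TI parameters across a transition region
#'
#' The interpolation law for a functionally graded transversely isotropic
#' material: given the two terminal ("pure" tissue) fits and a
#' constituent distribution `phi` over `T` layers, produce one TI
#' parameter set per layer such that the grading stiffness follows `phi`
#' in the straightened-fiber regime and the slope discontinuity at the
#' regime change stays bounded between the terminal values. Per layer:
#'
#' * `C1, C2, C3, C5` (and `K`) blend linearly under `phi`;
#' * `lambda_star` and the discontinuity index `f` blend under the
#'   monotone function `psi` (defaults to `phi`);
#' * terminals whose fit never reached the linear fiber regime
#'   (`lambda_max < lambda_star`) carry an ill-identified C5, which is
#'   replaced by the slope-continuity value ([c5_c1_continuity()]) with
#'   `f = 1` before grading; otherwise the terminal `f` comes from
#'   [discontinuity_index()];
#' * an isotropic terminal has no fiber regime at all: its `f` and
#'   `lambda_star` are set to 1 and then graded under `phi`, with `C3`
#'   and `C5` blending up from zero;
#' * each layer's `C4` is recovered from its `(f, C3, C5, lambda_star)`
#'   by [solve_C4()] and its `C6` by [c6_from_c0()].
#'
#' Layer 1 reproduces the (possibly C5-recomputed) first terminal and
#' layer `T` the second; `phi` is pinned to 0 and 1 at the ends by
#' definition of the constituent fraction.
#'
#' @param term1,termT [terminal_fit()] objects for the material-1 and
#'   material-T sides.
#' @param T number of layers (`>= 2`), terminal layers included.
#' @param phi_fn a [dist_spec()], a function of the layer coordinate, or
#'   a length-`T` numeric vector of fractions.
#' @param psi_fn monotone interpolant for `lambda_star` and `f`;
#'   `NULL` (default) means `psi == phi`. Same accepted forms as
#'   `phi_fn`. Must be non-decreasing on the sampled coordinates.
#' @param coords length-`T` layer coordinates, ordered from the
#'   material-1 side to the material-T side. Default: equally spaced on
#'   `[0, 1]` (or the `phi_fn` domain if it is a `dist_spec`).
#' @param coords_X1 optional transverse coordinates for bidirectional
#'   `phi`.
#' @return An object of class `"graded_stack"`: list with `T`, `coords`,
#'   `phi`, `psi`, `layers` (list of [ti_params()]), `f` (per-layer
#'   index). Coerce with `as.data.frame()`.
#' @examples
#' tv <- valve_presets("TV")
#' stk <- generate_fgm(terminal_fit(tv$LL, 1.5), terminal_fit(tv$CT, 1.5),
#'                     T = 8,
#'                     phi_fn = dist_spec("symmetric_sigmoid", c(2, 2),
#'                                        domain = list(X2 = c(0, 1))))
#' as.data.frame(stk)
#' @export
generate_fgm <- function(term1, termT, T, phi_fn, psi_fn = NULL,
                         coords = NULL, coords_X1 = NULL) {
  stopifnot(inherits(term1, "terminal_fit"), inherits(termT, "terminal_fit"))
  if (T < 2) stop("generate_fgm: need at least 2 layers")
  if (is.null(coords)) {
    span <- if (inherits(phi_fn, "dist_spec") && !is.null(phi_fn$domain$X2))
      phi_fn$domain$X2 else c(0, 1)
    coords <- seq(span[1], span[2], length.out = T)
  }
  if (length(coords) != T) stop("generate_fgm: coords must have length T")

  phi <- eval_fraction(phi_fn, coords, coords_X1, T)
  # constituent fraction is 0 / 1 at the terminal layers by definition
  phi[1] <- 0
  phi[T] <- 1
  any_isotropic <- term1$is_isotropic || termT$is_isotropic
  psi <- if (is.null(psi_fn) || any_isotropic) phi
         else eval_fraction(psi_fn, coords, coords_X1, T)
  psi[1] <- 0
  psi[T] <- 1
  if (any(diff(psi) < -1e-12))
    stop("generate_fgm: psi is not monotone non-decreasing on the layer coordinates")

  p1 <- term1$params
  pT <- termT$params

  # terminal discontinuity indices, with the uncrimped-fiber and
  # isotropic-terminal conventions applied before any blending
  fixup <- function(term) {
    p <- term$params
    if (term$is_isotropic)
      return(list(p = p, f = 1, lambda_star = 1))
    if (term$lambda_max < p$lambda_star) {
      p$C5 <- c5_c1_continuity(p)
      p$C6 <- c6_from_c0(p)
      return(list(p = p, f = 1, lambda_star = p$lambda_star))
    }
    list(p = p, f = discontinuity_index(p), lambda_star = p$lambda_star)
  }
  t1 <- fixup(term1)
  tT <- fixup(termT)
  p1 <- t1$p
  pT <- tT$p

  C1t <- interpolate_scalar(p1$C1, pT$C1, phi)
  C2t <- interpolate_scalar(p1$C2, pT$C2, phi)
  C3t <- interpolate_scalar(p1$C3, pT$C3, phi)
  C5t <- interpolate_scalar(p1$C5, pT$C5, phi)
  Kt  <- interpolate_scalar(p1$K, pT$K, phi)
  lst <- interpolate_scalar(t1$lambda_star, tT$lambda_star, psi)
  ft  <- interpolate_scalar(t1$f, tT$f, psi)

  layers <- vector("list", T)
  for (t in seq_len(T)) {
    C4t <- if (C3t[t] > 0 && C5t[t] > 0) {
      tryCatch(solve_C4(ft[t], C3t[t], C5t[t], max(1, lst[t])),
               error = function(e)
                 stop("generate_fgm: C4 solve failed at layer ", t, ": ",
                      conditionMessage(e)))
    } else {
      # degenerate fiber term (isotropic end): C4 is inert, keep the
      # non-degenerate terminal's exponent for continuity of the column
      if (pT$C3 > 0) pT$C4 else p1$C4
    }
    layers[[t]] <- ti_params(C1 = C1t[t], C2 = C2t[t], C3 = C3t[t],
                             C4 = C4t, C5 = C5t[t],
                             lambda_star = max(1, lst[t]), K = Kt[t])
  }
  structure(list(T = T, coords = coords, phi = phi, psi = psi,
                 layers = layers, f = ft),
            class = "graded_stack")
}

# accept dist_spec / function / numeric vector for phi and psi
eval_fraction <- function(fn, coords, coords_X1, T) {
  vals <- if (inherits(fn, "dist_spec")) {
    dist_eval(fn, X1 = coords_X1, X2 = coords)
  } else if (is.function(fn)) {
    fn(coords)
  } else if (is.numeric(fn)) {
    if (length(fn) != T) stop("fraction vector must have length T")
    fn
  } else {
    stop("phi/psi must be a dist_spec, a function, or a numeric vector")
  }
  if (any(!is.finite(vals)) || any(vals < -1e-9) || any(vals > 1 + 1e-9))
    stop("distribution values must lie in [0, 1]")
  pmin(1, pmax(0, vals))
}

#' @export
as.data.frame.graded_stack <- function(x, ...) {
  do.call(rbind, lapply(seq_len(x$T), function(t) {
    p <- x$layers[[t]]
    data.frame(t = t, X2 = x$coords[t], phi = x$phi[t], psi = x$psi[t],
               C1 = p$C1, C2 = p$C2, C3 = p$C3, C4 = p$C4, C5 = p$C5,
               C6 = p$C6, lambda_star = p$lambda_star, K = p$K, f = x$f[t])
  }))
}

#' @export
print.graded_stack <- function(x, ...) {
  cat("Graded TI stack with", x$T, "layers\n")
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Per-layer grading stiffness of a graded stack
#'
#' Evaluates [grading_stiffness()] on every layer at a common deviatoric
#' fiber stretch. In the regime beyond both terminal critical stretches
#' the profile is linear in the constituent fraction, so
#' `(kg_t - kg_1) / (kg_T - kg_1)` reproduces `phi(t)`.
#'
#' @param stack a [generate_fgm()] result.
#' @param lambda_t deviatoric fiber stretch (scalar).
#' @param mode passed to [grading_stiffness()].
#' @return numeric vector of per-layer kg, Pa.
#' @export
grading_stiffness_profile <- function(stack, lambda_t, mode = "analytic") {
  stopifnot(inherits(stack, "graded_stack"))
  vapply(stack$layers, grading_stiffness, numeric(1),
         lambda_t = lambda_t, mode = mode)
}

#' Alternative grading schemes for comparison
#'
#' Three ways to grade the same pair of terminals across `T` layers,
#' used to demonstrate why the full interpolation law is needed when the
#' terminals have dissimilar toe exponents and critical stretches:
#'
#' * **variant 1** -- every parameter except C5 blends under `phi`; C5 is
#'   then forced to slope continuity on the blended parameters. Because
#'   C4 blends linearly inside an exponential, mid-layers can become
#'   stiffer than either terminal.
#' * **variant 2** -- all parameters, C4 and `lambda_star` included,
#'   blend independently under `phi`. The blended C5 no longer matches
#'   the slope of the blended exponential branch, so mid-layers show a
#'   sharp kink at the regime change.
#' * **variant 3** -- the full interpolation law ([generate_fgm()] with
#'   `psi == phi`), which keeps the response inside the terminal
#'   envelope and the regime-change discontinuity bounded.
#'
#' @param variant 1, 2 or 3.
#' @param term1,termT [terminal_fit()] objects.
#' @param T layer count.
#' @param phi_fn distribution as in [generate_fgm()].
#' @param coords optional layer coordinates.
#' @return a `"graded_stack"`.
#' @export
case_study <- function(variant, term1, termT, T, phi_fn, coords = NULL) {
  stopifnot(variant %in% 1:3)
  if (variant == 3)
    return(generate_fgm(term1, termT, T, phi_fn, psi_fn = NULL,
                        coords = coords))
  if (is.null(coords)) {
    span <- if (inherits(phi_fn, "dist_spec") && !is.null(phi_fn$domain$X2))
      phi_fn$domain$X2 else c(0, 1)
    coords <- seq(span[1], span[2], length.out = T)
  }
  phi <- eval_fraction(phi_fn, coords, NULL, T)
  phi[1] <- 0
  phi[T] <- 1
  p1 <- term1$params
  pT <- termT$params
  layers <- vector("list", T)
  f <- numeric(T)
  for (t in seq_len(T)) {
    C1 <- interpolate_scalar(p1$C1, pT$C1, phi[t])
    C2 <- interpolate_scalar(p1$C2, pT$C2, phi[t])
    C3 <- interpolate_scalar(p1$C3, pT$C3, phi[t])
    C4 <- interpolate_scalar(p1$C4, pT$C4, phi[t])
    ls <- interpolate_scalar(p1$lambda_star, pT$lambda_star, phi[t])
    K  <- interpolate_scalar(p1$K, pT$K, phi[t])
    C5 <- if (variant == 1) {
      C3 * C4 * exp(C4 * (ls - 1))
    } else {
      interpolate_scalar(p1$C5, pT$C5, phi[t])
    }
    layers[[t]] <- ti_params(C1 = C1, C2 = C2, C3 = C3, C4 = C4, C5 = C5,
                             lambda_star = ls, K = K)
    f[t] <- discontinuity_index(layers[[t]])
  }
  structure(list(T = T, coords = coords, phi = phi, psi = phi,
                 layers = layers, f = f),
            class = "graded_stack")
}
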