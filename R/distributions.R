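#' Normalize a transition-region coordinate
#'
#' Maps the physical coordinate of a transition layer onto
#' `[-0.5, 0.5]`: `(X2t - X2_1) / (X2_T - X2_1) - 0.5`, clamped. The
#' material-1 end maps to -0.5 and the material-T end to +0.5.
#'
#' @param X2t coordinate(s) along the grading direction.
#' @param X2_1,X2_T span endpoints (material-1 and material-T sides);
#'   must differ.
#' @return normalized coordinate(s) in `[-0.5, 0.5]`.
#' @export
normalize_coord <- function(X2t, X2_1, X2_T) {
  if (X2_T == X2_1) stop("normalize_coord: degenerate span (X2_1 == X2_T)")
  pmin(0.5, pmax(-0.5, (X2t - X2_1) / (X2_T - X2_1) - 0.5))
}

#' Symmetric sigmoid distribution function
#'
#' Piecewise power sigmoid on the normalized coordinate:
#' `0.5*(1 + 2*x)^p5` on `[-0.5, 0]` and `1 - 0.5*(1 - 2*x)^p6` on
#' `[0, 0.5]`. Passes through 0, 0.5, 1 at x = -0.5, 0, +0.5 and is
#' non-decreasing for positive exponents.
#'
#' @param xbar normalized coordinate(s) in `[-0.5, 0.5]`; vectorized.
#' @param p5,p6 positive shape exponents of the lower/upper halves.
#' @return constituent fraction(s) in `[0, 1]`.
#' @export
symmetric_sigmoid <- function(xbar, p5, p6) {
  if (p5 <= 0 || p6 <= 0)
    stop("symmetric_sigmoid: exponents must be positive")
  xbar <- pmin(0.5, pmax(-0.5, xbar))
  ifelse(xbar <= 0,
         0.5 * (1 + 2 * xbar)^p5,
         1 - 0.5 * (1 - 2 * xbar)^p6)
}

#' Modified tanh distribution factor
#'
#' Saturating odd-symmetric factor used along the secondary (in-leaflet)
#' direction: with `u = p2 * (X1t - p3)`,
#' `p1 * (exp(u) - exp(-u)) / (exp(u) - exp(-u) + p4)`. Zero at
#' `X1t = p3`, tending to `p1` as `X1t -> +Inf`. Exponentials are
#' computed in shifted form so large `|u|` cannot overflow. The value is
#' not clamped here; the bidirectional wrapper clamps the product.
#'
#' @param X1t coordinate(s) transverse to the main grading direction.
#' @param p1 saturation level; @param p2 rate (> 0); @param p3 center;
#'   @param p4 offset (> 0).
#' @return factor value(s); may fall outside `[0, 1]`.
#' @export
tanh_modified <- function(X1t, p1, p2, p3, p4) {
  if (p2 <= 0 || p4 <= 0)
    stop("tanh_modified: p2 and p4 must be positive")
  u <- p2 * (X1t - p3)
  # multiply through by exp(-|u|) so neither branch overflows
  num <- ifelse(u >= 0, 1 - exp(-2 * u), exp(2 * u) - 1)
  den <- ifelse(u >= 0, 1 - exp(-2 * u) + p4 * exp(-u),
                exp(2 * u) - 1 + p4 * exp(u))
  if (any(abs(den) < 1e-12))
    stop("tanh_modified: denominator vanishes (singular parameter combination)")
  p1 * num / den
}

#' Bidirectional distribution function
#'
#' Product of the modified tanh factor in `X1` and the symmetric sigmoid
#' in the normalized `X2`, clamped to `[0, 1]` after the product (the
#' factors themselves are not clamped). Used when the constituent
#' fraction varies both along and transverse to the transition.
#'
#' @param X1t,X2t coordinates (vectorized, recycled together).
#' @param p length-6 shape vector `(p1, p2, p3, p4, p5, p6)`: the first
#'   four parameterize [tanh_modified()], the last two
#'   [symmetric_sigmoid()].
#' @param X2_1,X2_T span of the grading direction for coordinate
#'   normalization.
#' @return constituent fraction(s) in `[0, 1]`.
#' @export
bidirectional_dist <- function(X1t, X2t, p, X2_1, X2_T) {
  stopifnot(length(p) == 6)
  f1 <- tanh_modified(X1t, p[1], p[2], p[3], p[4])
  f2 <- symmetric_sigmoid(normalize_coord(X2t, X2_1, X2_T), p[5], p[6])
  pmin(1, pmax(0, f1 * f2))
}

#' Solve the smoothness constraints of the asymmetric sigmoid
#'
#' The asymmetric sigmoid generalizes the symmetric one by letting the
#' crossover (where the fraction reaches 0.5) sit at `x = p1` instead of
#' 0:
#'
#' lower branch `phi1(x) = phi11 + phi12 * (1 + 2*x)^w` on `[-0.5, p1]`,
#' upper branch `phi2(x) = phi21 + phi22 * (1 - 2*x)^p2` on `[p1, 0.5]`,
#'
#' subject to `phi1(-0.5) = 0`, `phi2(0.5) = 1`,
#' `phi1(p1) = phi2(p1) = 0.5` and matched first derivatives at `p1`.
#' Those five constraints determine the five unknowns in closed form:
#' `phi11 = 0`, `phi21 = 1`, `phi22 = -0.5 / (1 - 2*p1)^p2`,
#' `w = p2 * (1 + 2*p1) / (1 - 2*p1)` (from the slope match) and
#' `phi12 = 0.5 / (1 + 2*p1)^w`. Residuals of all five constraints are
#' checked before returning.
#'
#' @param p1 crossover coordinate, strictly inside `(-0.5, 0.5)`.
#' @param p2 upper-branch exponent, positive.
#' @return Named list `w, phi11, phi12, phi21, phi22`.
#' @examples
#' solve_asymmetric(0.301, 1.084)  # tricuspid-valve CT-PM optimum
#' @export
solve_asymmetric <- function(p1, p2) {
  if (p1 <= -0.5 || p1 >= 0.5)
    stop("solve_asymmetric: p1 must lie strictly inside (-0.5, 0.5)")
  if (p2 <= 0) stop("solve_asymmetric: p2 must be positive")
  w <- p2 * (1 + 2 * p1) / (1 - 2 * p1)
  sol <- list(w = w,
              phi11 = 0,
              phi12 = 0.5 / (1 + 2 * p1)^w,
              phi21 = 1,
              phi22 = -0.5 / (1 - 2 * p1)^p2)
  res <- asymmetric_residuals(sol, p1, p2)
  if (any(!is.finite(unlist(sol))) || max(abs(res)) > 1e-8)
    stop("solve_asymmetric: infeasible shape (p1 = ", p1, ", p2 = ", p2, ")")
  sol
}

# residuals of the five smoothness constraints (diagnostic / test hook)
asymmetric_residuals <- function(sol, p1, p2) {
  phi1 <- function(x) sol$phi11 + sol$phi12 * (1 + 2 * x)^sol$w
  phi2 <- function(x) sol$phi21 + sol$phi22 * (1 - 2 * x)^p2
  d1 <- 2 * sol$w * sol$phi12 * (1 + 2 * p1)^(sol$w - 1)
  d2 <- -2 * p2 * sol$phi22 * (1 - 2 * p1)^(p2 - 1)
  c(end0 = phi1(-0.5),
    end1 = phi2(0.5) - 1,
    cross1 = phi1(p1) - 0.5,
    cross2 = phi2(p1) - 0.5,
    slope = d1 - d2)
}

#' Evaluate the constrained asymmetric sigmoid
#'
#' @param xbar normalized coordinate(s) in `[-0.5, 0.5]`.
#' @param p1,p2 shape parameters as in [solve_asymmetric()].
#' @param sol optional pre-solved constraint solution (re-solved if
#'   missing).
#' @return constituent fraction(s) in `[0, 1]`.
#' @export
asymmetric_sigmoid <- function(xbar, p1, p2, sol = NULL) {
  if (is.null(sol)) sol <- solve_asymmetric(p1, p2)
  xbar <- pmin(0.5, pmax(-0.5, xbar))
  out <- ifelse(xbar <= p1,
                sol$phi11 + sol$phi12 * (1 + 2 * xbar)^sol$w,
                sol$phi21 + sol$phi22 * (1 - 2 * xbar)^p2)
  pmin(1, pmax(0, out))
}

#' Distribution-function specification
#'
#' A self-contained description of a constituent distribution
#' `phi(X, p)` mapping transition-region coordinates to constituent
#' fraction in `[0, 1]`: a family name, its shape-parameter vector and
#' the coordinate domain. Asymmetric sigmoids carry their solved
#' smoothness constants.
#'
#' @param family one of `"symmetric_sigmoid"` (p = p5, p6),
#'   `"asymmetric_sigmoid"` (p = p1, p2), `"tanh_modified"`
#'   (p = p1..p4, evaluated on raw X1), `"bidirectional"` (p = p1..p6)
#'   or `"linear"` (no parameters; a ramp in the normalized coordinate).
#' @param p numeric shape-parameter vector of the family's length.
#' @param domain list with `X2 = c(X2_1, X2_T)` (required except for
#'   pure `tanh_modified`) and optionally `X1 = c(lo, hi)`.
#' @return An object of class `"dist_spec"`.
#' @examples
#' spec <- dist_spec("symmetric_sigmoid", c(2, 2), domain = list(X2 = c(0, 1)))
#' dist_eval(spec, X2 = seq(0, 1, 0.25))
#' @export
dist_spec <- function(family = c("symmetric_sigmoid", "asymmetric_sigmoid",
                                 "tanh_modified", "bidirectional", "linear"),
                      p = numeric(), domain = list(X2 = c(-0.5, 0.5))) {
  family <- match.arg(family)
  np <- c(symmetric_sigmoid = 2, asymmetric_sigmoid = 2, tanh_modified = 4,
          bidirectional = 6, linear = 0)[[family]]
  if (length(p) != np)
    stop("dist_spec: family '", family, "' needs ", np, " parameters, got ",
         length(p))
  derived <- NULL
  if (family == "asymmetric_sigmoid") derived <- solve_asymmetric(p[1], p[2])
  if (family %in% c("symmetric_sigmoid", "asymmetric_sigmoid", "bidirectional",
                    "linear")) {
    if (is.null(domain$X2) || length(domain$X2) != 2)
      stop("dist_spec: domain$X2 span required for family '", family, "'")
  }
  structure(list(family = family, p = as.numeric(p), domain = domain,
                 derived = derived),
            class = "dist_spec")
}

#' Evaluate a distribution specification at coordinates
#'
#' @param spec a [dist_spec()] object.
#' @param X1 transverse coordinates (only used by `tanh_modified` and
#'   `bidirectional`).
#' @param X2 coordinates along the grading direction (normalized
#'   internally against `spec$domain$X2`).
#' @return constituent fraction(s) in `[0, 1]` (raw factor for the pure
#'   `tanh_modified` family, which is unclamped by design).
#' @export
dist_eval <- function(spec, X1 = NULL, X2 = NULL) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$p
  switch(spec$family,
    symmetric_sigmoid = {
      xb <- normalize_coord(X2, spec$domain$X2[1], spec$domain$X2[2])
      symmetric_sigmoid(xb, p[1], p[2])
    },
    asymmetric_sigmoid = {
      xb <- normalize_coord(X2, spec$domain$X2[1], spec$domain$X2[2])
      asymmetric_sigmoid(xb, p[1], p[2], sol = spec$derived)
    },
    tanh_modified = tanh_modified(X1, p[1], p[2], p[3], p[4]),
    bidirectional = bidirectional_dist(X1, X2, p, spec$domain$X2[1],
                                       spec$domain$X2[2]),
    linear = {
      xb <- normalize_coord(X2, spec$domain$X2[1], spec$domain$X2[2])
      xb + 0.5
    })
}

#' Fit a distribution function to normalized intensity data
#'
#' Least-squares fit of a distribution family to constituent-fraction
#' observations (e.g. normalized collagen diffraction intensity on a
#' grid of transition-region coordinates), by derivative-free
#' Nelder--Mead simplex search restarted from a seeded Latin-hypercube of
#' initial points -- the surface can be multimodal, so a single local
#' simplex is not trusted.
#'
#' @param grid data frame with columns `X1`, `X2`, `intensity` (fractions
#'   in `[0, 1]`; at least as many rows as free parameters).
#' @param family distribution family name as in [dist_spec()].
#' @param domain coordinate domain as in [dist_spec()].
#' @param lower,upper parameter bounds (defaults per family).
#' @param n_starts number of Latin-hypercube multistarts (default 8).
#' @param seed integer seed for the multistart design.
#' @return List with `spec` (fitted [dist_spec()]), `p`, `residual` (sum
#'   of squared errors) and `degenerate` (`TRUE` when the data carry no
#'   gradient, e.g. a constant grid, in which case the residual floor is
#'   reported rather than an error raised).
#' @export
fit_distribution <- function(grid, family = "symmetric_sigmoid",
                             domain = NULL, lower = NULL, upper = NULL,
                             n_starts = 8, seed = 1) {
  stopifnot(all(c("X2", "intensity") %in% names(grid)))
  if (any(grid$intensity < 0 | grid$intensity > 1))
    stop("fit_distribution: intensities must lie in [0, 1]")
  if (is.null(grid$X1)) grid$X1 <- 0
  if (is.null(domain))
    domain <- list(X2 = range(grid$X2), X1 = range(grid$X1))
  bounds <- switch(family,
    symmetric_sigmoid = list(lo = c(0.1, 0.1), hi = c(10, 10)),
    asymmetric_sigmoid = list(lo = c(-0.45, 0.2), hi = c(0.45, 5)),
    tanh_modified = list(lo = c(0.1, 0.05, min(grid$X1), 0.05),
                         hi = c(2, 20, max(grid$X1), 10)),
    bidirectional = list(lo = c(0.5, 0.05, min(grid$X1), 0.05, 0.1, 0.1),
                         hi = c(2, 20, max(grid$X1), 10, 10, 10)),
    stop("fit_distribution: unsupported family '", family, "'"))
  if (!is.null(lower)) bounds$lo <- lower
  if (!is.null(upper)) bounds$hi <- upper
  k <- length(bounds$lo)
  if (nrow(grid) < k)
    stop("fit_distribution: need at least ", k, " observations")

  sse <- function(par) {
    if (any(par < bounds$lo) || any(par > bounds$hi)) return(1e12)
    spec <- tryCatch(dist_spec(family, par, domain), error = function(e) NULL)
    if (is.null(spec)) return(1e12)
    pred <- tryCatch(dist_eval(spec, X1 = grid$X1, X2 = grid$X2),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(1e12)
    sum((pred - grid$intensity)^2)
  }

  starts <- latin_hypercube(n_starts, bounds$lo, bounds$hi, seed = seed)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], sse, method = "Nelder-Mead",
                   control = list(maxit = 2000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("fit_distribution: all multistarts failed for family '", family, "'")
  degenerate <- stats::var(grid$intensity) < 1e-12
  list(spec = dist_spec(family, best$par, domain),
       p = best$par, residual = best$value, degenerate = degenerate)
}

# seeded Latin-hypercube design over a box (one row per start)
latin_hypercube <- function(n, lo, hi, seed = 1) {
  k <- length(lo)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  u <- lhs::randomLHS(n, k)
  sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
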