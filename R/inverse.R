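# Compact differential-evolution global optimizer (DE/rand/1/bin) with
# box constraints. Deterministic for a given seed; used by both inverse
# problems, followed by a Nelder-Mead polish of the best member.
de_optimize <- function(fn, lower, upper, pop = 40, gens = 200,
                        F = 0.8, CR = 0.9, seed = 1, polish = TRUE) {
  k <- length(lower)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  X <- t(latin_hypercube_raw(pop, lower, upper))
  fx <- apply(X, 2, fn)
  for (g in seq_len(gens)) {
    for (i in seq_len(pop)) {
      r <- sample(setdiff(seq_len(pop), i), 3)
      v <- X[, r[1]] + F * (X[, r[2]] - X[, r[3]])
      v <- pmin(upper, pmax(lower, v))
      jrand <- sample.int(k, 1)
      cross <- stats::runif(k) < CR
      cross[jrand] <- TRUE
      u <- ifelse(cross, v, X[, i])
      fu <- fn(u)
      if (fu <= fx[i]) {
        X[, i] <- u
        fx[i] <- fu
      }
    }
  }
  best <- which.min(fx)
  par <- X[, best]
  val <- fx[best]
  if (polish) {
    pol <- stats::optim(par, function(p) {
      if (any(p < lower) || any(p > upper)) return(1e12)
      fn(p)
    }, method = "Nelder-Mead", control = list(maxit = 1000, reltol = 1e-14))
    if (pol$value <= val) {
      par <- pol$par
      val <- pol$value
    }
  }
  list(par = par, value = val)
}

# LHS rows without touching the caller's RNG bookkeeping (de_optimize
# already manages the seed)
latin_hypercube_raw <- function(n, lo, hi) {
  u <- lhs::randomLHS(n, length(lo))
  sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
}

#' Force--displacement curve
#'
#' Uniaxial tension record of a "pure" tissue specimen: displacements
#' (mm, strictly increasing from 0) with measured forces (N, 0 at zero
#' displacement), plus the reference gauge length and cross-section area
#' that map displacement to stretch and nominal stress to force.
#'
#' @param displacements,forces paired vectors.
#' @param gauge_length reference gauge length, mm.
#' @param area reference cross-section area, mm^2.
#' @return An object of class `"fd_curve"`.
#' @export
fd_curve <- function(displacements, forces, gauge_length, area) {
  displacements <- as.numeric(displacements)
  forces <- as.numeric(forces)
  if (length(displacements) != length(forces))
    stop("fd_curve: displacements and forces must pair up")
  if (displacements[1] != 0 || forces[1] != 0)
    stop("fd_curve: first point must be (0, 0)")
  if (any(diff(displacements) <= 0))
    stop("fd_curve: displacements must be strictly increasing")
  if (gauge_length <= 0 || area <= 0)
    stop("fd_curve: gauge length and area must be positive")
  structure(list(displacements = displacements, forces = forces,
                 gauge_length = gauge_length, area = area),
            class = "fd_curve")
}

# forward model: predicted forces (N) for a parameter set on a curve's grid
predict_fd <- function(p, curve) {
  stretch <- 1 + curve$displacements / curve$gauge_length
  uniaxial_response(p, stretch) * curve$area * 1e-6  # Pa * mm^2 -> N
}

#' Fit terminal TI parameters to a force--displacement curve
#'
#' Inverse problem for a "pure" tissue fit: finds the deviatoric TI
#' coefficients whose incompressible uniaxial response reproduces a
#' measured tension curve, minimizing the sum of squared force residuals
#' with a seeded differential-evolution search (log-scaled stiffnesses)
#' followed by a Nelder--Mead polish. The bulk modulus is held fixed
#' (default 1.464e8 Pa) and C2 is fixed at 0; C6 always follows from C0
#' continuity. Note the usual identifiability caveat: C3 and C4 trade
#' off on toe-only data, so fits are judged in response space (force
#' error, R^2), not coefficient by coefficient.
#'
#' @param curve an [fd_curve()] (more than 3 points).
#' @param K fixed bulk modulus, Pa.
#' @param C2 fixed second matrix coefficient, Pa.
#' @param bounds list with `lower`/`upper` for
#'   `(log10 C1, log10 C3, C4, lambda_star, log10 C5)`; sensible tissue
#'   defaults if `NULL`.
#' @param seed integer seed for the evolutionary search.
#' @param pop,gens population size and generation count of the search.
#' @return List with `fit` (a [terminal_fit()] whose `lambda_max` is the
#'   largest stretch in the curve), `r_squared`, `sse`, and
#'   `predicted` forces on the curve grid.
#' @export
fit_terminal_ti <- function(curve, K = 1.464e8, C2 = 0, bounds = NULL,
                            seed = 7, pop = 40, gens = 200) {
  stopifnot(inherits(curve, "fd_curve"))
  if (length(curve$displacements) <= 3)
    stop("fit_terminal_ti: need more than 3 points")
  max_stretch <- 1 + max(curve$displacements) / curve$gauge_length
  if (is.null(bounds))
    bounds <- list(lower = c(1, 0, 1, 1.001, 3),
                   upper = c(8, 7, 120, max_stretch + 0.05, 10))

  unpack <- function(x) {
    ti_params(C1 = 10^x[1], C2 = C2, C3 = 10^x[2], C4 = x[3], C5 = 10^x[5],
              lambda_star = x[4], K = K)
  }
  sse <- function(x) {
    p <- tryCatch(unpack(x), error = function(e) NULL)
    if (is.null(p)) return(1e12)
    r <- predict_fd(p, curve) - curve$forces
    s <- sum(r^2)
    if (!is.finite(s)) 1e12 else s
  }
  opt <- de_optimize(sse, bounds$lower, bounds$upper, pop = pop, gens = gens,
                     seed = seed)
  p_hat <- unpack(opt$par)
  pred <- predict_fd(p_hat, curve)
  ss_res <- sum((curve$forces - pred)^2)
  ss_tot <- sum((curve$forces - mean(curve$forces))^2)
  list(fit = terminal_fit(p_hat, lambda_max = max_stretch),
       r_squared = 1 - ss_res / ss_tot,
       sse = ss_res,
       predicted = pred)
}

#' Estimate distribution shape parameters from a strain profile
#'
#' Inverse problem for the transition region: given a normalized
#' fiducial strain profile measured across a graded specimen (e.g. from
#' collagen D-period changes under load) and the two terminal fits,
#' recover the shape parameters `(p1, p2)` of the constrained asymmetric
#' sigmoid that the grading followed. For each candidate the forward
#' pipeline runs end-to-end -- solve the sigmoid's smoothness
#' constraints, grade the chain ([generate_fgm()], `psi == phi`), solve
#' the serial-chain equilibrium at the maximum load step, read
#' normalized fiducial strains -- and the squared profile mismatch at
#' that step is minimized by the seeded evolutionary search. Only the
#' top load step enters the objective: that is where the fibers are
#' straightened and the molecular-to-macroscopic strain relation is
#' linear, and normalization makes the comparison scale-free.
#'
#' @param profile_exp a strain profile as returned by
#'   [make_strain_profile()]: list with `steps` (applied engineering
#'   strains), `strains` (fiducial x step matrix, max-normalized at the
#'   top step).
#' @param geom a [chain_geometry()].
#' @param terminals list of two [terminal_fit()] objects (material-1 =
#'   first, i.e. the `phi = 0` side).
#' @param bounds list with `lower`/`upper` on `(p1, p2)`; default
#'   `(-0.45, 0.2)` to `(0.45, 5)`.
#' @param seed integer seed.
#' @param pop,gens search size (defaults sized for a 2-parameter
#'   problem).
#' @return List with `p_hat`, `residual`, `profile_sim` (normalized
#'   simulated strains at the top step) and `identifiable` (`FALSE` when
#'   the objective is flat, e.g. a homogeneous chain).
#' @export
estimate_shape_parameters <- function(profile_exp, geom, terminals,
                                      bounds = NULL, seed = 3,
                                      pop = 20, gens = 40) {
  stopifnot(inherits(geom, "chain_geometry"), length(terminals) == 2)
  if (is.null(bounds))
    bounds <- list(lower = c(-0.45, 0.2), upper = c(0.45, 5))
  top <- which.max(profile_exp$steps)
  eps_exp <- profile_exp$strains[, top]
  T <- length(geom$layer_lengths)
  coords <- cumsum(geom$layer_lengths) - geom$layer_lengths / 2
  domain <- list(X2 = c(0, geom$total_length))
  top_stretch <- 1 + max(profile_exp$steps)

  sim_profile <- function(p) {
    spec <- dist_spec("asymmetric_sigmoid", p, domain)
    stack <- generate_fgm(terminals[[1]], terminals[[2]], T, spec,
                          coords = coords)
    state <- chain_equilibrium(geom, stack, top_stretch)
    fiducial_strains(state, geom, normalize = TRUE)
  }
  obj <- function(p) {
    sim <- tryCatch(sim_profile(p), error = function(e) NULL)
    if (is.null(sim)) return(1e6)  # infeasible candidates penalized
    sum((eps_exp - sim)^2)
  }

  opt <- de_optimize(obj, bounds$lower, bounds$upper, pop = pop, gens = gens,
                     seed = seed)
  if (opt$value >= 1e6)
    stop("estimate_shape_parameters: no feasible shape parameters found")
  # flatness diagnostic: objective spread over a coarse probe grid
  probe <- rbind(c(-0.3, 0.5), c(0, 1), c(0.3, 2))
  spread <- diff(range(vapply(seq_len(nrow(probe)), function(i)
    obj(probe[i, ]), numeric(1))))
  list(p_hat = opt$par,
       residual = opt$value,
       profile_sim = sim_profile(opt$par),
       identifiable = spread > 1e-10)
}
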