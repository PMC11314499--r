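#' Specification of an analytic multi-well potential
#'
#' Defines the separable potential used by [simulate_brownian()]. Energies
#' are in units of kT and lengths in reduced units. Each dimension
#' contributes independently according to the distinct well centers it
#' holds:
#'
#' * one center `c`: harmonic well `U = k (x - c)^2 / 2` with stiffness
#'   `k = well_depths[1]`;
#' * two centers `c1 < c2`: symmetric quartic double well
#'   `U = B ((x - m)^2 - a^2)^2 / a^4` with midpoint `m`, half-separation
#'   `a` and barrier height `B = barrier_heights[1]` between the minima.
#'
#' A 2D spec whose centers form a 2x2 grid therefore gives a quadruple
#' well (a double well per axis).
#'
#' @param dimension 1 or 2.
#' @param well_centers list of numeric coordinate vectors (one per well).
#' @param well_depths positive energies per well (kT); used as harmonic
#'   stiffness for single-well axes.
#' @param barrier_heights positive barrier energies (kT) for double-well
#'   axes.
#' @param kT thermal energy (reduced units), default 1.
#' @return An object of class `potential_spec`.
#' @export
potential_spec <- function(dimension = 1L,
                           well_centers = list(0),
                           well_depths = 1,
                           barrier_heights = 4,
                           kT = 1) {
  stopifnot(dimension %in% c(1L, 2L), length(well_centers) >= 1,
            all(is.finite(well_depths)), all(well_depths > 0),
            all(is.finite(barrier_heights)), all(barrier_heights > 0),
            kT >= 0)
  centers <- do.call(rbind, lapply(well_centers, function(c.) {
    stopifnot(length(c.) == dimension)
    as.numeric(c.)
  }))
  per_dim <- lapply(seq_len(dimension), function(d) {
    cs <- sort(unique(centers[, d]))
    if (length(cs) > 2)
      stop("at most two distinct well centers per dimension are supported")
    cs
  })
  structure(
    list(dimension = as.integer(dimension), centers = centers,
         per_dim = per_dim,
         well_depths = well_depths, barrier_heights = barrier_heights,
         kT = kT),
    class = "potential_spec")
}

# Potential energy and gradient, evaluated per dimension and summed.
potential_energy <- function(spec, x) {
  x <- rbind(x)
  U <- 0
  for (d in seq_len(spec$dimension)) {
    cs <- spec$per_dim[[d]]
    xd <- x[, d]
    if (length(cs) == 1) {
      k <- spec$well_depths[1]
      U <- U + 0.5 * k * (xd - cs)^2
    } else {
      m <- mean(cs); a <- diff(cs) / 2
      B <- spec$barrier_heights[1]
      U <- U + B * ((xd - m)^2 - a^2)^2 / a^4
    }
  }
  U
}

potential_gradient <- function(spec, x) {
  x <- rbind(x)
  g <- matrix(0, nrow(x), spec$dimension)
  for (d in seq_len(spec$dimension)) {
    cs <- spec$per_dim[[d]]
    xd <- x[, d]
    if (length(cs) == 1) {
      k <- spec$well_depths[1]
      g[, d] <- k * (xd - cs)
    } else {
      m <- mean(cs); a <- diff(cs) / 2
      B <- spec$barrier_heights[1]
      g[, d] <- 4 * B * (xd - m) * ((xd - m)^2 - a^2) / a^4
    }
  }
  g
}

#' Simulate overdamped (Brownian) dynamics on an analytic potential
#'
#' Euler--Maruyama integration of the overdamped Langevin equation
#' `x <- x - grad U(x) dt + sqrt(2 kT dt) xi` with standard-normal `xi`,
#' whose stationary law is the Boltzmann distribution `exp(-U/kT)`.
#' The time step is validated against the gradient magnitude at the well
#' centers so that one deterministic step cannot jump across a well.
#'
#' @param spec a [potential_spec()].
#' @param n_steps number of stored frames (>= 1).
#' @param dt integration time step (reduced units).
#' @param seed integer seed; trajectories are reproducible.
#' @param x0 starting point; default is the first well center.
#' @param bound divergence guard: error if `|x|` exceeds it (default 1e3).
#' @return Object of class `continuous_trajectory`: list with `frames`
#'   (`n_steps x dimension` matrix), `dt` and the `spec`.
#' @export
simulate_brownian <- function(spec, n_steps, dt = 1e-3, seed = 1L,
                              x0 = NULL, bound = 1e3) {
  stopifnot(inherits(spec, "potential_spec"), n_steps >= 1, dt > 0)
  if (is.null(x0)) x0 <- spec$centers[1, ]
  # dt sanity: deterministic displacement at a typical point must be small
  # relative to the well layout scale
  scale_len <- max(1, diff(range(spec$centers)))
  probe <- spec$centers + 0.1 * scale_len
  gmax <- max(abs(potential_gradient(spec, probe)), 1e-12)
  if (gmax * dt > 0.1 * scale_len)
    stop(sprintf("dt = %g too large for this potential (per-step drift %.3g exceeds 10%% of the well spacing %.3g)",
                 dt, gmax * dt, scale_len))
  set.seed(as.integer(seed))
  d <- spec$dimension
  x <- as.numeric(x0)
  sig <- sqrt(2 * spec$kT * dt)
  noise <- matrix(stats::rnorm(n_steps * d), n_steps, d)
  # specialized tight loops per potential shape (the generic path calls
  # the analytic gradient and is an order of magnitude slower)
  n_wells_dim <- vapply(spec$per_dim, length, 1L)
  X <- matrix(NA_real_, n_steps, d)
  if (all(n_wells_dim == 1)) {
    k <- spec$well_depths[1]
    cc <- vapply(spec$per_dim, `[`, numeric(1), 1)
    for (t in seq_len(n_steps)) {
      x <- x - k * (x - cc) * dt + sig * noise[t, ]
      X[t, ] <- x
    }
  } else if (all(n_wells_dim == 2)) {
    m <- vapply(spec$per_dim, mean, numeric(1))
    a <- vapply(spec$per_dim, function(cs) diff(cs) / 2, numeric(1))
    B4 <- 4 * spec$barrier_heights[1] / a^4
    for (t in seq_len(n_steps)) {
      xm <- x - m
      x <- x - B4 * xm * (xm * xm - a * a) * dt + sig * noise[t, ]
      X[t, ] <- x
    }
  } else {
    for (t in seq_len(n_steps)) {
      g <- potential_gradient(spec, x)[1, ]
      x <- x - g * dt + sig * noise[t, ]
      X[t, ] <- x
    }
  }
  if (!all(is.finite(X)) || max(abs(X)) > bound)
    stop(sprintf("trajectory diverged (|x| > %g); reduce dt = %g", bound, dt))
  structure(list(frames = X, dt = dt, spec = spec),
            class = "continuous_trajectory")
}

#' Discretize a continuous trajectory by well membership
#'
#' Assigns each frame to the nearest well center of the generating
#' potential, giving a ground-truth microstate sequence for MSM tests.
#'
#' @param ctraj a `continuous_trajectory`.
#' @return Integer vector of 1-based well indices per frame.
#' @export
assign_wells <- function(ctraj) {
  stopifnot(inherits(ctraj, "continuous_trajectory"))
  centers <- ctraj$spec$centers
  D <- outer(rowSums(ctraj$frames^2), rowSums(centers^2), "+") -
    2 * ctraj$frames %*% t(centers)
  max.col(-D, ties.method = "first")
}
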