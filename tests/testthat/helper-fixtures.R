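# shared fixtures and small independent oracles used across test files

# rotation matrix from axis-angle
rot_axis_angle <- function(axis, theta) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# rmsd after optimal superposition, by brute-force rotation search
# (random quaternion grid followed by local axis-angle refinement);
# independent of the SVD route under test
brute_force_rmsd <- function(mobile, reference, n_grid = 20000L) {
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  score_R <- function(R) sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  best <- Inf; best_aa <- c(0, 0, 0)
  set.seed(42)
  for (i in seq_len(n_grid)) {
    R <- random_rotation()
    s <- score_R(R)
    if (s < best) {
      best <- s
      th <- acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
      ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
      best_aa <- if (sum(ax^2) > 1e-12) th * ax / sqrt(sum(ax^2)) else c(0, 0, 0)
    }
  }
  obj <- function(aa) {
    th <- sqrt(sum(aa^2))
    R <- if (th < 1e-12) diag(3) else rot_axis_angle(aa, th)
    score_R(R)
  }
  stats::optim(best_aa, obj, control = list(reltol = 1e-14))$value
}

# random reversible MSM on n states (positive symmetric counts)
random_reversible_msm <- function(n, seed) {
  set.seed(seed)
  S <- matrix(stats::runif(n * n, 0.1, 1), n, n)
  S <- S + t(S)
  C <- round(1000 * S)
  estimate_msm(C, reversible = TRUE, lag = 1L)
}

# small random molecular system (single group by default)
random_system <- function(n, seed, two_groups = FALSE, spread = 6) {
  set.seed(seed)
  grp <- if (two_groups) rep(c("receptor", "ligand"),
                             c(ceiling(n / 2), floor(n / 2)))
         else rep("receptor", n)
  molecular_system(
    coords = matrix(stats::runif(3 * n, -spread, spread), n, 3),
    charges = stats::runif(n, -0.5, 0.5),
    sigma = stats::runif(n, 2.5, 3.5),
    epsilon = stats::runif(n, 0.05, 0.2),
    radii = stats::runif(n, 1.2, 1.8),
    masses = rep(12, n),
    residue = seq_len(n),
    chain = ifelse(grp == "receptor", "R", "L"),
    group = grp)
}

# random p x p orthogonal matrix (QR of a Gaussian matrix)
random_rotation_matrix <- function(p, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(p * p), p, p)))
}

# AR(1) series with stationary unit variance
ar1_series <- function(phi, n) {
  x <- numeric(n)
  e <- stats::rnorm(n, sd = sqrt(1 - phi^2))
  for (t in 2:n) x[t] <- phi * x[t - 1] + e[t]
  x
}

# well-separated Gaussian blobs
make_blobs <- function(centers, n_per, sd = 0.3, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(stats::rnorm(2 * n_per, sd = sd), ncol = 2), 2,
          centers[i, ], "+")))
}
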