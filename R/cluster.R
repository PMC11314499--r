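# squared Euclidean distances between rows of X and rows of C
dist2_to_centers <- function(X, C) {
  outer(rowSums(X^2), rowSums(C^2), "+") - 2 * X %*% t(C)
}

# k-means++ seeding (deterministic given the RNG state)
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  if (k > 1) {
    d2 <- pmax(dist2_to_centers(X, centers[1, , drop = FALSE])[, 1], 0)
    for (j in 2:k) {
      if (sum(d2) <= 0) {
        idx <- sample.int(n, 1)
      } else {
        idx <- sample.int(n, 1, prob = d2)
      }
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, pmax(dist2_to_centers(X, centers[j, , drop = FALSE])[, 1], 0))
    }
  }
  centers
}

# One Lloyd run from a k-means++ start; returns centers, assignment,
# inertia and the per-iteration inertia log (non-increasing).
lloyd_run <- function(X, k, tol = 1e-6, max_iter = 500L) {
  centers <- kmeanspp_init(X, k)
  log_inertia <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- dist2_to_centers(X, centers)
    assign <- max.col(-D, ties.method = "first")
    log_inertia <- c(log_inertia, sum(D[cbind(seq_len(nrow(X)), assign)]))
    new_centers <- centers
    for (j in seq_len(k)) {
      pts <- which(assign == j)
      if (length(pts) > 0) {
        new_centers[j, ] <- colMeans(X[pts, , drop = FALSE])
      } else {
        # revive an empty cluster at the farthest point
        new_centers[j, ] <- X[which.max(apply(D, 1, min)), ]
      }
    }
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < tol) break
  }
  D <- dist2_to_centers(X, centers)
  assign <- max.col(-D, ties.method = "first")
  list(centers = centers, assignment = assign,
       inertia = sum(D[cbind(seq_len(nrow(X)), assign)]),
       log_inertia = log_inertia)
}

#' Restarted k-means clustering in TICA (or any reduced) space
#'
#' k-means++ initialization followed by Lloyd iterations until the
#' maximum center shift falls below `tol` (or 500 iterations). The whole
#' procedure is restarted `n_restarts` times (default 10) from
#' independent seedings and the minimum-inertia solution is returned.
#' Results are deterministic for a fixed seed.
#'
#' @param Y frames-by-dimensions numeric matrix.
#' @param k number of centers (>= 1, <= number of distinct points).
#' @param n_restarts independent restarts (default 10).
#' @param seed integer seed.
#' @param tol Lloyd convergence threshold on center movement.
#' @return Object of class `cluster_model`: `k`, `centers`, `inertia`
#'   (minimum over restarts), `assignment`, `n_restarts`, `seed`,
#'   `log_inertia` (iteration log of the winning restart).
#' @export
cluster_kmeans <- function(Y, k, n_restarts = 10L, seed = 1L, tol = 1e-6) {
  Y <- as.matrix(Y)
  n_distinct <- nrow(unique(Y))
  if (k > n_distinct) stop("k exceeds the number of distinct points")
  stopifnot(k >= 1, n_restarts >= 1)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(split_seed(seed, 100L + r))
    run <- lloyd_run(Y, k, tol = tol)
    if (is.null(best) || run$inertia < best$inertia) best <- run
  }
  structure(
    list(k = as.integer(k), centers = best$centers, inertia = best$inertia,
         assignment = best$assignment, n_restarts = as.integer(n_restarts),
         seed = as.integer(seed), log_inertia = best$log_inertia),
    class = "cluster_model")
}

#' Choose k by maximum curvature of the inertia curve
#'
#' Runs restarted k-means for each k in an ascending grid and picks the k
#' with the largest discrete second difference of inertia -- a formalized
#' elbow rule that does not rely on eyeballing the curve.
#'
#' @param Y reduced data matrix.
#' @param k_grid ascending integer grid, length >= 3.
#' @param n_restarts,seed as in [cluster_kmeans()].
#' @return List with `k` (chosen), `table` (data frame of k, inertia,
#'   curvature).
#' @export
select_k <- function(Y, k_grid, n_restarts = 10L, seed = 1L) {
  if (length(k_grid) < 3) stop("k grid must contain at least 3 values")
  if (is.unsorted(k_grid, strictly = TRUE)) stop("k grid must be ascending")
  inertia <- vapply(seq_along(k_grid), function(i) {
    cluster_kmeans(Y, k_grid[i], n_restarts, seed = split_seed(seed, 200L + i))$inertia
  }, numeric(1))
  curv <- rep(NA_real_, length(k_grid))
  for (i in 2:(length(k_grid) - 1))
    curv[i] <- inertia[i - 1] - 2 * inertia[i] + inertia[i + 1]
  list(k = k_grid[which.max(curv)],
       table = data.frame(k = k_grid, inertia = inertia, curvature = curv))
}

#' Assign frames to microstates by nearest cluster center
#'
#' Ties are broken toward the lowest center index.
#'
#' @param model a [cluster_model].
#' @param Y data in the clustering space.
#' @return Integer vector of 1-based microstate labels (a discrete
#'   trajectory).
#' @export
assign_clusters <- function(model, Y) {
  Y <- as.matrix(Y)
  if (ncol(Y) != ncol(model$centers))
    stop("dimensionality does not match the cluster centers")
  D <- dist2_to_centers(Y, model$centers)
  max.col(-D, ties.method = "first")
}
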