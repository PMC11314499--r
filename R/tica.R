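#' Feature matrix container
#'
#' A frames-by-features numeric matrix with a physical frame spacing,
#' optionally split into several trajectory segments so that no lagged
#' pairs are formed across segment joins.
#'
#' @param values numeric matrix (frames x features) or list of such
#'   matrices (one per trajectory segment).
#' @param frame_interval time between frames (ns).
#' @param labels optional feature labels.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, frame_interval = 1, labels = NULL) {
  segs <- if (is.list(values)) lapply(values, as.matrix) else list(as.matrix(values))
  p <- unique(vapply(segs, ncol, 1L))
  if (length(p) != 1) stop("all segments must share the feature dimension")
  if (any(vapply(segs, function(s) any(!is.finite(s)), TRUE)))
    stop("feature matrix contains missing or non-finite values")
  if (is.null(labels)) labels <- paste0("f", seq_len(p))
  structure(list(segments = segs, n_features = p,
                 frame_interval = frame_interval, labels = labels),
            class = "feature_matrix")
}

as_feature_matrix <- function(X, frame_interval = 1) {
  if (inherits(X, "feature_matrix")) X
  else feature_matrix(X, frame_interval = frame_interval)
}

# lagged pair blocks (X_t, X_{t+lag}) within each segment
lagged_pairs <- function(fm, lag) {
  X0 <- list(); Xt <- list()
  for (s in fm$segments) {
    n <- nrow(s)
    if (n > lag) {
      X0[[length(X0) + 1L]] <- s[1:(n - lag), , drop = FALSE]
      Xt[[length(Xt) + 1L]] <- s[(lag + 1):n, , drop = FALSE]
    }
  }
  if (length(X0) == 0) stop("no segment is longer than the lag")
  list(X0 = do.call(rbind, X0), Xt = do.call(rbind, Xt))
}

#' Time-lagged independent component analysis
#'
#' Solves the generalized eigenproblem `C(tau) v = lambda C(0) v` for
#' mean-free data, with the time-lagged covariance symmetrized as
#' `(C + C^T)/2` (reversible estimate, so eigenvalues are real) and
#' clipped to at most 1. Components are normalized to unit instantaneous
#' variance (`v^T C(0) v = 1`). Eigenvalues are the autocorrelations of
#' the components at the chosen lag; the leading components are the
#' slowest collective coordinates of the input.
#'
#' @param X a [feature_matrix()] or plain frames-by-features matrix.
#' @param lag lag time in frames (>= 1, < segment length).
#' @param ridge non-negative ridge added to the diagonal of `C(0)` to
#'   regularize rank-deficient features (default 0: error on singular).
#' @param var_cutoff cumulative kinetic-variance fraction (squared
#'   eigenvalues) retained by the default projection dimension.
#' @return Object of class `tica_model` with `lag`, `means`, `C0`, `Ct`,
#'   `eigenvalues` (descending), `eigenvectors` (columns), `dim`
#'   (retained dimension), `frame_interval`.
#' @export
estimate_tica <- function(X, lag = 1L, ridge = 0, var_cutoff = 0.95) {
  fm <- as_feature_matrix(X)
  stopifnot(lag >= 1)
  lp <- lagged_pairs(fm, lag)
  N <- nrow(lp$X0)
  mu <- colMeans(rbind(lp$X0, lp$Xt))
  A <- sweep(lp$X0, 2, mu); B <- sweep(lp$Xt, 2, mu)
  C0 <- (crossprod(A) + crossprod(B)) / (2 * N)
  Ct <- (crossprod(A, B) + crossprod(B, A)) / (2 * N)
  C0 <- C0 + diag(ridge, ncol(C0))
  e0 <- eigen(C0, symmetric = TRUE)
  tol <- 1e-10 * max(e0$values, 1)
  if (any(e0$values < tol))
    stop("instantaneous covariance is singular; add a ridge (e.g. ridge = 1e-8) or drop constant features")
  W <- e0$vectors %*% diag(1 / sqrt(e0$values), length(e0$values)) %*% t(e0$vectors)
  M <- W %*% Ct %*% W
  M <- (M + t(M)) / 2
  em <- eigen(M, symmetric = TRUE)
  lambda <- pmin(em$values, 1)
  V <- W %*% em$vectors          # v' C0 v = I by construction
  ord <- order(lambda, decreasing = TRUE)
  lambda <- lambda[ord]; V <- V[, ord, drop = FALSE]
  kin <- cumsum(lambda^2) / sum(lambda^2)
  structure(
    list(lag = as.integer(lag), means = mu, C0 = C0, Ct = Ct,
         eigenvalues = lambda, eigenvectors = V,
         dim = max(1L, which(kin >= var_cutoff)[1]),
         frame_interval = fm$frame_interval),
    class = "tica_model")
}

#' Project data onto the slowest TICA components
#'
#' @param model a [tica_model].
#' @param X data with the same feature dimension used for estimation.
#' @param dim number of components (default: the model's retained
#'   dimension).
#' @return Frames-by-`dim` matrix, columns ordered by eigenvalue,
#'   mean-free with respect to the training means.
#' @export
tica_project <- function(model, X, dim = model$dim) {
  fm <- as_feature_matrix(X)
  if (fm$n_features != length(model$means))
    stop("feature count does not match the TICA model")
  if (dim > ncol(model$eigenvectors))
    stop("dim exceeds the model's retained dimension")
  Xall <- do.call(rbind, fm$segments)
  sweep(Xall, 2, model$means) %*% model$eigenvectors[, seq_len(dim), drop = FALSE]
}
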