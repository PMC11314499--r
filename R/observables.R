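#' Kabsch superposition of two coordinate sets
#'
#' Finds the proper rotation and translation minimizing the (optionally
#' weighted) least-squares deviation of `mobile` onto `reference`, via the
#' SVD of the weighted covariance with a determinant sign correction so
#' the rotation is never a reflection.
#'
#' @param mobile,reference `n x 3` coordinate matrices, `n >= 3`,
#'   non-collinear.
#' @param weights optional non-negative per-atom weights.
#' @return List with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (A) and `fitted` (the transformed mobile coordinates). The
#'   transform is `fitted = mobile %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference) || ncol(mobile) != 3)
    stop("mobile and reference must be matched n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("at least 3 atoms are required for superposition")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  # collinearity check on the reference geometry
  if (svd(Q * sqrt(w))$d[2] < 1e-9 * max(1, svd(Q * sqrt(w))$d[1]))
    stop("degenerate (collinear) geometry: rotation is not determined")
  H <- t(P * w) %*% Q
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- sweep(P %*% t(R), 2, cr, "+")
  rmsd <- sqrt(sum(w * rowSums((fitted - reference)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm),
       rmsd = rmsd, fitted = fitted)
}

#' Superpose every frame of a trajectory onto its mean structure
#'
#' Iterates fit-to-mean until the mean structure moves less than `tol`
#' (A, max coordinate change), the standard reference for fluctuation
#' analysis when no crystal structure is singled out.
#'
#' @param traj a [trajectory()].
#' @param selection optional integer vector of atom indices used both for
#'   fitting and output (default: all atoms).
#' @param tol convergence threshold on the mean structure (A).
#' @param max_iter iteration cap.
#' @return A superposed [trajectory()] restricted to `selection`.
#' @export
superpose_trajectory <- function(traj, selection = NULL, tol = 1e-6,
                                 max_iter = 50L) {
  nf <- n_frames(traj)
  if (nf < 2) stop("superposition to a mean needs at least 2 frames")
  sel <- if (is.null(selection)) seq_len(traj$n_atoms) else selection
  frames <- lapply(seq_len(nf), function(i) get_frame(traj, i)[sel, , drop = FALSE])
  mean_xyz <- frames[[1]]
  for (it in seq_len(max_iter)) {
    frames <- lapply(frames, function(f) kabsch_superpose(f, mean_xyz)$fitted)
    new_mean <- Reduce("+", frames) / nf
    shift <- max(abs(new_mean - mean_xyz))
    mean_xyz <- new_mean
    if (shift < tol) break
  }
  out <- trajectory(frames, frame_interval = traj$frame_interval)
  out$mean_structure <- mean_xyz
  out
}

#' Root-mean-square fluctuation and B-factors per atom
#'
#' After iterated mean-structure superposition, computes
#' `rmsf_i = sqrt(mean_t |x_i(t) - <x_i>|^2)` and the isotropic
#' crystallographic B-factor `B_i = (8 pi^2 / 3) rmsf_i^2`.
#'
#' @param traj a [trajectory()] (superposed internally).
#' @param selection optional atom indices.
#' @return Data frame with columns `atom`, `rmsf` (A), `b_factor` (A^2).
#' @export
rmsf <- function(traj, selection = NULL) {
  if (n_frames(traj) < 2)
    stop("fluctuations are undefined for a single-frame trajectory")
  st <- superpose_trajectory(traj, selection)
  nf <- n_frames(st)
  mean_xyz <- st$mean_structure
  dev2 <- rowSums(vapply(seq_len(nf), function(i) {
    rowSums((get_frame(st, i) - mean_xyz)^2)
  }, numeric(st$n_atoms))) / nf
  r <- sqrt(dev2)
  data.frame(atom = seq_len(st$n_atoms), rmsf = r,
             b_factor = (8 * pi^2 / 3) * r^2)
}

#' Radius of gyration per frame
#'
#' `Rg = sqrt(sum m_i |x_i - x_com|^2 / sum m_i)`; unit masses unless
#' `mass_weighted` and a topology with masses is attached.
#'
#' @param traj a [trajectory()].
#' @param mass_weighted use topology masses (default TRUE when available).
#' @return Numeric vector of per-frame Rg (A).
#' @export
radius_of_gyration <- function(traj, mass_weighted = !is.null(traj$topology)) {
  m <- if (mass_weighted) {
    if (is.null(traj$topology)) stop("mass weighting requires a topology")
    traj$topology$masses
  } else rep(1, traj$n_atoms)
  if (sum(m) <= 0) stop("total mass must be positive")
  vapply(seq_len(n_frames(traj)), function(i) {
    xyz <- get_frame(traj, i)
    com <- colSums(xyz * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  }, numeric(1))
}

#' Dynamic cross-correlation map
#'
#' Normalized cross-correlations of positional fluctuations,
#' `C_ij = <dx_i . dx_j> / sqrt(<|dx_i|^2><|dx_j|^2>)` with deviations
#' taken from the time mean after superposition. `C_ij = 1` is fully
#' correlated motion, `-1` fully anti-correlated.
#'
#' @param traj a [trajectory()] with >= 2 frames.
#' @param selection optional atom indices.
#' @param superpose superpose to the mean first (default TRUE).
#' @return Object of class `correlation_map`: the `n x n` matrix with
#'   unit diagonal.
#' @export
dccm <- function(traj, selection = NULL, superpose = TRUE) {
  if (n_frames(traj) < 2) stop("DCCM needs at least 2 frames")
  st <- if (superpose) superpose_trajectory(traj, selection)
        else {
          sel <- if (is.null(selection)) seq_len(traj$n_atoms) else selection
          tr <- trajectory(lapply(seq_len(n_frames(traj)), function(i)
            get_frame(traj, i)[sel, , drop = FALSE]),
            frame_interval = traj$frame_interval)
          tr$mean_structure <- matrix(colMeans(tr$coords), ncol = 3, byrow = TRUE)
          tr
        }
  nf <- n_frames(st); n <- st$n_atoms
  dev <- lapply(seq_len(nf), function(i) get_frame(st, i) - st$mean_structure)
  # <dx_i . dx_j> accumulated over frames
  S <- Reduce("+", lapply(dev, function(D) D %*% t(D))) / nf
  v <- diag(S)
  if (any(v < 1e-14)) {
    stop("zero-variance atom(s): ",
         paste(which(v < 1e-14), collapse = ", "))
  }
  C <- S / sqrt(outer(v, v))
  diag(C) <- 1
  C <- (C + t(C)) / 2
  structure(C, class = c("correlation_map", "matrix"))
}

#' Principal component modes of a superposed trajectory
#'
#' Eigendecomposition of the `3N x 3N` covariance matrix of superposed
#' coordinates. Eigenvalues (A^2) are the variances along each collective
#' mode; the first eigenvector is the dominant concerted motion.
#'
#' @param traj a [trajectory()].
#' @param selection optional atom indices.
#' @param n_modes number of modes to keep (<= 3N).
#' @return Object of class `mode_set`: list with `eigenvalues` (A^2,
#'   descending), `eigenvectors` (`3N x n_modes`, orthonormal columns),
#'   `mean_structure` (`N x 3`).
#' @export
pca_modes <- function(traj, selection = NULL, n_modes = 3L) {
  if (n_frames(traj) < 2) stop("PCA needs at least 2 frames")
  st <- superpose_trajectory(traj, selection)
  X <- st$coords
  if (n_modes > ncol(X)) stop("n_modes may not exceed 3N")
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / nrow(X)
  e <- eigen(C, symmetric = TRUE)
  structure(
    list(eigenvalues = pmax(e$values, 0),
         eigenvectors = e$vectors[, seq_len(n_modes), drop = FALSE],
         n_modes = as.integer(n_modes),
         mean_structure = st$mean_structure,
         total_variance = sum(pmax(e$values, 0))),
    class = "mode_set")
}

#' Export a PCA mode as a porcupine-style structure pair
#'
#' Writes a two-model PDB (mean structure, then mean plus the scaled mode
#' displacement) and a CSV of the per-atom displacement vectors, the
#' standard input for drawing porcupine arrows.
#'
#' @param modes a [pca_modes()] result.
#' @param mode which mode to export (default 1).
#' @param scale displacement scale factor (A per unit eigenvector).
#' @param pdb_path,csv_path output files.
#' @export
export_porcupine <- function(modes, mode = 1L, scale = 10,
                             pdb_path, csv_path) {
  v <- matrix(modes$eigenvectors[, mode], ncol = 3, byrow = TRUE)
  displaced <- modes$mean_structure + scale * v
  write_trajectory_pdb(trajectory(list(modes$mean_structure, displaced)),
                       pdb_path)
  utils::write.csv(
    data.frame(atom = seq_len(nrow(v)), dx = v[, 1], dy = v[, 2],
               dz = v[, 3]),
    csv_path, row.names = FALSE)
  invisible(pdb_path)
}
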