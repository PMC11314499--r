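# Coulomb constant in kcal*A/(mol*e^2)
KE_COULOMB <- 332.0636

pair_scope_idx <- function(system, pair_scope) {
  n <- nrow(system$coords)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  if (pair_scope == "inter") {
    g <- system$group
    keep <- g[idx[, 1]] != g[idx[, 2]]
    idx <- idx[keep, , drop = FALSE]
  }
  idx
}

pair_distances <- function(coords, idx) {
  d <- sqrt(rowSums((coords[idx[, 1], , drop = FALSE] -
                       coords[idx[, 2], , drop = FALSE])^2))
  if (any(d < 1e-6)) stop("coincident atoms (r < 1e-6 A)")
  d
}

#' Pairwise Coulomb energy
#'
#' Gas-phase sum `E = sum_{i<j} k_e q_i q_j / (eps r_ij)` with
#' `k_e = 332.0636 kcal A / (mol e^2)`, over all pairs (`"intra"`) or
#' receptor--ligand pairs only (`"inter"`).
#'
#' @param system a [molecular_system()].
#' @param coords optional coordinate override (`n x 3`, A).
#' @param pair_scope `"intra"` (all pairs) or `"inter"` (cross-group).
#' @param dielectric relative permittivity (default 1).
#' @return Energy in kcal/mol.
#' @export
pairwise_coulomb <- function(system, coords = NULL,
                             pair_scope = c("intra", "inter"),
                             dielectric = 1) {
  pair_scope <- match.arg(pair_scope)
  if (is.null(coords)) coords <- system$coords
  idx <- pair_scope_idx(system, pair_scope)
  if (nrow(idx) == 0) return(0)
  d <- pair_distances(coords, idx)
  sum(KE_COULOMB * system$charges[idx[, 1]] * system$charges[idx[, 2]] /
        (dielectric * d))
}

#' Pairwise Lennard-Jones energy
#'
#' `E = sum 4 eps_ij [(sigma_ij/r)^12 - (sigma_ij/r)^6]` with
#' Lorentz--Berthelot combining rules (arithmetic-mean sigma,
#' geometric-mean epsilon).
#'
#' @inheritParams pairwise_coulomb
#' @param radius_scale multiplies the per-atom sigma before combining
#'   (used for SIE's scaled-radii van der Waals term).
#' @return Energy in kcal/mol.
#' @export
pairwise_lj <- function(system, coords = NULL,
                        pair_scope = c("intra", "inter"),
                        radius_scale = 1) {
  pair_scope <- match.arg(pair_scope)
  if (is.null(coords)) coords <- system$coords
  idx <- pair_scope_idx(system, pair_scope)
  if (nrow(idx) == 0) return(0)
  d <- pair_distances(coords, idx)
  sig <- radius_scale * (system$sigma[idx[, 1]] + system$sigma[idx[, 2]]) / 2
  eps <- sqrt(system$epsilon[idx[, 1]] * system$epsilon[idx[, 2]])
  sr6 <- (sig / d)^6
  sum(4 * eps * (sr6^2 - sr6))
}
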