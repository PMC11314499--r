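#' Nonpolar surface parameters
#'
#' Surface-tension coefficient and offset of the empirical nonpolar
#' solvation term `dGsurf = gamma * dSASA + beta`.
#'
#' @param gamma surface tension (kcal/(mol A^2)), default 0.0072.
#' @param beta offset (kcal/mol), default 0.
#' @return Object of class `nonpolar_params`.
#' @export
nonpolar_params <- function(gamma = 0.0072, beta = 0) {
  structure(list(gamma = gamma, beta = beta), class = "nonpolar_params")
}

#' Nonpolar (surface) solvation term
#'
#' @param dsasa change in solvent-accessible surface area (A^2).
#' @param params a [nonpolar_params()].
#' @return `gamma * dsasa + beta` in kcal/mol.
#' @export
nonpolar_surf <- function(dsasa, params = nonpolar_params()) {
  params$gamma * dsasa + params$beta
}

# restrict a molecular system to one group
subsystem <- function(system, group) {
  keep <- system$group == group
  molecular_system(system$coords[keep, , drop = FALSE],
                   system$charges[keep], system$sigma[keep],
                   system$epsilon[keep], system$radii[keep],
                   system$masses[keep], system$residue[keep],
                   system$chain[keep], system$group[keep])
}

#' Assemble a binding-energy breakdown from per-term values
#'
#' The binding free energy is the sum of the gas-phase molecular
#' mechanics terms, the polar (generalized Born) and nonpolar (surface)
#' solvation changes, and the entropy penalty:
#' `dGbind = dEele + dEvdW + dGgb + dGsurf - TdS` (with the `-TdS` column
#' stored as the signed value that is added). The polar interaction
#' energy is `dGpol = dEele + dGgb`.
#'
#' @param eele,evdw,ggb,gsurf,tds term values (kcal/mol); `tds` is the
#'   `-TdS` entry (positive for an entropy penalty), default 0.
#' @return Object of class `energy_breakdown` with `terms`, `dGpol`,
#'   `dGbind`.
#' @export
energy_breakdown <- function(eele, evdw, ggb, gsurf, tds = 0) {
  terms <- c(dEele = eele, dEvdW = evdw, dGgb = ggb, dGsurf = gsurf,
             minus_TdS = tds)
  structure(
    list(terms = terms,
         dGpol = eele + ggb,
         dGbind = eele + evdw + ggb + gsurf + tds),
    class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Endpoint binding free energy (kcal/mol)\n")
  print(round(x$terms, 2))
  cat(sprintf("dGpol  = %.2f\ndGbind = %.2f\n", x$dGpol, x$dGbind))
  invisible(x)
}

select_snapshots <- function(n_avail, n_snapshots) {
  if (n_snapshots > n_avail)
    stop("n_snapshots exceeds the available frames")
  unique(round(seq(1, n_avail, length.out = n_snapshots)))
}

#' Snapshot-averaged MM-GBSA binding free energy
#'
#' Single-trajectory protocol: receptor, ligand and complex conformations
#' are taken from the same frames, so the gas-phase differences reduce to
#' the receptor--ligand cross terms while the solvation differences are
#' computed as complex minus isolated receptor minus isolated ligand.
#' Per snapshot:
#' `dEele` = inter-group Coulomb, `dEvdW` = inter-group Lennard-Jones,
#' `dGgb` = GB(complex) - GB(receptor) - GB(ligand),
#' `dGsurf = gamma * (SASA_cx - SASA_rec - SASA_lig) + beta`.
#' The entropy penalty `-TdS`, when supplied, is averaged over an evenly
#' strided subset of the energy snapshots (entropy estimates are costly,
#' so fewer frames are conventionally used).
#'
#' @param traj a [trajectory()] of the complex.
#' @param system the [molecular_system()] topology (receptor/ligand
#'   groups set).
#' @param n_snapshots snapshots extracted (evenly strided over frames).
#' @param entropy_term `"none"`, a single `-TdS` value, or a per-snapshot
#'   vector aligned with the energy snapshots.
#' @param n_entropy_snapshots size of the strided entropy subset
#'   (default: all energy snapshots).
#' @param eps_solvent,eps_solute GB dielectrics (defaults 78.5 / 1).
#' @param probe_radius,n_sphere_points SASA settings.
#' @param nonpolar a [nonpolar_params()].
#' @return An `energy_breakdown` whose `terms` are snapshot averages,
#'   plus `per_snapshot` (data frame), `sd` (per-term standard
#'   deviations) and `n_snapshots`.
#' @export
mmgbsa <- function(traj, system, n_snapshots = 300L,
                   entropy_term = "none",
                   n_entropy_snapshots = NULL,
                   eps_solvent = 78.5, eps_solute = 1,
                   probe_radius = 1.4, n_sphere_points = 960L,
                   nonpolar = nonpolar_params()) {
  if (nrow(system$coords) != traj$n_atoms)
    stop("topology does not match the trajectory")
  snaps <- select_snapshots(n_frames(traj), n_snapshots)
  rec_idx <- which(system$group == "receptor")
  lig_idx <- which(system$group == "ligand")
  rec <- subsystem(system, "receptor")
  lig <- subsystem(system, "ligand")
  per <- data.frame(snapshot = snaps, dEele = NA_real_, dEvdW = NA_real_,
                    dGgb = NA_real_, dGsurf = NA_real_)
  for (s in seq_along(snaps)) {
    xyz <- get_frame(traj, snaps[s])
    per$dEele[s] <- pairwise_coulomb(system, xyz, "inter")
    per$dEvdW[s] <- pairwise_lj(system, xyz, "inter")
    gb_cx <- gb_polar(system, xyz, eps_solvent, eps_solute)
    gb_r <- gb_polar(rec, xyz[rec_idx, , drop = FALSE], eps_solvent, eps_solute)
    gb_l <- gb_polar(lig, xyz[lig_idx, , drop = FALSE], eps_solvent, eps_solute)
    per$dGgb[s] <- gb_cx - gb_r - gb_l
    sa_cx <- sasa(system, xyz, probe_radius, n_sphere_points)$total
    sa_r <- sasa(rec, xyz[rec_idx, , drop = FALSE], probe_radius, n_sphere_points)$total
    sa_l <- sasa(lig, xyz[lig_idx, , drop = FALSE], probe_radius, n_sphere_points)$total
    per$dGsurf[s] <- nonpolar_surf(sa_cx - sa_r - sa_l, nonpolar)
  }
  tds_mean <- 0
  if (!identical(entropy_term, "none")) {
    tds <- as.numeric(entropy_term)
    if (length(tds) == 1) tds <- rep(tds, length(snaps))
    if (length(tds) != length(snaps))
      stop("entropy values must align with the energy snapshots")
    ns_ent <- if (is.null(n_entropy_snapshots)) length(snaps)
              else min(n_entropy_snapshots, length(snaps))
    sub <- unique(round(seq(1, length(snaps), length.out = ns_ent)))
    tds_mean <- mean(tds[sub])
  }
  out <- energy_breakdown(mean(per$dEele), mean(per$dEvdW),
                          mean(per$dGgb), mean(per$dGsurf), tds_mean)
  out$per_snapshot <- per
  out$sd <- vapply(per[, -1], stats::sd, numeric(1))
  out$n_snapshots <- length(snaps)
  out$entropy_label <- if (identical(entropy_term, "none"))
    "none (term = 0)" else "supplied -TdS values"
  out
}

#' Per-residue decomposition of the interaction energy
#'
#' Splits the snapshot-averaged inter-group Coulomb, Lennard-Jones, GB
#' and surface terms over residues. Pairwise energies (Coulomb, LJ and
#' the GB pair differences between the complex and the isolated species)
#' are attributed half to each partner residue; per-atom SASA differences
#' go to their own residue. Residue shares therefore sum to the
#' corresponding totals by construction. Residues whose total share is
#' below `hotspot_cutoff` (default -0.8 kcal/mol) are flagged as binding
#' hotspots.
#'
#' @inheritParams mmgbsa
#' @param hotspot_cutoff flag residues with total energy below this value
#'   (kcal/mol).
#' @return Data frame with one row per residue: group, chain, residue,
#'   per-term shares, `total` and `hotspot`.
#' @export
per_residue_decomposition <- function(traj, system, n_snapshots = 10L,
                                      eps_solvent = 78.5, eps_solute = 1,
                                      probe_radius = 1.4,
                                      n_sphere_points = 960L,
                                      nonpolar = nonpolar_params(),
                                      hotspot_cutoff = -0.8) {
  if (nrow(system$coords) != traj$n_atoms)
    stop("topology does not match the trajectory")
  snaps <- select_snapshots(n_frames(traj), n_snapshots)
  n <- traj$n_atoms
  res_key <- paste(system$group, system$chain, system$residue, sep = ":")
  res_levels <- unique(res_key)
  rid <- match(res_key, res_levels)
  nres <- length(res_levels)
  rec_idx <- which(system$group == "receptor")
  lig_idx <- which(system$group == "ligand")
  rec <- subsystem(system, "receptor")
  lig <- subsystem(system, "ligand")
  acc <- matrix(0, nres, 4,
                dimnames = list(res_levels, c("eele", "evdw", "ggb", "gsurf")))
  inter <- outer(system$group, system$group, "!=")
  # attribute pair energies half-and-half to the partner residues.
  # For matrices whose unordered-pair energy appears once (Coulomb/LJ,
  # symmetric with both triangles filled) the energy is sum(E)/2 and the
  # half-share is rowSums(E)/2; for GB pair terms the full double sum
  # (self terms once) IS the energy, so the half-share is rowSums(E).
  half_split <- function(E, double_sum = FALSE) {
    per_atom <- if (double_sum) rowSums(E) else rowSums(E) / 2
    as.numeric(tapply(per_atom, rid, sum))
  }
  for (s in seq_along(snaps)) {
    xyz <- get_frame(traj, snaps[s])
    D <- as.matrix(stats::dist(xyz)); diag(D) <- Inf
    if (any(D[inter] < 1e-6)) stop("coincident atoms (r < 1e-6 A)")
    # Coulomb / LJ cross-pair energies
    Ec <- KE_COULOMB * outer(system$charges, system$charges) / D
    sig <- outer(system$sigma, system$sigma, "+") / 2
    eps <- sqrt(outer(system$epsilon, system$epsilon))
    sr6 <- (sig / D)^6
    Elj <- 4 * eps * (sr6^2 - sr6)
    Ec[!inter] <- 0; Elj[!inter] <- 0
    acc[, "eele"] <- acc[, "eele"] + half_split(Ec)
    acc[, "evdw"] <- acc[, "evdw"] + half_split(Elj)
    # GB pair-term differences complex vs isolated species
    R_cx <- born_radii_obc(system, xyz)
    G_cx <- gb_pair_terms(system$charges, xyz, R_cx, eps_solute, eps_solvent)
    G_iso <- matrix(0, n, n)
    R_r <- born_radii_obc(rec, xyz[rec_idx, , drop = FALSE])
    G_iso[rec_idx, rec_idx] <- gb_pair_terms(rec$charges,
                                             xyz[rec_idx, , drop = FALSE],
                                             R_r, eps_solute, eps_solvent)
    R_l <- born_radii_obc(lig, xyz[lig_idx, , drop = FALSE])
    G_iso[lig_idx, lig_idx] <- gb_pair_terms(lig$charges,
                                             xyz[lig_idx, , drop = FALSE],
                                             R_l, eps_solute, eps_solvent)
    acc[, "ggb"] <- acc[, "ggb"] + half_split(G_cx - G_iso, double_sum = TRUE)
    # per-atom SASA differences
    sa_cx <- sasa(system, xyz, probe_radius, n_sphere_points)$atom_area
    sa_iso <- numeric(n)
    sa_iso[rec_idx] <- sasa(rec, xyz[rec_idx, , drop = FALSE],
                            probe_radius, n_sphere_points)$atom_area
    sa_iso[lig_idx] <- sasa(lig, xyz[lig_idx, , drop = FALSE],
                            probe_radius, n_sphere_points)$atom_area
    dsa <- nonpolar$gamma * (sa_cx - sa_iso)
    acc[, "gsurf"] <- acc[, "gsurf"] +
      as.numeric(tapply(dsa, rid, sum))
  }
  acc <- acc / length(snaps)
  meta <- do.call(rbind, strsplit(res_levels, ":", fixed = TRUE))
  out <- data.frame(group = meta[, 1], chain = meta[, 2],
                    residue = as.integer(meta[, 3]),
                    dEele = acc[, "eele"], dEvdW = acc[, "evdw"],
                    dGgb = acc[, "ggb"], dGsurf = acc[, "gsurf"],
                    row.names = NULL)
  out$total <- rowSums(acc)
  out$hotspot <- out$total < hotspot_cutoff
  out
}

#' Quasi-harmonic configurational entropy (Schlitter estimate)
#'
#' Upper-bound entropy from the mass-weighted coordinate covariance:
#' `S = (k_B/2) sum ln(1 + k_B T e^2 m sigma^2 / hbar^2)` over the
#' covariance eigenvalues. Returned as `T*S` in kcal/mol so that an
#' entropy penalty can be formed as `-(TS_complex - TS_rec - TS_lig)`.
#' This is a coarse stand-in for normal-mode entropies; treat the
#' absolute numbers with caution.
#'
#' @param traj a superposed [trajectory()].
#' @param masses per-atom masses (amu).
#' @param temperature Kelvin, default 300.
#' @return `T*S` in kcal/mol.
#' @export
quasiharmonic_entropy <- function(traj, masses, temperature = 300) {
  if (n_frames(traj) < 2) stop("entropy needs at least 2 frames")
  X <- traj$coords
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / nrow(X)            # A^2
  m3 <- rep(masses, each = 3)
  Cm <- C * sqrt(outer(m3, m3))           # amu A^2
  ev <- pmax(eigen(Cm, symmetric = TRUE, only.values = TRUE)$values, 0)
  # k_B T e^2 amu A^2 / hbar^2, per Kelvin: 0.0206143; e^2 = 7.389056
  arg <- 7.389056 * 0.0206143 * temperature * ev
  kBT <- 0.0019872041 * temperature       # kcal/mol
  (kBT / 2) * sum(log1p(arg))
}
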