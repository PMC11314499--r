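#' Construct a molecular system container
#'
#' Holds per-atom parameters for energy calculations: coordinates (A),
#' partial charges (e), Lennard-Jones sigma (A) and epsilon (kcal/mol),
#' intrinsic Born radii (A), masses (amu), 1-based residue indices, chain
#' labels and a group label distinguishing receptor from ligand atoms.
#'
#' @param coords `n x 3` coordinate matrix (Angstrom).
#' @param charges partial charges (e).
#' @param sigma,epsilon Lennard-Jones parameters (A; kcal/mol).
#' @param radii intrinsic Born radii (A), all positive.
#' @param masses atomic masses (amu).
#' @param residue 1-based residue index per atom, non-decreasing within a
#'   chain.
#' @param chain chain label per atom.
#' @param group `"receptor"` or `"ligand"` per atom.
#' @return Object of class `molecular_system`.
#' @export
molecular_system <- function(coords, charges, sigma, epsilon, radii,
                             masses, residue, chain, group) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  stopifnot(ncol(coords) == 3)
  lens <- c(length(charges), length(sigma), length(epsilon), length(radii),
            length(masses), length(residue), length(chain), length(group))
  if (any(lens != n))
    stop("all per-atom arrays must have the same length as coords")
  if (any(radii <= 0)) stop("Born radii must be positive")
  for (ch in unique(chain)) {
    r <- residue[chain == ch]
    if (is.unsorted(r)) stop("residue indices must be non-decreasing within a chain")
  }
  if (!all(group %in% c("receptor", "ligand")))
    stop("group labels must be 'receptor' or 'ligand'")
  structure(
    list(coords = coords, charges = as.numeric(charges),
         sigma = as.numeric(sigma), epsilon = as.numeric(epsilon),
         radii = as.numeric(radii), masses = as.numeric(masses),
         residue = as.integer(residue), chain = as.character(chain),
         group = as.character(group)),
    class = "molecular_system")
}

#' Generate a toy receptor--ligand bead complex
#'
#' Packs `n_receptor_atoms` beads into a compact cluster, then places
#' `n_ligand_atoms` beads in a shallow pocket at the receptor surface.
#' Lennard-Jones and charge parameters are drawn from typical protein-atom
#' ranges (sigma 2.5--3.5 A, epsilon 0.05--0.2 kcal/mol, q in
#' [-0.5, 0.5] e) and charges are shifted uniformly so the net charge
#' equals `net_charge` exactly. No two atoms sit closer than
#' `0.8 * (sigma_i + sigma_j) / 2`.
#'
#' @param n_receptor_atoms,n_ligand_atoms bead counts (>= 1).
#' @param seed integer seed; output is a pure function of the inputs.
#' @param net_charge requested total charge (e), default 0.
#' @param max_tries placement retries per bead before giving up.
#' @return A [molecular_system()] with beads grouped into 3-atom residues.
#' @export
make_toy_complex <- function(n_receptor_atoms, n_ligand_atoms, seed = 1L,
                             net_charge = 0, max_tries = 2000L) {
  stopifnot(n_receptor_atoms >= 1, n_ligand_atoms >= 1)
  set.seed(split_seed(seed, 7L))
  n <- n_receptor_atoms + n_ligand_atoms
  sigma <- stats::runif(n, 2.5, 3.5)
  epsilon <- stats::runif(n, 0.05, 0.2)
  charges <- stats::runif(n, -0.5, 0.5)
  charges <- charges + (net_charge - sum(charges)) / n
  radii <- stats::runif(n, 1.2, 1.8)
  masses <- stats::runif(n, 12, 16)

  min_ok <- function(x, placed, i, js) {
    if (length(js) == 0) return(TRUE)
    d <- sqrt(colSums((t(placed[js, , drop = FALSE]) - x)^2))
    all(d >= 0.8 * (sigma[i] + sigma[js]) / 2)
  }
  coords <- matrix(NA_real_, n, 3)
  # receptor: sequential insertion into a ball sized for the bead count
  R_ball <- 2.2 * max(1.5, n_receptor_atoms^(1 / 3))
  for (i in seq_len(n_receptor_atoms)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- stats::runif(3, -R_ball, R_ball)
      if (sum(x^2) > R_ball^2) next
      if (min_ok(x, coords, i, seq_len(i - 1))) { ok <- TRUE; break }
    }
    if (!ok) stop("receptor bead placement failed; increase max_tries")
    coords[i, ] <- x
  }
  # ligand: cluster just outside the receptor surface along a random
  # direction (a surface pocket for a convex bead cluster)
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  proj <- coords[seq_len(n_receptor_atoms), , drop = FALSE] %*% u
  anchor <- max(proj) + 3.2  # ~ contact distance for typical sigma
  for (j in seq_len(n_ligand_atoms)) {
    i <- n_receptor_atoms + j
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- anchor * u + stats::rnorm(3, sd = 1.2) +
        (j - 1) * 1.1 * u  # extend outward as the ligand grows
      if (min_ok(x, coords, i, seq_len(i - 1))) { ok <- TRUE; break }
    }
    if (!ok) stop("ligand bead placement failed; increase max_tries")
    coords[i, ] <- x
  }

  group <- rep(c("receptor", "ligand"), c(n_receptor_atoms, n_ligand_atoms))
  res_r <- (seq_len(n_receptor_atoms) - 1L) %/% 3L + 1L
  res_l <- (seq_len(n_ligand_atoms) - 1L) %/% 3L + 1L
  molecular_system(coords, charges, sigma, epsilon, radii, masses,
                   residue = c(res_r, res_l),
                   chain = rep(c("R", "L"), c(n_receptor_atoms, n_ligand_atoms)),
                   group = group)
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("molecular_system: %d atoms (%d receptor, %d ligand), net charge %.4f e\n",
              nrow(x$coords), sum(x$group == "receptor"),
              sum(x$group == "ligand"), sum(x$charges)))
  invisible(x)
}
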