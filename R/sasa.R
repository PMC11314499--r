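#' Quasi-uniform points on the unit sphere (Fibonacci lattice)
#'
#' Deterministic point set used by the Shrake--Rupley surface estimate;
#' a golden-angle spiral gives near-uniform coverage at any count.
#'
#' @param n number of points (>= 1).
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake--Rupley)
#'
#' For each atom, the fraction of quasi-uniform test points on the
#' probe-inflated sphere of radius `r_i + probe` lying outside every
#' neighbouring probe-inflated sphere, times the sphere area
#' `4 pi (r_i + probe)^2`. With probe 1.4 A and van der Waals radii this
#' is the conventional SASA; the same routine with other radii/probe
#' settings serves as the molecular-surface-area (MSA) estimate.
#'
#' @param radii per-atom radii (A), or a [molecular_system()] whose
#'   `radii` are used.
#' @param coords `n x 3` coordinates (A); defaults to the system's.
#' @param probe_radius probe radius (A), >= 0, default 1.4.
#' @param n_sphere_points test points per atom (>= 32), default 960.
#' @param radius_scale multiplies the atomic radii before inflation (used
#'   by SIE's scaled-radii surface term).
#' @return List with `atom_area` (A^2 per atom) and `total` (A^2).
#' @export
sasa <- function(radii, coords = NULL, probe_radius = 1.4,
                 n_sphere_points = 960L, radius_scale = 1) {
  if (inherits(radii, "molecular_system")) {
    if (is.null(coords)) coords <- radii$coords
    radii <- radii$radii
  }
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(radii) != n || any(!is.finite(radii)))
    stop("per-atom radii are required for SASA")
  stopifnot(probe_radius >= 0, n_sphere_points >= 32)
  r <- radii * radius_scale + probe_radius
  pts <- fibonacci_sphere(n_sphere_points)
  area <- numeric(n)
  D2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    nb <- which(D2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    test <- sweep(pts * r[i], 2, coords[i, ], "+")
    free <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      d2 <- rowSums(sweep(test, 2, coords[j, ])^2)
      free <- free & d2 > r[j]^2
      if (!any(free)) break
    }
    area[i] <- mean(free) * 4 * pi * r[i]^2
  }
  list(atom_area = area, total = sum(area))
}
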