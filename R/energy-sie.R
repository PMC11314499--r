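#' SIE scoring-function parameters
#'
#' Calibrated coefficients of the solvated interaction energy function:
#' overall proportionality `alpha` (absorbing configurational-entropy
#' loss), solute interior dielectric `D_in`, van der Waals radius scaling
#' `rho`, molecular-surface coefficient `gamma` (kcal/(mol A^2)) and
#' additive constant `C` (kcal/mol).
#'
#' @param alpha default 0.1048.
#' @param D_in default 2.25.
#' @param rho default 1.1.
#' @param gamma default 0.0129.
#' @param C default -2.89.
#' @return Object of class `sie_params`.
#' @export
sie_params <- function(alpha = 0.1048, D_in = 2.25, rho = 1.1,
                       gamma = 0.0129, C = -2.89) {
  structure(list(alpha = alpha, D_in = D_in, rho = rho, gamma = gamma,
                 C = C), class = "sie_params")
}

#' Solvated interaction energy (SIE)
#'
#' `dGbind = alpha * [E_c + dG_R + E_vdW + gamma * dMSA] + C` where `E_c`
#' is the intermolecular Coulomb energy at the interior dielectric,
#' `dG_R` the reaction-field change on binding, `E_vdW` the
#' intermolecular Lennard-Jones energy and `dMSA` the change in molecular
#' surface area (with radii scaled by `rho`). All components must be
#' finite.
#'
#' @param ec,gr,evdw components in kcal/mol.
#' @param dmsa surface-area change (A^2).
#' @param params a [sie_params()].
#' @return Object of class `sie_breakdown`: the components, the bracket
#'   sum and `dGbind`.
#' @export
sie <- function(ec, gr, evdw, dmsa, params = sie_params()) {
  vals <- c(ec, gr, evdw, dmsa)
  if (any(!is.finite(vals))) stop("all SIE components must be finite")
  bracket <- ec + gr + evdw + params$gamma * dmsa
  structure(
    list(E_c = ec, dG_R = gr, E_vdW = evdw, dMSA = dmsa,
         bracket = bracket, params = params,
         dGbind = params$alpha * bracket + params$C),
    class = "sie_breakdown")
}

#' Compute SIE components from a molecular system
#'
#' Evaluates the component energies for one configuration of a
#' receptor--ligand complex: intermolecular Coulomb at `eps = D_in`,
#' intermolecular Lennard-Jones with sigma scaled by `rho`, the
#' reaction-field change from the generalized Born model at interior
#' dielectric `D_in` (complex minus receptor minus ligand), and the
#' surface-area change with `rho`-scaled radii and a 1.4 A probe.
#'
#' @param system a [molecular_system()] with receptor/ligand groups.
#' @param coords optional coordinate override.
#' @param params a [sie_params()].
#' @param probe_radius probe for the surface term (default 1.4 A).
#' @param n_sphere_points surface quadrature points.
#' @return A `sie_breakdown` (see [sie()]).
#' @export
sie_from_system <- function(system, coords = NULL, params = sie_params(),
                            probe_radius = 1.4, n_sphere_points = 960L) {
  if (is.null(coords)) coords <- system$coords
  rec_idx <- which(system$group == "receptor")
  lig_idx <- which(system$group == "ligand")
  rec <- subsystem(system, "receptor")
  lig <- subsystem(system, "ligand")
  ec <- pairwise_coulomb(system, coords, "inter", dielectric = params$D_in)
  evdw <- pairwise_lj(system, coords, "inter", radius_scale = params$rho)
  gr <- gb_polar(system, coords, eps_solute = params$D_in) -
    gb_polar(rec, coords[rec_idx, , drop = FALSE], eps_solute = params$D_in) -
    gb_polar(lig, coords[lig_idx, , drop = FALSE], eps_solute = params$D_in)
  msa <- function(sys, xyz) sasa(sys, xyz, probe_radius, n_sphere_points,
                                 radius_scale = params$rho)$total
  dmsa <- msa(system, coords) - msa(rec, coords[rec_idx, , drop = FALSE]) -
    msa(lig, coords[lig_idx, , drop = FALSE])
  sie(ec, gr, evdw, dmsa, params)
}
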