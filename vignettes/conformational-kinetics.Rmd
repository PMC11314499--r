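---
title: "Conformational kinetics and endpoint binding energetics with allokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational kinetics and endpoint binding energetics with allokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokin)
```

## What this package models

`allokin` implements the two halves of a standard computational study of
protein conformational regulation, exemplified by bromodomain systems in
which an orthosteric and an allosteric inhibitor jointly reshape the
conformational ensemble:

1. **Conformational kinetics.** Trajectory frames are reduced to slow
   collective coordinates by time-lagged independent component analysis
   (TICA), discretized into microstates by restarted k-means, assembled
   into a Markov state model (MSM), validated by implied-timescale
   convergence and the Chapman–Kolmogorov (CK) test, coarse-grained into
   metastable macrostates, and analysed with transition-path theory
   (TPT): committors, reactive fluxes and a ranked pathway table.
2. **Binding energetics.** Endpoint binding free energies by
   snapshot-averaged MM-GBSA with per-residue decomposition, and by the
   solvated interaction energy (SIE) scoring function.

Running molecular dynamics itself is out of scope: the package consumes
trajectories (multi-model PDB or flat numeric frames) and provides a
synthetic-data module that generates dynamics with *known* ground truth,
so every estimator can be tested quantitatively.

## The kinetic model

### TICA

For mean-free features $x_t$, TICA solves the generalized eigenproblem
$C(\tau)\,v = \lambda\, C(0)\,v$, where $C(0)$ is the instantaneous and
$C(\tau)$ the time-lagged covariance. We use the reversible
(symmetrized) estimate $C(\tau) \leftarrow (C(\tau)+C(\tau)^\top)/2$ so
eigenvalues are real, clip them at 1, and normalize components to unit
instantaneous variance. The eigenvalue of a component equals its
autocorrelation at the lag, so leading components are the slowest
coordinates. Choices worth knowing:

* **TICA lag** defaults to 1 frame and is configurable; it is an open
  parameter of the workflow rather than something the data dictate.
* **Retained dimension** defaults to the smallest dimension capturing
  95% of the kinetic variance (cumulative squared eigenvalues).
* **Rank-deficient features** produce an error advising a ridge
  (`ridge = 1e-8` suffices for an exactly constant feature); we prefer
  an explicit decision over silently dropping directions.
* **Multiple trajectory segments** contribute lagged pairs separately —
  pairs never straddle a segment join, which would fabricate
  transitions.

### Microstate discretization

k-means with k-means++ seeding and Lloyd iterations (center-shift
tolerance $10^{-6}$, at most 500 iterations), restarted 10 times by
default with the best-inertia solution kept; ten restarts mirrors common
practice for clustering MD projections and the whole procedure is a pure
function of its seed. The number of clusters can be fixed (`k`) or
chosen by `select_k()`, which formalizes the elbow rule as the maximum
discrete second difference (curvature) of the inertia-versus-k curve —
the elbow is otherwise notoriously subjective. Assignment ties break to
the lowest center index so labellings are deterministic.

We deliberately hand-roll the Lloyd loop rather than wrapping
`stats::kmeans`: the contract here requires k-means++ seeding, an
auditable per-iteration inertia log and seed-stable restarts, and the
test suite cross-checks our solution quality against `stats::kmeans`.

### MSM estimation

Transition counts $C_{ij}$ at lag $\tau$ use sliding-window counting by
default (every start frame; maximal data at the cost of correlated
counts; strided counting is available). The model is restricted to the
largest strongly connected state set, with dropped states reported —
never silently renumbered; if that set carries under half of the counts
the estimate aborts. The reversible estimator row-normalizes the
symmetrized counts $(C+C^\top)/2$, which satisfies detailed balance
exactly and has stationary distribution proportional to the symmetrized
row sums. This is simpler than maximum-likelihood reversible estimation
and is what makes the backward-committor identity $q^- = 1 - q^+$ exact
in the TPT stage; the cost is a small bias when the data are strongly
irreversible, which our synthetic ground truth is not.

The **Markov time** is selected as the smallest lag whose slowest
implied timescale $t_i(\tau) = -\tau / \ln|\lambda_{i+1}(\tau)|$ changes
by less than 5% (relative) against the next two larger lags.
Non-positive eigenvalues yield no defined timescale and are flagged
rather than dropped. The **CK test** compares $P(k\tau)$ re-estimated
from data against $P(\tau)^k$; since the benchmark literature states
only that "the difference" should be below 5%, we had to pick a norm: we
use the maximum row total-variation distance
$\max_i \tfrac12 \sum_j |\Delta P_{ij}|$, which is scale-free and reads
as misplaced probability mass per state.

### Coarse graining

Macrostates are obtained PCCA-style: microstates are embedded as the
rows of the top-$n$ right-eigenvector matrix of $P$ and clustered with
restarted k-means. Soft memberships come from a Gaussian kernel on the
spectral distances (row-normalized); they are a diagnostic, not a
fuzzy-set optimum as in PCCA+. Macrostate populations are sums of the
stationary distribution over members.

### Transition-path theory

With source set $A$ and sink set $B$, the forward committor solves the
linear boundary-value problem
$q^+_i = \sum_{j \in B} T_{ij} + \sum_{j \notin A \cup B} T_{ij} q^+_j$
(direct dense solve; a fixed-point iteration is kept as an independent
cross-check). Gross reactive flux is
$f_{ij} = \pi_i\, q^-_i\, T_{ij}\, q^+_j$ and the net flux
$f^+_{ij} = \max(0,\, f_{ij} - f_{ji})$ — we read the net-flux formula
as containing an implicit zero floor, the only interpretation that keeps
fluxes non-negative. Pathways are extracted by iterative **bottleneck
decomposition**: repeatedly find the widest $A \to B$ path (maximal
minimum-capacity edge) on the residual net-flux network, record it with
its bottleneck flux, subtract, and stop when less than `min_fraction`
(default 1%) of the total flux remains. Path percentages are each
path's share of the extracted flux. Ranked tables print at three
significant figures with a Total row; fluxes are converted to s$^{-1}$
through lag $\times$ frame interval. When a macrostate map is supplied,
endpoint sets are the member microstates of the chosen macrostates. An
optional population-weighted secondary ranking (weights proportional to
the product of the states' stationary populations) is available but off
by default.

## The energy model

### MM-GBSA

Using the single-trajectory protocol (complex, receptor and ligand
conformations from the same frames),

$$\Delta G_{bind} = \Delta E_{ele} + \Delta E_{vdW} + \Delta G_{gb} +
\Delta G_{surf} - T\Delta S.$$

Gas-phase terms reduce to receptor–ligand cross sums: Coulomb with
$k_e = 332.0636$ kcal·Å/(mol·e²) and Lennard-Jones with
Lorentz–Berthelot combining. Polar solvation uses the generalized Born
model with OBC(II) effective radii (offset 0.09 Å, uniform descreening
scale 0.8, coefficients 1.0/0.8/4.85) — the common Amber default, stated
here as an assumption since endpoint studies often leave the GB flavour
unstated. Dielectrics default to 1 (solute) and 78.5 (solvent). The
nonpolar term is $\gamma\,\Delta SASA + \beta$ with $\gamma = 0.0072$
kcal/(mol·Å²), $\beta = 0$; SASA is Shrake–Rupley on a deterministic
Fibonacci sphere lattice (default 960 points, within 2% of a
10,000-point reference on random systems). Snapshots are evenly strided
from the trajectory (the benchmark protocol draws 300 for energies and a
100-frame subset for entropies); the entropy penalty $-T\Delta S$ is
accepted as supplied values averaged over an evenly strided subset, or
can be estimated by a quasi-harmonic (Schlitter) routine — a coarse,
clearly-labelled stand-in for normal-mode entropies.

Per-residue decomposition attributes each receptor–ligand pair energy
half to each partner residue; GB pair-term differences
(complex minus isolated species) are attributed the same way, and
per-atom SASA differences go to their own residue. Shares therefore sum
to the totals by construction, and residues below $-0.8$ kcal/mol
(configurable) are flagged as hotspots.

### SIE

$$\Delta G_{bind} = \alpha\,[E_c(D_{in}) + \Delta G_R + E_{vdW} +
\gamma\,\Delta MSA(\rho)] + C$$

with the calibrated constants $\alpha = 0.1048$, $D_{in} = 2.25$,
$\rho = 1.1$, $\gamma = 0.0129$ kcal/(mol·Å²), $C = -2.89$ kcal/mol.
The arithmetic of the scoring function is exact and separately
testable. When components are computed from a structure, the
reaction-field change $\Delta G_R$ uses the GB model at interior
dielectric $D_{in}$ — a documented surrogate for the boundary-element
Poisson solver used in the original SIE implementation, adequate for the
bead systems generated here.

## What the synthetic generators emulate — and what they do not

* `make_transition_matrix()`/`sample_discrete_chain()` produce
  metastable Markov chains with known $T$ and stationary law: ground
  truth for the estimator, the implied timescales and the CK test.
* `simulate_brownian()` integrates overdamped Langevin dynamics
  (Euler–Maruyama, $x \leftarrow x - \nabla U\,dt + \sqrt{2 kT\,dt}\,\xi$)
  on analytic single/double/quadruple wells whose Boltzmann law and slow
  modes are known. Overdamped rather than underdamped dynamics keeps
  the exact stationary distribution with one parameter fewer; thermostat
  details of real MD are deliberately not modelled. Reduced units
  throughout.
* `make_toy_complex()` builds receptor–ligand bead complexes with
  typical protein-atom parameter magnitudes
  ($\sigma \in [2.5, 3.5]$ Å, $\varepsilon \in [0.05, 0.2]$ kcal/mol,
  $q \in [-0.5, 0.5]$ e, exact net charge), a packed receptor cluster
  and a surface-docked ligand.

Passing tests on these systems demonstrates estimator correctness —
recovery of known transition matrices, committor closed forms, Born
limits — not fidelity to any real protein: solvent structure, explicit
force fields, sub-state heterogeneity and sampling pathology of real MD
are all outside what the generators produce. Trajectory-dependent
published quantities (RMSF profiles, per-system macrostate counts,
absolute fluxes and energy tables) require microseconds of MD and are
therefore treated as worked-example *inputs*, not reproduction targets.

## Numerical choices and degenerate inputs

* Seeds: one integer seed drives everything through a documented
  splitting hash (`split_seed()`), so stages and restarts have
  independent reproducible streams below $2^{31}$.
* Kabsch superposition errors on fewer than 3 atoms or collinear
  reference geometry; the rotation always has determinant $+1$.
* RMSF superposes to the iterated mean structure (convergence
  $10^{-6}$ Å) — stable and standard when no crystal reference is
  singled out; B-factors use the isotropic relation
  $B = (8\pi^2/3)\,\mathrm{RMSF}^2$.
* "Molecular surface area" is computed as total SASA with a
  configurable probe (1.4 Å default); we do not maintain a second
  surface definition.
* DCCM errors on zero-variance atoms by index; committor solves report
  singular systems; count matrices error when a lag reaches a
  trajectory length; CK requires $\max(k)\,\tau$ inside every
  trajectory.
* The divergence guard in the Brownian integrator names the offending
  `dt`; the pre-check bounds the deterministic per-step drift at 10% of
  the well spacing.

## Problem sizes used in the shipped analyses

The bundled analysis scripts and the validation suite run at desk
scale, chosen so that statistical bands are meaningfully powered:
$10^5$-step chains for estimator recovery (max transition-probability
error $\le 0.02$), $2\times10^6$-step double-well runs (enough well
hops that the $\pm 2\%$ symmetry band on the populations is well
powered), $10^5$-frame feature matrices for TICA recovery, and
bead complexes of tens of atoms for the energy kernels, which are
verified against brute-force double loops at $10^{-10}$.

## Known limitations

* Reversible estimation by count symmetrization (not ML detailed
  balance); no Bayesian uncertainty, no hidden Markov models.
* PCCA-style crisp clustering of eigenvector rows rather than PCCA+
  simplex optimization; membership softness is heuristic.
* GB is OBC(II) only; no salt screening; no Poisson–Boltzmann solver.
* Entropy: supplied values or quasi-harmonic estimate only; no
  normal-mode analysis.
* The pathway decomposition is deterministic bottleneck extraction;
  alternative decompositions of the same flux network exist when
  intermediate states are not unique.
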