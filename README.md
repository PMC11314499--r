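# allokin

Conformational kinetics and endpoint binding energetics for molecular
trajectories, in R.

Proteins regulated by orthosteric and allosteric ligands — bromodomains
are the motivating example — change both their conformational dynamics
and their binding thermodynamics when inhibitors bind. Quantifying this
from simulation takes two analysis chains that this package implements
end to end, together with synthetic generators that make every stage
testable against known ground truth:

1. **Kinetics**: trajectory observables (Kabsch RMSD, RMSF/B-factors,
   radius of gyration, Shrake–Rupley SASA, cross-correlation maps, PCA
   modes) → TICA dimensionality reduction → restarted k-means
   microstates → Markov state model with implied-timescale lag
   selection and Chapman–Kolmogorov validation (5% rule) → PCCA-style
   macrostates → transition-path theory: committors
   `q+_i = Σ_{j∈B} T_ij + Σ_{j∉A∪B} T_ij q+_j`, reactive flux
   `f_ij = π_i q−_i T_ij q+_j`, net flux `max(0, f_ij − f_ji)`, and a
   ranked pathway table from bottleneck decomposition with path shares
   `P_i = f_i / Σ_j f_j`.
2. **Energetics**: snapshot-averaged MM-GBSA,
   `ΔG_bind = ΔE_ele + ΔE_vdW + ΔG_gb + ΔG_surf − TΔS`
   (OBC(II) generalized Born, `ΔG_surf = 0.0072·ΔSASA`), with
   per-residue decomposition and a −0.8 kcal/mol hotspot rule; and the
   SIE function
   `ΔG_bind = α[E_c(D_in) + ΔG_R + E_vdW + γ·ΔMSA(ρ)] + C` with
   α = 0.1048, D_in = 2.25, ρ = 1.1, γ = 0.0129, C = −2.89.

## Worked example

A two-state system with known kinetics, from simulation to pathway
table:

```r
library(allokin)
b <- run_pipeline(demo_config(seed = 1))
writeLines(b$summary)
```

which prints (seed 1):

```
== allokin pipeline summary ==
seed: 1
Markov time: 50 frames (0.05 ns)
CK test: PASS (threshold 5%; max deviation 0.008)
macrostates: 2, populations: 0.499, 0.501
top pathways:
     Pathways Path Flux (s^-1) Percentage of Total Coarse Flux (%)
 SA.1 -> SB.5         1.06e+08                              11.600
 ...
        Total         9.19e+08                             100.000
MM-GBSA dGbind = -0.39 kcal/mol (entropy: none (term = 0))
SIE dGbind = -3.01 kcal/mol
```

The demo simulates Brownian dynamics on a symmetric double well
(barrier 1.5 kT), so the two macrostate populations must be 0.5/0.5 up
to sampling error — here 0.499/0.501 — the CK test must pass at the 5%
threshold, and the pathway shares must sum to 100%. The energy lines
score a toy receptor–ligand bead complex.

The same steps are available as narrative scripts under `analysis/`
(`01_simulate.R` … `06_report.R`), which write their tables under
`results/`. Worked examples on published endpoint-energy tables are in
`analysis/05_energy.R`: summing the per-term averages
(−21.51 − 27.77 + 30.09 − 3.83 + 20.60) reproduces the printed
ΔG_bind = −2.42 kcal/mol, and the three printed path fluxes
(2.09×10⁻⁴, 1.22×10⁻⁶, 1.20×10⁻⁶ s⁻¹) give the printed total
2.11×10⁻⁴ s⁻¹ with a 98.9% leading share.

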