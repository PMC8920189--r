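# hxkdyn

Comparative protein-dynamics analysis in R, built around the question:
*how does a point mutation that never touches the active site still
cripple catalysis?* For two-domain enzymes such as yeast hexokinase-2,
catalysis requires the large and small subdomains to close around the
bound sugar; a remote substitution (e.g. the 2-deoxyglucose-resistance
mutation G238V) can act allosterically, by changing the flexibility of
cleft-lining residues, the coupling of the mutation site to the rest of
the protein, and the open/closed conformational equilibrium itself.
`hxkdyn` implements the descriptor battery used to make that argument
from molecular-dynamics ensembles, plus the enzyme-kinetics and
growth-curve formulas used for the matching wet-lab read-outs.

## What it computes

For trajectories stored as multi-model PDB files (trimmed of their
pre-equilibration segment, strided, and backbone-aligned with a
reflection-safe Kabsch fit):

* **RMSF / delta-RMSF** — per-residue root-mean-square fluctuation of
  residue centers of geometry; difference maps classified at a 0.85 A
  threshold by which system is more flexible, with the
  B = (8 pi^2/3) RMSF^2 B-factor conversion.
* **Dynamic cross-correlation** —
  `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)` over C-alpha
  displacements from their time averages; element-wise difference
  matrices and single-residue coupling profiles.
* **Residue interaction networks** — C-beta nodes (C-alpha for
  glycine), edges within 6.7 A; fractional shortest-path betweenness
  per frame and its ensemble average, per-residue Cohen's d between
  systems, and the fraction of all shortest paths passing through a
  residue group.
* **Domain closure** — mass-weighted radius of gyration as an
  open/closed order parameter, compared across systems by
  Kruskal-Wallis, Conover-Iman post hoc (Holm-adjusted) and Cohen's d;
  chi1 dihedral series (default quartet CG2-CB-CA-C) with
  gauche-/gauche+/anti rotamer occupancies; grid-based cleft-volume
  estimates.
* **Kinetics and growth** — Michaelis-Menten Km/Vmax/specific activity
  via the Lineweaver-Burk double-reciprocal regression (nonlinear
  cross-check included), and doubling times
  `td = ln(2) (t2 - t1) / (ln OD2 - ln OD1)` with percent-growth
  normalization.
* **Synthetic ensembles** — seeded generators for
  correlated-fluctuation trajectories (residue RMSF converges to
  `sigma * sqrt(3)`, empirical DCC converges to a target correlation
  matrix) and rigid hinge open/close trajectories (monotone or bimodal
  RoG by construction), so every stage is validated by parameter
  recovery.

`run_comparison()` chains all of it — trim, align, concatenate
replicates, descriptors, statistics — into one deterministic report.

## A worked example

Build a 26-residue toy protein, generate a "wild-type" ensemble with
uniform 0.4 A per-axis fluctuations and a "mutant" ensemble whose
residues 231-236 fluctuate at 1.0 A, and compare:

```r
library(hxkdyn)

ref <- make_test_protein(26, resno_start = 225L)
sigma_wt  <- rep(0.4, 26)
sigma_mut <- replace(sigma_wt, match(231:236, 225:250), 1.0)
wt  <- gen_fluctuation_trajectory(ref, sigma_wt,  n_frames = 400, seed = 20)
mut <- gen_fluctuation_trajectory(ref, sigma_mut, n_frames = 400, seed = 21)

cfg <- comparison_config(list(wt = list(wt), mut = list(mut)),
                         discard_ns = 0, groups = list(hairpin = 231:236))
report <- run_comparison(cfg)
report
#> Comparative dynamics report
#>   systems: wt, mut
#>   contrast: wt - mut
#>   delta-RMSF classes: neutral=20, other-more-flexible=6
#>   RoG Kruskal-Wallis: H = 0.2687 (df 1), p = 0.604

subset(report$delta_rmsf, class != "neutral")
#>  chain resno resid      delta               class
#>      A   231   ALA -1.0112462 other-more-flexible
#>      A   232   ALA -0.9835412 other-more-flexible
#>      A   233   ALA -0.9971117 other-more-flexible
#>      A   234   ALA -1.0441985 other-more-flexible
#>      A   235   ALA -1.0352458 other-more-flexible
#>      A   236   ALA -0.9841222 other-more-flexible
```

Exactly the six residues generated with the larger amplitude are
flagged as more flexible in the mutant, and the signed deltas recover
the construction: `(0.4 - 1.0) * sqrt(3) = -1.04 A`. The RoG omnibus
test correctly does not reject for these translation-only ensembles
(the two systems share the same closure behavior).

The kinetics side works the same way — generate, fit, read off:

```r
tab <- gen_kinetics_table(Km = 0.23, Vmax = 27.6,
                          S = c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4))
fit_lineweaver_burk(tab$substrate_mM, tab$rate)
#> Michaelis-Menten fit (Lineweaver-Burk, n = 8)
#>   Km   = 0.23 mM
#>   Vmax = 27.6
#>   SA   = 27.6 per au
#>   R^2(1/v ~ 1/S) = 1.000000

gc <- gen_growth_curve(od0 = 0.1, doubling_time_h = 2.35, duration_h = 24)
doubling_time(gc$time_h, gc$od, 0, 24)
#> [1] 2.35
```

On noiseless input both estimators are exact: a Km of 0.23 mM, a
specific activity of 27.6 nmole/min/au, and a 2.35 h doubling time come
back to numerical precision.

See `vignettes/comparative-dynamics.Rmd` for the underlying models,
conventions (sign of the difference maps, rotamer bin edges, tie
handling in betweenness), and the limits of what the synthetic
generators can certify.

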