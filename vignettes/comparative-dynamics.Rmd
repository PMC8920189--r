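---
title: "Comparative protein dynamics with hxkdyn: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative protein dynamics with hxkdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hxkdyn)
```

## The problem this package addresses

Point mutations can impair an enzyme without touching its active site:
by changing how the protein *moves*, a remote substitution can raise the
entropic cost of substrate binding, bias a side chain away from the
rotamer the catalytic cycle needs, or shift the equilibrium between the
open and closed conformations of a two-domain fold. Hexokinases are the
canonical example: catalysis requires the large and small subdomains to
close around the bound hexose, and anything that disturbs the
cleft-lining residues or the closure motion shows up directly in the
Michaelis constant. Establishing such an allosteric mechanism from
molecular-dynamics (MD) ensembles requires a battery of comparative
descriptors, and this package implements that battery as reusable,
tested components:

* per-residue root-mean-square fluctuations (RMSF) and their
  wild-type-minus-mutant difference map with a flexibility
  classification;
* dynamic cross-correlation (DCC) matrices and their differences;
* residue interaction networks with betweenness centrality,
  time-averaged over an ensemble, plus shortest-path participation
  fractions of residue groups;
* radius-of-gyration (RoG) distributions as an open/closed order
  parameter, with the accompanying non-parametric statistics
  (Kruskal-Wallis, Conover-Iman post hoc, Cohen's d);
* side-chain chi1 dihedral series with rotamer classification, and a
  grid-based estimate of the catalytic-cleft volume;
* Michaelis-Menten kinetics via the Lineweaver-Burk estimator and
  growth-curve doubling times, the wet-lab read-outs such a study pairs
  with the simulations.

Because production MD trajectories are rarely redistributable, the
package also ships seeded generators that produce trajectories with the
*statistical structure* the analyses assume, so that every pipeline
stage can be validated by parameter recovery rather than by eyeballing.

## Data model and preprocessing

Structures and trajectories are plain S3 objects: an atom table
(name, residue, chain, number, element) plus either one coordinate set
(`md_structure`) or a frames-by-coordinates matrix with strictly
increasing times in ns (`md_trajectory`). I/O is multi-model PDB
(`MODEL`/`ENDMDL`), delegated to bio3d with added validation: a missing
file, models with inconsistent atom counts, and unparseable coordinates
raise distinct, named conditions. Alternate locations other than blank
or `A` are dropped; insertion codes are kept verbatim; residue numbering
is never rewritten. PDB files carry no time metadata, so frame times
default to the frame index times a configurable stride (10 ps, matching
the analysis stride used throughout).

Every trajectory analysis sits behind the same preprocessing:
`trim_and_stride()` removes the pre-equilibration segment (default 5 ns)
and subsamples to the analysis stride (default 10 ps), and
`align_trajectory()` superposes each frame onto the first frame by its
backbone heavy atoms (N, CA, C, O) using a reflection-safe Kabsch fit
(sign correction on the smallest singular value, so the rotation is
always proper). Alignment is *per trajectory*, to its own first frame;
cross-system comparisons therefore compare internally aligned ensembles
rather than ensembles in a shared reference frame, and the difference
maps inherit that convention. Replicate simulations of one system are
trimmed, aligned and then concatenated and treated as a single ensemble;
a per-replicate mode is retained wherever a per-frame series is needed
for effect sizes.

## The descriptors

**RMSF.** For each residue the center of geometry of its heavy atoms is
tracked and RMSF is the root-mean-square distance from its time-average
position. Hydrogens are excluded from the center because heavy-atom
centers are the common convention and make the measure insensitive to
proton placement. The difference map `delta_rmsf()` stores the signed
delta (reference minus other, i.e. WT minus mutant) and classifies each
residue by *which system is more flexible* at a threshold of 0.85 A.
The classification is deliberately symmetric in the two systems: a
residue is `other-more-flexible` when RMSF_other - RMSF_ref >= 0.85 A,
`ref-more-flexible` in the mirrored case, `neutral` otherwise. The
optional B-factor column uses the isotropic Debye-Waller relation
B = (8 pi^2 / 3) RMSF^2; this conversion is exposed as an explicit,
documented formula precisely because reported B-factors in the
literature do not always state their convention.

**DCC.** `dcc_matrix()` implements
C_ij = \<dr_i . dr_j\> / sqrt(\<dr_i^2\>\<dr_j^2\>) with dr_i the
displacement of residue i's node atom (C-alpha by default) from its
time-average position, averaged over the retained frames. Residues with
zero mean-square displacement have no defined correlation; their entries
are `NA`, never imputed zeros. Matrix differences (`delta_dcc()`) are
entry-wise, with zero diagonal, and a single residue's row can be pulled
out as a per-residue profile — the natural way to ask how a mutation
site's coupling to the rest of the protein changed.

**Residue networks and centrality.** Nodes are C-beta atoms (C-alpha
for glycine, which has none), edges connect node atoms within 6.7 A
(inclusive). Betweenness uses the standard unweighted shortest-path
definition — tied shortest paths count fractionally, endpoints are not
interior, unreachable pairs contribute nothing — computed with igraph;
the test suite checks it against an exhaustive path-enumeration oracle
on hundreds of small random geometric graphs. `ensemble_bc()` rebuilds
the graph every frame and averages, and `bc_effect_size()` compares two
systems residue-by-residue via Cohen's d over the per-frame values.
`group_path_fraction()` answers "what fraction of all shortest paths
pass through this group?": per connected pair, the fraction of its tied
shortest paths with at least one group member interior, averaged over
pairs. A path counts once even if it crosses several members, because
"present in X% of the paths" reads as path-level membership; a
per-member counting mode is exposed for the alternative bookkeeping,
since published percentages do not always state which convention they
used.

**Geometry.** RoG defaults to mass-weighted (the convention of the
standard trajectory-analysis libraries; a geometric option exists).
Dihedrals follow the standard signed convention (cross-checked against
bio3d) and are reported in (-180, 180]. The default chi1 quartet is
CG2-CB-CA-C — the quartet used in the valine rotamer analysis this
package was built around — even though IUPAC chi1 is N-CA-CB-CG1; the
IUPAC quartet is one argument away. Rotamer bins are centered on the
canonical conformers with edges at 0 and +/-120 degrees: gauche- =
[-120, 0), gauche+ = [0, 120), anti elsewhere; the open-state (~-51
degrees) and closed-state (~160 degrees) valine conformations fall
comfortably inside gauche- and anti respectively, so the +/-10 degree
uncertainty typical of crystal-versus-ensemble comparisons never
straddles a bin edge. Cleft volume is a deliberately simple grid
estimate: points of a regular grid (0.5 A default spacing) inside a
union of inclusion spheres and farther than 1.09 A from every protein
heavy atom, times the voxel volume. This reproduces the *idea* of
grid-based pocket volumetrics; ligand-defined regions, per-element
radii and probe sweeps are out of scope, which is why the function
should be used for within-study comparisons, not absolute volumes.

**Statistics.** Kruskal-Wallis is computed from pooled mid-ranks with
the standard tie correction and a chi-square reference distribution; it
agrees with `stats::kruskal.test` to 1e-10 on random data, and the
fully-tied case returns H = 0, p = 1 rather than an error. The
Conover-Iman post hoc test is implemented in-package (no R
implementation is available in the supported dependency set): pooled
rank means compared with a pooled-variance t statistic that shrinks
with the omnibus H, Student's t with N - k degrees of freedom, and Holm
adjustment by default (uniformly more powerful than Bonferroni; the
adjustment method is an argument). Cohen's d uses the pooled-SD
definition, with the conventional verbal labels (0.2/0.5/0.8).

**Kinetics and growth.** The Lineweaver-Burk estimator is the primary
Km/Vmax route because it is the estimator named by the assay protocol
this package accompanies: ordinary least squares of 1/v on 1/[S],
Vmax = 1/intercept, Km = slope/intercept, specific activity = Vmax per
absorbance unit of extract. Zero-rate points are excluded with a
warning; a non-positive intercept aborts. A direct nonlinear fit
(`fit_michaelis_menten()`, Levenberg-Marquardt) is provided as a
cross-check and agrees exactly on noiseless data — on noisy data the
two estimators weight errors differently and the double-reciprocal fit
is known to amplify low-[S] noise, which is why both are exposed.
Doubling times use td = ln(2) (t2 - t1) / (ln OD2 - ln OD1) over a
caller-chosen window; the automatic window picks the longest stretch
whose log-OD regression has R^2 >= 0.99, which is documented as a
heuristic — with noiseless saturating curves it can admit one
stationary-phase point, so explicit windows (or a stricter threshold)
are preferred when the phases are known.

## What the synthetic generators emulate — and what they do not

`gen_fluctuation_trajectory()` produces an equilibrium ensemble in
which every residue translates rigidly about its reference position
with isotropic Gaussian displacements of per-axis standard deviation
sigma_i, coupled across residues through the symmetric square root of a
target correlation matrix (independent drivers per axis). Two exact
consequences make it the right validation input: residue RMSF converges
to sigma_i * sqrt(3), and the empirical DCC converges to the target
matrix. The suite asserts both (within 5% at 10,000 frames and 0.05 at
20,000 frames, fixed seeds). `gen_hinge_trajectory()` rotates one rigid
block about a hinge axis by a per-frame closure schedule, with optional
isotropic jitter: monotone schedules give strictly monotone RoG series,
and bimodal schedules give the bimodal open/closed RoG distributions
that motivate the rank-based statistics.

These generators emulate the *statistical* structure of an equilibrated
MD ensemble, not its physics: there are no bonded constraints, no
side-chain repacking, no solvent, no anharmonicity, and residue motions
are pure translations. Passing tests therefore demonstrate that the
analysis chain measures what it claims to measure on inputs with known
ground truth; they do not certify force-field-level realism, and
trajectory-derived quantities from real simulations (path-participation
percentages, per-residue effect sizes, omnibus statistics over millions
of frames) depend on the ensemble actually analyzed. The toy protein
(`make_test_protein()`) is an extended poly-alanine chain with explicit
N, CA, C, O, CB atoms, optional glycines (exercising the C-alpha node
rule) and valines (exercising chi1); at the 6.7 A cutoff its residue
graph is a simple chain, which makes hand-computed network expectations
possible.

All generators are pure functions of their arguments and a seed
(bit-identical repeats, caller RNG untouched, via `withr::with_seed`).

## Parameters that matter

| parameter | default | where | why |
|---|---|---|---|
| equilibration discard | 5 ns | `trim_and_stride()` | drop the pre-equilibrated segment before any statistics |
| analysis stride | 10 ps | `trim_and_stride()`, PDB times | decorrelates frames while keeping ensembles large |
| backbone set | N, CA, C, O | alignment, RMSD | standard backbone-heavy-atom convention |
| network cutoff | 6.7 A | `build_residue_graph()` | C-beta contact distance of residue-interaction networks |
| RMSF-difference threshold | 0.85 A | `delta_rmsf()` | flexibility classification bound |
| DCC node atom | CA | `dcc_matrix()` | per-residue backbone proxy |
| chi1 quartet | CG2-CB-CA-C | `chi1_series()` | the valine rotamer-analysis quartet; IUPAC optional |
| grid spacing / exclusion | 0.5 A / 1.09 A | `pocket_volume()` | ~3% sphere-volume error; uniform heavy-atom radius |
| Conover adjustment | Holm | `conover_posthoc()` | controls FWER without Bonferroni's conservatism |

## Numerical choices and degenerate inputs

Superposition requires >= 3 non-collinear points and excludes
reflections. Immobile residues yield `NA` correlations; zero pooled SD
yields Cohen's d of 0 when the means agree (identical series) and `NA`
otherwise (flagged, not fabricated). Fully tied rank data give H = 0
and post hoc p = 1. `residue_fraction()` rounds to two decimals because
that is how such percentages are printed. The correlation square root
floors eigenvalues at zero and rejects materially non-PSD targets
(tolerance 1e-8). Distance thresholds are inclusive (a pair exactly at
6.7 A is an edge). The PDB writer emits fixed-column records with
3-decimal coordinates, so a read/write/read round trip preserves
coordinates to 5e-4 A.

## Problem sizes used by the test suite

The suite validates on deliberately small systems chosen so every
oracle stays exact: toy chains of 3-26 residues, random geometric
graphs of <= 8 nodes (200 instances against exhaustive path
enumeration), correlation toys of <= 10 residues against a double-loop
oracle at 1e-10, convergence runs of 10,000-20,000 frames on 6-8
residue systems, and pipeline runs of tens of frames. These sizes make
the full suite complete in well under a minute while still exercising
every code path; scaling to real proteins is linear in atoms times
frames for the per-frame descriptors and is dominated by the per-frame
betweenness (O(nm) per frame) for the network analysis.

## Known limitations

* No binary trajectory formats (DCD/XTC) or mmCIF; multi-model PDB is
  the interchange format, and solvent/ions are assumed stripped.
* Per-residue (not per-atom) fluctuation maps; no crystallographic
  B-factor refinement.
* Unweighted networks only: no contact-strength weighting, community
  detection or current-flow centralities.
* The cleft-volume estimate is comparative, not absolute (uniform
  exclusion radius, no probe).
* The Lineweaver-Burk estimator inherits the double-reciprocal noise
  amplification; use the nonlinear cross-check on noisy data.
* ATP kinetics measured at a fixed, sub-saturating co-substrate
  concentration are apparent constants; the single-substrate model is
  fitted as printed, and the package does not attempt bi-substrate
  kinetics.

## A minimal worked comparison

```{r example, eval = FALSE}
ref <- make_test_protein(26, resno_start = 225L)
sigma_wt <- rep(0.4, 26)
sigma_mut <- replace(sigma_wt, match(231:236, 225:250), 1.0)
wt  <- gen_fluctuation_trajectory(ref, sigma_wt,  n_frames = 400, seed = 20)
mut <- gen_fluctuation_trajectory(ref, sigma_mut, n_frames = 400, seed = 21)

cfg <- comparison_config(list(wt = list(wt), mut = list(mut)),
                         discard_ns = 0,
                         groups = list(hairpin = 231:236))
report <- run_comparison(cfg)
report
subset(report$delta_rmsf, class != "neutral")
```

The six residues generated with the larger amplitude are the six
classified `other-more-flexible`, the signed deltas recover
(0.4 - 1.0) * sqrt(3) ~ -1.04 A, and the RoG omnibus test does not
reject for these translation-only ensembles — exactly the pattern the
construction implies.
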