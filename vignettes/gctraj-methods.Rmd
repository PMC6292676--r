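---
title: "Methods: generalized-correlation and essential-dynamics analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generalized-correlation and essential-dynamics analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gctraj)
```

## The problem

Large nucleoprotein machines such as CRISPR–Cas9 function through
collective domain motions: the HNH nuclease docks at the DNA cleavage site
only when the recognition (REC) lobe senses the RNA:DNA hybrid and
rearranges around it. Long molecular-dynamics trajectories record these
events, but the interesting quantity — *how strongly the motion of one
domain depends on another's* — is not directly visible in coordinates.
`gctraj` extracts it in three layers: per-frame geometric monitors
(distances, salt bridges, contacts), covariance-level descriptions
(essential-dynamics PCA), and information-theoretic coupling (the
generalized correlation matrix and its domain-level scores).

## The generalized correlation statistic

### Model and estimator

For each selected residue, the displacement vector is its Cα position
minus the time mean, taken after removing global rotation/translation.
For a residue pair the mutual information
$I[\mathbf{x}_i, \mathbf{x}_j]$ is estimated with the Kraskov
(algorithm 1) $k$-nearest-neighbour estimator in the 6-dimensional joint
space under the max-norm:
$$
\hat I = \psi(k) + \psi(F) - \frac{1}{F}\sum_f
\left[\psi(n_x^{(f)} + 1) + \psi(n_y^{(f)} + 1)\right],
$$
where $n_x^{(f)}$ and $n_y^{(f)}$ count marginal neighbours strictly
inside the joint $k$-th neighbour distance. The estimate is mapped to
$$
r_{MI} = \sqrt{1 - e^{-2\hat I/3}} \in [0, 1],
$$
the Lange–Grubmüller generalized correlation for 3-dimensional variables.
For isotropic jointly Gaussian displacements with per-dimension
correlation $\rho$, $I = -\tfrac32\log(1-\rho^2)$ and $r_{MI} = |\rho|$
exactly; this closed form is the package's primary oracle and is exercised
by the test suite and the acceptance script at $F = 5000$, $k = 6$.

### Numerical choices

* **$k = 6$, stride 1** by default. Small $k$ lowers bias and raises
  variance; 6 is the conventional compromise and is recorded, along with
  the frame count and stride, in every `gc_matrix` result.
* **Marginal standardization.** True MI is invariant under per-variable
  rescaling, but the max-norm neighbourhoods are not when marginals live
  on very different scales. Each displacement coordinate is scaled to unit
  standard deviation before estimation, which restores the invariance in
  practice (verified to 0.02 in the tests) and is statistically a no-op.
* **Tie-breaking jitter.** $k$-NN estimators assume continuous samples;
  finite-precision trajectories contain exact ties. A deterministic jitter
  of ~1e-10 of each coordinate's range, drawn from a seeded local RNG,
  breaks ties without affecting estimates and keeps every result
  bit-reproducible. The seed is part of the configuration and of the run
  manifest.
* **Clamping.** The estimator can return slightly negative values for
  independent data; estimates are clamped at 0 before the $r_{MI}$
  transform. A consequence worth knowing: near independence the square
  root amplifies the remaining positive noise, so the practical floor of
  $r_{MI}$ at $F = 5000$ is about 0.05 — estimates below that level mean
  "no detectable coupling", not a measured strength.
* **Degenerate inputs** (zero-variance coordinates, or `y` an exact copy
  of `x`, for which MI is unbounded) are rejected with an explicit error.
* **Superposition check.** Computing couplings on an unfitted trajectory
  conflates global motion with internal correlation. `gc_matrix()` warns
  when the selection centroid drifts beyond `drift_tol` (1 Å default)
  unless the trajectory is marked superposed — by `superpose()`, or by a
  generator that draws displacements in a fixed frame.

### Per-residue and inter-domain scores

The per-residue score sums a residue's coefficients over partners passing
a threshold, $\mathrm{GCs}_i = \sum_{j \ne i} GC_{ij}\,[GC_{ij} \ge t]$,
with $t = 0.60$ by default — high enough to sit above the estimator noise
floor and the pervasive weak correlations of a connected polymer. The
score is bounded by $N - 1$ and is monotone non-increasing in $t$.

The inter-domain score accumulates qualifying cross-domain coefficients
and **normalizes by the number of qualifying pairs**. The normalization
wording is genuinely ambiguous ("the number of coupling residues i and
j"): dividing by qualifying *pairs* guarantees a score in $[0, 1]$, never
exceeding the largest qualifying coefficient, matching the intended 0 (not
correlated) to 1 (correlated) reading; dividing by the number of distinct
participating *residues* does not stay bounded by 1. The pair
normalization is therefore the default, the residue-union variant remains
available via `normalization = "residues"`. Diagonal (intra-domain) cells
aggregate $i \ne j$ pairs within the domain and can be excluded with
`include_intra = FALSE`. Every `domain_scores` object records threshold,
normalization and a hash of the resolved domain map.

## Essential-dynamics PCA

The $3N \times 3N$ covariance of mean-centered Cα coordinates is built
with the population ($1/F$) normalization and diagonalized exactly
(`eigen`, symmetric). Conventions:

* eigenvalues are clamped at 0 (they are mean-square fluctuations, in Å²)
  and sum to the covariance trace to relative 1e-8;
* each eigenvector's largest-magnitude component is made positive, fixing
  the sign indeterminacy so repeated runs and downstream projections are
  reproducible;
* projections of the input frames onto the modes have zero mean by
  construction, and `project_frames()` on the producing trajectory
  reproduces the stored projections exactly;
* `mode_displacements()` splits an eigenvector into per-residue 3-vectors
  (the porcupine-plot quantity), whose squared magnitudes sum to 1.

The fit selection for `superpose()` defaults to all protein Cα atoms.
Whether mobile domains should be excluded from the fit is a genuine
modelling choice — the fit defines which part of the motion counts as
"internal" — so the selection is exposed rather than fixed. One caveat
surfaced by the synthetic generators and worth stating: when a system is
small and its programmed couplings are strongly collective, a least-squares
fit absorbs part of that collective motion into the rigid-body degrees of
freedom and deflates the measured coupling. The generators therefore draw
displacements in a fixed frame and mark their output as already
superposed; for real trajectories, fitting remains the default and is the
correct treatment.

## Geometric monitors

* **Pair distances** are Euclidean distances between selection centroids,
  with no periodic imaging — input trajectories are assumed pre-imaged
  with the solute whole.
* **Salt bridges** are measured between the mass-weighted centre of mass
  of the acidic side chain's carboxylate oxygens (Asp OD1/OD2, Glu
  OE1/OE2) and that of the basic side chain's nitrogen group (Lys NZ, Arg
  NH1/NH2/NE, His ND1/NE2). A strength class is assigned per frame from
  distance bins — strong ≤ 3.5 Å, medium ≤ 4.5 Å, weak ≤ 6.0 Å, else
  none. The bins and the 4.5 Å formation cutoff used by
  `scan_salt_bridges()` are exposed defaults: published analyses typically
  colour-code strength without printing bin bounds, so these values are a
  documented convention, not a measurement. Occupancy (fraction of frames
  within the cutoff) is reported alongside, so either reading of
  "strength" is available.
* **Contacts** report the per-frame minimum heavy-atom distance between a
  residue and a partner selection plus the partner residue achieving it,
  ties broken toward the lowest residue number. A residue monitored
  against its own selection legitimately reports 0.
* **Smoothing** is a centered moving average with truncated end windows;
  the raw series is always retained.

Nucleic-acid conventions are configuration, not code: "the scissile
phosphate at target-strand position −3 (PAM-relative)" becomes a concrete
`{chain, resno, elety: P}` monitor entry, because author numbering of the
nucleotides varies between depositions.

## Domain maps

Domains are named lists of 1-based inclusive residue ranges in author
numbering; maps must be pairwise disjoint and every range must resolve to
at least one Cα atom, enforced loudly at resolution time.
`spycas9_domain_map()` ships a documented default for the DNA-bound
*S. pyogenes* Cas9 complex (REC1 94–179/308–496, REC2 180–307, REC3
497–713, HNH 775–908, RuvC 1–59/718–774/909–1098, PI 1099–1368, bridge
helix 60–93 as its own entry by default since pooling it with RuvC is a
matter of taste). Published figures colour domains without printing
boundaries, and reasonable assignments differ by a few residues at the
seams; since domain scores depend on the map, every score object records a
hash of the map that produced it and any user map can be substituted.

## Synthetic generators: what passing tests do and do not show

The generators define the study conditions under which the package is
validated, in place of multi-microsecond trajectories that are rarely
deposited.

* `make_block_trajectory()` draws stationary Gaussian displacements with a
  block correlation structure — identical and independent across x/y/z, so
  the Gaussian closed form $r_{MI} = |\rho|$ applies exactly — around a
  Cα-only pseudo-protein. The implied residue correlation matrix is
  validated for positive semi-definiteness and emitted as machine-readable
  ground truth consumed directly by the tests. Defaults (amplitude 1 Å,
  intra-block correlation 0.9, 3000 frames) represent strongly coherent
  domains at a sampling depth where the estimator is accurate to a few
  hundredths. Note that programmed couplings of 0.85 and 0.45 between
  three blocks are jointly infeasible for large blocks at high intra-block
  correlation (the implied matrix loses positive semi-definiteness as
  block aggregation amplifies effective coupling); the replicate studies
  therefore use two-residue blocks at intra-block correlation 0.95, the
  feasible regime closest to those targets.
* `make_transition_trajectory()` produces a two-plateau sigmoidal distance
  trace with additive Gaussian noise, defaulting to 19.4 → 8.0 Å with
  0.5 Å noise over 4000 frames and a mid-trajectory switch — an
  activation-like event in which a catalytic-domain distance relaxes onto
  the cleavage site. `fit_transition()` refits the logistic model by
  Levenberg–Marquardt; under the default conditions the change-point is
  recovered to well within 2% of the trajectory length.
* `make_salt_bridge_fixture()` builds a minimal Asp/Lys structure whose
  side-chain COM–COM distance equals the request exactly.

What these conditions deliberately omit: anharmonicity and multi-state
kinetics, solvent and ions, nucleic-acid mechanics, time correlation
(frames are drawn independently), and the slow convergence of real
covariances. Passing the suite therefore demonstrates that the estimators
and aggregations are correct and well-calibrated on data with known truth;
it does not certify that any particular real trajectory is long enough for
its GC matrix to be converged — that remains the analyst's judgement, for
which the frame-window option (`frame_window()`, e.g. the settled last
quarter of a run) and the recorded estimator metadata are the tools.

## Problem sizes

The shipped validation uses desk-scale sizes chosen to keep the estimator
in its accurate regime: Gaussian benchmarks at 5000 frames, block-recovery
tests at 800–3000 frames with 4–9 residues, PCA recovery at 2000 frames,
transitions at 4000 frames, and 50 seeded replicates for the rank-recovery
study. Reference distances against the deposited 5F9R/5Y36 structures are
verified whenever the RCSB archive is reachable; they are measurements on
experimental depositions and have no synthetic stand-in.

## Known limitations

* The estimator's $r_{MI}$ floor near independence (~0.05 at 5000 frames)
  means very weak couplings are indistinguishable from zero; the 0.60
  score threshold sits far above it.
* All-pairs estimation is $O(N^2 F^2)$; for thousands of residues at deep
  sampling, use the stride and frame-window options.
* Trajectory formats are DCD and multi-model PDB; XTC input is not
  supported.
* No periodic-boundary reimaging is performed; trajectories must arrive
  with the solute whole.
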