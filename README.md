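# gctraj

Cooperative domain motions in biomolecular machines — the coupling between a
nuclease domain and the recognition lobe of CRISPR–Cas9 is the motivating
case — leave their trace in the correlated fluctuations of residue positions
along a molecular-dynamics trajectory. `gctraj` quantifies those couplings
from any topology + trajectory pair, with no dependence on the MD engine
that produced them.

## What it computes

**Generalized correlation.** For residues *i*, *j* with 3-D Cα displacement
vectors **x**ᵢ, **x**ⱼ (coordinates minus their time mean, after
least-squares superposition), the package estimates the mutual information
*I*[**x**ᵢ, **x**ⱼ] with a Kraskov *k*-nearest-neighbour estimator
(max-norm, *k* = 6 by default) and maps it onto the Lange–Grubmüller
coefficient

    r_MI(i, j) = sqrt(1 − exp(−2 I / 3))  ∈  [0, 1],

which, unlike a Pearson cross-correlation map, captures non-linear and
mutually orthogonal correlated motions. For isotropic jointly Gaussian
displacements with per-dimension correlation ρ, r_MI = |ρ| exactly — the
basis of the package's quantitative self-checks.

**Coupling scores.** Per residue, GCs(i) = Σ_{j≠i} GC_ij over coefficients
passing a threshold (0.60 by default) — a measure of both the number and
the intensity of a residue's strong couplings. Per domain pair, the
qualifying cross-domain coefficients are summed and divided by the number
of qualifying pairs, giving an inter-domain score from 0 (uncorrelated) to
1 (fully coupled), recorded together with the domain map that produced it.

**Around the core statistic:** essential-dynamics PCA of the Cα covariance
(eigenvalues = mean-square fluctuations, PC1/PC2 projections, per-residue
mode vectors), side-chain COM–COM salt-bridge monitors with occupancy
scans, atom-pair distance and nearest-contact monitors, a YAML-driven
pipeline with manifests, and seeded synthetic-trajectory generators with
exact statistical ground truth (block-correlated Gaussian fluctuations and
two-plateau conformational transitions).

## Worked example

Generate a two-domain system with a programmed inter-domain coupling of
0.7, estimate the coupling matrix, and aggregate it over the domain map:

```r
library(gctraj)

traj <- make_block_trajectory(
  blocks = c(REC = 4, HNH = 4), inter_cor = 0.7, intra_cor = 0.9,
  n_frames = 2000, seed = 1
)
gcm <- gc_matrix(traj, k = 6)
gcm
#> <gc_matrix> 8 residues, 2000 frames, k = 6; off-diagonal GC: median 0.680, max 0.882

domains <- resolve_domains(list(
  REC = list(chain = "A", ranges = list(c(1, 4))),
  HNH = list(chain = "A", ranges = list(c(5, 8)))
), traj)
tidy(domain_coupling_scores(gcm, domains, threshold = 0.6))
#> # A tibble: 3 × 4
#>   domain_a domain_b score n_pairs
#>   <chr>    <chr>    <dbl>   <int>
#> 1 REC      REC      0.877       6
#> 2 REC      HNH      0.676      16
#> 3 HNH      HNH      0.873       6
```

The REC–HNH score of 0.68 recovers the programmed coupling of 0.7 to
within the estimator's accuracy at 2000 frames; the diagonal cells reflect
the stronger (0.9) within-domain coupling. Monitors work the same way — a
noisy activation-like transition is refit to machine precision:

```r
ser <- pair_distance_series(make_transition_trajectory(seed = 2), 1, 2)
fit_transition(ser)
#> # A tibble: 1 × 5
#>      v1    v2 midpoint steepness sigma
#>   <dbl> <dbl>    <dbl>     <dbl> <dbl>
#> 1  19.4  8.01    0.500      19.7 0.502
```

For real systems: `read_structure()` + `read_trajectory()` (PDB topology,
DCD or multi-model PDB frames), `spycas9_domain_map()` or your own ranges,
then the same calls; or drive everything from a YAML configuration with
`run_pipeline()` (see `inst/extdata/example_config.yaml` and the CLI
wrapper in `inst/cli/`).

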