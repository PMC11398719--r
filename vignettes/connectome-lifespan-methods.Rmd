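---
title: "Methods: structural connectome efficiency and cognition across the lifespan"
author: "connlife"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural connectome efficiency and cognition across the lifespan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Fluid cognitive ability declines with age, but not uniformly across
people. One candidate substrate is the brain's structural connectivity
(SC) network: the white-matter connections between parcellated grey-matter
regions, summarized per subject as a symmetric matrix of streamline
probabilities (tractography streamline counts normalized by the number of
possible connections, so each entry lies in [0, 1]) and a companion matrix
of mean streamline distances in millimetres. `connlife` implements a full
analysis chain for asking which connections and which regional network
properties relate to age and to fluid intelligence across the adult
lifespan, and whether some network differences *support* cognition in
older age rather than merely tracking decline.

The chain is: quality control and consistency thresholding of the
subject-level matrices; weighted graph measures per subject; behavioral
partial least squares (PLS) linking brain variables to age and fluid
intelligence, with permutation, bootstrap-ratio and split-half inference;
rolling-window correlations across the lifespan with BCa bootstrap
confidence intervals; and multilinear models relating local efficiency to
whole-brain network structure. A synthetic-cohort generator with planted
latent structure provides ground truth for validating every stage by
recovery.

## Quality control and thresholding

An edge survives the *consistency threshold* when at least a fraction
`minFraction` (default 0.5) of subjects have a nonzero streamline
probability there; the boundary is inclusive ("at least half"). Subjects
are then excluded, in a fixed order: (1) missing behavioral data, (2) any
region left with zero connections after masking, (3) connectome density
(fraction of possible undirected pairs with a connection, computed after
masking) three or more SDs from the cohort mean, in a single
non-iterative pass. The order matters and is deliberately
non-iterative: iterated exclusion could cascade, and the descriptive
intent is a one-shot outlier screen.

Two numerical choices deserve note. The density SD is the descriptive
(population, denominator-n) SD of the cohort densities: the screen asks
how far a subject sits from this cohort's spread, not from an estimated
superpopulation SD; with a sample SD a single extreme subject among n
can never exceed (n-1)/sqrt(n) SDs, which for small cohorts would make
the stated 3 SD rule vacuous. The boundary comparison includes a 1e-12
absolute tolerance so exact-boundary cases are not lost to floating-point
rounding. A zero SD (all densities equal) excludes no one.

## Weighted graph measures

Edge lengths are inverse weights, `l = 1/w`: stronger connections are
shorter. Because weights are at most 1, every finite length is at least 1
and all efficiencies land in [0, 1]. Whether to invert or to use the
negative logarithm is a known degree of freedom in connectomics; the
inverse is the standard choice for probability-like weights and is
recorded in output metadata.

* **Nodal efficiency** of region j: the mean of `1/l_ij` over the other
  N - 1 regions, with `1/Inf = 0` for disconnected pairs. High for hubs.
* **Local efficiency** of region i: shortest paths are recomputed *within*
  the subgraph induced by i's neighbors after removing i itself, and
  `1/l` averaged over ordered neighbor pairs; regions with fewer than two
  neighbors score 0. Subgraph edges keep their original weights (no
  re-weighting by the stem edges) — the simpler of the published variants.
* **Clustering**: the Onnela geometric-mean-of-triangles coefficient on
  weights rescaled by the maximum weight.
* **Characteristic path length**: the mean finite off-diagonal shortest
  path length; disconnected pairs are omitted rather than imputed.
* **Small-worldness**: `sigma = (C/C_null)/(L/L_null)` against
  degree-preserving Maslov-Sneppen rewired nulls (default 10 nulls, 10
  swap attempts per edge) with the observed weight multiset shuffled onto
  the rewired topology. The null model is unavoidably a choice; degree-
  preserving rewiring is the field default. A null that loses
  connectedness after 10 attempts falls back to its largest component
  with a warning. Zero swap attempts leave the network untouched, making
  sigma exactly 1 — a useful self-test.

Whole-brain summaries are SC total (sum of streamline probabilities over
undirected pairs) and mean SC distance (mean streamline distance over
connected pairs).

## Behavioral PLS

The brain block X (vectorized retained edges, or region-wise nodal/local
efficiency) and behavior block Y (age in years, fluid intelligence on the
Cattell scale) are linked through the behaviors-by-brain-variables
Pearson correlation matrix R, decomposed by SVD into latent variables
(LVs): orthonormal behavior saliences U, brain saliences V, and singular
values S. Correlation (rather than covariance) makes the decomposition
invariant to the scale of any brain variable. Each LV is oriented so its
largest-magnitude behavior salience is positive; this sign convention is
arbitrary but fixed, and reported LV-behavior correlation signs depend on
it.

* **Permutation test.** Rows of Y are permuted jointly (preserving the
  behavior covariance) and the SVD refit; per LV,
  `p = (1 + #(S_perm >= S_obs)) / (nPerm + 1)`. The add-one estimator
  avoids zero p values.
* **Bootstrap ratios.** Subjects are resampled with replacement; each
  bootstrap SVD is aligned to the original by an orthogonal Procrustes
  rotation computed on the behavior saliences (axis/sign indeterminacy is
  otherwise fatal to SE estimation). The BSR of a brain variable is its
  *singular image* — salience times singular value — divided by the
  bootstrap SE of that quantity. The singular image is the quantity the
  field's reference implementation bootstraps; dividing the *normalized*
  salience by its bootstrap SE instead produces systematically inflated
  ratios, because bootstrap singular values are positively biased and
  shrink the spread of normalized coordinates. |BSR| >= 2 is the
  conventional reliability rule. Bootstrap samples in which any column
  goes constant are redrawn (at most 100 times each).
* **Split-half reproducibility.** Subjects are repeatedly halved; per LV,
  singular-vector similarity is the absolute correlation of the halves'
  brain saliences after greedy LV matching, and singular-value similarity
  is the matched product of half singular values normalized by the
  squared full-data singular value. Z_svec and Z_sval are mean/SD of
  these draws over splits; null Zs repeat the procedure with Y freshly
  permuted each split, and an LV counts as reproducible when its Z
  exceeds 2 plus the null Z. The exact similarity formulas of the
  originating method are not uniquely pinned down in the literature we
  follow; these definitions are documented alternatives, and the tests
  exercise their calibration (signal flagged, permuted labels not), not
  numeric equality with any external implementation.
* **Reliable patterns.** Variables passing the BSR threshold are reported
  one salience sign at a time; in edge mode the summary includes
  per-region degree over selected edges, hub regions (degree > 3), and
  the percentage split into left-intra-, right-intra- and
  interhemispheric connections (summing to 100).

## Lifespan statistics

**Rolling correlation.** Windows are 10 years wide and step 1 year,
starting at integer years from `floor(min age)` to
`floor(max age) - width + 1` with half-open membership
`[start, start + width)`. Sliding 1-year steps (rather than disjoint
tiles) are adopted because they are the only stepping that reproduces the
expected bin count over a 18.5-88.9-year cohort (62 windows). Each
window's Pearson r gets a bias-corrected and accelerated (BCa) bootstrap
CI; windows with fewer than 3 subjects report NA.

**BCa intervals.** Bias correction z0 from the fraction of bootstrap
replicates below the point estimate (ties counted half, and the fraction
clamped away from 0 and 1 so z0 stays finite); acceleration from
jackknife skewness (zero when the jackknife is degenerate). With z0 = 0
and a = 0 the interval reduces to the percentile interval; a fully
degenerate bootstrap distribution collapses the interval to the point
estimate.

**t tests.** Paired t with df = n - 1 (identical vectors return t = 0,
p = 1 rather than erroring); independent-samples t uses the Welch
correction by default, with a pooled-variance option (df = n1 + n2 - 2)
matching the convention implied by whole-cohort df reporting.

**Regression models.** Mean local efficiency over a configurable region
set (typically the PLS-flagged regions) is regressed by OLS on: Model 1 —
age, sex, small-worldness, SC total; Model 2 — age, sex, small-worldness,
mean SC distance; Model 3 — all five. Sex is coded with female as
reference ("Sex (male)" row). CIs are `estimate +/- t_{.975,df} * SE`.
Rank-deficient or near-collinear designs (condition number above 1e10)
are refused with the offending terms named. Group (YA vs OA) coefficients
are compared by 95% CI overlap — deliberately conservative, and reported
as such. No multiple-testing correction is applied beyond the PLS
permutation/BSR machinery, mirroring the analysis convention this
package reproduces.

The age-group split is at 50 years: younger adults strictly below,
subjects at or above the boundary counted as older adults.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated. Defaults: 600 subjects, ages uniform on 18.5-89 years, sex
balanced, fluid intelligence on a Cattell-like scale (mean 33, SD 6.5)
constructed as `rho * z(age) + sqrt(1 - rho^2) * z(noise)` with rho =
-0.65 and the noise orthogonalized against age in sample, so the realized
correlation equals the target exactly; 64 regions in two lateralized
blocks ("hemispheres" by coordinate sign, so intra/interhemispheric
reporting is testable) — a deliberately smaller parcellation than the
218-region atlas it emulates, chosen for fast graph computation, with
larger counts available by configuration.

Connectomes follow a distance-decay template: regions get random 3D
coordinates (mm scale), template weight proportional to `exp(-d/30mm)`,
sparsified to 35% density by keeping the strongest template edges (which
preferentially keeps short intrahemispheric connections, as in real SC).
Per-subject weights multiply the template by lognormal noise (SD 0.3 on
the log scale) and by planted effects, applied on the log scale so
weights stay nonnegative, then rescale globally to a maximum of 1.
Distances are Euclidean distances on the shared coordinates with a small
per-subject lognormal jitter (SD 0.05): without it every subject would
share one distance matrix and "mean SC distance" would be constant,
making the distance-bearing regression models unestimable. The source
data this emulates has subject-specific streamline curvature, so the
jitter restores a real feature, not just a numerical convenience.

Planted effects carry loadings per SD of age and per SD of
age-residualized cognition on an edge support (or the connections of a
region set), giving known ground truth for PLS and rolling-window
recovery. The default recovery component spans 120 intrahemispheric
edges with loadings -0.6 (age) and +0.45 (cognition).

What the generator does *not* emulate: spatial autocorrelation of edge
noise, subject-specific connection supports (all subjects share the
template support, so consistency thresholding and isolated-region
exclusion are exercised by constructed fixtures instead), atlas
peculiarities, head-motion or tractography artifacts, and any
non-lognormal weight distribution — the empirical distribution of
streamline probabilities is not documented for the source data, and
lognormality is an explicit assumption. Passing recovery tests therefore
demonstrates correctness of the machinery under these idealized
conditions, not robustness to every property of real dMRI data.

## Calibration facts worth knowing

Null bootstrap ratios are t-like rather than exactly standard normal
(finite subjects), and the across-edge spread of a single realized cohort
fluctuates a few percent around what subject-resampling estimates. In
practice the false-positive rate of |BSR| >= 2 selection on a null edge
hovers near 5% and varies between cohorts of the same design; treat the
threshold as the field does — a reliability heuristic, not an exact
size-0.05 test. The permutation p, by contrast, is a valid Monte-Carlo p
by construction, and the BCa interval attains close-to-nominal coverage
for correlation statistics at moderate n; both facts are verified by the
package's calibration tests at reduced Monte-Carlo sizes (500 replicate
datasets for the permutation test; 1000 simulations with 500 bootstrap
replicates for BCa coverage).

## Problem sizes used in the test suite

Unit tests run on cohorts of 10-60 subjects with 8-16 regions; recovery
and calibration checks use 150-600 subjects with 16-64 regions, 100-200
permutations, 200-500 bootstrap replicates and 50-100 splits. These sizes
were chosen so the full suite completes in about a minute while keeping
every Monte-Carlo margin comfortable; the pipeline defaults (`runConfig`)
use a reduced resampling profile of 100 for the same reason, with the
full 1000-iteration study profile one argument away.

## Known limitations

* Analyses are cross-sectional; no longitudinal or mixed-effects models.
* Group-stratified (sex) PLS is not implemented; the reproduced analysis
  found no sex group effect and dropped it.
* The split-half Z definitions are one concrete reading of a loosely
  specified method (see above).
* Brain-surface rendering and anatomical interpretation are out of scope;
  outputs are tables (CSV) and reports (JSON).
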