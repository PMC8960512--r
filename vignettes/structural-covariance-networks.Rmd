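---
title: "Structural covariance network analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural covariance network analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scnet)
```

## The analysis

Structural covariance networks describe the coordination of regional brain
anatomy across individuals. `scnet` implements the group-level analysis used
in multiple sclerosis (MS) T1-weighted MRI studies: regional grey-matter
fractions (values in $[0,1]$, one row per subject, one column per region —
conventionally the 116 regions of the AAL atlas) are correlated across the
subjects of one group, and the resulting association matrix is analysed as a
weighted undirected graph. The pipeline has four stages:

1. **Nodes** — regions of a parcellation, carried as columns of an
   `scn_cohort`.
2. **Association** — Spearman rank correlation between each pair of regions
   over the group's subjects (average ranks at ties). Spearman is preferred
   over Pearson for its insensitivity to outliers and skewed distributions.
3. **Association matrix** — negative correlations are set to zero (several
   parameters are undefined on signed graphs); the diagonal is zero; no
   thresholding or binarisation beyond that, so the graph stays fully
   weighted. Exact-zero correlations count as absent edges for degree.
4. **Parameters** — the nodal set: degree $k_i$, strength $s_i$,
   characteristic path length $l_i$, clustering coefficient $C_i$, global
   efficiency $E_i$, local efficiency $E^{loc}_i$, within-module degree
   z-score $z_i$ and participation coefficient $P_i$; the global level is
   the nodal mean over all regions (infinite path lengths excluded, their
   count reported), plus the graph-level transitivity $T$, modularity $Q$,
   assortativity $r$ and small-worldness $\sigma$.

One graph exists **per group**, not per subject: covariance across subjects
is the edge definition, so inference must compare groups as wholes. That is
why the inferential engine is a label-permutation test (below), and why each
group needs at least 3 subjects for edges to be defined at all.

## Weighted conventions

The classical parameter definitions are binary; the package uses the
standard weighted generalisations and isolates each behind one documented
function:

* **Path length**: edge length $= 1/w$, so strong associations are short;
  distances are weighted shortest paths (Floyd–Warshall). Unreachable pairs
  are $\infty$; nodal and global path-length means exclude infinite entries
  rather than propagate them, which keeps the statistic finite on the
  near-complete graphs covariance analysis produces.
* **Clustering**: the Onnela geometric-mean formula on max-normalised
  weights, $C_i = \frac{1}{k_i(k_i-1)}\sum_{jh}
  (\hat w_{ij}\hat w_{jh}\hat w_{hi})^{1/3}$ with $\hat w = w/\max(w)$, zero
  for $k_i < 2$. Transitivity is the ratio of the summed numerator to the
  summed $k_i(k_i-1)$.
* **Local efficiency**: global efficiency of the subgraph induced by a
  node's neighbours.
* **Modularity / communities**: seeded Louvain maximisation of Newman
  weighted modularity at resolution 1; the detected partition is the one
  used for $z_i$ and $P_i$. $z_i$ standardises within-module strength
  inside each module (0 where the module SD is 0); $P_i = 1 - \sum_m
  (s_{im}/s_i)^2$ (0 for isolated nodes).
* **Assortativity**: Pearson correlation of endpoint degrees over all
  edges, both orientations; the strength variant is available as an option.
  Degree-regular graphs make it undefined — the package returns `NaN` with
  a warning rather than an arbitrary number.
* **Small-worldness**: $\sigma = (C/C_{rand})/(L/L_{rand})$ against
  degree-preserving edge-rewired null graphs whose weight multiset is
  randomly reassigned to the surviving edges; `n_random` defaults to 20
  inside permutation loops and 100 outside (the pipeline default), a
  compromise between null-estimate stability and cost.

All metric kernels are validated against independent brute-force
implementations (triple loops, exhaustive simple-path enumeration,
exhaustive partition search on up to 8 nodes) at tolerance $10^{-10}$ in the
test suite.

## Permutation inference

For a pair of groups, the observed difference of every parameter
(comparison minus reference) is referenced against the null distribution
obtained by reshuffling subjects between the two groups (group sizes
preserved), rebuilding both graphs and recomputing all parameters — 1000
permutations by convention. A single permutation sequence serves all
parameters (joint resampling): the procedure is described as one loop, and
joint resampling is both cheaper and valid; per-parameter marginal
inference is unaffected.

Significance at the global level uses the **95 % CI rule**: the difference
is significant when it falls outside the 2.5–97.5 percentile interval of
the permutation null. The percentiles are computed with the rank-based
(type-6) quantile estimator: for an exchangeable observed value the
probability of exceeding either bound is then close to 2.5 % per tail at
any permutation count, so the rule's level stays at its nominal 5 %
(interpolation types that sit further inside the sample, such as R's
default type 7, make the rule measurably anti-conservative at moderate
permutation counts). This operationalises "the distribution of the group
lying outside the 95 % CI of the reference" — the only reading consistent
with a permutation test. A two-sided p-value is also reported with the
add-one estimator $p = (1 + \#\{|d^{perm}| \ge |d^{obs}|\})/(B+1)$, which
can never be exactly zero. The two rules agree on the vast majority of
cases (a tested invariant); disagreements at the boundary are possible
because percentile interpolation and the two-sided tail count discretise
differently.

Permutations on which a parameter is undefined (assortativity on a
degree-regular permuted graph, path length on an edgeless one) are recorded
as missing and excluded from that parameter's null; a parameter with more
than 20 % exclusions is flagged unreliable rather than silently reported.

Nodal maps are corrected across regions per parameter with the
Benjamini–Hochberg step-up procedure at $q = 0.05$, conjoined with the
requirement that the raw p-value is at most 0.05. The conjunction is stated
in the field as "p both ≤ 0.05 and ≤ the FDR-corrected p"; since BH-adjusted
p-values are never below raw ones, its effective content is *membership in
the BH discovery set and raw p ≤ 0.05*, which is how `fdr_bh()` implements
and documents it.

Pooled contrasts (healthy controls versus all MS subtypes together) relabel
the pooled subjects **before** permutation, so the shuffled labels are
reference versus pooled group.

## The synthetic cohort generator

Clinical covariance cohorts are rarely shareable, so the generator
reproduces the statistical structure the analysis assumes and lets every
claim be exercised end to end:

* a shared multivariate-normal draw per subject — group mean profile
  (default a fixed 0.35–0.55 grey-matter-fraction gradient) plus a common
  base covariance (default: six equal blocks, region SD 0.04, within-block
  correlation 0.45, between-block 0.15 — a coarse community structure of
  the kind lobar anatomy induces);
* per-subject **lesion loads** in ml from log-normal distributions moment
  matched to published MS cohort statistics: 0.3 ± 0.8 (controls),
  15.3 ± 18.7 (relapsing–remitting), 25.5 ± 29.9 (progressive). The heavy
  right tail is characteristic of MS lesion volumes. (Published pooled
  "MS total" moments are internally inconsistent with their subgroups, so
  the generator parameterises subgroups and pools implicitly.)
* the **original arm** adds independent regional noise with variance
  `heterogeneity_gain × lesion_load` — the imprint of unfilled lesions on
  segmentation. The default gain of $2\times10^{-4}$ makes the lesion-noise
  SD at a typical 20 ml load about 1.5 × the base regional SD: strong
  heterogeneity, as described for unfilled MS data.
* the **filled arm** omits that noise but perturbs
  $\mathrm{Poisson}(\texttt{artefact\_rate} \times \text{load})$ randomly
  chosen regions per subject by $\pm$`artefact_magnitude` — filling
  artefacts. Defaults: 0.25 artefacts per ml (a few per typical MS subject,
  of the order of published artefact censuses) and 0.05 grey-matter-fraction
  units. No quantitative artefact magnitude is published in GM-fraction
  units; it is a free parameter and is reported with every experiment here.
* all values are clipped to $[0,1]$; with default parameters clipping
  affects well under 1 % of values (a tested invariant). One master seed
  drives deterministic per-component streams; identical configurations are
  bit-identical.

### The planted group effect

A mean shift cannot alter a correlation network, so group effects must act
on covariance. The default mechanism, `effect_type = "shared_factor"`, adds
a rank-one common disease factor to the affected regions of the affected
groups: coordinated atrophy, the classic source of *increased* structural
covariance in MS. This choice matters for the paired-arm experiment: the
original arm's lesion noise *attenuates* correlations, i.e. acts in the
opposite direction to the shared factor, so heterogeneity masks the true
effect exactly as described for unfilled data, and removing the noise
(filling) unmasks it. The alternative `"disconnection"` mechanism (scaling
the affected regions' covariance down) is retained, but in that case the
noise pushes the same way as the effect and the original arm can only gain
sensitivity — a regime in which lesion filling cannot help; the package
documents rather than hides this asymmetry.

### What the generator does not emulate

Spatial autocorrelation of noise, covariate structure (age, sex), scanner
effects, non-Gaussian marginals, and any image-space lesion geometry (that
is the phantom module's domain). Passing validation studies on this
generator therefore demonstrates the *statistical machinery* — calibration,
FDR control, the variance-masking mechanism — not fidelity to any
particular clinical dataset.

## Lesion filling on volumes

`fill_lesions()` implements local-neighbourhood filling: iteratively, every
unfilled lesion voxel with at least one filled or non-lesion 6-neighbour
receives the mean intensity of those neighbours, synchronously per pass,
until the mask is exhausted — intensities propagate from the rim inward.
The operator is exact on constant volumes, the identity on empty masks,
idempotent, local (voxels untouched outside the mask) and
shape-preserving; the test suite checks it against an independent
pass-by-pass recurrence. Mean aggregation over the 6-neighbourhood is the
simplest faithful reading of "filling with the intensity of adjacent
voxels"; median aggregation would be marginally more edge-preserving but is
not what the description implies.

Probability-map inputs are binarised at 0.5 (configurable) before filling.
`generate_phantom()` builds a three-shell brain-like phantom (WM core, GM
shell, CSF rim) with spherical lesions, optionally with a filling mask
dilated beyond the true lesion — emulating the overshoot of binarised
lesion probability maps at tissue interfaces. That overshoot is what makes
artefacts *outside* the true lesion possible at all: a filling operator
confined to a perfect mask can never change tissue there. With it, the
artefact surrogate (`tissue_change_score()` on nearest-mean
classifications, ties to the earlier class for determinism) grows with
lesion volume, the synthetic analogue of the strong positive
lesion-volume–artefact correlation reported for real filled images.

## Validation studies and their sizes

The acceptance-level test suite runs, on one CPU:

* metric–oracle equivalence over 25 fixture graphs of up to 8 nodes at
  $10^{-10}$;
* type-I calibration of the CI rule: 500 exchangeable-null replicates
  (two groups of 20, 10 regions, 500 permutations each), per-parameter
  rejection rate within two binomial SDs of 0.05. The parameter set here
  excludes local efficiency and small-worldness, which multiply the cost of
  every permutation ~20–40-fold at realistic sizes; both are validated at
  the metric level instead and remain available in `permutation_compare()`;
* FDR control: 1000 synthetic 116-region nodal maps with 10 % true effects,
  mean realised false-discovery proportion at most $q$;
* the paired-arm contrast: 50 replicate cohorts of 19 + 30 subjects, 116
  regions, 200 permutations, 8 global parameters — the lesion-filled arm
  must detect at least as many significant parameters as the original arm
  in at least 80 % of replicates;
* the artefact census (Spearman > 0.5 at default rates) and the filling
  recurrence checks.

`scripts/acceptance.R` recomputes scaled versions of the same quantities
from a fresh seed and writes them as JSON.

## Known limitations

* Group-level graphs mean no per-subject network statistics and no
  covariate adjustment; designs needing them require different machinery
  (e.g. jackknife covariance networks).
* Louvain is a heuristic: the partition (and hence $z$, $P$, $Q$) is the
  seeded optimum found, not a certified global optimum — exhaustive search
  in the tests confirms optimality only on small graphs.
* The conjunction FDR rule is implemented as stated in the field but is
  effectively BH ∧ (p ≤ 0.05), and with $q = 0.05$ it coincides with plain
  BH whenever the number of regions tested is at least one.
* Permutation p-values are exchangeability-based; group-specific variance
  (which the generator deliberately creates) technically violates
  exchangeability under the null of equal means only — the package follows
  the field's practice of permuting anyway, and its calibration study
  bounds the practical consequence under the null actually simulated.
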