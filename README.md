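# scnet — structural covariance network analysis for MS MRI studies

`scnet` is an R package for group-level **structural covariance network**
analysis of regional grey-matter fractions, the graph-theory approach used
to study network reorganisation in multiple sclerosis (MS) from T1-weighted
MRI. It is written for neuroimaging researchers who have (or simulate)
subject × region grey-matter-fraction tables with group labels, and who
want the full pipeline — graphs, parameters, inference — reproducible from
a single seed.

## What it computes

For each group, the edge between regions *i* and *j* is the Spearman rank
correlation of the two regions' grey-matter fractions across the group's
subjects; negative correlations are set to zero and the graph stays fully
weighted. On each graph the package computes the standard parameter set —
nodal degree *k*, strength *s*, characteristic path length *l* (edge length
1/*w*), Onnela clustering *C*, global and local efficiency *E*,
within-module degree z-score and participation coefficient (from a seeded
Louvain partition), and at the global level their nodal means plus
transitivity *T*, modularity *Q*, assortativity *r* and small-worldness
σ = (C/C_rand)/(L/L_rand) against degree-preserving rewired nulls.

Groups are compared with **label-permutation tests** (1000 permutations by
convention): a difference is significant when it lies outside the 95 % CI
(2.5–97.5 percentiles) of the permutation null; nodal maps are corrected
across regions with the Benjamini–Hochberg procedure at *q* = 0.05
conjoined with raw *p* ≤ 0.05.

Two companion modules close the loop on the lesion-filling question:

* `fill_lesions()` — a local-neighbourhood filling operator for 3-D
  volumes (iterative inward 6-neighbour mean), with phantom generation and
  an artefact score for filling-induced tissue-class changes;
* `generate_cohort()` — a synthetic cohort simulator producing paired
  "original" and "lesion-filled" arms: lesion-load-driven heterogeneity
  noise in the former, sparse artefact perturbations in the latter, and an
  optional planted group effect (a shared coordinated-atrophy factor), so
  the claim *lesion filling increases the detection rate of network
  alterations* can be tested end to end without any imaging data.

## Worked example

```r
library(scnet)

cfg <- cohort_config(n_regions = 20, group_sizes = c(HC = 15, MS = 20),
                     lesion_load_mean_sd = list(HC = c(0.3, 0.8),
                                                MS = c(15.3, 18.7)),
                     affected_regions = 1:20, effect_size = 0.6,
                     effect_groups = "MS", seed = 42)
arms <- generate_cohort(cfg)

g <- build_association_matrix(arms$filled, "HC")
graph_metrics(g, seed = 1, n_random = 20)
#> Network parameters: group 'HC' (20 regions, 4 modules)
#>   average_degree         11.1000
#>   average_strength       3.1089
#>   average_path_length    4.9417
#>   clustering             0.2052
#>   global_efficiency      0.2519
#>   local_efficiency       0.2712
#>   transitivity           0.1918
#>   modularity             0.2275
#>   assortativity          -0.0522
#>   small_worldness        1.0223

permutation_compare(arms$filled, "HC", "MS",
                    parameters = c("average_strength", "clustering",
                                   "modularity", "assortativity"),
                    n_perm = 1000, seed = 7)
#> Permutation comparison: HC vs MS (15 vs 20 subjects, 1000 permutations)
#>   global: 2/4 parameters significant (95% CI rule)
#>     average_strength       diff  +3.2402  CI [ -3.2510,   2.9185]  p=0.0420 *
#>     clustering             diff  +0.1535  CI [ -0.1648,   0.1585]  p=0.0689
#>     modularity             diff  -0.1705  CI [ -0.1548,   0.1187]  p=0.0200 *
#>     assortativity          diff  -0.0897  CI [ -0.1799,   0.1330]  p=0.2478
```

The MS group's planted coordinated-atrophy factor raises its inter-regional
covariance: average strength is significantly higher and modularity
significantly lower than in controls — strengthened diffuse coupling
dissolves community structure. The per-subject artefact census on the same
cohort correlates with lesion load:

```r
counts <- artefact_count_per_subject(arms$filled, arms$original)
round(attr(counts, "spearman"), 2)
#> [1] 0.82
```

An end-to-end run (simulate → graphs → metrics → comparisons → CSV/JSON
artefacts) is one call:

```r
run_pipeline(list(mode = "synthetic",
                  cohort_config = list(group_sizes = c(HC = 19, RRMS = 30, PMS = 19)),
                  design = list(c("HC", "MS"), c("HC", "RRMS"),
                                c("HC", "PMS"), c("RRMS", "PMS")),
                  pool = list(MS = c("RRMS", "PMS")),
                  n_perm = 1000, seed = 1),
             out_dir = "results/run1")
```

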