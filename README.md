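# scnet — structural covariance network analysis of cortical thickness

`scnet` builds and compares **structural covariance networks (SCNs)** from
region-of-interest cortical thickness tables, for researchers studying how
an intervention (here, one night of restricted sleep in a two-condition
crossover cohort) reorganizes group-level brain structure. Nodes are the 68
cortical regions of the Desikan–Killiany atlas; edges are across-subject
Pearson correlations of mean thickness that survive Benjamini–Hochberg FDR
control and a positivity filter.

The analysis core, per condition:

- correlation matrix *r<sub>ij</sub>* with exact p-values from
  *t = r√((n−2)/(1−r²))*;
- BH step-up at *q* = 0.05 over the 2278 undirected pairs, keeping
  positive significant edges, binarized;
- graph metrics: clustering *C*, characteristic path length *L*, global
  and local efficiency, nodal degree / efficiency / betweenness, and
  small-world indices γ = *C*/*C*<sub>rand</sub>,
  λ = *L*/*L*<sub>rand</sub>, σ = γ/λ against 100 degree-preserving
  Maslov–Sneppen rewirings;
- paired condition-label permutation inference: each subject's two
  condition rows are randomly swapped and the **entire** pipeline
  (thresholding included) is re-run per permutation; nodal results are BH
  corrected across ROIs.

A synthetic cohort generator (`simulate_cohort()`) reproduces the
statistical structure the analysis assumes — block covariance modules,
within-subject reliability, injected thinning or covariance effects — so
the whole pipeline is testable without MRI data. Summary-statistic
demographics tests (`two_sample_t_from_summary()`, `chi_square_2x2()`)
recompute cohort-table p-values from printed means/SDs/counts.

## Worked example

Simulate the default 80-subject crossover cohort (43 young, 37 old, four
bilateral background covariance modules at r = 0.4) with an injected
10-ROI cingulo-insular module whose correlation rises from 0.2 to 0.5
under sleep restriction, then test for network differences:

```r
library(scnet)

cing <- as.character(outer(c("lh_", "rh_"),
  c("caudalanteriorcingulate", "posteriorcingulate",
    "rostralanteriorcingulate", "isthmuscingulate", "insula"), paste0))
spec <- cohort_spec(
  covariance_modules = c(default_cohort_spec(seed = 1)$covariance_modules,
                         list(list(rois = cing, r = 0.2))),
  covariance_effects = list(list(rois = cing, condition = "restricted",
                                 dr = 0.3)),
  seed = 1)
tab <- simulate_cohort(spec)

cov_r <- correlation_matrix(tab[tab$condition == "restricted", ])
net_r <- threshold_fdr(cov_r, q = 0.05)
net_r
#> Binary SCN: 68 nodes, 135 edges
round(network_metrics(net_r, n_random = 100, seed = 2)$global, 3)
#>        C        L E_global  E_local    gamma   lambda    sigma
#>    0.516    1.379    0.075    0.557    6.228    0.567   10.978

perm <- permute_conditions(tab, n_perm = 1000, n_random = 100, seed = 11)
permutation_summary(perm)
#>    metric restricted   full difference p_two_sided
#>         C     0.5156 0.3163     0.1993      0.0440
#>         L     1.3791 1.3956    -0.0166      0.9151
#>  E_global     0.0746 0.0445     0.0301      0.0919
#>   E_local     0.5574 0.3634     0.1940      0.0679
#>     gamma     6.3060 4.9899     1.3162      0.2957
#>    lambda     0.5694 0.5045     0.0649      0.6214
#>     sigma    11.0753 9.8911     1.1842      0.6693
```

The injected covariance increase surfaces as a higher clustering
coefficient under restriction (difference +0.199, permutation two-sided
p = 0.044) with local efficiency close behind, while path length and the
small-world indices are unchanged — the module adds local triangles, not
long-range shortcuts. σ ≫ 1 in both conditions: thresholded covariance
networks are strongly small-world.

Demographics from printed summaries:

```r
anx <- two_sample_t_from_summary(group_summary(2.79, 2.45, 43),
                                 group_summary(1.46, 1.46, 37))
#> anxiety: t = 2.89, df = 78, p = 0.005
```

The same analysis runs non-interactively from a YAML config
(`run_pipeline("config.yaml", "out/")`, or the `scnet-pipeline` script
under `inst/scripts/`), writing correlation matrices, networks,
metric/permutation JSON reports, and a manifest with the config hash and
all seeds; identical config + seed reproduces every output byte-for-byte.

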