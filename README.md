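# refstab

Reference-gene stability evaluation and multi-reference normalization for
qRT-PCR, in R.

Relative quantification by qRT-PCR stands or falls with the reference
(housekeeping) genes used to normalize it: a reference that itself responds
to the tissue or treatment under study silently rewrites the target gene's
fold changes. `refstab` implements the complete selection workflow a
practitioner runs before trusting a normalization:

- **Efficiency handling** — per-assay amplification efficiency from a
  dilution series via `E = 10^(-1/slope)`, and efficiency-corrected
  relative quantities `Q = E^(minCt − Ct)` (the `2^-ΔCt` transform,
  generalized to gene-specific `E`).
- **Four per-gene stability statistics** — comparative delta-Ct
  (mean pairwise SD, `delta_ct_msd()`), BestKeeper (descriptive stats and
  correlation with the geometric-mean index, `bestkeeper()`), geNorm
  (M-values with iterative exclusion and the `V(n/n+1) < 0.15` gene-number
  rule, `genorm()` / `genorm_v_curve()`) and a NormFinder-style
  inter/intra-group stability value (`normfinder()`).
- **Consensus ranking** — cross-entropy Monte-Carlo minimization of the
  summed Spearman footrule distance to the four rankings
  (`aggregate_ce()`), with an exhaustive oracle for small panels
  (`aggregate_exhaustive()`).
- **Combination scoring** — GrayNorm-style evaluation of every candidate
  reference-gene subset by how close each treatment group's mean `1/NF`
  stays to 1 relative to a control group (`graynorm()`).
- **Target normalization** — multi-reference normalization factors
  (per-sample geometric means) and calibrator-anchored relative expression
  with group mean ± SE (`normalization_factor()`, `relative_expression()`).
- **Synthetic data with ground truth** — `generate_dataset()` simulates
  multi-condition Ct panels (stable and treatment-responsive genes,
  per-sample loading offsets, gene-specific efficiencies, planted target
  fold changes) so every stage is testable end to end.

The published 14-gene rank tables from a *Metasequoia* reference-gene
screen (tissues, two hormone-treatment series) ship under `inst/extdata/`
as ready-made inputs for the aggregation stage, along with the
corresponding assay efficiencies.

## Worked example

```r
library(refstab)

ds <- generate_dataset(synthetic_spec(seed = 101))   # 8 candidates + 1 target
cfg <- pipeline_config(ds$ct, ds$sheet, ds$eff, targets = "TGT1", seed = 101)
bundle <- run_pipeline(cfg)

consensus_report(bundle)
#>       method combination
#> 1   delta_ct    S1+S2+S3
#> 2 bestkeeper    S2+S1+S3
#> 3     genorm    S1+S2+S3
#> 4 normfinder    S1+S2+S3
#> 5 rankaggreg    S1+S2+S3
#> 6   graynorm    S2+S3+U2
```

`S1`–`S3` are the generator's planted stable genes: all four per-gene
algorithms and their rank-aggregation consensus recover the stable triple.
(The GrayNorm row illustrates the combination score's documented
sensitivity to per-sample loading noise — see the vignette's limitations
section.)

```r
bundle$v_curve
#>   V2/3   V3/4   V4/5   V5/6   V6/7   V7/8
#> 0.0407 0.1399 0.1099 0.1251 0.1864 0.2430
#> recommended n = 2 (threshold 0.15)
```

`V2/3 = 0.041 < 0.15`: two reference genes would already suffice for this
panel by the geNorm rule.

```r
bundle$expression$TGT1
#> relative_expression of TGT1 (calibrator group 'control')
#>    group mean_fold         se n
#>  control  1.000000 0.06403722 3
#>   treatA  1.132473 0.04174426 3
#>   treatB  4.275838 0.08836276 3
```

The target was simulated at fold 4 in `treatB`; normalized against the
best reference combination it is estimated at 4.28 ± 0.09 (mean ± SE over
the three biological replicates), with the calibrator group anchored at 1.

To aggregate pre-computed rank lists (e.g. published tables) without Ct
data:

```r
lists <- read_rankings(system.file("extdata",
                                   "metasequoia_tissue_rankings.csv",
                                   package = "refstab"))
aggregate_ce(lists, seed = 1)
#> consensus_ranking (cross_entropy): objective = 54 after 23 iteration(s)
#> 1 AP-2  2 Cpn60b  3 elF-5A  4 EF1a  5 ACT2  6 GIIa  7 RP  8 RPL17 ...
```

A thin command-line wrapper with `run`, `aggregate` and `simulate`
subcommands lives at `inst/scripts/refstab.R`.

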