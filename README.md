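# purinedelta

Comparative metabolomics of purine biosynthesis, as a tested R pipeline.

## What this is for

Small-cohort metabolomics studies — a handful of humans, chimpanzees and
macaques per tissue, or 9–12 mice per genotype — ask whether metabolite
concentrations shift between groups and whether the shifts concentrate in a
pathway. The motivating case is de novo purine biosynthesis and the enzyme
adenylosuccinate lyase (ADSL, catalyzing SAICAR→AICAR and SAMP→AMP): do its
pathway metabolites sit systematically lower in one lineage or genotype,
and do the supporting biophysical assays (enzyme kinetics, thermal
stability, tetramer dissociation) point the same way?

`purinedelta` packages that entire analysis for anyone with a
metabolite-by-sample intensity table: preprocessing, per-metabolite
statistics, the study-level aggregate tests, the assay computations, and a
synthetic-data generator with known ground truth so every stage is testable
without the original measurements.

## The statistics at the core

Operating on log-scale intensities, with the average-log fold change
`Δ̂ᵢ = mean(log xᵢ,A) − mean(log xᵢ,B)` per metabolite:

* **Permutation count test** — the number of metabolites with nominal
  t-test p < 0.05 is referred to its distribution under B = 1000
  size-preserving label shuffles; `p = (1 + #{C_b ≥ C_obs}) / (1 + B)`,
  with exact enumeration on small designs (4 vs 4 → all 70 assignments).
* **Lineage-specific filter** — significant in the same direction between
  the focal group and each outgroup, non-significant between outgroups.
* **Pathway aggregation** — Fisher's combination (χ² with 2k df) of the
  direction-consistent member p-values per pathway, plus a hypergeometric
  over-representation alternative.
* **Purine-vs-rest** — two-sided Wilcoxon rank-sum test of fold changes,
  curated purine-biosynthesis metabolites against all other annotated
  metabolites.
* **Direction binomial** — exact tail of Binomial(n, ½) for the number of
  decreases among detected metabolites; sidedness is an explicit argument
  (10 down of 12, two-sided → 0.0386; 9 down of 10, one-sided → 0.0107).
* **Assay computations** — specific activity from an A282 time course via
  Beer–Lambert (nmole/min/µg), BCA standard-curve inversion, thermal-melt
  midpoint (temperature of 50% folded, plateau-rescaled, interpolated),
  native-gel tetramer fraction T/(M+T) with half-dissociation
  interpolation, and single/mixed substrate activity ratios.

Preprocessing follows the field's conventions: internal-standard
normalization with ×3000 scaling and log10 transform, the ≥ 50% missingness
filter, upper-quartile normalization on the log scale, PCA outlier
screening at 3 SD on PC1/PC2, and Gaussian-kernel SVR flagging of
run-order-confounded metabolites.

## Worked example

Simulate a two-genotype study (10 vs 10 animals, 100 metabolites) with a
planted −0.5 log10 suppression of an 8-metabolite purine pathway, then run
the core statistics:

```r
library(purinedelta)

pa  <- setNames(rep("pb", 8), sprintf("m%04d", 1:8))
des <- simulation_design(c(hum = 10, wt = 10), n_metabolites = 100,
                         pathway_assignment = pa,
                         planted_effects = data.frame(pathway_id = "pb",
                                                      group = "hum",
                                                      effect = -0.5),
                         dropout_rate = 0.05, seed = 42)
sim <- simulate_intensity_table(des)
sim$table
#> intensity_table: 100 metabolites x 20 samples [log10 scale]
#>   missing entries: 104 (5.2%)
#>   groups: hum (n=10), wt (n=10)

d <- diff_test(sim$table, "hum", "wt")
head(d[order(d$p_value), ], 3)
#>   metabolite_id log_fc  p_value adj_p direction n_a n_b
#> 3         m0003 -0.708 4.99e-07    NA      down  10  10
#> 5         m0005 -0.630 1.87e-06    NA      down  10  10
#> 7         m0007 -0.652 2.75e-06    NA      down   9  10

permutation_count_test(sim$table, "hum", "wt", B = 1000, seed = 7)
#> permutation_result: 12 significant metabolites (inner alpha 0.05)
#>   p = 0.007992  (1000 label assignments, seed 7)

mem <- data.frame(metabolite_id = sprintf("m%04d", 1:100),
                  pathway_id = c(rep("pb", 8), rep(c("q1", "q2"), 46)))
map <- pathway_map(mem, purine_flag = names(pa))
pb_vs_rest(d, map)[c("p", "median_shift")]
#> $p
#> [1] 3.217132e-06
#> $median_shift
#> [1] -0.5261236
```

Reading the output: 12 of 100 metabolites pass the nominal cutoff where ~5
are expected by chance, and no label shuffle out of 1000 reached that count
(permutation p ≈ 0.008); the purine-flagged fold changes sit 0.53 log10
units below the rest (rank-sum p ≈ 3×10⁻⁶), recovering the planted −0.5
suppression. The top metabolites are all planted pathway members, called
`down` with fold changes near the truth.

The whole chain — preprocessing, per-stratum testing, permutation, pathway
statistics, manifest — runs from one config via `run_pipeline()` (see
`?run_pipeline`), or from a shell via
`Rscript inst/scripts/purinedelta.R --config run.yaml --out results/`.

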