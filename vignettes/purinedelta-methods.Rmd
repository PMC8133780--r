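---
title: "Statistical methods and design choices in purinedelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods and design choices in purinedelta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(purinedelta)
```

## The problem

Comparative metabolomics asks whether metabolite concentrations differ
systematically between groups — species, genotypes, or edited cell lines —
and whether those differences concentrate in particular pathways. The
motivating application for this package is the question whether de novo
purine biosynthesis operates at a lower level in modern humans than in
other primates, and whether two amino-acid substitutions in
adenylosuccinate lyase (ADSL), the homotetrameric enzyme catalyzing the
SAICAR→AICAR and SAMP→AMP steps of the pathway, are sufficient to produce
such a shift in model systems. The data are metabolite-by-sample intensity
tables from CE-MS, GC-MS or LC-MS, with small group sizes (4–12 individuals
per group), substantial detection dropout, and instrument drift — a regime
where preprocessing and the choice of test matter as much as the test
itself.

`purinedelta` implements the complete analysis chain as tested, reusable
functions, together with a synthetic-data generator that carries known
ground truth so every stage can be verified without access to any
particular study's measurements.

## The analysis model

All statistics operate on **log-scale intensities** (log10 after
internal-standard normalization for GC/CE-MS-style data, log2 plus
upper-quartile normalization for LC-MS-style data; the container carries an
explicit scale flag). The per-metabolite model is deliberately plain: for
metabolite $i$ and groups $A, B$, the effect estimate is the
average-log fold change

$$\widehat{\Delta}_i \;=\; \overline{\log x}_{iA} - \overline{\log x}_{iB},$$

computed over non-missing values only (pairwise deletion; no imputation,
because the data generating process for the missingness is unknown). The
per-metabolite p-value comes from a two-sided two-sample $t$ test (Welch by
default; a pooled-variance option is provided because "Student's t-test"
does not pin the variant) or the exact Wilcoxon rank-sum test for small,
possibly non-normal cell-line groups.

Four aggregate statistics sit on top:

1. **Permutation count test.** The number of metabolites with nominal
   $p < \alpha_{inner}$ (default 0.05, strict inequality) is compared with
   its distribution under $B$ (default 1000) size-preserving label
   shuffles. The p-value uses the add-one estimator
   $p = (1 + \#\{C_b \ge C_{obs}\})/(1+B)$: the plain ratio of permutations
   can return an invalid 0, while the add-one form treats the identity
   labelling as one more null draw. When the design admits fewer than $B$
   distinct assignments (4 vs 4 samples: 70), all assignments are
   enumerated exactly instead. The eligible metabolite set is frozen on
   the true labels so observed and null counts range over the same
   metabolites.
2. **Lineage-specific filter.** A metabolite is specific to a focal group
   when both focal-vs-outgroup contrasts are significant in the same
   direction while the outgroup-vs-outgroup contrast is not (all at
   unadjusted $\alpha = 0.05$ by default, matching a per-tissue screening
   use; BH adjustment is available for genome-scale cell-line screens).
3. **Pathway aggregation.** For each pathway and direction, the p-values
   of the direction-consistent detected members are combined by Fisher's
   method, $-2\sum_k \ln p_k \sim \chi^2_{2k}$; the upper tail is the
   pathway's cumulative p-value. A hypergeometric over-representation p is
   reported alongside. "Cumulative p-value" admits several readings;
   Fisher's combination was chosen because it uses the member p-values
   themselves (not just their count), reduces to the identity for a
   single-metabolite pathway, and is the field's default combiner.
4. **Purine-versus-rest and direction tests.** The distribution of
   $\widehat{\Delta}_i$ for the curated purine-biosynthesis metabolite set
   is compared against all other annotated metabolites by a two-sided
   rank-sum test (invariant under any common strictly increasing transform
   of the fold changes). The direction binomial test is exact:
   one-sided p is the binomial tail in the direction of the observed
   majority at success probability ½; the two-sided p doubles it, capped
   at 1. Sidedness is an explicit argument with no default, because
   published values mix both conventions (10 down of 12 two-sided gives
   0.0386 → "0.04"; 9 down of 10 one-sided gives 11/1024 → "0.01").
   The doubling rule — not the likelihood-based rule of
   `stats::binom.test` — is what reproduces such printed values, which is
   why the test is assembled from `pbinom` directly.

## Preprocessing

* **Internal-standard normalization** divides each intensity by the
  sample's spiked-standard intensity, scales by 3000 (the conventional
  factor that keeps the log10 ratios positive), and log10 transforms.
  Several standards are averaged geometrically.
* **Missingness filter**: metabolites with ≥ 50% missing values are
  removed (the "detected in less than half of the samples" rule;
  the two published phrasings — "less than half detected" and "≥ 50%
  missing" — are the same rule and are unified as ≥). With a stratifying
  column the rule applies within each stratum and a metabolite failing
  anywhere is dropped; the pipeline itself splits strata first, so this is
  a convenience for combined tables.
* **Upper-quartile normalization** subtracts the per-sample 75th
  percentile on the log scale. Division by the upper quartile before the
  log and subtraction after it are the same operation; operating on the
  log scale makes the idempotence and offset-invariance properties exact.
* **PCA outlier detection** (via `stats::prcomp`, centered, on metabolites
  with complete data or mean-imputed ones): samples whose PC1 or PC2 score
  lies more than 3 SD from the component mean are reported, in one pass.
  The 3-SD rule is a package decision — published analyses report "one to
  two outliers per tissue" without a criterion — and detection is
  deliberately separated from exclusion so the excluded set is always
  visible in the analysis code.
* **Run-order confound flagging** fits a Gaussian-kernel support vector
  regression (`e1071::svm`) of each metabolite on the measurement run
  order and flags metabolites whose fitted trend explains ≥ 30% of
  variance. Hyperparameters were fixed a priori: run-order indices are
  standardized, the kernel width uses the median pairwise-distance
  heuristic, $\varepsilon = 0.01$ and cost 10. With these settings a
  noiseless low-frequency sinusoid is captured (R² ≈ 0.8) while white
  noise at $n = 50$ is flagged in well under 5% of cases. The R²
  threshold is configurable because no published value exists.

## The synthetic-data generator

`simulate_intensity_table()` emulates the statistical structure the
analysis assumes, not the instrument physics:

* per-metabolite baseline means drawn from a wide hyperdistribution
  (log10-normal, mean 4, SD 1 — a plausible dynamic range for quantified
  MS intensities);
* Gaussian between-sample noise, default SD 0.2 log10 units (~60%
  coefficient of variation on the linear scale, typical of tissue
  metabolomics; no published per-metabolite variance estimates exist, so
  this is a free parameter chosen once);
* planted pathway-level shifts: a constant log10 effect added to all
  metabolites of a pathway in one group — coordinated, as real pathway
  regulation would be;
* dropout, either missing-completely-at-random (default) or left-censored
  at a global intensity quantile (a detection-limit mechanism); the
  missingness mechanism of real instruments is unknown, so both are
  available and MCAR is the default for its analytic transparency;
* smooth run-order drift: a random sum of 1–3 sinusoids scaled to a set
  amplitude, added to a subset of metabolites — low-frequency so that a
  kernel regression can capture it;
* outlier samples: a global shift of 5 between-sample SDs (comfortably
  past the 3-SD screening rule), in a random direction.

Ground truth (true group means, affected metabolites, drift metabolites,
outlier identities) is returned with the table. `simulate_melt_curve()`
plays the same role for the thermal-denaturation assay: a two-state
sigmoid, fraction folded $1/(1+e^{s(T-T_m)})$, sampled at 1 °C steps with
Gaussian signal noise.

What the generator does **not** emulate: correlated metabolites (real
pathways co-vary even without group effects), heavy-tailed or skewed
noise, batch structure beyond run order, intensity-dependent variance, or
annotation errors in the pathway map. Passing tests therefore demonstrate
that the machinery is correct under its own assumptions, not that those
assumptions hold for any particular instrument.

## Numerical choices and degenerate inputs

* Two groups with zero variance and equal means are a defined degenerate
  case: $p = 1$ (equal constants cannot be evidence of difference);
  zero variance with different means yields $p$ at machine epsilon.
* Fisher combination of all-1 p-values returns 1 within numerical
  tolerance; pathways with no direction-consistent member are omitted
  rather than scored.
* The melting midpoint rescales the signal to fraction folded using
  3-point plateau means at the temperature extremes and interpolates the
  0.5 crossing linearly; anchoring plateaus at the temperature ends (not
  at signal extremes) makes the estimate invariant to affine transforms
  and to the orientation of the ellipticity signal.
* The permutation test canonicalizes sample order internally, so results
  are invariant to the column order of the input for a fixed seed.
* Kinetic slopes use all time points by default; an optional
  initial-linear-window selector (best-R² prefix of ≥ 5 points) handles
  substrate depletion curving late time points.

## Known statistical limitations

Three properties of the method are worth knowing; all are quantified by
the package's own test suite and acceptance script, not assumptions:

* **The permutation p-value of a count statistic is discrete.** With
  $m = 200$ independent null metabolites the observed count is
  approximately Binomial(200, 0.05), whose largest atom has mass ≈ 0.13.
  The permutation p-value is calibrated at every attainable level, but
  its distribution has gaps of that size, so distance-to-uniform
  statistics (e.g. Kolmogorov–Smirnov against Uniform(0,1)) plateau near
  the atom mass regardless of the number of permutations.
* **Near-identity shuffles create a p-value atom just above the floor.**
  With strong planted effects, a label permutation that swaps a single
  pair of samples (expected about 0.5 times per 1000 draws at
  $n = 10+10$) preserves most of the signal and can tie or exceed the
  observed count, giving $p = 2/(B+1)$ instead of $1/(B+1)$ in a
  non-negligible fraction of runs. This is a property of the statistic,
  not an implementation artifact.
* **The lineage filter's two focal contrasts are correlated.** They share
  the focal samples, so under the null their $t$ statistics have
  correlation ½ and the joint false-call rate is ≈ 3.5× the $\alpha^2$
  that independence would predict (≈ 0.9% at $\alpha = 0.05$). The test
  suite verifies the implementation against a correlated Monte-Carlo
  oracle rather than the independence heuristic.

## Problem sizes

The bundled checks run at deliberately modest scale, chosen to make the
Monte-Carlo error small relative to the asserted tolerances: calibration
over 200 seeds at 200 metabolites and $B = 1000$; power sweeps over 50
seeds; null-rate estimates over 2000–5000 metabolites; enumeration oracles
over all rank-sum designs up to 6+6 and all binomial configurations up to
$n = 20$.

## A minimal session

```{r example}
pa <- setNames(rep("pb", 8), sprintf("m%04d", 1:8))
des <- simulation_design(c(hum = 10, wt = 10), n_metabolites = 100,
                         pathway_assignment = pa,
                         planted_effects = data.frame(pathway_id = "pb",
                                                      group = "hum",
                                                      effect = -0.5),
                         dropout_rate = 0.05, seed = 42)
sim <- simulate_intensity_table(des)
d <- diff_test(sim$table, "hum", "wt")
permutation_count_test(sim$table, "hum", "wt", B = 1000, seed = 7)

mem <- data.frame(metabolite_id = sprintf("m%04d", 1:100),
                  pathway_id = c(rep("pb", 8), rep(c("q1", "q2"), 46)))
map <- pathway_map(mem, purine_flag = names(pa))
pb_vs_rest(d, map)[c("p", "median_shift")]
```
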