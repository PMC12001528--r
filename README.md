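# mbresil

Quantifying gut-microbiome **resilience** — how hard a perturbation hits a
microbial community and how it recovers — from longitudinal taxa abundance
tables.

Ecological resilience is increasingly treated as a quantitative, *bivariate*
property: a disturbance has a magnitude, and the system has a recovery
behaviour, and neither alone tells the whole story. `mbresil` implements a
data-driven pipeline that summarises each subject's response to a
perturbation (an exercise bout, a diet switch, an antibiotic course) by two
functional principal component scores, without pre-committing to any single
hand-picked curve feature such as a slope or an area under the curve.

## The method

Starting from a samples × taxa relative-abundance table (e.g. a genus-level
16S table) and per-sample metadata (subject, condition, timepoint, baseline
flag), the pipeline:

1. **Zero replacement.** Log-ratio methods need strictly positive parts;
   zeros are imputed multiplicatively (each zero in a closed row becomes a
   small δ and nonzero parts are shrunk by 1 − zδ, preserving their
   ratios), or by a Bayesian-multiplicative rule for count tables.
2. **Log-ratio analysis (LRA).** A weighted PCA of the log-composition
   matrix (uniform row weights, mean closed abundance as column weights)
   decomposes the total log-ratio variance into per-taxon contributions;
   the smallest taxon set explaining ≥ 90 % of the variance is retained
   and rows are re-closed on that subcomposition.
3. **Distance trajectories.** For each subject × condition, the Aitchison
   distance
   d(u, v) = ‖clr(u) − clr(v)‖₂, with clr(u)ₖ = log(uₖ / g(u)),
   is computed between every timepoint and the pre-perturbation baseline,
   giving one distance-versus-time curve per trajectory. The Aitchison
   metric is scale-invariant and behaves consistently under taxon
   selection.
4. **Functional PCA.** The curve family Xᵢ(t) is decomposed via the
   Karhunen–Loève expansion Xᵢ(t) = μ(t) + Σₖ ξᵢₖ φₖ(t), computed as a
   quadrature-weighted PCA on the observed grid (trapezoid weights by
   default). Each trajectory is summarised by its first two scores
   (ξ₁, ξ₂): in perturbation–recovery families ξ₁ tracks the overall
   magnitude of displacement and ξ₂ the timing of the recovery.
5. **Outliers.** Trajectories whose (ξ₁, ξ₂) pair falls beyond the fence
   of a Tukey-halfspace-depth bagplot (a bivariate boxplot) are flagged as
   globally atypical.

A synthetic-study generator with known ground truth (per-trajectory shock
magnitude and recovery halflife in CLR space) makes the whole pipeline
testable end to end, and `simulate_family()` renders curves over a regular
(ξ₁, ξ₂) grid to visualise what the two scores mean.

## Worked example

A small synthetic study (6 dogs × 2 exercise conditions × 6 timepoints,
30 genera, sparse counts) ships with the package:

```r
library(mbresil)

table_path <- system.file("extdata", "synthetic_study_table.tsv", package = "mbresil")
meta_path  <- system.file("extdata", "synthetic_study_metadata.tsv", package = "mbresil")

res <- run_pipeline(table_path, meta_path, pipeline_config(seed = 1))
res
#> mbresil pipeline: 12 trajectories, 10 of 30 taxa selected
#> Explained variance: FPCA1 95.0%, FPCA2 4.7%
#> Mean distance from baseline: 1.416 +/- 0.194 (n = 60)
```

Ten of the thirty genera carry 90 % of the compositional variance; the
twelve trajectories are dominated by a single mode of variation (95 % of
the variability), with a second mode adding another 4.7 %. Components and
scores are ordinary tibbles:

```r
tidy(res$fpca)
#> # A tibble: 2 × 4
#>   component eigenvalue explained_fraction cumulative
#> 1 FPCA1          53.3              0.950       0.950
#> 2 FPCA2           2.63             0.0468      0.997

score_group_summary(res$scores)
#> # A tibble: 4 × 5
#>   condition score    mean    sd     n
#> 1 atv       FPCA1  1.72    7.03     6
#> 2 atv       FPCA2  0.0224  1.75     6
#> 3 wheel     FPCA1 -1.72    7.79     6
#> 4 wheel     FPCA2 -0.0224  1.65     6

dplyr::filter(res$outlier_flags, outlier)
#> # A tibble: 2 × 6
#>   subject_id condition FPCA1 FPCA2 depth outlier
#> 1 subj_01    wheel     -3.23 -2.57     1 TRUE
#> 2 subj_03    atv       10.8  -3.17     1 TRUE
```

Mean ATV-bout scores sit above the wheel-bout scores on FPCA1 (a stronger
average displacement), and two trajectories fall outside the bagplot fence.
`plot_trajectories()`, `plot_group_mean()`, and `autoplot()` on the FPCA
and bagplot objects draw the standard figures; a thin command-line wrapper
over the same functions is installed at `inst/cli/mbresil.R`.

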