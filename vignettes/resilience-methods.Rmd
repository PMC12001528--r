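---
title: "Measuring microbiome resilience with mbresil: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring microbiome resilience with mbresil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbresil)
```

## The problem

A longitudinal microbiome study observes each subject's community at a
baseline and a handful of timepoints after a perturbation. "Resilience" has
two faces — how far the community is displaced, and how it returns — and
single-number indices (a slope, an area under the curve, a time to
recovery) must pick one of them in advance. `mbresil` instead summarises
each trajectory by the first two scores of a functional principal component
analysis (FPCA) of the whole family of curves, letting the data decide
which modes of variation matter.

This vignette documents the statistical model, every tunable parameter that
matters, the synthetic data used for validation, and the numerical and
design decisions behind the implementation.

## Compositional preliminaries

Sequencing abundances are compositional: only relative information is
meaningful. All analyses therefore work on closed rows (parts summing
to 1) and log-ratio transforms. The centred log-ratio (CLR) of a strictly
positive composition $u$ is $\mathrm{clr}(u)_k = \log(u_k/g(u))$ with
$g(u)$ the geometric mean, and the Aitchison distance between two
compositions is the Euclidean distance of their CLRs:

$$d(u,v)=\Big[\sum_{k=1}^{D}\big(\log\tfrac{u_k}{g(u)}-\log\tfrac{v_k}{g(v)}\big)^2\Big]^{1/2}.$$

This is a true metric, invariant to rescaling of either vector and
equivariant under permutation of parts, and — unlike, say, Jensen–Shannon
divergence — consistent under taxon subsetting, which matters because the
pipeline selects taxa before computing trajectories. Natural logarithms are
used everywhere; a different base would rescale all distances, scores and
eigenvalues by a constant without changing any ranking or fraction.

**Zero replacement.** The CLR requires positive parts. The default is
multiplicative replacement: in a closed row with $z$ zeros, each zero
becomes $\delta$ and the nonzero parts are multiplied by $1-z\delta$, so
the row stays closed and ratios among observed parts are untouched.
`delta = "auto"` uses $0.65\times$ the smallest nonzero proportion in the
table, a widely used convention that keeps imputed values strictly below
anything observed; an explicit $\delta$ must satisfy $z\delta<1$ for every
row, otherwise the row would lose all observed mass and the call errors. A
`bayes_multiplicative` option implements a geometric Bayesian-multiplicative
rule for count tables under a uniform prior (one pseudo-count per taxon): a
zero cell in a row totalling $n_i$ reads becomes $1/(n_i+D)$ of the row.
Published zero-replacement implementations differ in prior and strength;
exact parity with any particular one is not claimed, and the deterministic
multiplicative rule is the default because it is transparent and testable
by hand.

## Log-ratio analysis and taxon selection

Genus tables are wide and extremely sparse, and most taxa carry almost no
compositional variation. Log-ratio analysis (LRA) is the weighted PCA of
the log-composition matrix with uniform row weights $r_i = 1/n$ and the
mean closed abundance of each taxon as its column weight $c_j$. The
implementation fixes the double-centring order: rows are centred against
the column weights (a weighted CLR), then columns against the row weights,
giving $y_{ij}$; the total variance is $\sum_{ij} r_i c_j y_{ij}^2$ and
taxon $j$'s contribution is its column share of that sum. This definition
satisfies the classical identity that the total equals a $c$-weighted
average of all pairwise log-ratio variances
$\tfrac12\sum_{j,k}c_jc_k\,\mathrm{Var}(\log(p_j/p_k))$, which the test
suite verifies against a brute-force computation; contributions are also
invariant to rescaling any sample row before closure.

`select_taxa()` ranks taxa by decreasing contribution (ties broken
alphabetically, for determinism) and keeps the shortest prefix whose
cumulative contribution reaches the threshold (default **0.90**). Because
contributions measure variance share rather than mean abundance, rare but
dynamic taxa can be selected. Selection can be applied per condition or
pooled simply by slicing the input table before fitting; the pipeline pools
by default, matching a design where all conditions are scored in one common
plane. After selection, rows are re-closed on the chosen subcomposition.

## Trajectories

For each subject × condition, `build_trajectories()` computes the Aitchison
distance between every timepoint and a baseline. Two baseline modes exist:
the per-group flagged baseline (default; exactly one flag per group is
enforced) and a single fixed sample shared by all trajectories, which is
how long-term drift of the baseline state itself can be measured.
Decisions worth knowing:

* `include_t0 = TRUE` (default) prepends the baseline point itself at its
  own time with distance 0. Anchoring every curve at zero pins the
  functional mean at the start of the grid; it is toggleable because a
  family could equally be analysed from the first post-perturbation
  sample onward.
* The "immediately post-perturbation" sample needs a numeric hour for the
  grid; study metadata should assign it one (the bundled generator uses
  0.5 h, on the scale of a short exercise bout).
* Missing data: a wholly absent subject × condition is simply absent. A
  group missing individual grid points is, by `complete_trajectories()`,
  either dropped (default) or linearly interpolated from its observed
  points; extrapolation beyond a group's observed range is never done — a
  group missing a grid endpoint is dropped under either policy.
* Group summaries use the sample standard deviation ($n-1$) over
  $\sqrt{n}$; with $n=1$ the standard error is reported as `NA`, not 0.

## Functional PCA on a short, irregular grid

With only ~6 timepoints, basis smoothing is underdetermined, so FPCA is
computed directly on the observed grid as a quadrature-weighted PCA with no
pre-smoothing. Writing $W=\mathrm{diag}(w)$ for the quadrature weights, the
sample covariance $C(s,t)$ (denominator $n-1$) is symmetrised as
$W^{1/2}CW^{1/2}$ and eigen-decomposed; eigenvectors map back through
$W^{-1/2}$ so eigenfunctions are orthonormal under
$\langle f,g\rangle_w=\sum_t w_tf(t)g(t)$, and scores are the quadrature
form of the integral $\xi_k=\int(X_i-\mu)\phi_k$. Consequences verified in
the tests: the eigenvalue total equals the weighted covariance trace;
reconstruction from all components reproduces the fitting curves to
$10^{-8}$; and with uniform weights ($w_t\equiv1$) the fit coincides
exactly with ordinary matrix PCA, which serves as an oracle.

Parameters and conventions:

* **Weights** (default `"trapezoid"`): trapezoid-rule weights respect the
  irregular spacing (0, 0.5, 3, 6, 24, 48 h) so that the dense early
  window does not dominate the integral; `"uniform"` is available for
  exact PCA equivalence. Grids with fewer than 3 points fall back to
  uniform.
* **K** (default 2): the number of retained components, at most
  $\min(n-1, m)$. Two scores are the point of the method — a
  magnitude-like mode and a recovery-timing mode — and explained
  fractions are always reported so the adequacy of $K=2$ is visible.
* **Sign convention**: eigenfunction signs are arbitrary in principle, so
  they are fixed by $\sum_t w_t\phi_k(t)\ge 0$ (first nonzero element
  positive in the zero-sum tie case). Statements like "more resilient
  trajectories have low first scores" are only reproducible under a fixed
  convention.
* Eigenvalues are clipped at zero (they can go microscopically negative in
  floating point) and explained fractions are eigenvalue shares of the
  total trace.

`simulate_family()` renders $\mu + a\phi_1 + b\phi_2$ over a Cartesian
grid of $(a,b)$ values; projecting those curves back through
`fpca_scores()` returns the generating grid to $10^{-8}$, a round-trip
identity the acceptance tests exercise. `score_distance_correlation()`
reports the Pearson correlation between each score and the distance at
each timepoint — the diagnostic that justifies reading score 1 as overall
displacement when it correlates positively with distance everywhere.

## Bagplot outliers

Atypical trajectories are flagged on the $(\xi_1,\xi_2)$ plane with a
bagplot, the bivariate boxplot. Tukey halfspace depth — the minimum number
of points in any closed halfplane through a query point — is computed
*exactly* by an angular sweep (the count only changes when the boundary
rotates past a data point), verified against a 3600-direction brute-force
oracle. The depth median is the centroid of the deepest points; the bag is
the convex hull of the $\lceil n/2\rceil$ deepest points, with depth ties
at the cut resolved by distance to the median (exact ties included); the
fence inflates the bag by a factor of **3** about the depth median, the
conventional bagplot constant; points strictly outside the fence are
outliers. The bag is built from the deepest half of the points rather than
interpolated depth contours — simpler, deterministic, and adequate at the
tens-of-trajectories scale this method targets; at least 10 points and a
genuinely two-dimensional configuration are required. Published bagplot
implementations vary in fence factor and tie policy, so exact parity of
outlier sets with any of them is not claimed.

## The synthetic-study generator

`generate_study()` emulates the data the pipeline is designed for, with
known ground truth. Defaults describe a 15-subject, 3-condition,
6-timepoint design (0, 0.5, 3, 6, 24, 48 h) over 100 taxa:

* **Baselines**: each subject's baseline CLR vector is a shared
  heavy-tailed taxon profile ($\sigma=2$ across taxa, giving a few
  dominant and many rare genera) plus subject-specific offsets
  ($\sigma=0.5$).
* **Shock**: per condition, a sparse direction over `shock_direction_dim`
  = 10 taxa, centred and scaled to unit CLR norm so that a trajectory's
  true magnitude *is* its peak Aitchison distance. Per trajectory, a
  magnitude $|N(8, 4^2)|$ in CLR units (peak distances ~4–16, the scale
  seen in real exercise trajectories) rises linearly from 0 to its peak
  at 4.5 h — the centre of the empirically observed 3–6 h peak window —
  and decays exponentially with halflife $N(12, 3^2)$ h truncated at
  0.5 h, so recovery is mostly complete by 24–48 h. The magnitude spread
  is deliberately the dominant source of between-trajectory variation:
  that is the regime in which a first FPCA score is interpretable as
  impact, and it makes the generator's rank-recovery property
  (|Spearman| ≥ 0.8 between true magnitude and the first score at
  $n=60$, noise off) hold robustly rather than marginally.
* **Noise**: optional multinomial resampling at `sequencing_depth` reads,
  and optional zeroing of the globally smallest cells (never a row's
  maximum) to hit `sparsity_zeros_frac` (default 0.6) zero cells.
* Identical configurations and seeds yield bit-identical studies.

What the generator does **not** emulate: taxon–taxon correlation beyond the
shared shock direction, overdispersion beyond multinomial, fecal-versus-
swab sample-type effects, baseline drift between conditions, and seasonal
structure. Passing tests on synthetic data therefore demonstrate the
correctness and calibration of the algorithms under the generative model,
not biological validity on any particular real dataset.

## Pipeline, reproducibility, and problem sizes

`run_pipeline()` chains zero replacement → LRA → selection → re-closure →
trajectories → FPCA → correlations → outlier flags, re-raising any failure
with its stage name. Artifacts are written as long-format CSV (tolerant of
missing timepoints) with numerics at 9 significant digits, plus the FPCA
model as JSON and a manifest carrying the package version, full
configuration and its hash, and record counts — identical inputs and
configuration reproduce every file byte for byte. Outlier flagging needs at
least `bagplot_min_n = 10` trajectories and $K\ge2$; below that, flags are
reported as `NA` rather than inventing a bag from too few points.

The validation suite sizes its experiments to be decisive yet quick: the
distance oracle runs 100 random pairs at $D=10$ and 1000 metric triples;
the LRA identity 50 random 20×15 tables; FPCA recovery 20 replicates of
200 curves on the 6-point grid with score variances (4, 1), realised
exactly in each sample so the expected explained fractions (0.8, 0.2) are
sharp; depth checks run clouds up to $n=500$; the end-to-end recovery
experiment uses 60 subjects. The whole suite completes in well under a
minute on a single core.

## Known limitations

* FPCA here is the fixed-grid, no-smoothing variant: trajectories must
  share the common grid after the missing-data policy, and sparse or
  highly irregular designs (where PACE-style covariance smoothing is the
  standard remedy) are out of scope.
* With ~6 grid points, at most 6 eigenfunctions exist and the trapezoid
  quadrature is coarse; scores are best read comparatively, within one
  fitted family.
* Taxon selection is dataset-specific; selected lists will differ between
  datasets and should not be read as a universal signature.
* The bagplot flags score-plane outliers only; a trajectory can be odd in
  ways invisible to two scores.
* Distances to a baseline discard the direction of compositional change;
  two trajectories displaced oppositely by equal amounts look identical.
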