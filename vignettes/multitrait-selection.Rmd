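---
title: "Multitrait genotype evaluation and MGIDI selection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multitrait genotype evaluation and MGIDI selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mgidi)
```

This vignette is the package's account of the statistical machinery it
implements: the models, their assumptions, the tunable parameters and the
numerical choices. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The trial model

All analyses start from plot-level phenotypes of a randomized complete
block design (RCBD): `n` genotypes, each observed once in each of `r`
complete blocks, for `K` quantitative traits. Per trait,

$$Y_{ij} = \mu + G_i + B_j + \varepsilon_{ij},$$

with genotypes treated as fixed effects and blocks as a nuisance
stratum. `rcbd_anova()` fits this by least squares with sequential
(block-then-genotype) sums of squares; for balanced data this reduces to
the classical closed-form decomposition, and it degrades gracefully to the
general least-squares fit when plots are missing (a genotype seen in fewer
than two blocks triggers a warning and the residual degrees of freedom
adjust through the fit). Significance codes follow the usual mapping
(`***` < 0.001, `**` < 0.01, `*` < 0.05, `ns` otherwise).

Two degenerate cases are handled explicitly rather than left to floating
point: a constant response gives all-zero mean squares and is reported as
`ns` with `p = 1`; a perfectly additive table (zero residual MS with a
positive effect MS) is reported as `p = 0`. Zero is detected at a relative
tolerance of `1e-12` on the squared response scale.

## Variance components, heritability and coefficients of variation

Equating mean squares to their expectations in the balanced design gives

$$\hat\sigma^2_g = \max\!\left(0, \frac{MS_g - MS_e}{r}\right), \qquad
  \hat\sigma^2_p = \hat\sigma^2_g + MS_e.$$

Negative estimates are truncated at zero with a warning, the standard EMS
practice. Broad-sense heritability is

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_p / d}.$$

The divisor `d` deserves comment. The textbook convention uses the number
of replicates, but published trial reports in this crop literature are
frequently only reproducible with `d` equal to the number of genotypes;
the shipped worked examples reproduce all ten published heritabilities to
two decimals only under that convention. `heritability()` therefore takes
`d` as an explicit argument and `variance_summary()` defaults it to the
number of genotypes; pass `divisor = r` for the replicate convention.

Coefficients of variation are $\sqrt{v}/\bar x$ with `v` the genotypic
variance (GCV), phenotypic variance (PCV) or residual MS (experimental
CV). Classification bins follow the conventional scheme: GCV/PCV below
10% low, 10 to below 20% intermediate, 20% and above high; heritability
below 30% low, 30-60% intermediate, above 60% high. The published bin
edges overlap at 10% ("0-10" vs "10-20"); we resolve the boundary upward
(exactly 10% is intermediate, exactly 20% high, exactly 60% heritability
intermediate), matching the "greater than or equal to 20%" phrasing of
the high band.

Because $\sigma^2_p \ge \sigma^2_g$ by construction, `GCV <= PCV` holds
for every input — this is asserted as a test invariant.

## Trait structure: correlations, PCA, path analysis

Correlation, ordination, clustering and the selection index all operate on
**genotype means** over blocks, not plot values: genotype-level structure
is the quantity of interest, the means are the best linear summary under
the trial model, and with 42 genotypes the degrees of freedom of published
genotype-level analyses match this choice.

Significance of a Pearson correlation uses the exact t transform
$t = r\sqrt{(n-2)/(1-r^2)}$. PCA is an eigendecomposition of the trait
correlation matrix; loadings are reported correlation-scaled
(eigenvector $\times \sqrt{\lambda}$), so the squared loadings of one
trait sum to 1 over all components and each component's squared loadings
sum to its eigenvalue. Components are retained when $\lambda > 1$ strictly
(Kaiser rule; the threshold is an argument). Loading signs are whatever
the eigensolver returns — they are arbitrary up to a component-wise flip
and are deliberately not post-processed.

Path analysis solves the standardized normal equations
$R_{xx} b = r_{xy}$ for the direct effects, reports the indirect effect of
predictor $i$ via $j$ as $r_{ij} b_j$, and the residual effect as
$\sqrt{1 - b^\top r_{xy}}$. The identity "direct + sum of indirects =
total correlation" is algebraic and is asserted to `1e-9` in the tests. A
predictor correlation matrix with condition number above `1e8` is rejected
as collinear rather than silently inverted.

## Gower clustering

With all traits quantitative, the Gower coefficient reduces to the
range-normalized mean absolute difference,
$d(i,j) = K^{-1}\sum_t |x_{it}-x_{jt}|/\text{range}_t \in [0,1]$.
Zero-range traits carry no information and are dropped with a warning.
The implementation is checked in the tests both against a brute-force loop
and against `cluster::daisy` as an independent reference.

The number of clusters is chosen by scanning `k = 2..min(10, n-1)` and
maximising the mean silhouette width of the cut hierarchical tree, ties
going to the smallest `k`. Linkage defaults to UPGMA (average), the common
default for Gower matrices; single, complete and Ward (on squared
dissimilarities) are available. Cut labels are relabeled so cluster 1 is
the largest — a deterministic convention that makes outputs stable across
input orderings.

Per-cluster summaries report trait means of cluster members and an LSD at
the 5% level, $t_{0.975,\,df_e}\sqrt{2\,MS_e/\tilde n}$, with $\tilde n$
the harmonic mean of cluster sizes times the block count. The error term
for the LSD is not uniquely determined by the published tables; we use the
pooled residual MS of the per-trait RCBD fits and record that choice in
the output metadata. The significance flag per trait comes from a one-way
ANOVA of genotype means across clusters at the 0.001 level, matching the
dichotomous flags of published cluster tables.

## The MGIDI index

Four steps:

1. **Rescaling.** Each trait is mapped linearly onto `[0, 100]` so that
   100 is the desired extreme: max maps to 100 for increase-sense traits
   and to 0 for decrease-sense traits. The published formula for this step
   is typographically garbled; it is implemented as the standard linear
   range transform the accompanying text describes. The map is monotone,
   so per-trait rankings are preserved (reversed for decrease-sense), and
   the correlation structure is preserved up to sign flips of
   decrease-sense columns — both asserted as invariants.
2. **Factor analysis.** Initial loadings are the correlation-scaled
   eigenvectors of the rescaled-trait correlation matrix for factors with
   eigenvalue above 1 (at least one factor is always kept), followed by a
   varimax rotation with Kaiser normalization. Varimax is the canonical
   choice for MGIDI-style simple structure; rotation preserves
   communalities, which the tests assert to `1e-9`. Factor scores use the
   regression method, $S = Z R^{-1} \Lambda$, the standard choice
   consistent with distance-in-score-space semantics. A singular `R` is
   ridge-stabilized (`1e-8` on the diagonal) with a warning.
3. **Ideotype.** The ideotype is the all-100 rescaled row — by
   construction of the senses, the best observed value in every trait —
   scored with exactly the same standardization and transform as the
   genotypes.
4. **Distance and selection.** MGIDI is the Euclidean distance between a
   genotype's factor scores and the ideotype's. Genotypes are ranked
   ascending and `round(alpha/100 * n)` (at least one) are selected; ties
   break by genotype ID. The default `alpha = 15`% is chosen because at
   `n = 42` it retains six genotypes, the selection size of the
   evaluation this package's demonstration emulates; it is an explicit
   argument everywhere.

Predicted gains per trait are $SG\% = (\bar X_s - \bar X_o)/\bar X_o
\cdot H^2 \cdot 100$ on original trait units, with totals split by sense;
selecting all genotypes gives zero gain for every trait (asserted).
Strength/weakness profiles split each genotype's squared distance across
factors; the proportions sum to one, and `1/m` is the reference value of
equal factor contribution. A genotype exactly at the ideotype has
undefined proportions and is reported uniform with a flag.

MGIDI is invariant to genotype input order and to any orthogonal
re-rotation applied consistently to scores and ideotype (distance is
rotation-equivariant); the order invariance is tested directly.

## The synthetic trial generator

`simulate_trial()` draws
$Y_{ijt} = \mu_t + g_{it} + b_{jt} + e_{ijt}$ with
$g_i \sim MVN(0, \Sigma_g)$, $b_{jt} \sim N(0, sd_{b,t}^2)$ and
$e_{ij} \sim MVN(0, \Sigma_e)$. Genotype effects are drawn once per trial
and then treated as fixed — matching the fixed-genotype analysis model —
while the MVN draw makes the covariance structure controllable; recovery
tests can condition on the realized effects, which are attached to the
returned table. Identical configurations reproduce byte-identical data.

The shipped demonstration configuration (`demo_trial_config()`) emulates a
published 42-genotype x 3-block tiger nut evaluation: trait means and
residual variances from the trial's published summary statistics,
genotypic variances from its published variance components (the implied
heritabilities at divisor 42 span roughly 0.84-0.98), block variances
backed out of the published block mean squares, and a genetic correlation
matrix encoding the published sign pattern of trait associations at
moderate magnitudes (0.45-0.6 for strongly starred pairs, 0.1 baseline),
eigenvalue-clipped to the nearest valid correlation matrix. These values
were fixed once from the published tables and are not tuning knobs.

What the generator does **not** emulate: spatial field trends,
genotype-by-environment structure, categorical traits, non-normal errors,
and bounded traits (values are not clipped by default, because clipping
percentages to `[0, 100]` would bias variance recovery; an optional
`clip_range` exists for realism demonstrations). Consequently, passing
recovery tests show that the estimators are correct *under the stated
model*, not that the model captures every feature of real field data. And
because the source trial's raw plot data were never deposited, synthetic
checks cannot certify its genotype-level results (cluster memberships,
exact loadings) — only the published quantities that are deterministic
functions of other published quantities are reproduced exactly.

## Numerical choices and degenerate inputs

* Covariance square roots use the symmetric eigendecomposition with small
  negative eigenvalues (within `1e-8` relative) clipped to zero; genuinely
  indefinite matrices are rejected with the offending matrix named.
* Constructed correlation matrices are made valid by eigenvalue clipping
  at `1e-6` followed by renormalization to unit diagonal.
* Negative EMS components truncate at zero with a warning; `H2` is
  clamped to `[0, 1]`; zero-over-zero heritability is `NA` with a warning.
* Ties: silhouette scan takes the smallest `k`; selection breaks index
  ties by genotype ID; cluster relabeling orders by size then first
  appearance. All outputs are therefore deterministic for a given input.
* The balanced-ANOVA identity `SS_total = SS_block + SS_genotype +
  SS_residual` is asserted at relative tolerance `1e-9`.

## Validation problem sizes

The test suite validates stochastic behavior at sizes chosen to make
Monte-Carlo error small relative to the tolerances while keeping the suite
fast: variance-component recovery uses 50 replicates of 200-genotype,
3-block trials (the mean estimate must sit within 3 Monte-Carlo standard
errors of the generating value); permutation concordance for correlation
significance uses 10,000 shuffles over all 45 trait pairs of a 42-genotype
demonstration trial; the ANOVA F-test is checked against a 4,000-shuffle
within-block permutation; planted-partition recovery uses the 9/31/2
cluster sizes of the emulated trial plus 100 seeded silhouette scans; and
planted-ideotype recovery runs 50 seeded trials. These sizes are the
package's own validation design.

## Known limitations

* Only the fixed-genotype, random-block least-squares model is provided:
  no REML/mixed-model machinery, no spatial correction, no
  multi-environment analysis.
* Gower support covers quantitative traits only.
* A second-stage factor analysis restricted to the selected subset is
  possible by re-running `mgidi()` on the subset's means, but no
  convention is imposed for comparing loadings across such refits.
* Alternative selection indices (Smith-Hazel, FAI-BLUP) are out of scope.
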