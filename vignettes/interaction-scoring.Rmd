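---
title: "Scoring genetic interactions in matrix co-RNAi screens"
author: "crisscross"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring genetic interactions in matrix co-RNAi screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisscross)
```

## The measurement and the model

A matrix combinatorial-RNAi screen measures one number per well — here a
viability proxy such as ATP luminescence after several days of double
knockdown — for every unordered pair of reagents in a panel. Phenotypes of
non-interacting perturbations combine multiplicatively on the raw scale
when growth is exponential: if perturbations scale the growth rate as
`n(t) = n0 exp((1 + m1 x1 + m2 x2) k t)`, then the log phenotype relative
to the unperturbed culture is exactly `(m1 x1 + m2 x2) k t`. This is why
the package models **log2 readouts** and why `grow()` satisfies log-scale
additivity to machine precision for all parameter values. An interaction is
a deviation from that additive expectation:

    y_ijk = y0_k + m_ik + m_jk + w_ij + eps_ijk .

`neutrality_gap()` quantifies how this additive definition differs from the
multiplicative convention built on relative growth rates (`rho = 1 + m`
under exponential growth, see `relative_growth_rate()`): the two neutral
predictions differ by exactly `m1 * m2`, negligible for weak perturbations
(0.01 at `m1 = m2 = 0.1`) but substantial for strong ones. The additive
log-scale definition also stays interpretable when a perturbation makes the
net growth rate negative.

## Plate normalization by the shorth

Plates carry multiplicative offsets (incubation, reagent batches, reader
drift). Each plate's log2 values are centered by the **midpoint of the
shorth** of its co-RNAi wells: sort the values, slide a window containing
`ceiling(n/2)` of them, take the window(s) of minimal range, and return the
mean of their interval midpoints `(min + max)/2`. The shorth midpoint
estimates the mode, so it tracks the bulk of (mostly non-interacting) pair
wells and is insensitive to the tail of strong phenotypes and to outliers;
control wells are excluded from the estimate but centered with the same
coefficient. Ties between windows of equal range are resolved by averaging
midpoints, which keeps the estimator symmetric on symmetric samples. Both
the interval midpoint (default) and the mean of the in-window values are
implemented (`method` argument); the literal reading of "midpoint" is the
interval center, and the two behave almost identically here.

A property worth knowing: shortest-half estimators converge slowly
(at rate n^(-1/3)) and can flip between competing windows, so at ~240
sample wells per plate the plate center carries a sampling jitter of
roughly 0.08–0.1 log2 units under the benchmark noise model — an order of
magnitude more than a plate mean. The consequences for testing are
discussed below.

## Fitting baselines and main effects

Within every replicate group k, the package minimizes the squared pair-mean
residuals — equivalently, ordinary least squares of the group's co-RNAi
wells on {baseline + indicator_i + indicator_j} — under the identifiability
constraint `sum_i m_ik = 0`, implemented through the sum-contrast
reparameterisation rather than post-hoc centering. The constraint choice
does not affect the interaction scores. By default one parameter set is
fitted per **biological** replicate (32 free parameters for 16 reagents in
2 biological replicates, `count_parameters(16, 2)`), absorbing
batch-to-batch variation in seeding, incubation and transfection; `pooled`
(16 parameters) and `technical` (320) parameterisations are available.
Control and self-pair wells never enter the fit: the criterion uses only
co-RNAi wells, which provides many more observations than the control
wells, and single-gene controls are reserved for quality control
comparison.

Two properties of this criterion matter for interpretation:

* **It is conservative.** Because main effects are free to explain as much
  variation as possible, part of every true interaction is absorbed by
  them: for a single interacting pair among N = 16 reagents the expected
  score is exactly 104/120 of the true effect, and reagents carrying
  several interactions shrink more. This is the intended behaviour — it
  errs on the side of calling fewer, better-supported interactions — but it
  means planted-truth recovery is unbiased only when interactions are rare
  and it motivates planting benchmark interactions on disjoint pairs (see
  `default_benchmark_config()`).
* **Robust variants** (L1, Huber with c = 1.345, least-trimmed squares
  retaining 75% of pair-group cells) are provided for screens where
  interactions are not rare or some are very large; they are solved by
  iteratively reweighted least squares (convergence when the largest
  parameter change is below 1e-8, at most 200 iterations, with a warning
  and a flag on non-convergence). On clean additive data all losses agree
  with least squares.

Interaction scores are residual means over all measurements of a pair
(`estimate_interactions()`), with per-pair replicate counts recorded for
the degrees of freedom downstream. `fit_diagnostic_trend()` estimates the
local mean of the residuals against the predicted no-interaction value by
loess (span 0.5, 100 grid points); trends there indicate scale or model
misspecification.

## Testing

Per pair, the **ordinary t** uses `t = w / (s / sqrt(K))` with `K - 1`
degrees of freedom on the residuals; the per-pair variance ignores the
(design-dependent, small) uncertainty of the fitted main effects. The
**moderated t** shrinks each pair's variance toward a prior,
`s2_post = (d0 s0^2 + d s^2)/(d0 + d)`, with the prior fitted across pairs
by moment matching of `log s^2` via digamma/trigamma equations of the
scaled-F model from the microarray moderated-t literature. When the
dispersion of the log variances is at or below its theoretical minimum the
prior is degenerate (`d0 = Inf`) and the pooled variance is the
bias-corrected log-scale pool `exp(mean(log s^2 - digamma(d/2) + log(d/2)))`
— the raw geometric mean would underestimate the variance severely at
small df (by a factor of ~0.69 at d = 3) and inflate every statistic. The
two analytic limits are exact: `d0 = 0` reproduces the ordinary t, and
`d0 = Inf` with equal K makes the statistic proportional to the effect
size. Tests are two-sided (interactions of both signs are real), and
Benjamini–Hochberg adjustment is applied across all scored pairs once per
test type.

**Error control and parameterisation.** The plate-center jitter described
above cancels out of the interaction scores (it is absorbed, on average, by
the group baseline) but it inflates each pair's *within-pair* standard
deviation whenever one baseline is shared across several plates. Under the
biological parameterisation the residual t-tests are therefore
**conservative** on null data (empirical type-I error ~0.006 at nominal
0.05 under the benchmark conditions) — valid but not exact. Under the
fully parameterised technical model, where each plate-occurrence has its
own baseline and the centering error is absorbed exactly, both tests run at
their nominal level (measured 0.046/0.049 on 2040 null pair-tests). The
package's calibration checks use the technical parameterisation for this
reason; users who need calibrated p-values with few replicates should be
aware of this trade-off, which is precisely the parameterisation choice
discussed with the model above.

**False-null estimation.** `schweder_spjotvoll()` plots `(1 - p, N(p))`
(`N(p)` = number of p-values exceeding p) and fits a line through the graph
values at x = 0 and x = 0.5 exactly — no regression over a range — whose
value at x = 1 estimates the number of true nulls; the false-null estimate
`m - (2 N(0.5) - N(1))` is floored at zero. The estimate is accurate when
non-null p-values concentrate below 0.5 and null p-values are uniform; the
conservative fit criterion slightly violates the latter when the planted
interaction mass is large (main effects absorb interaction signal and shift
null residuals), which is why the scalability benchmark
(`scalability_config()`) plants its 472 non-null effects just above the
4-standard-error detectability floor.

**Method benchmarking.** `build_benchmark_reference()` declares pairs with
full-data ordinary-t p < 0.001 positive and everything else negative — an
imperfect reference, but sufficient for *comparing* rankings as long as it
is enriched for truth (pseudo-ROC logic). `benchmark_roc()` re-analyses
plate subsets self-contained (fit, prior and tests recomputed per subset;
the alternative of reusing full-data main effects is noted but not used),
sweeps thresholds to one ROC curve per subset, and averages curves
vertically on a common 101-point FPR grid. On two technical replicates the
variance is near-constant across pairs, so the moderated t is nearly
equivalent to the effect size and both beat the ordinary t (whose single
degree of freedom is hopeless); with biological replicates and
gene-pair-dependent variance the moderated t also beats the raw effect
size. The simulator exposes both regimes (`sigma_w_bio`, `var_prior`).

## Networks

`profile_correlation()` correlates rows of the interaction matrix
(Spearman by default; Pearson available). The two columns indexed by the
pair itself are excluded — the diagonal is undefined and the mutual entry
would inject the pair's own score into its similarity (standard E-MAP
practice; switchable via `exclude_mutual`). `interaction_graph()` draws an
edge when the FDR-adjusted p-value is below 0.1 **and** |w| exceeds 0.3
log2 units — the effect-size cutoff guards against the many statistically
significant but tiny effects that high replication produces —
and `correlation_graph()` uses |c| > 0.8 (strict). Genes whose profiles
are generated by a shared complex form cliques in the correlation graph.

## The simulator and what passing tests mean

`simulate_screen()` draws data exactly from the model above: the
criss-cross layout (16 rows × 24 columns, positive controls in column 7
and negative controls in column 14 by default — the negative-control
placement is the package's choice, as is one of the two control columns'
polarity; real screens may place both positive columns), log2-additive
baselines and main effects, a sparse symmetric planted interaction matrix,
per-plate offsets Uniform(−0.5, 0.5), Gaussian log-scale noise (sd 0.1 by
default), biological-replicate heterogeneity as sd-0.05 perturbations of
baselines and main effects, and controls 4 log2 units apart with sd 0.1
(implying Z′ ≈ 0.85). Main effects are drawn Uniform(−1, 1) and centered,
giving the ~2-log2-unit dynamic range typical of viability panels.
Technical-replicate labels encode plate × symmetric occurrence, so the
benchmark design has 10 technical replicates per biological replicate and
20 measurements per pair. Optional knobs create gene-pair-dependent
variance (`var_prior`, a scaled inverse-chi-square draw per pair) and
per-biological-replicate interaction jitter (`sigma_w_bio`).

What the simulator does **not** emulate: spatial (row/column/edge)
artifacts — the analysis deliberately contains no spatial correction, so
simulated passing says nothing about plates that need one; reagent
off-target effects and knockdown-efficiency differences (reagent = gene
here); saturating or lagged growth (the logistic case appears only in the
relative-growth-rate tests); and non-Gaussian heavy-tailed readout noise
beyond what the robust losses are tested with. Recovery and calibration
results on simulated screens are therefore statements about the method
under its own assumptions, not about any particular laboratory's data.

Problem sizes used by the packaged checks: the benchmark screen is the
full 16-reagent design (2720 wells); recovery statistics use 200 seeded
screens; ranking comparisons 100 seeds × (10 single-plate + 5 paired-plate)
subsets; the scalability study 100 seeds of an 84-reagent, 2-plate virtual
design (3486 pairs, ~14k wells each). All stochastic tests fix their seeds.

## Numerical choices and degenerate inputs

* Shorth window `h = ceiling(n/2)`; range ties within a relative tolerance
  of `sqrt(.Machine$double.eps)` are averaged; single values are their own
  shorth; non-finite values are excluded with a warning.
* Zero within-pair variance yields a degenerate-flagged test (p = 0 for a
  nonzero effect, p = 1 otherwise); pairs with fewer than 2 measurements
  are untestable (`NA`) but still receive a moderated statistic through the
  prior when one exists.
* The trigamma inverse is solved by Newton iteration (relative tolerance
  1e-12) with asymptotic branches at both extremes.
* Missing wells simply reduce a pair's K; a reagent must appear in at
  least two distinct pairs per group or the fit aborts with a
  rank-deficiency error naming it.
* Pairs are keyed by the lexicographically sorted reagent-id tuple
  throughout, so all outputs are invariant to the stored orientation of a
  well's reagent pair.

## Known limitations

The estimator's conservativeness (above) biases strong interactions toward
zero by a design-dependent factor; no correction is applied because the
bias direction is the method's stated intent. P-values under the default
biological parameterisation are conservative in the presence of plate-center
jitter. The false-null estimate inherits both effects at high interaction
density. Joint sparse (LASSO-type) interaction regression and Bayesian
alternatives are out of scope, as are vendor file formats, spatial polish
corrections, and any genome-annotation overlay.
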