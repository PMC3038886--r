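---
title: "Confident predictability: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confident predictability: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localminimax)
```

This vignette records how the method works, why the defaults are what
they are, what the synthetic generators do and do not emulate, and the
numerical decisions made where the design was genuinely open. It states
no empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## The model

We classify patients into normal (0) versus cancer (1) from expression
intensities. The pipeline has two stages.

**Stage 1 — k-TSP features.** For genes $(i, j)$ let $p_c$ be the
fraction of class-$c$ training samples with $g_i < g_j$ (ties count as
"not less": the event is a strict inequality). The pair score is
$\Delta = |p_0 - p_1|$; exact ties are broken by the rank score
$\Gamma$ — each gene's intensities are replaced by their ranks across
the $N$ patients (average ranks on ties) and $\Gamma$ is the absolute
between-class difference of the mean rank difference — then
lexicographically by gene id, which makes the selection a deterministic
function of the data. A greedy scan of the sorted pair list takes the
top $k$ pairs subject to gene disjointness. Because both $\Delta$ and
$\Gamma$ see only orderings, the whole selection is invariant under any
strictly increasing per-gene transformation — the property that makes
TSP-style rules robust to normalization choices.

**Stage 2 — local minimax estimation.** Each sample becomes the
$k$-vector of within-pair differences. Around a query $x_0$ we assume
the true conditional probability $f$ can be written on a ball $V$ as
$f = \alpha + (1-\alpha) f_1 - \alpha f_2$, with each $f_l$ a positive,
(0,1)-bounded finite sum of Gaussian kernels centered in $V$ —
a smoothness assumption whose strength scales with the bandwidth
$\sigma$. Over that class, and over all noise with variance at most
$1/4$ (Bernoulli labels satisfy this), the affine estimator
$F(w) = w^* + \sum_j w_j Y_j$ minimizing the worst-case MSE at $x_0$
has a closed form: a kernel ridge solve
$w = (K + \gamma I)^{-1} k$ with $\gamma = (0.5 / M_V)^2$ over the $i$
nearest training points, offset $w^* = \alpha(1 - \sum_j w_j)$, and
bound $\pounds_i = M_V^2 (1 - k^\top w)$, where
$M_V = \sqrt{\alpha^2 + (1-\alpha)^2}\, e^{r_i^2 / 4\sigma^2}$ bounds
the kernel norm of $f - \alpha$ on the ball of radius $r_i$. The
neighborhood size $i^\ast$ is chosen to minimize $\pounds_i$ by
exhaustive scan over $i = 1..N$ ($\pounds_i$ is not assumed unimodal;
ties go to the smallest $i$). One-sided level-$(1-\beta)$ intervals are
$F \pm \rho\sqrt{1 + z_\beta^2}$ with $\rho = \sqrt{\pounds_{i^\ast}}$;
the extra $\sqrt{1+z^2}$ (relative to the usual $z$) accounts for the
estimator's unknown bias within the class.

Two facts drive the package's architecture and tests. First, the same
estimator arises from two algebraically identical routes: the
$(i{+}1)\times(i{+}1)$ inverse of $\sigma^* + M^2 K^*$ (kept as
`tikhonov_fit_direct()`, the test oracle) and the $i\times i$ ridge
solve (`tikhonov_fit()`, the production path — a linear solve, never an
explicit inverse). Second, $w$, $\pounds$, $i^\ast$ and hence all
interval *widths* depend only on the predictor geometry, never on the
labels; this is what keeps the intervals approximately valid even
though feature selection reused the training labels, and it is asserted
exactly in the suite.

### On the exponent in $M_V$

The smoothness bound must satisfy
$M_V \ge \sup \lVert f - \alpha \rVert$ over the model class. Writing
$f_1 = \sum a_i K(z_i, \cdot)$ with $f_1 < 1$ on $V$ and
$c = \max_{x \in V} \min_{y \in V} K(y, x)$, one gets
$\lVert f_1 \rVert^2 = \sum_i a_i f_1(z_i) \le \sum_i a_i \le 1/c$,
so the max–min kernel factor enters with exponent $-1/2$ — any
non-negative exponent would make $M_V$ bounded by
$\sqrt{\alpha^2+(1-\alpha)^2} \le 1$ and *decreasing* in the ball
radius, which cannot dominate a supremum that grows as the ball grows.
For a Gaussian kernel on a ball of radius $r$ the max–min has the
closed form $c = e^{-r^2/2\sigma^2}$ (the inner max is attained at the
center, the inner min at the antipodal boundary point); the test suite
verifies this by grid search rather than assuming it.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `k` | 10 | pairs | interpretable signature size; small enough that each pair can be read as a biomarker rule |
| `sigma_fraction` | 0.5 | fraction of the query-to-furthest distance | reference setting; 0.7 is the common alternative. Cross-validating $\sigma$ is deliberately avoided — it would replace local analysis by a global average |
| `alpha` | 0.5 | — | minimizes $\sqrt{\alpha^2+(1-\alpha)^2}$, i.e. the tightest bound; encodes a neutral prior constant |
| `beta` | 0.10 | — | one-sided 90% intervals |
| `p_threshold` | 0.35 | probability | a CP call asserts the true probability lies in `[0, 0.35]` or `[0.65, 1]` with 90% confidence; smaller = stricter triage |
| `adjustment_e` | 0 | probability | expected label-reuse correction: labels enter the *reported* estimate as $e + (1-2e)Y$. Affects neither class calls nor widths; 0.05 is a conservative alternative |

`sigma_sweep()` / `cohort_sigma_sweep()` scan fractions 0.2–1.4; the
suggested lower limit is the distance to the $\lceil N/5\rceil$-th
closest training point divided by the distance to the furthest
(ceiling chosen as the rounding rule — no rule was stated).

## Synthetic data: what it emulates, what it does not

**Planted-pair cohorts** (`generate_cohort()`) emulate the input the
method was designed for: a handful of gene pairs whose within-sample
ordering flips between classes, buried among uninformative genes. Each
gene gets its own mean level (sd 2 intensity units around a baseline of
8, emulating the spread of per-gene expression levels); the two genes
of a planted pair share one level and are split by a strictly positive
gap around a noisy per-sample center, with the low/high assignment
flipped by class with probability `separation` (default 0.95). Two
design points deserve a note:

* the ordering is imposed by construction, so
  $P(g_a < g_b \mid \text{class})$ equals `separation` exactly in
  expectation rather than emerging from a shifted-means race;
* the within-pair gap is deliberately *small* (margin 0.5 vs center
  noise sd 1). Any class-linked ordering flip necessarily shifts each
  member gene's marginal distribution, so a gap that dwarfs the
  biological center noise would make pairs formed across two planted
  pairs nearly as discriminative as the planted pairs themselves — an
  artifact, not a signal the generator intends. Keeping the gap small
  confines the class signal to the planted orderings, which is also
  the realistic regime: informative pairs in real data invert reliably
  without large expression differences.

Not emulated: probe effects, batch structure, heavy-tailed intensity
distributions, missing values, correlated noise between genes. A green
end-to-end test therefore establishes that the pipeline recovers
rank-flip signals planted under i.i.d. Gaussian noise — not that it
handles real microarray pathologies.

**Model-class truths** (`generate_pk_alpha()`) exist to validate the
MSE bound and interval coverage, which is only meaningful when the
truth actually lies in the assumed class. The kernel centers of $f_1$
and $f_2$ are placed *at the query*, so $f$ belongs to the class of
every candidate ball $V_i$ — matching the theorem's hypothesis without
tracking which $i$ the estimator picks — and the generator derives
$\sigma$ with the estimator's own fraction rule so the two RKHSs
coincide. Coefficients in $(0,1)$ guarantee $0 < f_l < 1$ everywhere
and give the kernel norm of $f - \alpha$ in closed form,
$|(1-\alpha)a - \alpha b|$, always below the smoothness bound of any
ball. Labels are Bernoulli (variance $f(1-f) \le 1/4$, inside the
assumed noise bound). The coverage test is therefore a check of the
mathematics and the implementation, not of robustness to model
misspecification; with data whose truth is rougher than the class
allows, the bound has no guarantee.

## Numerical choices

* **Exact quantiles.** $z_{0.10} = 1.2815516$,
  $\sqrt{1+z^2} = 1.6255382$; rounded multipliers (1.62 and the like)
  found in worked examples are superseded. At three decimals this can
  shift a reported endpoint by 0.001.
* **Clipping.** The reported probability is the adjusted estimate
  clipped to $[0,1]$; the interval is computed from the *unclipped*
  adjusted estimate and then clipped. This is the only rule consistent
  with a published worked example whose estimate prints as 0 while the
  interval's upper endpoint exceeds $\rho\sqrt{1+z^2}$ above 0.
  Class calls always use the unadjusted estimate at threshold 0.5, so
  `adjustment_e` can never change a call.
* **Ties.** Equal intensities count as "not less" in $\Delta$ scoring;
  rank ties get average ranks; equal distances sort by original
  training index; equal $\pounds_i$ pick the smaller neighborhood;
  equal $(\Delta, \Gamma)$ pick the lexicographically smaller pair.
  With tied intensities the two orientations of a pair can disagree on
  both $\Delta$ and the $p_0 \ge p_1$ convention; the selector prefers
  the orientation with $p_0 \ge p_1$, then the larger $\Delta$, then
  the smaller leading id — and the independent brute-force oracle in
  the tests implements the same convention separately.
* **Rank direction.** $\Gamma$ ranks each gene's values across the $N$
  patients. (The original k-TSP literature ranks within each profile
  across genes; the wording followed here says "ranks among the N
  patients". Since $\Gamma$ only breaks exact $\Delta$ ties, the choice
  rarely matters.)
* **Degenerate inputs.** Coincident training points make the kernel
  system singular and raise an error instructing deduplication
  (averaging labels silently would change the estimator's meaning). A
  query coinciding with all training points has no bandwidth and
  errors. Single-class training sets are rejected at scoring time.
  Zero CP patients report an undefined error-in-CP as `NA` (printed
  "—"), never 0%.
* **Stability.** The production fit is an $O(i^3)$ linear solve of
  $(K + \gamma I) w = k$; the direct $(i{+}1)$-inverse is kept test-only.
  The two paths agree to $10^{-10}$ (relative) across the bandwidth
  regime the estimator actually visits ($\sigma$ from the fraction rule
  with fractions 0.2–1.4); tiny negative $\pounds$ from roundoff is
  clamped at 0 and anything below $-10^{-8}$ raises.

## Known limitations

* Binary classification only; the multi-class TSP extensions and the
  internal cross-validation for choosing $k$ are out of scope.
* Only the Gaussian kernel has the closed-form max–min factor used by
  `m_bound()`; kernel-shape optimization under a trace constraint and
  fusion of multiple local estimators are deliberately not implemented.
* The CP guarantee is conditional on the smoothness class: with
  `sigma_fraction` large the class is very smooth and intervals narrow
  accordingly — narrower intervals from a larger $\sigma$ are a
  stronger *assumption*, not more information.
* LOOCV re-selects features per fold ($O(G^2 N)$ per fold); for
  $G \sim 10^4$ genes expect minutes per fold in plain R. The readers
  accept values as-is; no normalization or missing-data handling is
  provided.
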