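---
title: "Criticality assessment of process parameters: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criticality assessment of process parameters: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsdpower)
```

## The problem

During stage 1 of pharmaceutical process validation, screening designs
(DoEs) are run on scale-down models of each unit operation to decide which
process parameters are *critical* — able to push a critical quality
attribute (CQA) past its specification. Standard practice declares a
parameter critical when its regression coefficient is significant, and
non-critical otherwise. That inference is one-sided: a non-significant
coefficient with a wide confidence interval may still hide an effect large
enough to breach the specification within the parameter's normal operating
range (NOR). This happens in particular when the residual variance realized
in the DoE turns out much larger than the set-point variance the experiment
was planned with.

`dsdpower` implements the statistical machinery to quantify that residual
risk: threshold and critical-effect algebra, a priori DoE power averaged
over randomized effect-weight combinations, stepwise model selection, a
permutation test for *retrospective* per-parameter power, and NOR-tightening
scans, tied together in a criticality-assessment workflow.

## Thresholds, critical gaps, critical effects

All factor settings are in coded units (screening range mapped to
$[-1, +1]$); NORs are expressed on the same scale and may extend beyond it.

For an intermediate unit operation, the acceptance threshold is derived
from the drug-substance upper specification limit (USL) through the
specific clearance factors $SC_u = c_{\mathrm{load}} / c_{\mathrm{pool}}$
of the downstream unit operations:
$\mathrm{threshold} = \mathrm{USL} \cdot \prod_u SC_u$. Using *mean*
clearance factors is deliberately conservative. A directly measured
intermediate threshold can be supplied instead.

The **critical gap** is the headroom left before the threshold. Two bases
are used:

* *set point* (planning stage): $CG = \mathrm{threshold} - \bar y_{SP}$,
  with $\bar y_{SP}$ the mean of replicate runs at set-point conditions;
* *worst case* (evaluation stage):
  $CG = \mathrm{threshold} - \max_{x \in \mathrm{NOR}} \hat y(x)$, the gap
  to the most adverse prediction of the selected model over the NOR box.

A non-positive gap is an error, never silently clamped: the workflow's
premise — headroom to protect — is violated and the user must see it.

The **critical effect** of parameter $i$ carrying a fraction $w_i$ of the
gap is
$$\beta_{crit,i} = \frac{w_i \, CG}{\max(NOR_{U,i} - sp_i,\; sp_i - NOR_{L,i})},$$
i.e. the smallest slope that consumes its share of the gap when the
parameter moves to its *farthest* NOR bound (the risk-conservative choice;
it handles asymmetric NORs). Injected critical effects take the sign that
moves predictions toward the threshold (positive for upper limits); the
formula itself defines only a magnitude, and power is sign-symmetric for
the designs used here. Halving a set-point-centered NOR exactly doubles
$\beta_{crit}$.

Since many parameters share one gap, effect combinations are enumerated on
a weight grid: for each parameter $i$ in turn, $w_i = a$ and
$w_{j \ne i} = (1-a)/(p-1)$ for $a \in \{0.01, 0.02, \ldots, 1\}$ with 100
steps by default, giving $C = 100\,p$ combinations. The value $a = 0$ is
excluded — it is uninformative for the indexed parameter and would break
the $C = 100\,p$ count. With $p = 1$ the grid degenerates to copies of
$w = 1$ so the mean equals the fixed-effect power.

## A priori power

Before experiments, the only noise estimate available is the set-point
standard deviation $\sigma_{SP}$; the expected residual sum of squares of
an $n$-run DoE is taken as $\widetilde{SS}_{res} = (n-1)\sigma_{SP}^2$
($n$ here is the DoE run count: the quantity must live on the DoE's scale
to be comparable with the signal sum of squares). For each weight
combination the noiseless response $\tilde y = X \beta_{crit}$ is
simulated on the design's main-effect columns and
$\widetilde{SS}_{tot} = \sum_i (\tilde y_i - \bar{\tilde y})^2$ formed.
Signal-to-noise is converted to noncentral-F power of the overall
regression test with $u = p$ and $\nu = n - p - 1$ degrees of freedom:
$f^2 = R^2/(1-R^2)$, $\lambda = f^2 \nu$,
$\mathrm{power} = 1 - F_{nc}(F_{crit} \mid u, \nu, \lambda)$, averaged
arithmetically over all $C$ combinations.

Two $R^2$ conventions are offered, because the definition is genuinely
ambiguous when $SS_{tot}$ comes from a noiseless signal:

* `"noiseless"` (default): $R^2 = 1 - \widetilde{SS}_{res} / \widetilde{SS}_{tot}$.
  When the expected noise exceeds the critical signal this is negative;
  $\lambda$ is then clamped to 0 (power $= \alpha$) and the combination is
  flagged "noise exceeds critical signal".
* `"conventional"`: $R^2 = \widetilde{SS}_{tot} / (\widetilde{SS}_{tot} +
  \widetilde{SS}_{res})$, i.e. signal over signal-plus-noise. This variant
  corresponds *exactly* to the distribution of the overall F statistic at
  noise variance $\widetilde{SS}_{res}/\nu$ (the test suite verifies it
  against a $10^5$-replicate Monte-Carlo F-test oracle to ±0.01), and its
  $\lambda$ exceeds the noiseless variant's by exactly $\nu$.

The default follows the noiseless convention because it is the more
conservative of the two; in the strong-signal regimes where a priori power
is quoted (power $\approx 1$) the difference is immaterial.

Uncertainty in $\lambda$ is propagated through
$\lambda_{upp/low} = \lambda \cdot \chi^2_{1 \mp \alpha}(\nu)/\nu$,
reported as a per-combination power interval. The interval level defaults
to the test's $\alpha$ and is configurable.

## Model selection

DoE responses are evaluated by stepwise multiple linear regression on a
deterministic candidate list (main effects, then pure quadratics of
numeric factors, then optional pairwise interactions). A candidate enters
when its partial p-value — the two-sided t-test of its coefficient when
added to the current model — is the smallest below 0.05; an included term
leaves when its p-value is the largest above 0.1; cycles repeat until the
structure stabilizes. Ties go to the earlier candidate, the intercept is
always kept, a term never enters if fewer than 2 residual degrees of
freedom would remain, collinear candidates are skipped with a notice, and
a numerically perfect fit stops entry (partial p-values on zero residual
variance are meaningless). Quadratic terms do not require their main
effect to be present (no heredity constraint).

The residual standard deviation $\hat\sigma_{residues}$ is computed from
*raw* residuals with denominator $\sqrt{n-1}$ — it is compared against
$\hat\sigma_{SP}$, estimated with the same denominator, so the ratio
$\hat\sigma_{residues}/\hat\sigma_{SP}$ is a like-for-like diagnostic of
the planning assumption. The usual $n-q-1$ denominator is available as an
option.

## Retrospective power by residual permutation

The parametric assumptions behind F-test power are fragile at screening
sample sizes, so realized power is estimated nonparametrically. Given the
selected model $y = \beta_0 + \beta_s X_s + R_{y|X_s}$, for every weight
combination $c$ over the non-significant parameters:

1. derive $\beta_{crit}^{(c)}$ from the worst-case critical gap;
2. permute the residuals, $R^*_{y|X_s}$;
3. synthesize
   $y^* = \beta_0 + \beta_s X_s + \beta_{crit}^{(c)} Z + R^*_{y|X_s}$,
   where $Z$ holds the main-effect columns of all non-significant
   parameters;
4. refit one OLS model on $[1 \mid X_s \mid Z]$ and record, per $Z$
   column, whether its coefficient is significant at $\alpha$.

The fraction of significant outcomes over all permutations and
combinations is the retrospective power of parameter $i$: the chance this
experiment would have caught a critical effect of $i$ had one been
present. With $\beta_{crit} = 0$ the procedure reduces to a permutation
null and its detection rate equals $\alpha$ — the calibration the test
suite checks at $10^4$ permutations to ±0.01.

Design choices worth recording:

* **Refit, not re-selection.** Step 4 is a single full OLS refit with
  per-coefficient t-tests, not a re-run of stepwise selection — it is
  deterministic, fast, and matches the question "would this coefficient
  have been significant". A `stepwise_inner` re-selection variant was
  considered and rejected for the default because it makes the estimand
  depend on the selection path.
* **Iteration accounting.** The permutation count (default 1000) applies
  *per combination*; a `"sampled"` strategy (each iteration draws a
  combination uniformly, the count being the total) is available when the
  full product is too expensive. Results are labelled with the strategy.
* **Z membership.** A factor counts as significant when *any* selected
  term involves it (main, quadratic or interaction): its influence on the
  worst-case prediction is already modelled, so it is excluded from the
  injected set.
* **Engine.** The permutation loop is vectorized: one QR/Cholesky solve
  per batch of permuted responses, identical in exact arithmetic to
  refitting each response with `lm()` (the test suite cross-checks the
  p-values against `lm()`/`summary()`); $10^5$ individual `lm()` calls
  would dominate the runtime otherwise.
* **Reproducibility.** One seeded generator drives all permutations, the
  combination loop order is fixed (parameter-major, ascending $a$), and
  identical configuration plus seed reproduces results bit-for-bit. The
  caller's RNG state is restored afterwards.

### NOR tightening

`nor_scan()` re-runs the assessment after shrinking one factor's NOR
symmetrically about its set point, with the same seed per fraction so
curves are comparable. Two distinct mechanisms emerge, both verified as
properties on synthetic data:

* tightening a **non-significant** factor steepens only its own critical
  effect — its power rises, the others are untouched (with a shared seed,
  exactly: on an orthogonal design the other coefficients' estimates and
  the refit residuals are invariant to the injected column's scale);
* tightening a **significant** model term pulls the worst-case prediction
  back from the threshold, enlarging the critical gap and thereby weakly
  raising *every* non-significant parameter's power.

The workflow reports such scans but never applies a tightening on its own;
narrowing a control range is a process decision with feasibility
constraints the statistics cannot see.

## Worst-case prediction over the NOR box

For additive models (main + pure quadratic terms) the maximization is
separable and solved coordinate-wise in closed form (bound or interior
stationary point). With interaction terms the objective is quadratic per
coordinate but not separable; the optimum is located by enumerating the
box vertices plus the center and polishing each start with exact
coordinate ascent. Up to 12 active factors are supported, far beyond
screening-design practice. Tests verify agreement with a dense grid-search
oracle for models up to quadratic-plus-interaction structure.

## The definitive screening design generator

DSDs are built by conference-matrix fold-over: runs are the rows of a
conference matrix $C$ (order 4: skew; orders 6 and 8: Paley construction),
their mirror images $-C$, and one all-zero center run. Main effects are
mutually orthogonal and orthogonal to quadratic effects. For an odd number
of factors $m$ no conference matrix of order $m$ exists (two $\pm1$
columns of odd length cannot be orthogonal after removing the diagonal
zeros), so the $(m+1)$-factor design is built and its last column dropped
— the standard construction — giving $2m+3$ runs (13 runs for 5 factors);
for even $m$, $2m+1$ runs. For even $m$ every non-center run has exactly
one factor at its mid level; for odd $m$ the fold-over pair whose zero
fell in the dropped column has none.

## The synthetic-data generator

`simulate_study()` draws DoE responses
$y = \beta_0 + X\beta_{true} + \varepsilon$ with Gaussian (or scaled-$t_3$)
residuals and set-point replicates $\mathcal N(\beta_0, \sigma_{SP}^2)$.
The two presets pin down the study conditions used throughout the tests
and the acceptance script:

* `scenario_pr_like()`: 4 factors, 9 runs, $\sigma_{resid} = \sigma_{SP} =
  0.01$, a threshold far above the operating point (CG $\approx 2500
  \sigma_{resid}$) — the regime where the planning assumption holds and
  all retrospective powers come out near 1;
* `scenario_cc1_like()`: 5 factors, 13 runs, NORs matching an industrial
  chromatography step (e.g. an asymmetric $[-1.1, 0]$ pooling range),
  null true effects, and $\sigma_{resid} = 8\,\sigma_{SP}$ — inside the
  8–250 range of residual-to-set-point sd ratios reported for such steps —
  with a threshold chosen so the a priori power is essentially 1 while the
  per-parameter retrospective powers land well below the 0.8 cutoff.

Six set-point replicates reflect common small-scale practice. What the
generator does *not* emulate: real responses have run-order effects,
analytical drift, and non-linearities beyond the quadratic; passing tests
demonstrate the statistical machinery is correct and calibrated under its
own model, not that any particular real unit operation is well described
by it. The heavy-tailed mode exercises the permutation test's
distribution-freeness, not a mechanistic error model.

## Problem sizes and numerical choices

Defaults follow the methodology's reference settings: $\alpha = 0.05$
(entry 0.05 / exit 0.10 for selection), 100 weight-grid steps, 1000
permutations per combination, power cutoff 0.8 (0.9 configurable). The
test suite and the acceptance script run the same machinery at reduced
sizes chosen as the package's own verification budget — typically 6–20
grid steps and 150–500 permutations, with $10^4$ permutations for the
calibration check — which bounds the Monte-Carlo error of any asserted
power at about 0.01–0.03. Ties in stepwise selection go to the earlier
candidate; rank-deficient refits are an error naming the offending
columns; degenerate inputs (constant response, zero-width NOR, gap already
spent) raise diagnostic errors rather than producing numbers.

## Limitations

* Criticality direction is per-CQA (`upper` by default, `lower` by
  symmetry); two-sided specifications would need two runs.
* Power is assessed for main effects of the non-significant parameters
  only, resting on the usual effect-sparsity argument for screening
  designs; interaction effects of unselected factors are not injected.
* No optimal-design search, no split-plot/blocked/mixture designs, no
  physical-unit conversions, and no risk-assessment (FMEA) scoring — the
  package starts from a coded design and ends at the criticality call.
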