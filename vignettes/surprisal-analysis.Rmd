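---
title: "Surprisal analysis of time-course gene expression: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surprisal analysis of time-course gene expression: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surprisalr)
```

## The model

Surprisal analysis treats a measured expression time course as a
maximal-entropy state deformed by a small number of constraints. For gene $i$
at time point $t$,

$$\ln X_i(t) \;=\; G_{i0}\,\lambda_0(t) \;+\; \sum_{\alpha\ge 1} G_{i\alpha}\,\lambda_\alpha(t),$$

where the first term is the time-invariant baseline — the expression
distribution at the entropy maximum, which is heterogeneous across genes
because transcripts differ intrinsically, not uniform — and each remaining
term is one *transcription pattern*: a fixed vector of per-gene weights
$G_{\cdot\alpha}$ whose Lagrange multiplier $\lambda_\alpha(t)$ measures how
strongly that constraint acts at time $t$. The *surprisal* of a gene is its
log-level's deviation from the baseline term.

Two consequences drive everything in the package:

* **Finite pattern budget.** With $A$ time points along a trajectory, exactly
  $A$ patterns exist ($\alpha = 0,\dots,A-1$) and using all of them
  reproduces the data exactly — noise and all. Usefulness comes from
  truncation: patterns are ranked by the magnitude $\omega_\alpha$ of their
  weight, and one or two time-varying patterns typically carry most of the
  signal.
* **Pattern-resolved changes.** Between two stages $t$ and $t'$,
  $\Delta_i = \sum_\alpha G_{i\alpha}\,(\lambda_\alpha(t') - \lambda_\alpha(t))$
  exactly; restricting the sum to one $\alpha$ isolates that pattern's
  contribution, which is what gene selection thresholds and what makes sign
  *inversions* of $\lambda_\alpha$ consequential — the entire pattern's gene
  set swaps over- and under-expression.

## Fitting

The fit is the economy singular value decomposition of the
**non-mean-centered** gene $\times$ time matrix $Y$ of natural-log levels,
$Y = U S V^\top$: gene weights $G = U$ (orthonormal columns), magnitudes
$\omega = \mathrm{diag}(S)$, fractional time profiles $P = V^\top$
(orthonormal rows), multipliers $\lambda = S V^\top$. Not centering is
essential: the baseline lives in the leading singular pair, which is exactly
what mean-centering would destroy. Because genes vastly outnumber time
points, this is equivalent to an eigendecomposition of the small
$A \times A$ matrix $Y^\top Y$ and costs nothing.

Numerical conventions, all deterministic:

* **Signs.** Singular-vector signs are arbitrary, so each profile row is
  flipped to make its largest-magnitude entry positive; the baseline profile
  is additionally required to have positive mean, so $\lambda_0 > 0$. A fixed
  convention is what makes inversion calls reproducible.
* **Normalization.** "Fractional weights" are normalized in the $L^2$ sense,
  $\sum_t P_{\alpha t}^2 = 1$ — the SVD's native convention, which makes
  $\lambda_\alpha = \omega_\alpha P_\alpha$ exact entrywise. (An $L^1$
  reading of "sums to unity" would break that identity; the $L^2$ choice is
  asserted by the package's normalization checks.)
* **Baseline acceptance.** The top-$\omega$ pattern is *accepted* as the
  baseline only if its fractional profile has coefficient of variation at
  most 0.2 (default); otherwise the fit is returned with no baseline
  identified, plus a warning. Constancy of $\lambda_0$ is a falsifiable
  check on the theory — `check_lambda0_constancy()` reports the CV against a
  0.05 default tolerance — not an assumption baked into the solver.
* **Ties and rank deficiency.** Near-equal singular values (relative gap
  $< 10^{-8}$) keep LAPACK's stable order but emit a degeneracy warning,
  since the split between tied patterns is not unique. Duplicate time
  columns succeed with numerically zero trailing $\omega$ and a warning.
* **Zeros.** $\ln 0$ is undefined, so zero levels are floored before the
  transform: half the smallest positive level by default, any positive
  constant by choice, or `"strict"` to refuse. The floor used is recorded on
  the object.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `alpha` (replicate filter) | 0.05 | paired t-test level; genes with $p <$ `alpha` are removed as replicate-inconsistent |
| `floor` | `"auto"` | substitute for zero levels (linear scale) before $\ln$ |
| `cv_baseline` | 0.2 | max CV of the leading profile to accept it as baseline |
| `tol_cv` | 0.05 | pass threshold for the $\lambda_0$ constancy report |
| `threshold` (gene selection) | 0.5 | ln-units; $e^{0.5}$-fold single-pattern change |
| `noise_floor` (inversions) | 5% of $\max_t\lvert\lambda_\alpha\rvert$ | weights below it are treated as "zero that is not exactly zero" |

The inversion noise floor exists because a fitted weight of zero is never
exactly zero: profiles belonging to smaller $\omega$ are increasingly
noise-sensitive, and without a floor a pattern hovering near zero would
produce sign-chatter calls. A sign change across one or more below-floor
points is still reported — as a single event spanning the stretch, flagged
`spans_below_floor`.

## Ingest filters

Two filters precede analysis, mirroring standard microarray practice. The
detection filter keeps a gene only if it is called present in *every*
replicate of at least one time point. The replicate-consistency filter runs a
per-gene paired t-test of the replicate-1 series against the replicate-2
series across time points and keeps genes the test does **not** reject at
level `alpha` — i.e. genes with no detectable systematic disagreement between
duplicates. The "pass = high p-value" reading is the one that makes this a
*consistency* filter; an `invert` flag provides the opposite rule. The test
is per-gene (not one global test) so that individual unreliable probes are
what get removed. Degenerate series bypass `t.test()`: identical replicates
are kept ($p=1$); a constant non-zero offset has an infinite t statistic and
is removed ($p=0$). Averaging of duplicates happens on the linear scale,
before the log transform.

## Entropy deficiency

As a summary of "how far from maximal entropy" the system sits at time $T$,
the package computes a Kullback–Leibler divergence between the current
normalized level distribution and the normalized baseline distribution:
$$D(T) = \sum_i p_i(T)\,\ln\frac{p_i(T)}{p^0_i},\qquad
p_i(T) \propto X_i(T),\quad p^0_i \propto e^{\lambda_0(T) G_{i0}}.$$
$D \ge 0$ always, $D = 0$ exactly when no time-varying constraint acts, and
$D$ depends only on the current levels — computing it from the raw column or
from the all-pattern reconstruction gives the same number to $10^{-10}$,
which is the state-function property the tests assert. This specific formula
is the package's own choice of deficiency functional; it is defined, stated,
and tested here on exactly those two properties.

## Trajectories

Branching designs are handled by decomposing each experimentally continuous
route (an ordered label sequence like `"1-5-7-8-10-12"`) independently on its
own columns — so a trajectory's result provably depends on nothing outside
it — and restoring cross-route comparability afterwards:
`align_patterns()` matches gene-weight columns between two fits by absolute
cosine (columns are unit vectors, so cosine is a dot product), greedy by
default with an exact assignment (`method = "optimal"`, dynamic programming
over pattern subsets — trivial at $A \le 12$) behind a flag. Different routes
may legitimately settle on different $\lambda_0$ values, since they can end
in different secular states; the suite tabulates them rather than flagging
them. Continuity itself is biology, not string syntax, so it is enforced
only when the user supplies an allowed-successor map.

## The synthetic generator

`simulate_expression()` runs the model forward: a heterogeneous baseline
($b_i \sim N(\mu, \sigma^2)$ on the ln scale, default $\mu=5$, $\sigma=1$ —
typical microarray log-intensity spreads), $K$ planted patterns with chosen
time profiles, lognormal replicate noise (additive on the ln scale, default
sd 0.05, matching small duplicate scatter), duplicates, and all-present
flags. Profile values are on the per-gene ln scale: a profile value $a$
moves a one-sigma gene by about $a$ ln-units.

Two generator conventions matter. Gene-weight columns are orthonormalized
against the constant gene vector, the baseline, and each other; profiles are
centered over time and mutually orthogonalized. This makes the planted
structure coincide with the SVD's orthogonality contract, so that with zero
noise recovery is *exact* (machine precision) and the planted $\lambda_0$ is
exactly constant — which is what turns recovery tests into sharp oracles
rather than approximate ones. These are numerical conventions for testability,
not biological claims.

The bundled `make_wi38_like_fixture()` (2000 genes, 12 points, duplicates,
noise sd 0.05) plants three patterns with zero-sum, mutually orthogonal
profiles chosen once from the qualitative anatomy the method is meant to
resolve: a dominant pattern constant-positive through label 7 that flips sign
at 8; an early-only pattern rising to label 7 and zero after; a late-onset
pattern active from label 8 with a sign change between labels 10 and 11.
Amplitudes (1.5/−2.1, up to 2.4, up to 1.55) set $\omega$ gaps wide enough
that noise at sd 0.05 cannot mix neighboring patterns (the noise matrix's
spectral norm is an order of magnitude below the smallest gap). Branching
routes are column subsets of the one matrix, so shared stages share values by
construction.

What the generator does *not* emulate: probe-level artifacts, realistic
present/absent call errors, intensity-dependent (heteroscedastic beyond
lognormal) noise, correlated gene modules that are not exactly orthogonal,
and baselines that drift. Passing recovery tests therefore demonstrates the
estimator's correctness and stability under the stated noise model — not that
real arrays satisfy the model.

## Problem sizes

Unit tests run on 60–500-gene matrices with 3–8 time points; the
study-condition checks use the full 2000-gene, 12-point fixture and random
2000×6 matrices; the filter null-retention simulation uses 1000 genes. These
sizes make every oracle exact or statistically sharp (3 standard errors)
while keeping the whole suite in the seconds range.

## Known limitations

* The decomposition is a least-squares/SVD fit, not an iterative
  maximum-entropy solver; no confidence intervals on $\lambda$ are provided.
* Baseline identification is heuristic (CV screen on the top profile); data
  whose dominant variation is time-varying return no baseline, by design.
* The entropy-deficiency functional is a stated choice (see above), and
  inversion calls inherit the arbitrariness of the 5% noise floor near
  threshold.
* Gene selection's optional p-value gate reuses whatever per-gene p-values
  the caller provides (by default the replicate-consistency p-values, where
  *passing* means $p \ge$ cutoff); it is a filter plumbing decision, not a
  differential-expression test.
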