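---
title: "Bounded-rational information costs of concurrent motor planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded-rational information costs of concurrent motor planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planinfo)
```

## The task and its generative structure

The package models a delayed-response task in which a participant steers a
cursor to a target field by a sequence of 2–4 button presses. A trial
proceeds in three phases. A *cue stimulus* $s_1$ first highlights a set of
potential targets; after a long delay, a *go-signal* $s_2$ — a half-frame
covering part of one response panel — identifies which potential target is
the actual one, and the movement must be produced immediately. Because the
go-signal never marks the target itself, the response can only be correct
if the cue information was retained across the delay.

The screen holds four response panels, each split into two halves; each
half contains one target at distance 2, two at distance 3 and two at
distance 4 (distance = number of button presses). That gives $|W| = 40$
hidden target states, $|A| = 80$ movement sequences (each off-axis target
is reached by exactly its two extremal monotone paths — all horizontal
steps first or all vertical steps first), and $|S_2| = 8$ half-frames.
Twelve experimental conditions cross the *target condition*
$c_T \in \{\text{'1'},\text{'11'},\text{'2'},\text{'4'}\}$ (one target; two
targets in one panel; two targets in two panels; four targets in four
panels) with the *sequence length* $c_S \in \{2,3,4\}$. Enumerating all
condition-consistent target combinations yields $|S_1| = 820$ cue stimuli,
with condition-wise counts $(8, 16, 16, 4, 16, 16, 24, 96, 96, 16, 256,
256)$. All conditions are equally likely, the cue is uniform within its
condition set, and the go-signal is uniform over the cued targets'
half-frames — support size 1, 2, 2 or 4 by target condition.

Only these set relations matter for the model: the on-screen pixel layout
never enters the probabilities. `build_task()` therefore works from an
abstract `panel_geometry()`; the default reproduces the cardinalities
above, and the constructor recomputes every cue-set size from closed-form
combinatorics and refuses geometries whose enumeration disagrees.

```{r task}
task <- build_task(default_geometry())
task
```

## The bounded-rational model

The agent forms a memory $m$ from the cue through a channel $p(m|s_1)$ and
chooses the action through $p(a|m,s_2)$, trading expected utility against
the information processed by the two channels:

$$\max_{p(m|s_1),\,p(a|m,s_2)}\;
E[U] \;-\; \tfrac{1}{\beta_1} I(M;S_1)
\;-\; \tfrac{1}{\beta_2}\bigl(I(A;M) + I(A;S_2|M)\bigr),$$

where $U(w,a)=1$ exactly when sequence $a$ reaches target $w$, so
$E[U] = 1 - \text{error rate}$. The inverse temperatures $\beta_1,
\beta_2$ set the memory and action capacities; both $\to\infty$ recovers a
Bayes-optimal maximum-expected-utility agent, and $\beta = 500$ serves as
the "not-bounded" reference throughout.

`solve_policy()` iterates the self-consistent optimality conditions: the
action channel is a softmax of the expected utility under the posterior
$p(w|m,s_2)$ against the action prior $p(a)$; the memory channel is a
softmax of the free-energy gain
$\Delta F(m,s_1)$ — the expected utility of acting from $m$ minus
$1/\beta_2$ times the expected action divergence — against the memory
prior $p(m)$; both priors are the policy-induced marginals, and
$p(w|m,s_2)$ is re-derived from the joint each sweep.

### Numerical choices

* **Log base.** All exponentials and divergences use natural logarithms
  internally; information is converted to bits only at reporting
  boundaries. At the capacities of interest the distinction is
  immaterial to the solution itself.
* **Update order.** One sweep updates $p(w|m,s_2) \to p(a|m,s_2) \to p(a)
  \to \Delta F \to p(m|s_1) \to p(m)$, so the action channel is current
  before the memory channel is scored.
* **Initialization.** The uniform memory channel is a *degenerate fixed
  point*: with $p(m|s_1)$ uniform, $p(w|m,s_2)$ and hence $\Delta F$ are
  constant in $m$, and the memory channel never moves (the test suite
  demonstrates this). The default is therefore an identity-biased start,
  $p(m|s_1) = (1-\varepsilon)\delta_{m,s_1} + \varepsilon/|M|$ — the
  canonical symmetry-breaking choice given that the memory alphabet is
  identified index-for-index with $S_1$. The converged tables shift only
  marginally with $\varepsilon$; a random init (seeded) is available for
  basin exploration.
* **Degenerate pairs.** Zero-mass $(m,s_2)$ pairs take the task prior
  $p(w|s_2)$ as their posterior; they carry vanishing weight.
* **Hygiene.** Softmaxes subtract the column maximum; probabilities are
  floored at $10^{-300}$ before logs. Convergence is declared when no
  table entry moves by more than `tol` (default $10^{-10}$) in a sweep.

### Multiple fixed points

The problem is not jointly convex, and at high capacity the fixed-point
map has several attractors that differ in how strongly the memory channel
compresses cue stimuli with compatible behavioural consequences (a cue can
share a memory state with any cue whose target assignment agrees on every
go-signal they can both encounter). From the identity-biased start the
solver converges to a moderately compressed solution; `solve_policy_annealed()`
(warm-started increase of $\beta_1$) reaches a more compressed fixed point
with an at-least-as-high variational objective — the test suite checks
that ordering. All solutions at $\beta_1=\beta_2=500$ are
utility-perfect to numerical precision; what varies between them is the
split of the information budget between the two channels. The anchor
values printed by `scripts/acceptance.R` use the deterministic default
(identity start, direct iteration) — the reproducible canonical choice,
not a per-quantity selection among basins.

## Information accounting under the two hypotheses

Both hypotheses share the memory cost per condition,
$$I_1(c_T,c_S) = \sum_{s_1} p(s_1|c_T,c_S)\, KL\bigl(p(m|s_1)\,\|\,p(m)\bigr).$$

**Delayed planning (H0).** The delay only reduces uncertainty; action
planning waits for the go-signal. The delay-phase action cost uses the
memory-conditioned marginal $p(a|m) = \sum_{s_2} p(s_2|m)\,p(a|m,s_2)$:
$$I_2^{H_0}(c_T,c_S) = \sum_{s_1} p(s_1|c)\sum_m p(m|s_1)\,
KL\bigl(p(a|m)\,\|\,p(a)\bigr).$$
($p(a|m)$ is not a solver output; it is derived by Bayes-consistent
marginalization, the policy-consistent choice.)

**Concurrent prospective planning (H1).** Every compatible go-signal is
anticipated and a plan formed for each, so the cost is the expected
per-plan divergence multiplied by the plan count
$N_{T,S} = 1, 4, 4, 16$ for $c_T = $ '1', '11', '2', '4':
$$I_2^{H_1}(c_T,c_S) = N_{T,S} \sum_{s_1} p(s_1|c)\sum_m p(m|s_1)
\sum_{s_2} p(s_2|s_1)\, KL\bigl(p(a|m,s_2)\,\|\,p(a)\bigr).$$

Averaging over the uniform condition prior ties the profiles to global
mutual informations, and these identities are verified to $10^{-6}$ bits
at every grid point of the test suite:
$\overline{I_1} = I(M;S_1)$, $\overline{I_2^{H_0}} = I(A;M)$,
$\overline{I_2^{H_1}/N} = I(A;M) + I(A;S_2|M)$. Two consequences worth
noting: $I_2^{H_1} \ge I_2^{H_0}$ condition-wise, and at any
utility-perfect high-capacity solution the per-plan divergence is pinned
near $\log_2(|A|/2)$ bits — the action channel must single out the two
correct sequences against a near-uniform action marginal — so the H1
expectation at maximal capacity is necessarily of order
$\overline{N} \cdot \log_2 40 \approx 33$ bits on this task.

## The regression-based hypothesis comparison

Condition-level delay-phase activity estimates are modelled as
$$\text{fMRI}(c) = \alpha_0 + \alpha_1 f(I_1(c)) + \alpha_2 f(I_2(c)) +
\varepsilon_c,$$
with $f$ one of four monotone links (identity, square, $\log(1+x)$,
logistic) and $\alpha_1,\alpha_2 \ge 0$ ($\alpha_0$ free, absorbing
baseline). The constrained least-squares problem is solved exactly by
enumerating the active sets of the two constraints.
`grid_search_fit()` selects the capacities maximizing $R^2$ over a solved
grid (ties toward larger $\beta_1+\beta_2$, then larger $\beta_2$) and
also reports the maximal-capacity fit as the "not-bounded" reference,
which the bounded best fit dominates by search-set inclusion.

The nested F-test for the contribution of $I_2$ compares the full and the
$I_1$-only model via classical *unconstrained* least-squares residuals,
$F = (RSS_r - RSS_f)/(RSS_f/(n-3))$ with $n-3 = 9$ degrees of freedom for
12 conditions. Using unconstrained residuals keeps the null distribution
exact — with sign-constrained residuals the statistic would be zero
whenever the unconstrained $\hat\alpha_2$ is negative, putting probability
mass one-half on $p = 1$ under the null; the test suite verifies the
p-values are uniform when $\alpha_2 = 0$ (Kolmogorov–Smirnov at 1%).
Group-level contrasts (`compare_group()`) implement the two-level
repeated-measures comparison (equivalently a paired t-test — no factor in
scope has more than two levels, so no sphericity machinery is needed),
the Wilcoxon signed-rank test with an optional Bonferroni divisor, and a
seeded sign-flip permutation test. `behavior_correlation()` regresses
observed performance $1-\text{error rate}$ on model-predicted $E[U]$ and
reports the fraction of significant slopes under shuffled pairings as a
false-positive control.

## The synthetic cohort generator

No subject data ships with the package; `generate_cohort()` emulates
exactly the inputs the analysis consumes: per subject, one activity value
per condition generated from the subject's ground-truth hypothesis,
capacities, link and coefficients plus independent homoscedastic Gaussian
noise — the assumption ordinary least squares and the F-test make — and a
behavioural error rate drawn as
$\text{Binomial}(n_{\text{trials}}, 1-E[U])/n_{\text{trials}}$ with
$n_{\text{trials}} = 120$, the typical session total. Noise levels are
calibrated in units of the across-condition spread of the noiseless
betas (`noiseless_spread()`), since the study's residual variances are
not available; 25% of that spread is the reference level at which the
recovery properties are stated. What passing recovery tests show is that
the *pipeline* is consistent — the generator implements the model the
fitter assumes. They cannot show that real delay-phase BOLD follows the
model: real data has inter-ROI and inter-condition noise correlation,
baseline drift and link-function uncertainty that the generator
deliberately omits (an ROI label is carried as metadata only).

One identifiability asymmetry is worth knowing: data generated under
concurrent prospective planning is recovered essentially always (the
$N$-multiplied profile has a distinctive condition signature), whereas
data generated under delayed planning admits an equally good H1 fit with
$\alpha_2$ near zero — the hypotheses are nested in explanatory power, so
"H1 fits better" is informative and "H1 fits no better" is the null
outcome, exactly the logic of the nested comparison.

## Problem sizes and defaults

The solver runs the full 820-stimulus task comfortably (a maximal-capacity
solve converges in under a hundred sweeps); capacity grids and simulation
studies use `reduced_geometry()` — two panels with the full per-half
target multiset: 74 stimuli, 9 conditions, several targets per half so
memory formation is genuinely required. The bundled capacity grid is
$\{5, 50, 500\}^2$; the grid resolution is a free choice exposed in
`pipeline_config()`. Cohort simulations use 19 subjects (the study's
cohort size) and 50 replicate cohorts in the acceptance checks. The
`mini_geometry()` task (4 targets, one per half) is the brute-force
oracle testbed; its halves are unambiguous, so it exercises the action
channel with zero memory demand — a useful degenerate case.

## Known limitations

* The fixed-point solution at a given capacity is basin-dependent (see
  above); reported information values are meaningful relative to the
  documented default initialization.
* The F-test's exactness argument assumes Gaussian residuals; for real
  data the permutation alternatives in `compare_group()` are the safer
  route.
* The generator does not model voxel-level time series, HRF convolution
  or scanner noise spectra; it operates at the GLM-beta level the
  regression analysis consumes.
* Capacity recovery is only identified up to grid resolution, and at high
  capacities neighbouring grid points can have identical profiles (the
  utility ceiling), so recovery is assessed within one grid step.
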