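---
title: "Idiographic symptom networks from experience-sampling series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Idiographic symptom networks from experience-sampling series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmnet)
```

## The data and the question

Experience sampling (ESM) signals a patient at random moments — here ten
times a day between 7:30 AM and 10:30 PM, consecutive signals 10 minutes
to 3 hours apart, four monitored days per week over about a year — to
rate momentary symptoms on 7-point Likert scales ("1" not at all, "7"
very). Five a-priori symptoms are analysed throughout, in a fixed
canonical order: `down`, `loss_of_control`, `paranoia`,
`hearing_voices`, `relaxed`. The patient's severity state on each day is
operationalized by the daily clozapine dose: 350 mg maintenance =
*stable*, 400 mg = *impending relapse*, 450 mg = *full relapse*.

The scientific question is dynamic: how strongly does each symptom at
one assessment predict each symptom at the next, does that network of
lagged influences change with severity state, and which symptom is the
most *central* — the most promising treatment target — in each state?

## The lagged regression network

For each state separately, five ordinary least-squares models are fit,
one per symptom as outcome:

$$y_i(t) = B_0 + \sum_{j=1}^{5} B_j \, y_j(t-1) + B_6\,d(t) + e$$

where $t-1$ is the *immediately preceding answered beep on the same
calendar day* and $d(t)$ is the calendar day, included so that slow
drift over the study year is not mistaken for lagged dependence
(de-trending). Because all data come from one subject there is no
multilevel structure and standard linear regression applies. The 25 lag
coefficients form the weighted directed adjacency $W$ with the
convention `W[i, j]` = edge $j \rightarrow i$; the diagonal holds the
autoregressive self-loops. Coefficients are left on the raw 1–7 scale
(an option z-scores within state), and per-coefficient p-values are the
usual OLS t-tests without multiplicity correction.

Choices the data force, and how we made them:

* **Lag definition.** With roughly half the beeps missed, requiring
  adjacent *scheduled* beeps would discard most of the data, while
  letting lags cross nights would mix 10-minute and 9-hour intervals.
  The lag is therefore the previous *answered* beep of the same day,
  whatever the gap; a `max_lag_minutes` filter is exposed but off by
  default.
* **Missingness.** A row enters a given model only if the outcome and
  all five lagged ratings are present (per-model casewise deletion), so
  the five models can have slightly different $n$.
* **State of a pair.** Taken from the current beep; the dose is constant
  within a day, so pairs cannot straddle states.
* **Stratification** means fitting each state's subset separately — no
  interaction terms — so each state yields its own 25-edge network.

### Spearman partial-correlation sensitivity networks

Regression coefficients from collinear lags can be unstable. As a
rank-based check, `spearman_partial_network()` replaces each coefficient
with the Spearman partial correlation between current symptom $i$ and
lagged symptom $j$, conditioning on the remaining four lags and the
calendar day — deliberately the same adjustment set as the regression,
since the exact conditioning set behind published sensitivity analyses
of this kind is rarely stated. All columns are rank-transformed, both
targets are residualized on the conditioning set, and the partial
correlation is the correlation of residuals; this survives the
perfect-association edge case where the rank correlation matrix is
singular. p-values use the t approximation with $n - 7$ degrees of
freedom. The network inherits rank invariance: any strictly increasing
transform of a symptom leaves it unchanged.

## Centrality

Edge weights can be negative (e.g. relaxed–paranoia), yet strengths and
distances must be positive, so all centrality computations use $|w|$ —
the convention of the standard network tooling for psychopathology
graphs — while signs are preserved in all exports.

* **Strength.** Outward strength = sum of $|w|$ over outgoing edges,
  inward strength = over incoming edges, node strength = their sum.
  The self-loop belongs to both sums and is therefore counted twice in
  node strength — in a 5-node network the autoregressive edge is real
  dynamics, not an artefact to discard.
* **Distances.** $d = 1/|w|$ per edge, so stronger connections are
  shorter; exact-zero coefficients mean "no edge" (a `threshold`
  argument can also zero small $|w|$; default 0). Self-loops never
  participate in paths.
* **Closeness** = $1/\sum_u d(v, u)$ over *outgoing* shortest distances;
  if any node is unreachable the sum is infinite and closeness is 0 —
  the natural limit of the inverse sum, rather than dropping terms.
* **Betweenness** counts, for each ordered pair of other nodes, the
  fraction of minimal-distance paths passing through the node (Brandes
  accumulation with fractional tie-splitting). Ties are detected with a
  relative tolerance of 1e-12; with continuously estimated weights exact
  ties have measure zero, so integer values emerge in practice.

The implementation is a 5-node Dijkstra/Brandes; the test suite verifies
it against an independent oracle that exhaustively enumerates every
simple path on hundreds of random weighted digraphs (to 1e-9), plus the
conservation law $\sum_v \text{in}(v) = \sum_v \text{out}(v) = \sum
|W|$, scale equivariance of closeness, scale invariance of betweenness,
and monotonicity of closeness under edge deletion.

A caveat carried over from the method itself: in weighted directed
networks several paths can have nearly equal length, making betweenness
fragile — the regression and Spearman networks can disagree noticeably
on betweenness while agreeing on strengths. Both are reported; the
discrepancy is surfaced, not resolved.

## The synthetic generator

No patient data are deposited, so the package carries its own
data-generating model, used both as the test bed and as the
study-condition stand-in. Per scheduled beep $k$ of a day in state $s$:

$$x_k = c_s + A_s x_{k-1} + \tau\, d + \varepsilon, \qquad
\varepsilon \sim N(0, \mathrm{diag}(\sigma_s^2))$$

on a latent continuous scale, observed as
$\mathrm{clamp}(\mathrm{round}(x), 1, 7)$. Key properties and defaults:

* **Sampling frame.** 201 monitored days, 4 per week, 10 beeps/day in
  the 450–1350 minute window with gaps in [10, 180] minutes. The
  scheduler samples gaps sequentially, truncating each gap to the range
  that provably leaves room for the remaining beeps — every draw is
  feasible by construction and the sampler has full support over the
  feasible set.
* **Completion.** Independent Bernoulli per beep, default
  $943/2010 \approx 0.469$, matching the answered fraction of the
  monitored year it emulates; a small per-item missingness
  (default 0.004) reproduces "partial missing data" on answered beeps
  (the study's mean of 939 complete observations per item against 943
  answered beeps implies an item-missingness rate of this order).
* **Episodes.** The default plan has 4 full-relapse episodes of
  {4, 15, 25, 25} monitored days (mean 17.25, range 4–25) and 2
  impending episodes of {7, 31} (mean 19, range 7–31), matching the
  reported episode counts and duration statistics. Episode durations are
  counted in *monitored* days (the analysis only ever sees monitored
  days, so episodes are defined as runs over the monitored-day index and
  durations sum exactly to the number of monitored days).
* **Dynamics.** Per-state lag matrices ($\rho(A_s) < 1$ enforced) encode
  the qualitative findings the analysis should detect: a positive
  down–paranoia loop, a negative relaxed–paranoia loop, a moderate
  negative relaxed→voices edge (−0.16) and positive
  down→loss-of-control edge (0.21) in the stable state; intermediate
  connectivity when relapse impends; and in full relapse a paranoia hub
  with strong outgoing edges to every symptom. Intercepts are set so
  stationary means track the observed severity ordering (down and loss
  of control up, relaxed down in full relapse; voices slightly lower
  when impending). Innovation sd 1.2–1.8 gives observed beep-to-beep
  sds near the reported 1.3–2.0.
* **Overnight handling.** The first beep of each day resets to the
  state's stationary distribution (default). Since the estimator never
  uses cross-night lags, cross-night dependence is unidentifiable from
  the analysed pairs; resetting keeps days exchangeable and lets the
  simulator vectorize across days. A `"carry"` mode propagates the last
  latent value instead.
* **Trend.** $\tau = 0$ by default; nonzero only in the de-trending
  tests.

Everything is deterministic given the config (which embeds the seed).

What the generator deliberately does *not* emulate: context/appraisal
items, event-contingent sampling, reactivity (answering affecting later
symptoms), non-Gaussian latent noise, or any claim about the real
patient's dynamics — the defaults are a plausible test bed, not an
estimate. Consequently, passing recovery tests show the estimator works
when its assumptions hold under realistic discretization and
missingness; they cannot validate the assumptions against clinical data.

## Attenuation, and what "recovery" means

Two mechanisms shrink estimated coefficients relative to $A_s$:
discretization (rounding/clamping is measurement error on the
predictors) and missed beeps (a lag pair that skips $k$ missed beeps
reflects $A^{k+1}$, so the estimand under 47 % completion is a blend of
powers of $A$). Both are properties of the *design*, not bugs in the
estimator; the tests therefore compare estimates not to $A_s$ but to a
Monte-Carlo oracle — the same generator and estimator run at ~70,000 lag
pairs and the same completion probability — and separately require the
*sign* of every strong edge ($|A| \ge 0.2$) to be recovered in at least
95 % of 50 year-length replicates. Strong-edge sizes in the recovery
configuration scale inversely with each state's share of monitored days
(0.25 stable / 0.35 impending / 0.30 full relapse), chosen a priori so
each state's expected pair count gives comfortable sign power. The
replicate-mean estimate per edge is required to sit within ±0.06 of the
oracle; the per-replicate sampling error at a single state's $n$ (about
130–350 pairs) is itself larger than that band, which is why the bias
check averages over replicates.

Calibration is checked the opposite way: with diagonal truth (five
independent symptom processes) the off-diagonal p-values of both methods
are nominal — the fraction below 0.05 stays in [0.03, 0.07] over 200
replicates.

## Numerical and degenerate-input choices

* Likert bounds, the scheduling window, gap bounds, unanswered-but-rated
  rows, and within-day dose changes are validation *errors* with row
  numbers, not warnings.
* A state/symptom cell with no observations is reported as missing, not
  zero; a single observation has a mean but no sd.
* A constant outcome is fit exactly by its intercept: slopes are zero by
  construction and $R^2$ is flagged undefined (the `lm` ratio would be
  0/0 noise).
* Constant or collinear lagged predictors raise an estimation error
  naming the offending column; fewer rows than parameters + 1 likewise.
* Networks that cannot be estimated for one state (too few pairs) are
  marked not estimable in the pipeline report without aborting other
  states.
* Pairwise state contrasts use Welch's t (unequal variances, two-sided,
  no multiplicity correction): group sizes are very unequal by design
  and the descriptive table flags individual cells. The beeps-per-day
  and within-day-sd comparisons are one-way ANOVAs; within-day sd
  requires at least two answered ratings in a day.

## Problem sizes used in the test suite

Unit tests run on hand-built series of a few days. Simulation-based
checks use the study frame (201 monitored days) with 50 replicates for
recovery, 200 for calibration, ~556 single-state days (≈5,000 pairs) for
the de-trending property, 20,000 single-state days for the Monte-Carlo
attenuation oracle, and 200 random 5-node digraphs for oracle
equivalence of the centrality code. These sizes make the full suite run
in well under a minute while leaving Monte-Carlo error far inside each
asserted tolerance.

## Limitations

* The dose→state mapping is the severity proxy; any dose outside the
  configured map is a hard error rather than a guess.
* Betweenness on 5-node weighted digraphs is coarse and tie-sensitive;
  treat it as descriptive.
* Closeness values depend on the coefficient scale; compare them within
  a method and scale, not across studies.
* The pipeline is single-subject by design: no pooling, no multilevel
  structure, no group inference.
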