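---
title: "Graded-response-model scale development: models, diagnostics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graded-response-model scale development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`grmbank` implements the item-response-theory workflow used to build and
refine patient-reported outcome scales from a polytomous item bank:
calibrate Samejima's graded response model (GRM) by marginal maximum
likelihood, screen items for misfit, local dependence and differential item
functioning (DIF), and assemble fixed short forms that trade measurement
precision against content coverage. This vignette explains the model, every
tunable that matters, the numerical choices, and what the package's
simulation-based tests do and do not establish.

## The model

For an item with $C$ ordered categories coded $0,\dots,C-1$, the GRM
specifies cumulative trace lines

$$P^*_{j}(\theta) = \frac{1}{1+\exp[-a(\theta-b_j)]},\qquad j=1,\dots,C-1,$$

with item slope (discrimination) $a>0$ and strictly increasing thresholds
(severities) $b_1<\dots<b_{C-1}$, both in units of the latent trait
$\theta$, which is standardized to mean 0, SD 1 in the reference
population. Category probabilities are differences of adjacent trace lines
($P^*_0\equiv 1$, $P^*_C\equiv 0$), so they always sum to one, and a
respondent at $\theta=b_j$ has exactly probability one half of answering in
category $j$ or above. Item information uses Samejima's closed form
$I(\theta)=\sum_k (P^{*\prime}_k-P^{*\prime}_{k+1})^2/P_k$ with
$P^{*\prime}_k=aP^*_k(1-P^*_k)$; it is additive over items, and test
information $I_T$ converts to a reliability scale as $1-1/I_T$, so
information 10 marks the conventional 0.90 adequacy bar. The unit tests pin
this algebra against a finite-difference Fisher-information oracle.

## Calibration

`fit_grm()` runs Bock–Aitkin EM: the E-step computes each respondent's
posterior over a fixed quadrature grid under the standard-normal
population (which identifies the metric), and the M-step refits each item
by BFGS with analytic gradients on the reparameterized scale
$(\log a,\ b_1,\ \log\Delta b)$, which keeps slopes positive and
thresholds ordered without constraints. Missing responses contribute
nothing to the likelihood — no listwise deletion, no imputation.
Convergence is declared when no parameter moves more than `tol` (default
$10^{-4}$, natural scale) in a cycle; the marginal log-likelihood trace is
stored and tested to be nondecreasing. Start values come from probit
transforms of the observed cumulative proportions.

**Quadrature resolution matters more than is commonly appreciated.** Each
respondent's posterior has SD roughly $1/\sqrt{I_T(\theta)}$; for a
51-item bank of slopes 2–4.5 that is about 0.1. If the node spacing
exceeds this, the discretized likelihood develops ripples whose maximum
can sit visibly away from the generating parameters — and *beat* them on
the discretized likelihood — at realistic sample sizes. The default is
therefore 121 equally spaced nodes on $[-6,6]$ (spacing 0.1), fine enough
that further refinement no longer moves the likelihood; short test banks
use coarser custom grids. The extreme
item "I lost weight without trying" ($b_4=9.39$) lies outside any
practical grid; its top thresholds are estimated with corresponding bias,
which is why recovery tests track a mid-bank item instead.

Unobserved categories abort calibration by default (`on_unobserved =
"error"`); `"collapse"` merges the empty category into its lower neighbour
and fits the item with fewer thresholds. An optional MAP prior (lognormal
on $a$, normal on $b$) is available but off by default, matching the
maximum-likelihood convention of the workflow this package codifies.

Standard errors use the empirical cross-product (outer product of
gradients) approximation to the observed information of the marginal
likelihood. A parametric-bootstrap test keeps it honest (agreement within
25% at $n=600$); the supplemented-EM refinement used by some commercial
software is a documented future hook, not implemented.

## Item fit (S-X²)

`item_fit_sx2()` groups respondents by rest score (summed score excluding
the item), computes model-expected category proportions per group by
integrating the item's trace lines against the Lord–Wingersky summed-score
distribution of the remaining items, and forms a Pearson $X^2$. Adjacent
score groups are merged from the extremes inward until every expected cell
reaches 1 (the classical convention; configurable); degrees of freedom are
(groups)$\times(C-1) - C$. P-values are Benjamini–Hochberg adjusted across
items and flagged at 0.01. Rest scores require complete response vectors;
because complete cases nearly vanish on a 51-item bank with realistic
missingness, `impute = "eap"` optionally fills missing cells with the
deterministic modal category of each respondent's posterior-predictive
distribution (a no-op on complete data). Null simulations put the
unadjusted type-I rate at 0.01 nominal comfortably inside [0.002, 0.03].

A caution discovered while validating the generator: an item driven by a
second dimension ($0.5\theta + 0.866\eta$) is *marginally
indistinguishable* from a genuine low-slope GRM item — mixing a logistic
over an independent normal is again nearly logistic — so S-X² has
essentially no power against it at any realistic $n$. The statistic
detects broken category structure (e.g. scrambled response labels)
powerfully, but "measures something else cleanly" is invisible to it;
dimensionality must be assessed upstream.

## Local dependence

`local_dependence()` compares, for every item pair, the observed joint
category table with the model-implied joint distribution integrated over
the population prior, and reports the approximately standardized value
$(X^2-\mathrm{df})/\sqrt{2\,\mathrm{df}}$ after merging sparse rows and
columns. Pairs at 10 or above are flagged; values in $[5,10)$ are reported
as borderline but never auto-flagged — they may reflect sparseness, and
the retain/remove call belongs to content review. The expected tables
deliberately use the population-marginal distribution, not per-respondent
posterior mixing: the posterior conditions on the very responses under
test and absorbs much of the dependence being tested, costing the
statistic most of its power against testlet-style violations.

## Scale-level fit

`model_fit()` reports $-2\log L$, AIC and BIC via their defining
identities, Cronbach's alpha on the pairwise-available covariance matrix,
marginal reliability (one minus the mean EAP posterior variance), and the
limited-information $M_2$ statistic on univariate plus bivariate margins
with one category dropped per item, with
$\mathrm{RMSEA}=\sqrt{\max(0,(M_2-\mathrm{df})/(\mathrm{df}\cdot n))}$.
The $M_2$ weight matrix is assembled analytically (margin covariances need
up to fourth-order joint probabilities; shared-item entries are corrected
by category-consistent triple products). Published df conventions for
$M_2$ vary across software and rarely match this construction, so the
package treats $M_2$/RMSEA as property-based quantities — under
well-specified simulations RMSEA sits at or near 0 — rather than numbers
to reproduce. For a 51-item five-category bank the margin vector exceeds
20,000 entries and the weight matrix several GB, so $M_2$ is skipped above
a margin cap (default 6,000) and computed for short forms, where it is
most informative.

## Differential item functioning

`dif_scan()` implements the two-group, no-preselected-anchors workflow:
(1) estimate the focal group's latent mean and SD with every item
anchored (shared parameters, reference fixed at N(0,1)); (2) fix those
moments and estimate all item parameters separately per group; (3) per
item, an omnibus Wald $\chi^2$ on the stacked parameter difference
(df $=C$), then for omnibus-significant items constrained slope (df 1) and
threshold (df $C-1$) tests — a significant slope difference means
non-uniform DIF, otherwise a significant threshold difference means
uniform DIF; (4) purify by re-anchoring on the non-flagged items and
repeating until the flagged set stabilizes. If the set oscillates the
union is kept with a warning (the stopping rule had to be chosen; a
stable-set criterion with a 10-iteration cap proved sufficient on every
fixture). All flags use $p<0.01$.

The difference covariance starts as the sum of the two groups' OPG blocks
but subtracts the two common modes of the latent metric (location:
$\partial b/\partial\mu = 1$; scale: $\partial(a,b)/\partial\log\sigma =
(-a,b)$), scaled by $1/n_r + 1/n_f$ and half that, respectively, with a
positive-definiteness guard. The moment-anchoring step aligns the two
groups' metrics, so metric sampling noise cancels in the difference while
each group's own SE still counts it, making the uncorrected omnibus test
conservative. With the correction, the simulated null type-I rate at the
0.01 level falls inside [0.002, 0.03], which the test suite verifies. DIF magnitude is
reported graphically: `group_icc_overlay()` returns both groups' curves
plus a population-weighted area between the expected-score curves; no
effect-size threshold is imposed.

## Short forms

`exclude_flagged()` applies the screening ledger: misfitting items, all
but the best-discriminating member of each locally dependent set, and
DIF-flagged items are set aside; named overrides can re-admit items on
content grounds, and every decision is recorded with its reasons.
`build_form()` codifies two deterministic strategies: *content-first*
walks the content criteria in order, taking the highest-slope eligible
item for each uncovered criterion before filling by slope rank;
*precision-first* takes top-slope items, breaking near-ties (slopes within
0.05) toward uncovered criteria. The 0.05 band makes the content nudge
explicit and testable. The packaged 10-item forms are the published item
lists themselves, not strategy output; strategy-vs-published comparisons
are advisory. `compare_forms()` refits each form and tabulates alpha,
$-2\log L$, AIC, BIC, RMSEA and the test information curve, reporting
$\Delta(-2\log L)$ only between nested forms.

One content-map decision was genuinely open: counting items by the
published criterion rows alone gives the content-prioritizing form 8 of 11
criteria, yet its developers counted 9. The trailing symptom row "withdrew
from others" maps naturally onto the clinically-significant-impairment
criterion (social withdrawal *is* impairment in social functioning), and
with that reading the counts come out 9 and 5 — the package adopts it.
Likewise the map marks "I felt unhappy" for both forms, following the
printed selection grid verbatim even though prose descriptions sometimes
contrast the two forms' mood items. No sleep items exist in the bank, so
the insomnia/hypersomnia criterion is uncoverable by construction.

## The synthetic-data generator

`simulate_study()` emulates the field conditions the diagnostics were
designed for: 825 respondents, a 49/51 two-group split, $\theta\sim
N(0,1)$ in both groups, 5.5% item-level missingness completely at random,
and the packaged 51-item generating parameters. Each item consumes its own
RNG substream, so the injection hooks — a shared testlet factor for local
dependence ($\theta' = (\theta + s\,u)/\sqrt{1+s^2}$, preserving unit
trait variance), threshold shifts and slope ratios for uniform and
non-uniform DIF, and the two misfit mechanisms — alter only the targeted
columns, bit for bit, and every run is reproducible from its seed.

What passing tests show, and what they do not: the generator draws from
the very model the pipeline fits, with MCAR missingness and a normal
population. Real response data bring non-normal trait distributions,
informative missingness, multidimensionality and response styles, none of
which these tests exercise. Recovery and calibration results here validate
the estimator and the diagnostics' null behaviour, not the model's
adequacy for any particular dataset.

## Problem sizes and numerical conventions

Simulation tests run at desk scale, chosen once: type-I suites use 10-item
(S-X²) and 8-item (DIF) banks at $n=1000$–2000 with 50–60 replicates;
power checks use the packaged short-form parameters at $n=2000$; recovery
checks use $n=2000$ (full bank, three seeds) and $n=5000$ (one form).
Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ before logs and
divisions; expected-count collapsing thresholds default to 1; all flags
default to the 0.01 level used throughout the workflow.

## Known limitations

Unidimensional GRM only (no multidimensional trace surfaces, guessing
parameters, or nominal models); two-group DIF only; no linking of
calibrations to external reporting metrics (e.g. T-scores); $M_2$ capped
on long banks; OPG rather than supplemented-EM standard errors; the
response-time filter expects per-response times in seconds and implements
exactly the two fast-responder rules (mean under 1 s, or a run of 10
under 1 s).
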