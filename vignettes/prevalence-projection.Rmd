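---
title: "Projecting chronic-disease prevalence from registry data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting chronic-disease prevalence from registry data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

For a chronic, essentially irreversible disease such as diabetes, three
quantities are linked by bookkeeping alone: the proportion of a birth cohort
that has the disease (prevalence), the probability that a disease-free member
acquires it during a year (cumulative incidence), and the death risks of the
diseased and disease-free parts of the cohort. National registries typically
observe prevalence (e.g. everyone who collected a glucose-lowering drug) and
total mortality, but not incidence. prevcast exploits the bookkeeping in both
directions: it *back-calculates* the incidence that must have occurred during
an observed baseline period, and then *projects* prevalence and patient counts
decades ahead under explicit assumptions about future incidence and survival.

## The recurrence

For one birth cohort and sex, write $p_y$ for the prevalence at the end of
year $y$, $m$ for the death risk of the whole cohort during year $y$, $m_1$
for the death risk of its diseased members, and $i$ for the cumulative
incidence among the disease-free. The end-of-year prevalence is the diseased
survivors plus the year's new cases, per survivor:

$$p_y \;=\; \frac{(1-m_1)\,p_{y-1} \;+\; \big((1-m) - (1-m_1)\,p_{y-1}\big)\, i}{1-m}.$$

The second factor in the numerator is the disease-free pool exposed to
incidence: all survivors minus the diseased survivors. Solving for $i$ gives
the exact inverse used for back-calculation:

$$i \;=\; \frac{(1-m)\,p_y - (1-m_1)\,p_{y-1}}{(1-m) - (1-m_1)\,p_{y-1}}.$$

`forward_prevalence_step()` and `backcalc_incidence()` implement the pair;
the suite verifies the round trip to $10^{-12}$ over ten thousand random
valid inputs. Because both equations work on proportions, every result is
invariant to population scale, which is what licenses applying a
closed-cohort identity to an open national population: migrants are assumed
to carry the prevalence of the cohort they join (an explicit, switchable
assumption — see below).

Note the placement of the division by $1-m$: the entire right-hand side is
divided by total survival. This is the unique reading under which the
inversion formula above is the exact algebraic inverse, which we verified
symbolically; implementations that divide only the second term do not invert
correctly.

## Closing the mortality model

Registries publish the *total* death risk $m$, while the recurrence needs
$m_1$. prevcast closes the gap with a relative mortality risk $rr$ for the
diseased, combined with the mixture identity
$p\,m_1 + (1-p)\,m_0 = m$ (`diabetic_death_risk()`). Two conventions are
supported for what $rr$ refers to:

* `vs_nondiabetic` (default): $m_1 = rr\,m_0$; the identity is solved
  exactly, so the population mortality budget is conserved by construction.
* `vs_total`: $m_1 = rr\,m$ directly; $m_0$ absorbs the remainder. This can
  become inconsistent when $p\,rr > 1$, which is reported as an error.

Published estimates say the *relative excess mortality* of diabetes declines
by about 1.6% per year. That phrase is ambiguous between two trends, so both
are implemented (`excess_mortality_model()`):

* `excess` (default): $rr(t) = 1 + (rr_0 - 1)(1-d)^t$ — the excess shrinks,
  $rr$ approaches but never crosses 1. We default to this convention because
  it remains meaningful over a 37-year horizon; the alternative drives $rr$
  below 1 (diseased outliving the disease-free), which no published estimate
  supports.
* `ratio`: $rr(t) = \max(rr_0(1-d)^t, 1)$ — the ratio itself shrinks,
  floored at 1.

The model carries a `reference_year`; negative elapsed times are used
internally so that baseline years before the anchor see the appropriately
*higher* historical relative risk.

## Demographic bookkeeping

Tables are tidy `(year, sex, age, value)` with single-year ages 20–100, the
top age being an absorbing "100 and above" pool (the bounded-array choice;
survivors of ages 99 and 100 merge, and the merged cohort's prevalence is the
survivor-weighted mean of the two). Counts are start-of-year; prevalence is
end-of-year; case counts multiply end-of-year cohort prevalence by
start-of-year denominators, matching how prescription registries report
prevalence. `advance_cohorts()` implements
$N(y{+}1, a{+}1) = N(y, a)(1 - m(y, a)) + M(y{+}1, a{+}1)$ with entrants
filling age 20, and conserves people exactly.

Two deliberately exposed assumptions, both unidentifiable from registry
prevalence alone:

* **Migrants** join with their cohort's prevalence (default `match`, which
  preserves population-size invariance) or disease-free (`zero`, for
  sensitivity runs).
* **Entrant cohorts** at age 20 receive the base-year age-20 prevalence
  scaled by the cumulative incidence-trend factor, so an incidence scenario
  also moves the young end of the surface; `entrant_scaling = FALSE` turns
  the scaling off.

## Scenarios, decomposition, and the flat-prevalence solver

`build_scenario()` encodes the standard grid: A (incidence constant,
relative mortality declining), B (+1%/yr incidence), C (−1%/yr), D (relative
risk frozen; general-population mortality still improves through the
mortality schedule). The incidence trend is a uniform multiplicative factor
$(1+\tau)^t$ applied to every age/sex cell, with $t$ counted from the base
year (the first projected year has $t = 1$); age-specific trends can be
supplied by editing the incidence surface itself.

`decompose_increase()` attributes the projected case increase to drivers by
counterfactual substitution: rescale the final-year population total to the
base-year total (population size), replace the final-year age/sex composition
with the base-year one (age structure), freeze the relative-mortality trend
(relative survival). Components are telescoping differences along a recorded
substitution order, so they and the residual (mostly falling general-population
mortality propagated through the recurrence) sum to the total increase
exactly. Because the drivers are not mutually exclusive, the order matters;
a Shapley-style mode averages each driver's marginal contribution over all
six orders.

`required_incidence_decline()` finds the constant annual incidence decline
$\delta$ that makes total adult prevalence (both sexes combined — the usual
headline metric) at the horizon equal its base-year value. Projected horizon
prevalence is monotone decreasing in $\delta$, so bisection on $[0, 0.2]$ is
valid; iterations stop when the prevalence gap is below $10^{-6}$ (absolute,
proportion scale), and the full trace is returned. If prevalence does not
rise even with no decline, the answer is 0.

## The synthetic country and its oracle

No national inputs ship with the package, so `generate_country()` builds a
self-contained substitute with known ground truth (it is labelled synthetic
throughout and makes no claim to reproduce any real forecast):

* **Population**: 7.5 million adults, a stable-population pyramid
  (survivorship discounted at 0.4%/yr growth), entrants growing 0.3%/yr, and
  Gaussian-profile net in-migration peaking near age 32 at 0.4% of a cohort.
* **Mortality**: Gompertz risks per sex (about $2\times10^{-4}$ at age 20
  rising to ~0.2 at 100+, women lower), improving 1%/yr over calendar time.
* **Incidence**: log-linear in age (5.5%/yr of age) with sex-specific levels
  and small seeded log-normal cell noise (sd 0.03) so the inverse problem is
  not artificially smooth.
* **Relative risk**: $1 + 3.5\,e^{-0.035(a-20)}$ — high in young adults,
  near 1.2 at the oldest ages — declining 1.6%/yr under the `excess`
  convention.
* **Prevalence**: a logistic-in-age curve plus a small age-flat young-adult
  component at the first baseline year (2007), then generated *forward*
  through the recurrence to 2013. Generating prevalence from incidence
  (never the reverse) makes back-calculation a genuine inverse problem; the
  suite requires recovery of every identifiable cell to $10^{-10}$.

The free curve parameters were calibrated once so the 2013 banded
prevalences (20–44 / 45–64 / 65+, by sex and total) sit within ±20% of
published Swedish registry values (e.g. 12.8% of women and 18.8% of men 65+)
and the overall incidence lands near 4.4 per 1000 disease-free adults; the
defaults are frozen in `synthetic_spec()`.

`microsimulate()` is the stochastic oracle: persons are allocated to
age/sex cells by largest-remainder rounding of the base-year composition
(deterministic, so the only randomness is in disease status and events),
then simulated yearly with exactly the transition risks the deterministic
projection applied (`project(..., keep_rates = TRUE)`): diseased die with
$m_1$, disease-free with $m_0$, and disease-free *survivors of the year*
acquire the disease with $i$ — the same within-year ordering as the
recurrence, so the deterministic path is the simulation's expectation. The
acceptance suite runs a closed cohort of 200 000 persons for 30 years and
requires agreement within 3 binomial standard errors at ≥95% of yearly
checkpoints.

What the synthetic country does *not* emulate: reporting noise and
ascertainment changes in real registries, migration waves with atypical
disease risk, diabetes-type structure, cohort effects in incidence, and any
actual national forecast vintage. Tests passing on it demonstrate the
*mechanics* — exact inversion, conservation, scenario ordering, additive
attribution — not the accuracy of any specific national projection.

## Numerical choices and degenerate inputs

* Back-calculated incidence may legitimately come out negative when observed
  prevalence falls faster than mortality explains; it is preserved and
  flagged (never silently clamped) in `estimate_baseline()`, while
  projections clamp incidence at 0.
* The back-calculation cannot identify the entry age (no previous-year link)
  or the absorbing 100+ bin (cohorts merge); those cells are skipped and
  `extend_incidence()` fills boundary ages by nearest-age value before
  projecting.
* A death risk of 1, an empty disease-free pool, or diseased survivors
  exceeding total survivors raise informative errors rather than NaNs.
* Scenario D freezes the *relative* risk; the general-population mortality
  schedule keeps improving, so diseased mortality still falls in absolute
  terms.
* The bisection bracket defaults to $[0, 0.2]$; a gap still positive at the
  upper end is reported as a bracket error with the residual gap, and gaps
  within tolerance at $\delta = 0$ return 0 immediately.

## Problem sizes used in the test suite

The unit tests run on 2–11-age toy cohorts over 2–10 years, where every
expected value is hand-evaluated or brute-forced in the test itself. The
heavier checks use the default synthetic country (81 ages × 2 sexes,
2007–2050): full-horizon projections for the four scenarios, decomposition
at the 2050 horizon, the flat-prevalence solver against a $10^{-4}$-resolution
grid-search oracle on a toy, and the 200 000-person, 30-year
microsimulation. The whole suite completes in roughly two minutes on one
CPU.

## Limitations

The model is a discrete-time, single-disease illness–death recurrence: no
remission, no disease-type structure, no duration dependence of mortality
(only age, sex and calendar trend), and incidence scenarios are uniform
multiplicative trends unless the user edits the surface. Attribution shares
depend on the substitution order (reported, with a Shapley option), and the
undiagnosed-disease adjustment (`apply_undiagnosed()`) is a post-hoc
multiplier under an explicitly declared convention, not a model of detection.
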