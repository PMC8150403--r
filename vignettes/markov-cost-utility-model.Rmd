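---
title: "A three-state Markov cost-utility model for guided iCBT in depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state Markov cost-utility model for guided iCBT in depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icbtcea)
library(ggplot2)
```

## The decision problem

Guided internet-based cognitive behavioural therapy (iCBT) for major
depressive disorder costs money to implement and deliver; it also moves
patients out of depression faster than usual care. Whether that trade-off
is worth paying for is a cost-utility question: how many euros does the
programme cost per quality-adjusted life-year (QALY) gained, and does that
price fall under the willingness-to-pay (WTP) threshold a decision-maker
accepts (30,000 EUR/QALY in the shipped case study)?

`icbtcea` answers it with a discrete-time Markov cohort model over three
health states:

* **remission** — PHQ-9 total score below 10,
* **depression** — PHQ-9 score of 10 or more,
* **death** — absorbing.

A cohort enters the model all-depressed at age 46 and is evolved in 1-year
cycles until age 100 (54 cycles). Each cycle, people may *recover*
(depression to remission), *relapse* (remission to depression), or die.
Background mortality comes from a sex-stratified annual life table;
depressed person-years carry an excess mortality expressed as a relative
risk (1.68 in the case study), applied on the hazard scale:

$$q_{\text{adj}}(x) = 1 - \bigl(1 - q(x)\bigr)^{\mathrm{RR}}.$$

The hazard-scale form is used rather than multiplying $q$ because a
multiplied probability can exceed 1 at old ages, while a scaled hazard
cannot; it also matches the epidemiological meaning of a mortality relative
risk.

## Transition structure

Death is resolved first within each cycle; recovery and relapse apply only
to survivors. With per-state death probabilities $q_{\text{rem}}$ and
$q_{\text{dep}}$ at the cohort's current age, the one-cycle matrix over
(remission, depression, dead) is

$$
P =
\begin{pmatrix}
(1-q_{\text{rem}})(1-p_{\text{rel}}) & (1-q_{\text{rem}})\,p_{\text{rel}} & q_{\text{rem}}\\
(1-q_{\text{dep}})\,p_{\text{rec}} & (1-q_{\text{dep}})(1-p_{\text{rec}}) & q_{\text{dep}}\\
0 & 0 & 1
\end{pmatrix}.
$$

The death-first ordering is a modelling choice: the underlying sources
specify annual transition probabilities and annual mortality but not their
within-cycle interaction. Resolving mortality first is the common
state-transition convention and keeps every row stochastic by construction.

Sexes are handled by evolving two cohorts — identical except for the life
table — and aggregating occupancy by the female fraction (0.681 in the case
study). Because everything except mortality is shared, this stratification
is exact; a `sex_mode = "mixture"` switch instead mixes the death
probabilities by the female fraction before evolving a single cohort, which
is the cruder approximation some tools use.

## Rewards, costing, and discounting

Rewards accrue on **end-of-cycle occupancy**: the QALYs and costs
attributed to cycle $t\in\{1,\dots,N\}$ use the state distribution after
$t$ transitions, and no half-cycle correction is applied. Per cycle and per
patient:

* QALYs: $u_{\text{rem}}\cdot\text{rem}(t) + u_{\text{dep}}\cdot\text{dep}(t)$;
* healthcare costs: per-state annual healthcare costs weighted by occupancy,
  plus the recurring intervention delivery cost for every alive person-year
  of the intervention arm;
* societal perspective: healthcare costs plus per-state annual productivity
  losses (implemented additively);
* the one-off implementation cost is charged once at cycle 0 and never
  discounted.

Discounting multiplies the cycle-$t$ reward by $(1+r)^{-t}$, with separate
rates for costs and effects (both 3\%/yr in the base case). The reward
convention and the position of the first discount factor are exactly the
kind of internals that hosted modelling tools leave undocumented; the
choices above are pinned, logged in every run manifest, and — as the
package's own validation shows — move lifetime results by at most a few
percent. They are one identified reason why published figures produced with
such a tool can only be matched approximately (see *Limitations*).

The incremental cost-effectiveness ratio is
$\mathrm{ICER} = \Delta C / \Delta E$, left undefined when
$|\Delta E| < 10^{-9}$. Dominance is classified by the cost-effectiveness
plane quadrant, and the intervention is called cost-effective when it
dominates, or sits in the NE quadrant with ICER at most the WTP, or in the
SW quadrant with ICER at least the WTP.

## Case-study parameters

The shipped configuration (`inst/extdata/superat.yaml`) encodes the
published input table of the case study: control recovery 29\%/yr and
relapse 14\%/yr versus intervention recovery 48.53\%/yr and relapse 0;
utilities 0.62/0.532 (control remission/depression) and 0.665/0.529
(intervention); one-off cost 395.26 EUR and recurring cost 2439 EUR/yr for
the intervention arm only; shared annual state costs of 451/826 EUR
(healthcare) and 991/1842 EUR (productivity losses); mortality RR 1/1.68.
The intervention's recovery probability and utilities derive from the
trial's paired baseline/post PHQ-9 measurements; `estimate_recovery_prob()`
and `utility_from_scores()` reproduce that pipeline for datasets that do
carry per-patient records (severity categories use the standard 10/15/20
cutoffs, and per-category utilities are collapsed to state utilities by a
count-weighted average).

## The life table

No per-country life-table extract is shipped. Instead the default fixture is
a synthetic Gompertz–Makeham table: the hazard at age $t$ is
$m(t) = c + a e^{bt}$ and the annual death probability integrates it over
the year,

$$q(x) = 1 - \exp\!\Bigl(-c - \tfrac{a}{b}\bigl(e^{b(x+1)} - e^{bx}\bigr)\Bigr),$$

so that the product of annual survival probabilities coincides exactly with
the closed-form survivor function. The per-sex parameters are fitted once so
that remaining life expectancy at age 46 is 37 years for women
($a = 9.554\times10^{-6}$, $b = 0.105$, $c = 2\times10^{-4}$) and 33 years
for men ($a = 2.101\times10^{-5}$, $b = 0.100$, $c = 5\times10^{-4}$) —
adult survival in line with what the case-study cohort implies. Real tables
load through `read_life_table()`, which accepts a plain `age,sex,qx` CSV and
the whitespace-delimited period-table text layout used by the Human
Mortality Database (open-ended `110+` rows close the table at that age with
$q = 1$). Ages beyond the table maximum return $q = 1$; the horizon is
capped at 100 anyway.

## Worked example

```{r base-case}
setup <- load_config(system.file("extdata", "superat.yaml", package = "icbtcea"))
fit <- run_base_case(setup)
tidy(fit)
```

All four variants (two perspectives, discounted and nondiscounted) land in
the NE quadrant — the programme buys QALYs at extra cost — with every ICER
under the 30,000 EUR/QALY threshold.

```{r ce-plane, fig.width = 6, fig.height = 4}
autoplot(fit)
```

## Deterministic sensitivity analyses

Both published scenarios are implemented, nondiscounted for costs as in the
original analysis:

```{r sweeps, fig.width = 6, fig.height = 4}
lt <- config_life_table(setup)
sw <- sweep_session_cost(setup$control, setup$intervention, setup$config, lt,
                         "healthcare")
autoplot(sw)
```

* **Session-cost reduction** (0–25\%): the recurring cost scales by
  $(1-x)$; the incremental effect is untouched, so the ICER is affine and
  decreasing in $x$, and a given reduction lowers both perspectives' ICERs
  by the same euro amount (the tests verify this identity to $10^{-6}$).
* **Effect discount rate** (0–5\%/yr, costs undiscounted): $\Delta C$ is
  constant across the sweep, so where the ICER crosses the WTP threshold
  the incremental effect is exactly $\Delta C/\mathrm{WTP}$;
  `wtp_intersection()` finds the crossing rate by bisection on the monotone
  rate-to-effect map, re-evaluating the full cohort model until the effect
  matches to $10^{-6}$.

Default grids are 26 points (by 1 percentage point) and 51 points (by 0.1
percentage point): fine enough for smooth plots, cheap enough to re-evaluate
the full model at every point.

## Validation design

Two independent routes guard the cohort engine:

* **Hand oracles**: two-cycle occupancies are checked against explicitly
  hand-multiplied matrices; degenerate setups (zero mortality, no relapse)
  have closed forms (geometric decay of the depressed fraction).
* **Microsimulation**: `microsimulate()` walks individuals through the same
  age-dependent matrices by categorical sampling. Its sample means are
  unbiased for the cohort model's occupancy and lifetime rewards, so
  agreement within three Monte-Carlo standard errors at $n = 10^5$ on the
  intervention, control, and a randomized configuration is a strong
  end-to-end check. Standard errors must also shrink like $1/\sqrt n$.

The synthetic PHQ-9 generator closes the loop on the estimation pipeline:
cohorts generated with a known remission probability $\theta$ must be
recovered by `estimate_recovery_prob()` within its Wilson 95\% interval at
the nominal coverage rate (93+ of 100 seeded replicates at $n = 5000$).

### What the synthetic data does not emulate

The generator draws baseline severities from a configured case-mix
(default 50\% mild / 35\% moderate / 15\% severe, a typical primary-care
referral mix; the published baseline table does not report the split) with
scores uniform within category, and post scores uniform within the target
state. Real PHQ-9 trajectories are neither uniform within category nor
independent of baseline severity; remission probability in practice falls
with baseline severity. None of this affects the transition estimates the
model consumes — they only see the dichotomised state — but utilities
estimated from generated scores should not be read as realistic, and
passing tests say nothing about, e.g., severity-dependent treatment effects.

## Numerical choices and degenerate inputs

* Occupancy vectors are required to stay on the probability simplex to
  $10^{-12}$ per cycle; the dead fraction must be nondecreasing.
* ICERs are reported unrounded; display rounding is left to the caller.
* An undefined ICER ($|\Delta E| < 10^{-9}$) yields `NA` and the
  `indifferent`/`dominant`/`dominated` classes handle the axes of the CE
  plane with a $10^{-9}$ tolerance.
* Terminal table ages force $q = 1$ regardless of relative risk
  ($1-(1-1)^{\mathrm{RR}} = 1$), so cohorts cannot outlive the table.
* Config validation collects *all* violations before failing, and unknown
  keys are rejected by name, so a typo cannot silently fall back to a
  default.

## Limitations

* The published case-study results were produced with a hosted modelling
  tool whose cycle/reward conventions are not documented; with the pinned
  conventions and the synthetic life table this package reproduces the
  published incremental costs and effects to within about 8\%, but the
  published ICERs are 9–15\% above the recomputed ones. The gap is
  structural, not a calibration issue: the published incremental values
  jointly imply that the usual-care cohort spent roughly a quarter of its
  living person-years depressed, whereas recovery 29\%/yr with relapse
  14\%/yr yields at least ~31\% under any reward convention. The package
  reports what the stated inputs produce.
* One-year cycles cannot represent within-year relapse-recovery churn; the
  annual probabilities absorb it.
* No probabilistic sensitivity analysis is implemented (the case study
  performed none); the deterministic sweeps are the only uncertainty
  analysis.
* Utilities enter as constants per state and arm; no EQ-5D mapping
  regression is provided, only the severity-category weighted average.

## Problem sizes used in the shipped checks

The validation suite runs the full 54-cycle model everywhere; the
microsimulation checks use $n = 10^5$ individuals per arm, chosen so that
Monte-Carlo standard errors are small enough to detect sub-percent engine
errors, and the parameter-recovery study uses 100 replicates of
$n = 5000$. All of it completes in a few minutes on a single CPU.
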