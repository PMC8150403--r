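# icbtcea

Cost-utility analysis of a guided internet-based cognitive behavioural
therapy (iCBT) programme for major depressive disorder, as a reusable,
tested R package. It is aimed at health-economics and psychiatry
researchers who want a transparent, scriptable counterpart to hosted
Markov-modelling tools: every convention (cycle rewards, discounting,
mortality adjustment) is explicit, logged, and covered by tests.

## The model

A discrete-time Markov cohort model over three states — *remission*
(PHQ-9 < 10), *depression* (PHQ-9 ≥ 10), and absorbing *death* — evolved in
1-year cycles from age 46 to 100. With annual recovery probability
p_rec, relapse probability p_rel, and age- and state-specific death
probabilities q_s, the one-cycle matrix resolves death first:

    P(dep -> rem)  = (1 - q_dep) * p_rec        P(rem -> dep) = (1 - q_rem) * p_rel
    P(dep -> dead) = q_dep                      P(dead -> dead) = 1

Background mortality comes from a sex-stratified annual life table (CSV or
HMD-style text, or a synthetic Gompertz–Makeham table); depression carries a
mortality relative risk applied on the hazard scale,
`q_adj = 1 - (1 - q)^RR`. Lifetime QALYs and costs (healthcare and societal
perspectives) accrue on end-of-cycle occupancy, discounted by `(1+r)^-t`,
and arms are compared by the incremental cost-effectiveness ratio
`ICER = ΔC / ΔE` against a willingness-to-pay threshold (30,000 EUR/QALY).
Two deterministic sensitivity analyses are built in: a session-cost
reduction sweep (0–25%) and an effect-discount-rate sweep (0–5%/yr) with
willingness-to-pay intersection finding. A seeded individual-level
microsimulation and a synthetic PHQ-9 cohort generator validate the engine
and the estimation pipeline end to end.

## Worked example

```r
library(icbtcea)

setup <- load_config(system.file("extdata", "superat.yaml", package = "icbtcea"))
fit <- run_base_case(setup)
tidy(fit)
#> # A tibble: 4 x 7
#>   perspective discounting   delta_cost delta_qaly   icer dominance cost_effective
#>   <chr>       <chr>              <dbl>      <dbl>  <dbl> <chr>     <lgl>
#> 1 healthcare  discounted        49336.       1.85 26690. NE        TRUE
#> 2 healthcare  nondiscounted     83931.       3.57 23498. NE        TRUE
#> 3 societal    discounted        44518.       1.85 24084. NE        TRUE
#> 4 societal    nondiscounted     76532.       3.57 21427. NE        TRUE
```

Each row is one perspective/discounting variant: the intervention costs
`delta_cost` euros more per patient over the lifetime horizon, gains
`delta_qaly` quality-adjusted life-years, and the ICER is their ratio. `NE`
means the north-east quadrant of the cost-effectiveness plane (more
effective, more costly); `cost_effective` compares the ICER with the
configured 30,000 EUR/QALY threshold — here the guided iCBT programme is
cost-effective in all four variants. `autoplot(fit)` draws the
cost-effectiveness plane; `sweep_session_cost()`, `sweep_effect_discount()`
and `wtp_intersection()` run the sensitivity analyses
(`vignette("markov-cost-utility-model")` walks through the science).

A thin command-line wrapper ships in `inst/cli/cea.R`:

```sh
Rscript inst/cli/cea.R run --config superat.yaml --out results/
Rscript inst/cli/cea.R sweep --which effect-discount --out results/
```

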