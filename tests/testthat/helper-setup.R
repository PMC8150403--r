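# Shared fixtures, all built in code.

# The shipped case-study setup (arms, config, synthetic life table).
case_setup <- function() {
  load_config(system.file("extdata", "superat.yaml", package = "icbtcea"))
}

# A zero-mortality life table: nobody dies until the terminal closure age.
immortal_table <- function(max_age = 110, sex = "female") {
  life_table(0:max_age, c(rep(0, max_age), 1), sex, source = "synthetic")
}

# A small constant-q table for hand calculations.
flat_table <- function(q, max_age = 110, sex = "female") {
  life_table(0:max_age, c(rep(q, max_age), 1), sex, source = "synthetic")
}

# Closed-form Gompertz-Makeham survivor function from age x0 to x.
gm_surv <- function(x, x0, a, b, c) {
  exp(-(c * (x - x0) + a / b * (exp(b * x) - exp(b * x0))))
}

# A generic intervention-like and control-like arm pair with shared state costs.
test_arms <- function() {
  list(
    intervention = arm_spec("intervention", p_recover = 0.4853, p_relapse = 0,
                            u_remission = 0.665, u_depression = 0.529,
                            cost_oneoff = 395.26, cost_recurring = 2439,
                            cost_healthcare = c(remission = 451, depression = 826),
                            cost_societal = c(remission = 991, depression = 1842)),
    control = arm_spec("control", p_recover = 0.29, p_relapse = 0.14,
                       u_remission = 0.62, u_depression = 0.532,
                       cost_healthcare = c(remission = 451, depression = 826),
                       cost_societal = c(remission = 991, depression = 1842))
  )
}

# Random but valid arm and config, for property-style tests.
random_arm <- function() {
  arm_spec("random",
           p_recover = stats::runif(1), p_relapse = stats::runif(1),
           u_remission = stats::runif(1), u_depression = stats::runif(1),
           cost_oneoff = stats::runif(1, 0, 1000),
           cost_recurring = stats::runif(1, 0, 3000),
           cost_healthcare = c(remission = stats::runif(1, 0, 1000),
                               depression = stats::runif(1, 0, 2000)),
           cost_societal = c(remission = stats::runif(1, 0, 1000),
                             depression = stats::runif(1, 0, 2000)))
}

random_config <- function(...) {
  model_config(start_age = sample(30:60, 1), horizon_age = sample(90:105, 1),
               female_fraction = stats::runif(1),
               discount_cost = stats::runif(1, 0, 0.05),
               discount_effect = stats::runif(1, 0, 0.05),
               rr_mortality = c(remission = 1, depression = stats::runif(1, 1, 3)),
               ...)
}
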