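test_that("zero discount rates make discounted and nondiscounted totals identical", {
  arms <- test_arms()
  cfg <- model_config(discount_cost = 0, discount_effect = 0)
  traj <- run_cohort(arms$intervention, cfg, fixture_life_table())
  for (p in c("healthcare", "societal")) {
    acc <- accumulate_outcomes(traj, p)
    expect_equal(acc$cost[1], acc$cost[2])
    expect_equal(acc$qalys[1], acc$qalys[2])
  }
})

test_that("a single cycle discounts the end-of-cycle reward by one year", {
  arm <- arm_spec("a", p_recover = 0, p_relapse = 0,
                  u_remission = 0.665, u_depression = 0.529)
  cfg <- model_config(start_age = 46, horizon_age = 47, discount_effect = 0.03)
  traj <- run_cohort(arm, cfg, immortal_table())
  acc <- accumulate_outcomes(traj, "healthcare")
  expect_equal(acc$qalys[acc$discounting == "discounted"], 0.529 / 1.03)
  expect_equal(acc$qalys[acc$discounting == "nondiscounted"], 0.529)
})

test_that("per-cycle healthcare cost weights state costs by occupancy", {
  arms <- test_arms()
  traj <- run_cohort(arms$control, model_config(), fixture_life_table())
  # control: no one-off, no recurring -> pure state costs
  expect_equal(traj$cost_healthcare[-1],
               (451 * traj$remission + 826 * traj$depression)[-1])
  expect_equal(traj$cost_intervention, rep(0, nrow(traj)))
  # intervention adds the recurring cost on every alive person-year and the
  # one-off at cycle 0
  ti <- run_cohort(arms$intervention, model_config(), fixture_life_table())
  expect_equal(ti$cost_intervention[1], 395.26)
  expect_equal(ti$cost_intervention[-1],
               (2439 * (ti$remission + ti$depression))[-1])
})

test_that("the one-off cost enters once, undiscounted, at model start", {
  arms <- test_arms()
  cfg <- model_config(discount_cost = 0.03)
  traj <- run_cohort(arms$intervention, cfg, fixture_life_table())
  acc <- accumulate_outcomes(traj, "healthcare")
  no_oneoff <- arms$intervention
  no_oneoff$cost_oneoff <- 0
  acc0 <- accumulate_outcomes(run_cohort(no_oneoff, cfg, fixture_life_table()), "healthcare")
  expect_equal(acc$cost - acc0$cost, rep(395.26, 2))
})

test_that("comparisons compute increments, the ICER, and dominance classes", {
  arms <- test_arms()
  cfg <- model_config()
  lt <- fixture_life_table()
  acc_i <- accumulate_outcomes(run_cohort(arms$intervention, cfg, lt), "healthcare")
  acc_c <- accumulate_outcomes(run_cohort(arms$control, cfg, lt), "healthcare")
  res <- compare_arms(acc_i, acc_c, wtp = 30000)
  expect_equal(res$icer * res$delta_qaly, res$delta_cost, tolerance = 1e-9)
  expect_equal(res$dominance, c("NE", "NE"))

  # identical arms: indifferent, ICER undefined
  self <- compare_arms(acc_c, acc_c)
  expect_true(all(is.na(self$icer)))
  expect_equal(self$dominance, c("indifferent", "indifferent"))

  # direct division oracle
  fake <- acc_c
  fake$cost <- acc_c$cost + 50924.53
  fake$qalys <- acc_c$qalys + 1.734
  oracle <- compare_arms(fake, acc_c)
  expect_equal(oracle$icer, rep(50924.53 / 1.734, 2))

  # cheaper and more effective: dominant, cost-effective at any threshold
  cheap <- acc_c
  cheap$cost <- acc_c$cost - 100
  cheap$qalys <- acc_c$qalys + 0.5
  dom <- compare_arms(cheap, acc_c, wtp = 1)
  expect_equal(dom$dominance, rep("dominant", 2))
  expect_true(all(dom$cost_effective))

  # mismatched accumulations are refused
  acc_s <- accumulate_outcomes(run_cohort(arms$control, cfg, lt), "societal")
  expect_error(compare_arms(acc_i, acc_s), "perspective")
})

test_that("societal costs are healthcare costs plus nonnegative productivity losses", {
  arms <- test_arms()
  cfg <- model_config()
  lt <- fixture_life_table()
  for (arm in arms) {
    traj <- run_cohort(arm, cfg, lt)
    hc <- accumulate_outcomes(traj, "healthcare")
    so <- accumulate_outcomes(traj, "societal")
    expect_true(all(so$cost >= hc$cost))
    expect_equal(so$qalys, hc$qalys)
  }
})

test_that("discounted totals fall monotonically in the discount rate", {
  arms <- test_arms()
  lt <- fixture_life_table()
  rates <- c(0, 0.01, 0.03, 0.05, 0.08)
  prev_cost <- Inf; prev_q <- Inf
  for (r in rates) {
    cfg <- model_config(discount_cost = r, discount_effect = r)
    acc <- accumulate_outcomes(run_cohort(arms$intervention, cfg, lt), "societal")
    cost_d <- acc$cost[acc$discounting == "discounted"]
    q_d <- acc$qalys[acc$discounting == "discounted"]
    expect_lte(cost_d, prev_cost); expect_lte(q_d, prev_q)
    prev_cost <- cost_d; prev_q <- q_d
  }
})

test_that("lifetime cost responds affinely to each unit-cost parameter", {
  arms <- test_arms()
  cfg <- model_config()
  lt <- fixture_life_table()
  cost_at <- function(recurring) {
    arm <- arms$intervention
    arm$cost_recurring <- recurring
    acc <- accumulate_outcomes(run_cohort(arm, cfg, lt), "healthcare")
    acc$cost[acc$discounting == "nondiscounted"]
  }
  c0 <- cost_at(0); c1 <- cost_at(1000); c2 <- cost_at(2000)
  expect_equal(c2 - c1, c1 - c0, tolerance = 1e-9)
})

test_that("cost-effectiveness-plane points sit below the WTP line iff ICER <= WTP", {
  arms <- test_arms()
  cfg <- model_config()
  lt <- fixture_life_table()
  res <- compare_arms(
    accumulate_outcomes(run_cohort(arms$intervention, cfg, lt), "healthcare"),
    accumulate_outcomes(run_cohort(arms$control, cfg, lt), "healthcare")
  )
  pts <- ce_plane_points(res)
  expect_equal(nrow(pts), 2)
  expect_equal(pts$below_wtp_line, pts$icer <= pts$wtp)
  # order-preserving mapping
  expect_equal(pts$discounting, res$discounting)
  expect_error(ce_plane_points(res[0, ]), "empty")
  expect_s3_class(ggplot2::autoplot(res), "ggplot")
})
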