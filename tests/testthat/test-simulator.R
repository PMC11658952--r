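test_that("energy balance at baseline gives a flat trajectory", {
  s <- ref_subject()
  ei_bal <- balancing_intake(s)
  expect_equal(rhs(0, 93.31, s, constant_intake(ei_bal)), 0,
               tolerance = 1e-12)
  traj <- simulate_weight(s, constant_intake(ei_bal), weeks = 6)
  expect_equal(traj$weight, rep(93.31, nrow(traj)), tolerance = 1e-9)
  # and the rhs sign convention: intake below expenditure -> weight falls
  expect_lt(rhs(0, 93.31, s, constant_intake(ei_bal - 100)), 0)
})

test_that("the 7700 kcal/kg conversion is exact in a degenerate config", {
  # freeze REE at a constant (zero slope), switch off AT and DIT; a fixed
  # 1100 kcal/d deficit must lose exactly 1 kg in 7 days
  cfg <- model_config(at_ceiling = 0, dit_coeff = 0,
                      cunningham_intercept = 1900, cunningham_slope = 0)
  s <- subject_baseline(93.31, "female", pal = 1.2, ei0 = 0)
  # pal multiplies the frozen REE: TEE = 1.2 * 1900 = 2280
  traj <- simulate_weight(s, constant_intake(2280 - 1100), weeks = 1,
                          config = cfg)
  expect_equal(traj$weight[1] - traj$weight[nrow(traj)], 1100 * 7 / 7700,
               tolerance = 1e-8)
})

test_that("adaptive solver agrees with the independent Euler oracle", {
  s <- ref_subject()
  # constant prescription, 8 weeks
  traj8 <- simulate_weight(s, constant_intake(800), weeks = 8)
  oracle8 <- euler_oracle(93.31, 1.6, function(t) 800, days = 56)
  expect_lt(abs(traj8$weight[nrow(traj8)] - oracle8), 0.005)
  # stepped prescription across the week-10 switch, 12 weeks
  traj12 <- simulate_weight(s, step_intake(), weeks = 12)
  oracle12 <- euler_oracle(93.31, 1.6, ll_ei, days = 84)
  expect_lt(abs(traj12$weight[nrow(traj12)] - oracle12), 0.005)
  # refined variant too
  trajr <- simulate_weight(s, constant_intake(800), weeks = 8,
                           config = model_config("refined"))
  oracler <- euler_oracle(93.31, 1.6, function(t) 800, days = 56,
                          variant = "refined")
  expect_lt(abs(trajr$weight[nrow(trajr)] - oracler), 0.005)
})

test_that("end-weight is stable across solver tolerances", {
  s <- ref_subject()
  ends <- vapply(c(1e-6, 1e-7, 1e-8), function(tol) {
    traj <- simulate_weight(s, step_intake(), weeks = 12,
                            rtol = tol, atol = tol)
    traj$weight[nrow(traj)]
  }, numeric(1))
  expect_lt(max(ends) - min(ends), 0.001)  # < 1 g over two orders
})

test_that("trajectory satisfies energy conservation and shape invariants", {
  s <- ref_subject()
  for (cfg in list(model_config("original"), model_config("refined"))) {
    traj <- simulate_weight(s, step_intake(), weeks = 12, config = cfg)
    expect_lt(abs(energy_closure(traj, cfg)), 0.001)
    # weight non-increasing while in deficit; grid strictly increasing
    expect_true(all(diff(traj$weight) <= 0))
    expect_true(all(diff(traj$t) > 0))
    expect_identical(traj$t[1], 0)
    expect_equal(traj$weight[1], 93.31)
    # all expenditure components non-negative
    expect_true(all(traj$ree_net >= 0 & traj$at >= 0 &
                      traj$paee >= 0 & traj$dit >= 0))
    # deceleration: week-over-week loss non-increasing after week 1
    # under constant intake
    trc <- simulate_weight(s, constant_intake(800), weeks = 12,
                           config = cfg)
    wk <- weekly_weights(trc)
    losses <- -diff(c(93.31, wk$weight))
    expect_true(all(diff(losses) <= 1e-6))
  }
})

test_that("refined model predicts slower loss than the original", {
  s <- ref_subject()
  for (wks in c(6, 9, 12)) {
    orig <- simulate_weight(s, step_intake(), weeks = wks,
                            config = model_config("original"))
    refi <- simulate_weight(s, step_intake(), weeks = wks,
                            config = model_config("refined"))
    loss_o <- 93.31 - orig$weight[nrow(orig)]
    loss_r <- 93.31 - refi$weight[nrow(refi)]
    expect_lte(loss_r, loss_o + 1e-6)
  }
  # ablation identity: with no FFM shift and identical REE equation the
  # two trajectory forms coincide
  cfg_o <- model_config("original", ffm_shift = 0)
  cfg_r <- model_config("refined", ffm_shift = 0,
                        ree_equation = "cunningham")
  to <- simulate_weight(s, constant_intake(800), weeks = 8, config = cfg_o)
  tr <- simulate_weight(s, constant_intake(800), weeks = 8, config = cfg_r)
  expect_equal(to$weight, tr$weight, tolerance = 1e-9)
})

test_that("dynamic prediction stays below the static 3500-kcal rule", {
  expect_equal(static_prediction(500, 1), 0.45359237, tolerance = 1e-12)
  expect_equal(static_prediction(0, 10), 0)
  expect_equal(static_prediction(500, 10), 4.5359237, tolerance = 1e-12)
  expect_error(static_prediction(500, -1), ">= 0")
  for (w0 in c(70, 100, 130)) {
    s <- subject_baseline(w0, "female")
    for (def in c(300, 900, 1500)) {
      ei <- max(intake_for_deficit(s, def), 0)
      traj <- suppressWarnings(
        simulate_weight(s, constant_intake(ei), weeks = 8)
      )
      dyn <- w0 - traj$weight[nrow(traj)]
      expect_lt(dyn, static_prediction(def, 8))
    }
  }
})

test_that("invalid simulations fail loudly", {
  s <- ref_subject()
  expect_error(simulate_weight(s, constant_intake(800), weeks = -2),
               "positive")
  expect_error(rhs(0, -5, s, constant_intake(800)), "diverged")
  # starving a light subject for a very long time drives weight to zero
  s_small <- subject_baseline(55, "female", ei0 = 0)
  expect_error(
    suppressWarnings(
      simulate_weight(s_small, constant_intake(0), weeks = 200)
    ),
    "diverged|converge"
  )
})
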