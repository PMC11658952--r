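test_that("baseline FFM fraction follows the lean-reference construction", {
  cfg <- model_config()
  # anchor: a subject at the lean reference weight has the reference FFM%
  expect_equal(baseline_ffm_fraction(60, "female", cfg), 0.72)
  expect_equal(baseline_ffm_fraction(70, "male", cfg), 0.85)
  # cohort-mean client: (0.72*60 + 0.25*33.31)/93.31
  expect_equal(baseline_ffm_fraction(93.31, "female", cfg),
               (0.72 * 60 + 0.25 * 33.31) / 93.31, tolerance = 1e-12)
  # FFM% strictly decreasing in weight above the lean reference
  w <- seq(61, 160, by = 1)
  fr <- baseline_ffm_fraction(w, "female", cfg)
  expect_true(all(diff(fr) < 0))
  # composition closure: FM + FFM = weight
  s <- ref_subject()
  st <- composition_state(c(93.31, 90, 85), s, cfg)
  fm <- st$weight - st$ffm_kg
  expect_equal(fm + st$ffm_kg, st$weight)
  expect_error(baseline_ffm_fraction(-1, "female"), "positive")
  expect_error(baseline_ffm_fraction(70, "dog"), "arg")
})

test_that("FFM% trajectories are anchored, continuous and saturate exactly", {
  orig <- model_config("original")
  refi <- model_config("refined")
  # baseline anchor and saturation values
  expect_equal(ffm_fraction_at(0, 0.55, orig), 0.55)
  expect_equal(ffm_fraction_at(0.10, 0.55, orig), 0.65)
  expect_equal(ffm_fraction_at(0.10, 0.55, refi), 0.60)
  expect_equal(ffm_fraction_at(0.20, 0.55, refi), 0.65)
  # exact saturation at and beyond the threshold
  xs <- seq(0.10, 0.99, by = 0.01)
  expect_true(all(ffm_fraction_at(xs, 0.55, orig) == 0.65))
  expect_true(all(ffm_fraction_at(pmax(xs, 0.20), 0.55, refi) == 0.65))
  # continuity across the thresholds
  eps <- 1e-12
  expect_lt(abs(ffm_fraction_at(0.10 - eps, 0.55, orig) -
                  ffm_fraction_at(0.10 + eps, 0.55, orig)), 1e-9)
  expect_lt(abs(ffm_fraction_at(0.20 - eps, 0.55, refi) -
                  ffm_fraction_at(0.20 + eps, 0.55, refi)), 1e-9)
  # non-decreasing over [0, 1)
  grid <- seq(0, 0.99, length.out = 400)
  for (cfg in list(orig, refi)) {
    vals <- ffm_fraction_at(grid, 0.55, cfg)
    expect_true(all(diff(vals) >= 0))
  }
  # refined lies below original before the original's saturation point
  mid <- seq(0.005, 0.095, by = 0.005)
  expect_true(all(ffm_fraction_at(mid, 0.55, refi) <
                    ffm_fraction_at(mid, 0.55, orig)))
  expect_error(ffm_fraction_at(-0.01, 0.55), "weight gain")
})

test_that("REE equations use the configured coefficients", {
  expect_equal(ree(50, model_config("original")), 500 + 22 * 50)
  expect_equal(ree(50, model_config("refined")), 413 + 19.7 * 50)
  # linearity: +1 kg FFM adds exactly the slope
  expect_equal(ree(51) - ree(50), 22)
  custom <- model_config(cunningham_intercept = 450, cunningham_slope = 20)
  expect_equal(ree(50, custom), 1450)
  expect_error(ree(0), "positive")
})

test_that("adaptive thermogenesis rises from zero to its REE ceiling", {
  cfg <- model_config()
  expect_equal(adaptive_thermogenesis(0, 1600, cfg), 0)
  expect_equal(adaptive_thermogenesis(0.10, 1600, cfg), 240)
  expect_equal(adaptive_thermogenesis(0.50, 1600, cfg), 240)
  # between the anchors: strictly inside (0, ceiling), matching the closed
  # form transcribed independently
  k <- -log(1 - 0.99) / 0.10
  mid <- 0.15 * 1600 * (1 - exp(-k * 0.05)) / (1 - exp(-k * 0.10))
  got <- adaptive_thermogenesis(0.05, 1600, cfg)
  expect_gt(got, 0)
  expect_lt(got, 240)
  expect_equal(got, mid, tolerance = 1e-12)
  # monotone non-decreasing, never above the ceiling
  grid <- seq(0, 0.99, length.out = 500)
  at <- adaptive_thermogenesis(grid, 1600, cfg)
  expect_true(all(diff(at) >= 0))
  expect_true(all(at <= 240 + 1e-12))
  # continuity at the threshold
  eps <- 1e-12
  expect_lt(abs(adaptive_thermogenesis(0.10 - eps, 1600, cfg) -
                  adaptive_thermogenesis(0.10 + eps, 1600, cfg)), 1e-9)
  expect_error(adaptive_thermogenesis(-0.1, 1600), "weight gain")
})

test_that("DIT is the configured fraction of intake", {
  expect_equal(dit(800), 40)
  expect_equal(dit(0), 0)
  expect_equal(dit(2000, model_config(dit_coeff = 0.10)), 200)
  expect_error(dit(-5), ">= 0")
})

test_that("total EE components are consistent and sum to the total", {
  s <- ref_subject()
  cfg <- model_config()
  ee <- total_ee(93.31, 800, s, cfg)
  expect_equal(ee$ree_net + ee$paee + ee$dit, ee$total)
  expect_equal(ee$paee, (1.6 - 1) * ee$ree_net)
  expect_equal(ee$at, 0)  # no adaptation before weight loss
  # sedentary floor: PAL = 1.2 is the index minimum; PAEE = 0.2 * REE_net
  s12 <- subject_baseline(93.31, "female", pal = 1.2, ei0 = 800)
  ee12 <- total_ee(93.31, 800, s12, cfg)
  expect_equal(ee12$paee, 0.2 * ee12$ree_net)
  # at AT saturation total = pal * 0.85 * REE + DIT
  w_sat <- 93.31 * 0.88
  ee_sat <- total_ee(w_sat, 800, s, cfg)
  expect_equal(ee_sat$total, 1.6 * 0.85 * ee_sat$ree_gross + 40,
               tolerance = 1e-12)
})
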