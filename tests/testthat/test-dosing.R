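test_that("cyclic dosing follows the on/off modulus rule", {
  s <- dose_schedule("hormone", "cyclic", 14, 7, dose = 0.8)
  expect_equal(cyclic_dose(10, s), 0.8)
  expect_equal(cyclic_dose(15, s), 0)
  expect_equal(cyclic_dose(21, s), 0.8)
  expect_equal(cyclic_dose(13.999, s), 0.8)
  expect_equal(cyclic_dose(14, s), 0)
  # zero before the start offset
  s2 <- dose_schedule("hormone", "cyclic", 14, 7, dose = 0.8, start_day = 30)
  expect_equal(cyclic_dose(10, s2), 0)
  expect_equal(cyclic_dose(31, s2), 0.8)
  # rest = 0 is the continuous limit
  s3 <- dose_schedule("hormone", "cyclic", 14, 0, dose = 0.5)
  cont <- dose_schedule("hormone", "continuous", dose = 0.5)
  tt <- seq(0, 100, by = 0.25)
  expect_equal(cyclic_dose(tt, s3), dose_at(tt, cont))
  expect_error(dose_schedule("hormone", "cyclic", 0, 0), "cyclic")
})

test_that("cyclic dosing is periodic and integrates to dose x on-days", {
  s <- dose_schedule("her2", "cyclic", 14, 7, dose = 0.8)
  tt <- seq(0, 20.999, by = 1e-3)
  expect_equal(cyclic_dose(tt, s), cyclic_dose(tt + 21, s))
  per_cycle <- sum(cyclic_dose(tt, s)) * 1e-3
  expect_equal(per_cycle, 0.8 * 14, tolerance = 1e-3)
})

test_that("Hill effect matches its closed form and is bounded/monotone", {
  p <- default_parameters()
  expect_equal(hill_effect(0, p), 0)
  expect_equal(hill_effect(p$ec50, p), p$max_drug_effect / 2)
  expect_equal(hill_effect(0.6, p), 0.7387961250362586, tolerance = 1e-12)
  cc <- sort(runif(200, 0, 10))
  eff <- hill_effect(cc, p)
  expect_true(all(diff(eff) >= 0))
  expect_true(all(eff <= p$max_drug_effect))
  expect_error(hill_effect(0.5, set_parameters(p, ec50 = 1e-12)), NA)
  p_bad <- p
  p_bad$ec50 <- -1
  expect_error(hill_effect(0.5, p_bad), "ec50")
  expect_error(hill_effect(-0.1, p), "concentration")
})

test_that("pharmacokinetic input converts dose to concentration flux", {
  p <- default_parameters()
  s <- dose_schedule("hormone", "continuous", dose = 0.8)
  flux <- pk_input(3, list(s), p)
  expect_equal(unname(flux[1]), 0.5 * 0.8 * 0.85 / 70, tolerance = 1e-12)
  expect_named(flux, "hormone")
  off <- dose_schedule("chemo", "cyclic", 7, 14, dose = 0.6)
  expect_equal(unname(pk_input(8, list(off), p)), 0)  # rest period
  # organ-function identity at baseline
  expect_equal(p$elimination_rate * p$liver_function * p$kidney_function,
               p$elimination_rate)
})

test_that("adaptive controller holds, steps and saturates as specified", {
  s <- dose_schedule("hormone", "adaptive", dose = 0.75,
                     monitoring_period = 21, target_ratio = 1.0,
                     min_dose = 0.6, max_dose = 0.9, step = 0.1)
  # ratio exactly at target: hold
  expect_equal(adaptive_dose_update(0.75, 1.0, s), 0.75)
  # growing burden: step up, saturate at max
  expect_equal(adaptive_dose_update(0.75, 1.2, s), 0.85)
  expect_equal(adaptive_dose_update(0.9, 1.5, s), 0.9)
  # shrinking burden: one controller update down
  expect_equal(adaptive_dose_update(0.75, 0.8, s), 0.65)
  expect_equal(adaptive_dose_update(0.6, 0.5, s), 0.6)
  expect_error(adaptive_dose_update(0.75, NaN, s), "ratio")
})

test_that("adaptive doses never leave their bounds on any burden history", {
  s <- dose_schedule("hormone", "adaptive", dose = 0.75)
  set.seed(5)
  for (i in 1:30) {
    hist <- data.frame(time = 0:210,
                       burden = 200 * exp(cumsum(rnorm(211, 0, 0.05))))
    for (t in seq(21, 210, by = 21)) {
      d <- adaptive_dose(t, s, hist)
      expect_gte(d, s$min_dose)
      expect_lte(d, s$max_dose)
    }
  }
  expect_error(adaptive_dose(21, s, data.frame(time = numeric(0),
                                               burden = numeric(0))),
               "empty")
})

test_that("hyperthermia sessions set temperature and scale therapy", {
  h <- hyperthermia_session(38.5, 2, 21)
  expect_equal(temperature_at(1, h), 38.5)
  expect_equal(temperature_at(2.5, h), 37.0)
  expect_equal(temperature_at(21.5, h), 38.5)
  expect_equal(temperature_at(10, NULL), 37.0)
  expect_equal(hyperthermia_modifier(37.0), 1.0)
  expect_equal(hyperthermia_modifier(38.5), 1.15)
  expect_equal(hyperthermia_modifier(38.5, coef = 0), 1.0)
  expect_error(hyperthermia_session(36.5), "temperature")
  expect_error(hyperthermia_session(38.5, 30, 21), "period")
})

test_that("controls map drug state onto the four therapy channels", {
  p <- default_parameters()
  prot <- treatment_protocol("immuno_combo", params = p)
  # no drug on board, raw-dose mode during the chemo on-window
  ctr <- controls_at(3, c(chemo = 0, immuno = 0), prot, p)
  expect_equal(ctr$uC, 0.6)
  expect_equal(ctr$uE, 0)
  expect_equal(ctr$immuno_boost, 1 + p$immuno_resist_boost * ctr$uI)
  # hill mode at the EC50 gives the half-maximal control
  opth <- model_options(control_mode = "hill")
  ctr2 <- controls_at(100, c(chemo = p$ec50, immuno = 0), prot, p, opth)
  expect_equal(ctr2$uC, p$max_drug_effect / 2)
  # quiet day: everything off
  ctr3 <- controls_at(10, c(chemo = 0, immuno = 0), prot, p, opth)
  expect_equal(ctr3$uC, 0)
  expect_equal(ctr3$immuno_boost, 1)
  expect_equal(ctr3$temperature, 37.0)
  # hyperthermia protocol reports session temperature
  ph <- treatment_protocol("hyperthermia", params = p)
  ctr4 <- controls_at(1, c(hormone = 0, her2 = 0), ph, p)
  expect_equal(ctr4$temperature, 38.5)
})
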