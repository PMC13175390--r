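test_that("total tumor burden sums exactly the six tumor compartments", {
  y <- initial_state()
  expect_equal(total_tumor_burden(y), 202.2)
  y0 <- initial_state(N1 = 0, N2 = 0, Q = 0, R1 = 0, R2 = 0, S = 0)
  expect_equal(total_tumor_burden(y0), 0)
  # immune cells and microenvironment compartments are excluded
  y2 <- initial_state(I1 = 1e6, I2 = 1e6, P = 99, A = 99, D = 5, M = 7)
  expect_equal(total_tumor_burden(y2), 202.2)
  yk <- initial_state(N1 = 1000, N2 = 0, Q = 0, R1 = 0, R2 = 0, S = 0)
  expect_equal(total_tumor_burden(yk), 1000)
  ybad <- initial_state(N1 = Inf)
  expect_error(total_tumor_burden(ybad), "non-finite")
})

test_that("intermediates follow the printed definitions", {
  p <- default_parameters()
  y <- initial_state()
  inter <- compute_intermediates(0, y, p)
  expect_equal(inter$total_tumor, 202.2)
  # 202.2/1000 is below the 0.3 hypoxia threshold
  expect_equal(inter$hypoxia_factor, 0)
  expect_equal(inter$immune_kill_factor, 1.0)
  expect_equal(inter$carrying_capacity_factor, 1 - 202.2 / 1000)
  expect_equal(inter$growth_factor, (1 - 0.2022) * 1.2)
  expect_equal(inter$acidosis_effect, 1 + 0.01 * 1 * 0.2022)
  # at total = K the logistic factor vanishes and hypoxia saturates
  yk <- initial_state(N1 = 1000, N2 = 0, Q = 0, R1 = 0, R2 = 0, S = 0)
  ik <- compute_intermediates(0, yk, p)
  expect_equal(ik$carrying_capacity_factor, 0)
  expect_equal(ik$hypoxia_factor, 1)
  # therapy effect is the eta-weighted control sum
  ctr <- control_inputs(uE = 1, uH = 1, uC = 1)
  it <- compute_intermediates(0, y, p, ctr)
  expect_equal(it$therapy_effect, 0.03)
  p_bad <- p
  p_bad$K <- 0
  expect_error(compute_intermediates(0, y, p_bad), "K")
})

test_that("circadian factor modulates as a unit-period sine", {
  p <- default_parameters()
  expect_equal(circadian_factor(0, p), 1.0)
  expect_equal(circadian_factor(0.25, p), 1.2)  # 6 h into a 24 h day
  expect_equal(circadian_factor(0.75, p), 0.8)
  p_off <- p
  p_off$circadian_enabled <- FALSE
  expect_identical(circadian_factor(123.45, p_off), 1.0)
  expect_error(circadian_factor(0, set_parameters(p, circadian_period = -1)),
               "positive")
  p_bad <- p
  p_bad$circadian_amplitude <- 1.0
  expect_error(circadian_factor(0, p_bad), "amplitude")
})

test_that("fractional memory factor matches its closed form", {
  expect_identical(fractional_factor(0, 0.8), 1.0)
  expect_equal(fractional_factor(5, 1.0), 0.01)
  expect_equal(fractional_factor(1, 0.75), 0.0125)
  expect_equal(fractional_factor(2, 0.75), 0.0114865088937534,
               tolerance = 1e-12)
  expect_error(fractional_factor(1, 0), "alpha")
  expect_error(fractional_factor(1, 1.2), "alpha")
  expect_error(fractional_factor(-1, 0.9), ">= 0")
})

test_that("memory factor is monotone in time and order", {
  tt <- seq(0.5, 400, length.out = 200)
  for (a in c(0.75, 0.85, 0.95)) {
    f <- fractional_factor(tt, a)
    expect_true(all(diff(f) <= 0))
  }
  alphas <- seq(0.75, 1, by = 0.05)
  for (t in c(1, 7, 100)) {
    f <- vapply(alphas, function(a) fractional_factor(t, a), numeric(1))
    expect_true(all(diff(f) <= 0))
  }
})

test_that("derivatives reduce correctly in limiting regimes", {
  p <- default_parameters()
  p$circadian_enabled <- FALSE
  # no tumor, no drugs, no regulatory cells: cytotoxic pool follows
  # baseline production minus death (all tumor-coupled terms at the floor)
  y <- initial_state(N1 = 0, N2 = 0, I1 = 25, I2 = 0, P = 0, A = 0,
                     Q = 0, R1 = 0, R2 = 0, S = 0, M = 0, G = 1)
  dy <- derivatives(5, y, p)
  ff <- fractional_factor(5, 1.0)
  total_floor <- 6e-6  # six floored tumor compartments
  supp_floor <- p$beta2 * 25 * 1e-6 / 26  # I2 sits at the floor
  expect_equal(dy[["I1"]],
               (p$phi1 + p$phi2 * total_floor / (1 + 0.01 * total_floor) -
                  supp_floor - p$delta_I * 25) * ff,
               tolerance = 1e-10)
  # pure drug decay transfers mass from D to Dm one-to-one
  y2 <- initial_state(D = 1)
  dy2 <- derivatives(5, y2, p)
  expect_equal(dy2[["D"]], -0.1 * ff * 1, tolerance = 1e-12)
  expect_equal(dy2[["Dm"]], +0.1 * ff * 1, tolerance = 1e-12)
})

test_that("drug mass balance holds at every evaluation without dosing", {
  set.seed(7)
  p <- default_parameters()
  for (i in 1:50) {
    y <- random_state()
    ctr <- control_inputs(uE = runif(1), uH = runif(1), uC = runif(1),
                          uI = runif(1))
    dy <- derivatives(runif(1, 0, 500), y, p, ctr)
    expect_equal(dy[["D"]] + dy[["Dm"]], 0, tolerance = 1e-15)
  }
})

test_that("modular RHS equals the independent monolithic transcription", {
  set.seed(101)
  worst <- 0
  for (i in 1:1000) {
    p <- if (i %% 3 == 0) random_parameters() else default_parameters()
    if (i %% 2 == 0) p$circadian_enabled <- FALSE
    y <- random_state()
    t <- runif(1, 0, 500)
    uE <- runif(1); uH <- runif(1); uC <- runif(1); uI <- runif(1)
    temp <- 37 + sample(c(0, 1.5), 1)
    boost <- 1 + p$immuno_resist_boost * uI
    rm <- sample(c(1, 1.2, 2), 1)
    a <- runif(1, 0.75, 1)
    flux <- runif(1, 0, 0.01)
    got <- derivatives(t, y, p,
                       control_inputs(uE, uH, uC, uI, temp, boost),
                       resistance_multiplier = rm, alpha = a, pk_flux = flux)
    want <- oracle_rhs(t, unname(y[state_names()]), p, uE, uH, uC, uI,
                       temp, boost, rm, a, flux)
    denom <- pmax(abs(want), 1e-300)
    rel <- max(abs(unname(got) - want) / pmax(denom, 1e-12))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-12)
})

test_that("growth response is non-increasing in total burden", {
  set.seed(11)
  for (i in 1:40) {
    p <- random_parameters()
    M <- runif(1, 0, 3)
    totals <- sort(runif(50, 0, 2 * p$K))
    g <- vapply(totals, function(tt) {
      ccf <- max(0, 1 - tt / p$K)
      ccf * (1 + 0.2 * M) / (1 + p$acidosis_factor * M * tt / p$K)
    }, numeric(1))
    expect_true(all(diff(g) <= 1e-12))
  }
})

test_that("with circadian disabled the RHS is autonomous up to the memory factor", {
  p <- default_parameters()
  p$circadian_enabled <- FALSE
  set.seed(3)
  for (i in 1:20) {
    y <- random_state()
    ctr <- control_inputs(uE = runif(1), uC = runif(1))
    t1 <- runif(1, 1, 250); t2 <- runif(1, 250, 500)
    d1 <- derivatives(t1, y, p, ctr, alpha = 0.8) / fractional_factor(t1, 0.8)
    d2 <- derivatives(t2, y, p, ctr, alpha = 0.8) / fractional_factor(t2, 0.8)
    expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-12)
  }
})

test_that("non-finite states are reported with the offending compartment", {
  p <- default_parameters()
  y <- initial_state()
  y["N1"] <- NaN
  expect_error(derivatives(0, y, p))
  p_huge <- set_parameters(p, lambda1 = 1e308)
  y2 <- initial_state()
  expect_error(derivatives(10, y2, p_huge), "non-finite")
})
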