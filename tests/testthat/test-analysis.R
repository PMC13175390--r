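# small synthetic grid used by the ranking/comparison tests
synthetic_grid <- function(rows) {
  g <- do.call(rbind, lapply(rows, function(r) {
    data.frame(alpha = r[[1]], profile = r[[2]], protocol = r[[3]],
               initial_burden = 202.2, final_burden = NA_real_,
               percent_reduction = r[[4]], resistance_fraction = r[[5]],
               efficacy_score = r[[4]] / (1 + r[[5]] / 100),
               converged = TRUE, method = "rk45", fallback_level = 0,
               stringsAsFactors = FALSE)
  }))
  class(g) <- c("fotsim_grid", class(g))
  g
}

test_that("outcome metrics implement the composite efficacy definition", {
  expect_equal(efficacy_score(0, 0), 0)
  expect_equal(efficacy_score(30, 0), 30)
  expect_equal(efficacy_score(32.76, 1.55), 32.25997, tolerance = 1e-6)
  # efficacy never exceeds the reduction
  set.seed(2)
  pr <- runif(100, 0, 100); rf <- runif(100, 0, 100)
  expect_true(all(efficacy_score(pr, rf) <= pr + 1e-12))
  # metrics computed from a real trajectory agree with direct arithmetic
  p <- default_parameters()
  cfg <- simulation_config(duration = 80, n_points = 81)
  res <- safe_solve(cfg, p, treatment_protocol("continuous", params = p))
  m <- outcome_metrics(res)
  b <- total_tumor_burden(res$state)
  expect_equal(m$percent_reduction, 100 * (1 - b[81] / b[1]))
  last <- res$state[81, ]
  expect_equal(m$resistance_fraction,
               100 * (last[["R1"]] + last[["R2"]]) / b[81])
  expect_equal(m$efficacy_score,
               m$percent_reduction / (1 + m$resistance_fraction / 100))
})

test_that("the default comparative design enumerates 140 configurations", {
  g <- grid_design()
  expect_equal(nrow(g), 140)
  expect_equal(length(default_alphas()), 7)
  expect_equal(nrow(unique(g)), 140)
  expect_equal(unname(table(g$alpha)), rep(20L, 7), ignore_attr = TRUE)
  expect_equal(unname(table(g$profile)), rep(35L, 4), ignore_attr = TRUE)
  expect_equal(unname(table(g$protocol)), rep(28L, 5), ignore_attr = TRUE)
})

test_that("a one-cell grid equals a direct solve plus metrics", {
  p <- default_parameters()
  cfg <- simulation_config(duration = 60, n_points = 61)
  g <- run_grid(alphas = 0.9, profiles = "young", protocols = "standard",
                config = cfg, baseline = p)
  expect_equal(nrow(g), 1)
  py <- apply_profile(p, "young")
  cfg$alpha <- 0.9
  m <- outcome_metrics(safe_solve(cfg, py,
                                  treatment_protocol("standard",
                                                     params = py)))
  expect_equal(g$efficacy_score, m$efficacy_score)
  expect_equal(g$percent_reduction, m$percent_reduction)
})

test_that("grid runs are deterministic across invocations and workers", {
  p <- default_parameters()
  cfg <- simulation_config(duration = 40, n_points = 41)
  g1 <- run_grid(alphas = c(0.8, 1.0), profiles = "average",
                 protocols = c("standard", "continuous"), config = cfg,
                 baseline = p, workers = 1)
  g2 <- run_grid(alphas = c(0.8, 1.0), profiles = "average",
                 protocols = c("standard", "continuous"), config = cfg,
                 baseline = p, workers = 2)
  expect_identical(g1$efficacy_score, g2$efficacy_score)
  expect_identical(g1, g2)
})

test_that("protocol ranking orders by efficacy with documented tie-breaks", {
  g <- synthetic_grid(list(
    list(0.75, "average", "continuous", 32.76, 1.55),
    list(0.75, "average", "adaptive", 31.35, 1.52),
    list(0.75, "average", "standard", 31.11, 1.50)
  ))
  r <- rank_protocols(g, alpha = 0.75)
  expect_equal(r$protocol, c("continuous", "adaptive", "standard"))
  expect_equal(r$rank, 1:3)
  expect_equal(optimal_protocol(g, "average", 0.75)$protocol, "continuous")
  # tie on efficacy (30 each): higher reduction wins
  g2 <- synthetic_grid(list(
    list(0.8, "average", "aaa", 30, 0),
    list(0.8, "average", "bbb", 60, 100)
  ))
  expect_equal(rank_protocols(g2, 0.8)$protocol, c("bbb", "aaa"))
  # full tie: alphabetical
  g3 <- synthetic_grid(list(
    list(0.8, "average", "zeta", 30, 0),
    list(0.8, "average", "alpha", 30, 0)
  ))
  expect_equal(rank_protocols(g3, 0.8)$protocol, c("alpha", "zeta"))
  # adding a strictly worse protocol never changes the argmax
  g4 <- rbind(g3, synthetic_grid(list(list(0.8, "average", "mid", 10, 5))))
  class(g4) <- class(g3)
  expect_equal(optimal_protocol(g4, "average", 0.8)$protocol, "alpha")
  expect_error(rank_protocols(g3, 0.99), "empty")
})

test_that("protocol variability summarizes the efficacy spread across orders", {
  g <- synthetic_grid(list(
    list(0.75, "average", "continuous", 32.26, 0),
    list(0.80, "average", "continuous", 30.09, 0),
    list(0.85, "average", "continuous", 31.00, 0),
    list(0.75, "average", "standard", 30, 0),
    list(0.80, "average", "standard", 30, 0),
    list(0.85, "average", "standard", 30, 0)
  ))
  v <- protocol_variability(g, "average")
  cont <- v[v$protocol == "continuous", ]
  expect_equal(cont$range, 32.26 - 30.09)
  expect_equal(cont$sd, sd(c(32.26, 30.09, 31.00)))
  expect_equal(cont$cv, 100 * cont$sd / mean(c(32.26, 30.09, 31.00)))
  std <- v[v$protocol == "standard", ]
  expect_equal(std$range, 0)
  expect_equal(std$cv, 0)
  g2 <- synthetic_grid(list(list(0.75, "average", "continuous", 30, 0)))
  expect_error(protocol_variability(g2, "average"), "two")
})

test_that("fractional/integer comparison recovers known differences", {
  # identical outcomes across alpha: all differences are zero
  rows <- list()
  for (a in c(0.75, 0.9, 1.0)) {
    rows <- c(rows, list(list(a, "average", "standard", 30, 1.5)))
  }
  cmp0 <- compare_fractional_integer(synthetic_grid(rows))
  expect_true(all(abs(cmp0$aggregate$difference) < 1e-12))
  expect_true(all(abs(cmp0$by_context$difference_pct) < 1e-12))
  # single fractional order: pooled equals the direct two-row difference
  g <- synthetic_grid(list(
    list(0.80, "young", "continuous", 31.30 * (1 + 1.5 / 100), 1.5),
    list(1.00, "young", "continuous", 30.19 * (1 + 1.5 / 100), 1.5)
  ))
  cmp <- compare_fractional_integer(g)
  ctx <- cmp$by_context
  expect_equal(ctx$integer_efficacy, 30.19, tolerance = 1e-9)
  expect_equal(ctx$fractional_efficacy, 31.30, tolerance = 1e-9)
  expect_equal(ctx$difference_pct, 100 * (31.30 - 30.19) / 30.19,
               tolerance = 1e-9)
  expect_equal(round(ctx$difference_pct, 2), 3.68)
  expect_equal(ctx$best_alpha, 0.80)
  # best-alpha convention on a two-order context
  g2 <- synthetic_grid(list(
    list(0.80, "young", "continuous", 32.38, 0),
    list(0.90, "young", "continuous", 30.00, 0),
    list(1.00, "young", "continuous", 30.19, 0)
  ))
  ctx2 <- compare_fractional_integer(g2)$by_context
  expect_equal(ctx2$best_alpha, 0.80)
  expect_equal(round(ctx2$best_difference_pct, 2), 7.25)
  expect_error(compare_fractional_integer(
    synthetic_grid(list(list(0.8, "average", "standard", 30, 1)))), "integer")
})

test_that("the sensitivity design enumerates 58 x 20 x 4 perturbations", {
  d <- sensitivity_design()
  expect_equal(nrow(d), 4640)
  expect_equal(length(unique(d$parameter)), 58)
  expect_equal(nrow(unique(d[, c("profile", "protocol")])), 20)
  expect_setequal(unique(d$level), c(-0.2, -0.1, 0.1, 0.2))
})

test_that("the sensitivity engine is exact on injected closed-form responses", {
  p <- default_parameters()
  # proportional response O = c * beta1: unit elasticity at every level
  sim_lin <- function(params, profile, protocol, alpha) {
    v <- 1000 * params$beta1
    c(percent_reduction = v, resistance_fraction = v, efficacy_score = v)
  }
  s <- sensitivity_analysis(p, parameters = "beta1", profiles = "average",
                            protocols = c("standard", "continuous"),
                            simulator = sim_lin)
  expect_equal(s$ranking$s_max, 1, tolerance = 1e-10)
  expect_true(all(abs(s$records$S - 1) < 1e-10))
  expect_equal(s$retention, 1)
  expect_equal(s$ranking$class, "critical")
  # affine response O = a + b * p gives S = b*p/(a + b*p) at the baseline
  a <- 10; b <- 300
  sim_aff <- function(params, profile, protocol, alpha) {
    v <- a + b * params$kappa_Q
    c(percent_reduction = v, resistance_fraction = v, efficacy_score = v)
  }
  s2 <- sensitivity_analysis(p, parameters = "kappa_Q", profiles = "young",
                             protocols = "standard", simulator = sim_aff)
  expect_equal(s2$ranking$s_max, b * p$kappa_Q / (a + b * p$kappa_Q),
               tolerance = 1e-10)
  # hand-checked single coefficient: O 30 -> 31.5 under +10%
  sim_tab <- function(params, profile, protocol, alpha) {
    v <- if (abs(params$beta1 - p$beta1) < 1e-15) 30 else
      if (params$beta1 > p$beta1) 31.5 else 28.5
    c(percent_reduction = v, resistance_fraction = v, efficacy_score = v)
  }
  s3 <- sensitivity_analysis(p, parameters = "beta1", profiles = "average",
                             protocols = "standard", levels = 0.1,
                             simulator = sim_tab)
  expect_equal(s3$records$S, rep(0.5, 3), tolerance = 1e-12)
})

test_that("sensitivity classification thresholds classify boundaries upward", {
  expect_equal(classify_sensitivity(c(1.2, 1.0, 0.7, 0.5, 0.49, NA)),
               c("critical", "critical", "important", "important",
                 "non-critical", NA))
})

test_that("non-converged sensitivity runs are excluded and counted", {
  p <- default_parameters()
  sim_flaky <- function(params, profile, protocol, alpha) {
    if (params$beta1 < p$beta1) {
      return(c(percent_reduction = NA_real_, resistance_fraction = NA_real_,
               efficacy_score = NA_real_))
    }
    v <- 1000 * params$beta1
    c(percent_reduction = v, resistance_fraction = v, efficacy_score = v)
  }
  expect_warning(
    s <- sensitivity_analysis(p, parameters = "beta1", profiles = "average",
                              protocols = "standard", simulator = sim_flaky),
    "retention")
  expect_equal(s$retention, 0.5)  # the two negative levels fail
  expect_equal(s$n_converged, 2)
  expect_equal(s$ranking$s_max, 1, tolerance = 1e-10)
})
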