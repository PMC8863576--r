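test_that("activating step: closed-form integral and limits", {
  st <- step_activating(0, 10, tau_a = 100, dt = 300)
  expect_equal(st$integral, 3000 - 1000 + 1000 * exp(-3), tolerance = 1e-12)
  expect_equal(st$A_R_end, 10 - 10 * exp(-3), tolerance = 1e-12)

  # instantaneous tracking and no-lag cases
  expect_equal(step_activating(0, 10, 0, 300)$integral, 3000)
  expect_equal(step_activating(7, 7, 500, 300)$integral, 7 * 300)
  expect_error(step_activating(10, 5, 100, 300), "A_F >= A_I")
  expect_error(step_activating(0, 10, 100, 0), "dt")
})

test_that("activating integral agrees with numerical quadrature", {
  set.seed(99)
  for (i in 1:200) {
    A_I <- runif(1, 0, 30)
    A_F <- A_I + runif(1, 0.1, 30)
    tau <- runif(1, 1, 1000)
    dt <- runif(1, 1, 3600)
    numeric_int <- integrate(function(t) A_F - (A_F - A_I) * exp(-t / tau),
                             0, dt, rel.tol = 1e-10)$value
    expect_equal(step_activating(A_I, A_F, tau, dt)$integral, numeric_int,
                 tolerance = 1e-8)
  }
})

test_that("deactivating step: latent state relaxes, realized tracks light", {
  st <- step_deactivating(30, 8, tau_d = 241, dt = 1200)
  expect_equal(st$A_R_end, 8 + 22 * exp(-1200 / 241), tolerance = 1e-12)
  expect_equal(round(st$A_R_end, 3), 8.151)
  expect_equal(st$integral, 8 * 1200)     # no shade penalty on realized A

  expect_equal(step_deactivating(30, 8, Inf, 600)$A_R_end, 30)
  expect_equal(step_deactivating(30, 8, 0, 600)$A_R_end, 8)
  expect_error(step_deactivating(5, 10, 100, 60), "A_F <= A_I")
})

test_that("constant light or zero activation lag forgoes nothing", {
  p <- it86_light()
  const <- light_regime(seq(0, 3600, by = 60), rep(900, 61), step_s = 60)
  res <- simulate_diurnal(const, p, tau_scenario(tau_a = 0, tau_d = 0))
  expect_equal(res$A_f_pct, 0, tolerance = 1e-10)

  # tau_a = 0 gives A_tau = A_Q on any regime (deactivation never
  # penalizes realized assimilation by construction)
  reg <- small_regime()
  res2 <- simulate_diurnal(reg, p, tau_scenario(tau_a = 0, tau_d = 500))
  expect_equal(res2$A_tau, res2$A_Q, tolerance = 1e-10)
})

test_that("lagged assimilation never exceeds potential and respects rate bounds", {
  p <- it86_light()
  reg <- small_regime()
  res <- simulate_diurnal(reg, p, tau_scenario(tau_a = 144, tau_d = 42))
  expect_lte(res$A_tau, res$A_Q)
  expect_gte(res$A_f_pct, 0)
  expect_equal(res$A_f_pct, 100 * (res$A_Q - res$A_tau) / res$A_Q)
  # realized step-mean rate stays within [min, max] of target/initial
  rate <- res$steps$realized / res$steps$dt
  expect_true(all(rate <= pmax(res$steps$A_F, res$steps$A_I) + 1e-9))
  expect_true(all(rate >= pmin(res$steps$A_F, res$steps$A_I) - 1e-9))
})

test_that("faster deactivation and slower activation both increase foregone assimilation", {
  p <- it86_light()
  reg <- small_regime()
  af <- function(tau_a, tau_d)
    simulate_diurnal(reg, p, tau_scenario(tau_a, tau_d))$A_f_pct
  # published-means contrast: in-vivo tau_d (241) vs in-vitro (132),
  # in-vitro tau_a (144) vs in-vivo (180)
  expect_lt(af(144, 241), af(144, 132))
  expect_lt(af(144, 132), af(180, 132))
})

test_that("halving the timestep of a smooth regime barely changes the result", {
  p <- it86_light()
  t1 <- seq(0, 14400 - 60, by = 60)
  t2 <- seq(0, 14400 - 30, by = 30)
  env <- function(t) 1500 * sin(pi * t / 14400)
  r1 <- light_regime(t1, env(t1), step_s = 60)
  r2 <- light_regime(t2, env(t2), step_s = 30)
  sc <- tau_scenario(144, 132)
  a1 <- simulate_diurnal(r1, p, sc)$A_tau
  a2 <- simulate_diurnal(r2, p, sc)$A_tau
  expect_lt(abs(a1 - a2) / a2, 0.005)
})

test_that("scenario table has reference rows, means, and degenerate-scenario identity", {
  reg <- small_regime()
  sc <- list(tau_scenario(0, 0, "instant"),
             tau_scenario(144, 132, "in_vitro"))
  tab <- scenario_table(vp, sc, reg)
  by_acc <- tab$by_accession
  expect_setequal(unique(by_acc$scenario), c("A_Q", "instant", "in_vitro"))
  expect_equal(sum(by_acc$scenario == "A_Q"), 4)
  expect_true(all(is.na(by_acc$A_f_pct[by_acc$scenario == "A_Q"])))

  # tau_a = tau_d = 0 reproduces the potential row exactly
  expect_equal(by_acc$A_diel_mmol[by_acc$scenario == "instant"],
               by_acc$A_diel_mmol[by_acc$scenario == "A_Q"],
               tolerance = 1e-12)

  # identical accessions give zero CI half-width
  same <- vp
  same[, -1] <- same[rep(1, 4), -1]
  tab2 <- scenario_table(same, sc[2], reg)
  expect_equal(tab2$means$A_f_pct_ci95[tab2$means$scenario == "in_vitro"],
               0, tolerance = 1e-10)
})
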