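test_that("mole fractions convert to partial pressures", {
  expect_equal(to_partial_pressure(400, 100), 40)
  expect_equal(to_partial_pressure(209.5, 101.325), 21.227588,
               tolerance = 1e-6)
  expect_equal(to_partial_pressure(0, 100), 0)
  expect_error(to_partial_pressure(10, 0), "pressure")
})

test_that("tobacco kinetic constants scale by Arrhenius from the 25 C reference", {
  k25 <- tobacco_kinetics(25)
  expect_equal(k25$K_C, 40.49)
  expect_equal(k25$K_O, 27.84)
  expect_equal(k25$Gamma_star, 4.275)

  k30 <- tobacco_kinetics(30)
  expect_true(all(unlist(k30) > unlist(k25)))  # positive Ea

  # independent hand evaluation of the Arrhenius formula at 30 C
  arrh <- function(k25, Ea) k25 * exp(Ea * 5 / (298.15 * 8.314 * 303.15))
  expect_equal(k30$K_C, arrh(40.49, 79430), tolerance = 1e-12)
  expect_equal(k30$K_O, arrh(27.84, 36380), tolerance = 1e-12)
  expect_equal(k30$Gamma_star, arrh(4.275, 37830), tolerance = 1e-12)

  expect_error(tobacco_kinetics(55), "range")
})

test_that("forward FvCB rate has the right limits", {
  ctx <- ctx30()
  expect_equal(fvcb_forward(120, ctx$Gamma_star, ctx), -ctx$R_d)
  expect_equal(fvcb_forward(120, 1e9, ctx), 120 - ctx$R_d,
               tolerance = 1e-6)
  # hand evaluation at 30 C, c_c = 25 Pa
  kin <- tobacco_kinetics(30)
  Km <- kin$K_C * (1 + to_partial_pressure(209.5, 101.325) / kin$K_O)
  expect_equal(fvcb_forward(239, 25, ctx),
               239 * (25 - kin$Gamma_star) / (25 + Km) - 1.52,
               tolerance = 1e-12)
})

test_that("one-point inversion is the exact inverse of the forward model", {
  ctx <- ctx30()
  set.seed(42)
  for (i in 1:50) {
    Vc <- runif(1, 20, 300)
    c_c <- runif(1, ctx$Gamma_star + 1, 60)
    A <- fvcb_forward(Vc, c_c, ctx)
    ci_pa <- c_c + A / ctx$g_m
    est <- one_point_vcmax(data.frame(A = A, ci_pa = ci_pa), ctx)
    expect_true(est$valid)
    expect_equal(est$Vcmax, Vc, tolerance = 1e-9)
  }
})

test_that("invalid records are flagged, not silently dropped", {
  ctx <- ctx30()
  rec <- one_point_vcmax(
    data.frame(A = c(-ctx$R_d, 30, -5), ci_pa = c(25, 2, 25)), ctx)
  expect_equal(rec$Vcmax[1], 0)                 # A = -R_d inverts to zero
  expect_false(rec$valid[2])                    # c_c below compensation
  expect_match(rec$reason[2], "Gamma_star")
  expect_false(rec$valid[3])                    # negative gross rate
  expect_match(rec$reason[3], "R_d")
})

test_that("Vc,max estimate increases with A at fixed c_i", {
  ctx <- ctx30()
  A <- seq(5, 25, by = 1)
  est <- one_point_vcmax(data.frame(A = A, ci_pa = rep(27, length(A))), ctx)
  expect_true(all(diff(est$Vcmax) > 0))
})

test_that("pressure cancels when applied consistently (unit audit)", {
  # mole-fraction route at explicit pressure vs partial-pressure route
  P <- 98.2
  ci_umol <- 270
  A <- 18
  kin <- tobacco_kinetics(30)
  ctx_pa <- fvcb_context(K_C = kin$K_C, K_O = kin$K_O,
                         Gamma_star = kin$Gamma_star, g_m = 2, R_d = 1.6,
                         O = to_partial_pressure(209.5, P))
  v1 <- one_point_vcmax(data.frame(A = A, ci = ci_umol, pressure_kpa = P),
                        ctx_pa)$Vcmax
  v2 <- one_point_vcmax(
    data.frame(A = A, ci_pa = to_partial_pressure(ci_umol, P)),
    ctx_pa)$Vcmax
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("the Rubisco-limited window keeps 1-5 min records inclusively", {
  rec <- data.frame(t_s = seq(0, 1200, by = 10), A = 15, ci_pa = 27)
  win <- vcmax_window(rec)
  expect_equal(nrow(win), 25)
  expect_equal(range(win$t_s), c(60, 300))

  ctx <- ctx30()
  bad <- data.frame(t_s = seq(60, 300, by = 10), A = 40,
                    ci_pa = rep(2, 25))  # c_c <= Gamma_star everywhere
  expect_error(vcmax_window(bad, ctx), "no valid records")
})
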