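test_that("piecewise activation-state model reproduces closed-form values", {
  p <- adenantha_s()
  # pre-shade plateau and continuity at shade onset
  expect_equal(s_piecewise(c(-5000, -1200), p), c(80, 80))
  # one deactivation time constant into shade: S = S_L + (S_H - S_L)/e
  expect_equal(s_piecewise(-1092, p), 59 + 21 * exp(-1), tolerance = 1e-12)
  expect_equal(round(s_piecewise(-1092, p), 2), 66.73)
  # induction starts from S_L and recovers to S_H
  long_shade <- piecewise_s_params(80, 59, tau_d = 10, tau_a = 144)
  expect_equal(s_piecewise(1e-9, long_shade), 59, tolerance = 1e-6)
  expect_equal(s_piecewise(1e6, long_shade), 80)
})

test_that("zero time constants give instantaneous transitions, not NaN", {
  p <- piecewise_s_params(80, 59, tau_d = 0, tau_a = 0)
  expect_equal(s_piecewise(-600, p), 59)   # anywhere in shade
  expect_equal(s_piecewise(10, p), 80)     # anywhere post-shade
  expect_false(anyNA(s_piecewise(seq(-2000, 2000, by = 7), p)))
})

test_that("shade and induction branches are monotone", {
  p <- adenantha_s()
  shade_t <- seq(-1199.9, 0, length.out = 400)
  post_t <- seq(0.01, 2000, length.out = 400)
  expect_true(all(diff(s_piecewise(shade_t, p)) < 0))
  expect_true(all(diff(s_piecewise(post_t, p)) > 0))
})

test_that("Vc,max induction follows the recovery exponential", {
  k <- adenantha_v()
  expect_equal(vcmax_induction(0, k), 95)
  expect_equal(vcmax_induction(1e7, k), 239)
  expect_equal(vcmax_induction(180, k), 239 - 144 * exp(-1),
               tolerance = 1e-12)
  expect_error(vcmax_induction(-1, k), "post-shade")
})

test_that("endpoint deactivation constant matches published column and is an upper bound", {
  taus <- vapply(seq_len(nrow(vp)), function(i)
    as.numeric(tau_d_from_endpoints(
      vcmax_kinetics(vp$Vcmax_H[i], vp$Vcmax_L[i], tau_a = 0))),
    numeric(1))
  expect_equal(round(taus), c(241, 242, 253, 248))
  expect_true(attr(tau_d_from_endpoints(adenantha_v()), "upper_bound"))

  # general endpoint form reduces to the +1 convention exactly
  k <- adenantha_v()
  expect_equal(
    as.numeric(tau_d_from_endpoints(k, vcmax_end_of_shade = 95 + 1)),
    as.numeric(tau_d_from_endpoints(k)), tolerance = 1e-12)

  expect_error(tau_d_from_endpoints(vcmax_kinetics(96, 95.5, tau_a = 0)),
               "undefined")
})

test_that("endpoint constant is antitone in the Vcmax drop and linear in shade duration", {
  gaps <- seq(5, 200, by = 5)
  taus <- vapply(gaps, function(g)
    as.numeric(tau_d_from_endpoints(vcmax_kinetics(239, 239 - g,
                                                   tau_a = 0))),
    numeric(1))
  expect_true(all(diff(taus) < 0))
  k1 <- vcmax_kinetics(239, 95, tau_a = 0, t_L = 600)
  k2 <- vcmax_kinetics(239, 95, tau_a = 0, t_L = 1800)
  expect_equal(as.numeric(tau_d_from_endpoints(k2)),
               3 * as.numeric(tau_d_from_endpoints(k1)))
})

test_that("noise-free series are recovered exactly by the piecewise fit", {
  p <- adenantha_s()
  ser <- gen_activation_series(p, noise_sd = 0, seed = 1, param_cv = 0)
  fit <- fit_piecewise_S(ser, t_L = 1200)
  expect_true(fit$convergence)
  expect_equal(unname(fit$params[c("S_H", "S_L", "tau_d", "tau_a")]),
               c(80, 59, 108, 144), tolerance = 1e-6)
  expect_lt(fit$sigma, 1e-6)
  # model discontinuity at the shade/sun boundary is reported
  expect_equal(fit$discontinuity, 21 * exp(-1200 / 108), tolerance = 1e-4)
})

test_that("piecewise fit rejects series missing a phase", {
  p <- adenantha_s()
  ser <- gen_activation_series(p, noise_sd = 0, seed = 1, param_cv = 0)
  expect_error(fit_piecewise_S(ser[ser$phase != "shade", ], t_L = 1200),
               "phases")
  expect_error(fit_piecewise_S(ser[, c("t_s", "phase")], t_L = 1200),
               "value")
})

test_that("noisy piecewise fits recover time constants with small median bias", {
  rec <- recovery_piecewise_S(40, adenantha_s(), noise_sd = 3,
                              base_seed = 400)
  expect_gt(nrow(rec), 35)
  expect_lt(abs(median(rec$tau_d) / 108 - 1), 0.15)
  expect_lt(abs(median(rec$tau_a) / 144 - 1), 0.15)
})

test_that("induction-window fit recovers noise-free parameters and rejects bad windows", {
  k <- adenantha_v()
  t <- seq(60, 300, by = 10)
  ser <- data.frame(t_s = t, value = vcmax_induction(t, k))
  fit <- fit_vcmax_induction(ser)
  expect_true(fit$convergence)
  expect_equal(unname(fit$params[c("Vcmax_H", "Vcmax_L", "tau_a")]),
               c(239, 95, 180), tolerance = 1e-5)

  early <- data.frame(t_s = c(30, t), value = c(90, ser$value))
  expect_error(fit_vcmax_induction(early), "window")
  expect_error(fit_vcmax_induction(ser[1:5, ]), ">= 6")
})

test_that("accession aggregation gives t-based confidence intervals", {
  agg <- aggregate_accession(list(c(tau_d = 100), c(tau_d = 140)),
                             c("acc1", "acc1"))
  expect_equal(agg$mean, 120)
  expect_equal(agg$ci95, qt(0.975, 1) * 20, tolerance = 1e-10)

  same <- aggregate_accession(rep(list(c(tau_a = 144)), 4), rep("a", 4))
  expect_equal(same$mean, 144)
  expect_equal(same$ci95, 0)

  single <- aggregate_accession(list(c(tau_a = 144)), "a")
  expect_true(is.na(single$ci95))
  expect_equal(single$n_individuals, 1L)

  # accession with only failed fits is dropped with a message
  bad <- structure(list(model = "piecewise_S", convergence = FALSE),
                   class = "rubidyn_fit")
  expect_message(
    agg2 <- aggregate_accession(list(c(tau_d = 100), bad), c("a", "b")),
    "omitted")
  expect_identical(unique(agg2$accession), "a")
})

test_that("published means satisfy the in-vitro/in-vivo deactivation ratio bound", {
  tau_d_V <- vapply(seq_len(nrow(vp)), function(i)
    as.numeric(tau_d_from_endpoints(
      vcmax_kinetics(vp$Vcmax_H[i], vp$Vcmax_L[i], tau_a = 0))),
    numeric(1))
  expect_lte(max(vp$tau_d_S / tau_d_V), 0.53)
})
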