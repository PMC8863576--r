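test_that("non-rectangular hyperbola matches hand evaluation and limits", {
  p <- it86_light()
  expect_equal(nrh_assimilation(0, p), -1.85)
  # hand evaluation at the sun PPFD of the experimental protocol
  expect_equal(nrh_assimilation(850, p), 26.67317, tolerance = 1e-5)

  # Blackman limit at theta = 1 is min(phi*Q, A_sat) - R_d
  b <- light_response_params(0.05, 30, 1, 2)
  expect_equal(nrh_assimilation(c(100, 5000), b), c(0.05 * 100 - 2, 28))

  # theta -> 0 tends to the rectangular hyperbola
  r <- light_response_params(0.05, 30, 1e-6, 2)
  Q <- c(50, 200, 800, 2000)
  expect_equal(nrh_assimilation(Q, r),
               0.05 * Q * 30 / (0.05 * Q + 30) - 2, tolerance = 1e-3)
})

test_that("light response is non-decreasing and concave in PPFD", {
  p <- it86_light()
  Q <- seq(0, 2500, by = 5)
  A <- nrh_assimilation(Q, p)
  expect_true(all(diff(A) >= 0))
  expect_true(all(diff(diff(A)) <= 1e-10))
  expect_lt(max(A), p$A_sat - p$R_d + 1e-9)
})

test_that("light-response fit recovers noise-free parameters at the assay design points", {
  truth <- light_response_params(phi = 0.063, A_sat = 39, theta = 0.78,
                                 R_d = 2.17)
  curves <- gen_response_curves(truth, seed = 1, noise_sd = 0)
  expect_equal(nrow(curves$light), 14)
  fit <- fit_light_response(curves$light)
  expect_true(fit$convergence)
  expect_equal(unname(fit$params[c("phi", "A_sat", "theta", "R_d")]),
               c(0.063, 39, 0.78, 2.17), tolerance = 1e-4)
})

test_that("noisy light-response fits recover the initial slope", {
  truth <- light_response_params(0.063, 39, 0.78, 2.17)
  phis <- vapply(1:40, function(i) {
    curves <- gen_response_curves(truth, seed = 700 + i, noise_sd = 0.5)
    fit <- fit_light_response(curves$light)
    if (fit$convergence) fit$params[["phi"]] else NA_real_
  }, numeric(1))
  expect_lt(abs(mean(phis, na.rm = TRUE) / 0.063 - 1), 0.10)
})

test_that("light-response fit rejects degenerate curves", {
  expect_error(fit_light_response(data.frame(x = c(0, 500, 1500),
                                             A = c(-2, 15, 25))), ">= 6")
  hi <- data.frame(x = seq(500, 2000, length.out = 8), A = 20)
  expect_error(fit_light_response(hi), "anchor R_d")
})

test_that("A/ci fit recovers noise-free FvCB parameters including g_m", {
  truth <- list(Vcmax = 120, J = 220, R_d = 1.8, g_m = 2)
  curves <- gen_response_curves(fvcb_truth = truth, seed = 2, noise_sd = 0)
  expect_equal(nrow(curves$co2), 15)
  fit <- fit_aci(curves$co2)
  expect_true(fit$convergence)
  expect_equal(fit$params[["Vcmax"]], 120, tolerance = 1e-3)
  expect_equal(fit$params[["J"]], 220, tolerance = 1e-3)
  expect_equal(fit$params[["R_d"]], 1.8, tolerance = 1e-2)
  expect_equal(fit$params[["g_m"]], 2, tolerance = 1e-2)
  expect_true(fit$vcmax_identifiable)
  expect_setequal(unique(fit$limitation), c("rubisco", "rubp"))
})

test_that("A/ci fit modes: fixed and infinite mesophyll conductance", {
  truth <- list(Vcmax = 120, J = 220, R_d = 1.8, g_m = 2)
  curves <- gen_response_curves(fvcb_truth = truth, seed = 3, noise_sd = 0)
  fx <- fit_aci(curves$co2, gm_mode = "fixed", g_m = 2)
  expect_true(fx$convergence)
  expect_equal(fx$params[["Vcmax"]], 120, tolerance = 1e-4)

  # infinite-g_m truth is recovered by the infinite-g_m fit
  inf_truth <- list(Vcmax = 120, J = 220, R_d = 1.8, g_m = Inf)
  ci <- gen_response_curves(fvcb_truth = inf_truth, seed = 4, noise_sd = 0)
  fi <- fit_aci(ci$co2, gm_mode = "infinite")
  expect_true(fi$convergence)
  expect_equal(fi$params[["Vcmax"]], 120, tolerance = 1e-4)
  expect_false("g_m" %in% names(fi$params))
})

test_that("noisy A/ci fits keep day respiration close to truth", {
  truth <- list(Vcmax = 120, J = 220, R_d = 1.8, g_m = 2)
  rds <- vapply(1:30, function(i) {
    curves <- gen_response_curves(fvcb_truth = truth, seed = 900 + i,
                                  noise_sd = 0.3)
    fit <- fit_aci(curves$co2)
    if (fit$convergence) fit$params[["R_d"]] else NA_real_
  }, numeric(1))
  expect_lt(abs(median(rds, na.rm = TRUE) / 1.8 - 1), 0.20)
})

test_that("curve entirely above the limitation transition flags Vcmax as unidentifiable", {
  truth <- list(Vcmax = 500, J = 150, R_d = 1.5, g_m = 5)
  curves <- gen_response_curves(fvcb_truth = truth, seed = 5, noise_sd = 0)
  expect_warning(fit <- fit_aci(curves$co2, init = list(
    Vcmax = 480, J = 150, R_d = 1.5, g_m = 5)), "unidentifiable")
  expect_false(fit$vcmax_identifiable)
})
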