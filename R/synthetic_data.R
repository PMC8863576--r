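# Seeded generators for every input the pipeline consumes: leaf-disc
# activation-state series on the experimental sampling schedule,
# 10-s-interval gas-exchange traces, and steady-state response curves.
# All generators are pure functions of (parameters, seed).

#' Leaf-disc sampling schedule for sun-shade-sun assays
#'
#' The experimental schedule: two pre-shade baseline samples, then within
#' each of the shade and post-shade phases samples every 15 s for the
#' first 2 min and every 2 min thereafter until 20 min — 36 sample times
#' in total at the defaults.
#'
#' @param pre_shade_times times before shade onset (s, positive).
#' @param fast_every,fast_until fast-phase interval and extent (s).
#' @param slow_every,until slow-phase interval and extent (s).
#' @return List with `pre_shade_times`, `within_phase_times` (applied to
#'   both shade and post-shade) and `phases`.
#' @export
#' @examples
#' sched <- default_schedule()
#' length(sched$pre_shade_times) + 2 * length(sched$within_phase_times)
default_schedule <- function(pre_shade_times = c(180, 60), fast_every = 15,
                             fast_until = 120, slow_every = 120,
                             until = 1200) {
  within <- c(seq(fast_every, fast_until, by = fast_every),
              seq(fast_until + slow_every, until, by = slow_every))
  stopifnot(all(pre_shade_times > 0), !anyDuplicated(within),
            all(within <= until))
  list(pre_shade_times = sort(pre_shade_times, decreasing = TRUE),
       within_phase_times = within,
       phases = c("shade", "post_shade"))
}

.phase_of <- function(t, t_L) {
  ifelse(t <= -t_L, "pre_shade", ifelse(t <= 0, "shade", "post_shade"))
}

#' Generate synthetic activation-state time series
#'
#' Evaluates the piecewise activation-state model at the sampling-schedule
#' times, adds Gaussian measurement noise, clips to [0, 100] and tags
#' phases. Among-individual variation is emulated by jittering the true
#' parameters per individual: lognormal on the time constants (preserves
#' positivity) and Gaussian on the asymptotes, both with coefficient of
#' variation `param_cv`.
#'
#' @param true_params a [piecewise_s_params()].
#' @param schedule a [default_schedule()] list.
#' @param noise_sd Gaussian measurement noise sd (percentage points);
#'   default 3.
#' @param n_individuals number of individuals to simulate.
#' @param seed RNG seed (required; generators are pure in (params, seed)).
#' @param param_cv among-individual coefficient of variation; 0 disables
#'   jitter.
#' @param accession accession label for the output.
#' @return Data.frame with columns `individual_id`, `accession`, `t_s`,
#'   `phase`, `value` (t relative to start of induction).
#' @export
gen_activation_series <- function(true_params, schedule = default_schedule(),
                                  noise_sd = 3, n_individuals = 1, seed,
                                  param_cv = 0.1, accession = "synthetic") {
  stopifnot(inherits(true_params, "piecewise_s_params"))
  if (missing(seed)) stop("gen_activation_series() requires a `seed`")
  .check_scalar(noise_sd, "noise_sd", 0, Inf)
  set.seed(seed)
  t_L <- true_params$t_L
  t_s <- c(-t_L - schedule$pre_shade_times,
           -t_L + schedule$within_phase_times,
           schedule$within_phase_times)
  sdlog <- sqrt(log(1 + param_cv^2))
  out <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    p <- true_params
    if (param_cv > 0) {
      p$tau_d <- p$tau_d * exp(rnorm(1, 0, sdlog))
      p$tau_a <- p$tau_a * exp(rnorm(1, 0, sdlog))
      p$S_H <- min(100, max(0, p$S_H + rnorm(1, 0, param_cv * p$S_H)))
      p$S_L <- min(p$S_H, max(0, p$S_L + rnorm(1, 0, param_cv * p$S_L)))
    }
    value <- s_piecewise(t_s, p) + rnorm(length(t_s), 0, noise_sd)
    out[[i]] <- data.frame(
      individual_id = sprintf("%s_%02d", accession, i),
      accession = accession, t_s = t_s, phase = .phase_of(t_s, t_L),
      value = pmin(100, pmax(0, value)), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a synthetic sun-shade-sun gas-exchange trace
#'
#' Forward-simulates a full induction experiment: the Vc,max trajectory is
#' held at `Vcmax_H` pre-shade, declines exponentially with `tau_d` during
#' shade and recovers with `tau_a` post-shade; net assimilation at each
#' 10-s log point is the Rubisco-limited FvCB rate at the chloroplastic
#' CO2 implied by the supplied intercellular CO2 trajectory (the implicit
#' `c_c = c_i - A/g_m` is solved exactly per point), plus Gaussian noise
#' on A. Intercellular CO2 dynamics are not modelled mechanistically:
#' default is a constant 27 Pa, optionally with a linear post-shade
#' drawdown.
#'
#' @param true_kinetics a [vcmax_kinetics()] with `tau_d` set.
#' @param ctx an [fvcb_context()].
#' @param ci_pa intercellular CO2 (Pa): a constant, or a function of time
#'   `t_s` (s relative to end of shade).
#' @param log_interval_s logging interval (s); default 10.
#' @param t_pre_s,t_post_s pre-shade and post-shade durations (s).
#' @param noise_sd Gaussian noise sd on A (umol m-2 s-1); default 0.5.
#' @param seed RNG seed (required).
#' @param accession,individual_id labels.
#' @param pressure_kpa pressure used to express `ci` as a mole fraction in
#'   the output.
#' @return Data.frame with columns `individual_id`, `accession`, `t_s`
#'   (s relative to end of shade), `A`, `ci` (umol mol-1), `Tleaf`,
#'   `ppfd`, `pressure_kpa`, plus the noise-free truth columns
#'   `Vcmax_true` and `ci_pa`.
#' @export
gen_gasex_series <- function(true_kinetics, ctx, ci_pa = 27,
                             log_interval_s = 10, t_pre_s = 2400,
                             t_post_s = 1200, noise_sd = 0.5, seed,
                             accession = "synthetic",
                             individual_id = "synthetic_01",
                             pressure_kpa = 101.325) {
  stopifnot(inherits(true_kinetics, "vcmax_kinetics"),
            inherits(ctx, "fvcb_context"))
  if (missing(seed)) stop("gen_gasex_series() requires a `seed`")
  if (is.na(true_kinetics$tau_d))
    stop("`true_kinetics$tau_d` must be set to simulate the shade decline")
  set.seed(seed)
  t_L <- true_kinetics$t_L
  t_s <- seq(-t_L - t_pre_s, t_post_s, by = log_interval_s)
  vc <- numeric(length(t_s))
  pre <- t_s < -t_L
  shade <- t_s >= -t_L & t_s < 0
  post <- t_s >= 0
  vc[pre] <- true_kinetics$Vcmax_H
  vc[shade] <- vcmax_shade(t_s[shade] + t_L, true_kinetics)
  vc[post] <- vcmax_induction(t_s[post], true_kinetics)
  ci_vec <- if (is.function(ci_pa)) ci_pa(t_s) else rep(ci_pa, length(t_s))
  # Rubisco-limited rate at the c_c implied by c_i: quadratic in A
  A_true <- .aci_model(ci_vec, vc, Inf, ctx$R_d, ctx$g_m,
                       .km_eff(ctx), ctx$Gamma_star)
  A <- A_true + rnorm(length(t_s), 0, noise_sd)
  data.frame(individual_id = individual_id, accession = accession,
             t_s = t_s, A = A,
             ci = ci_vec * 1000 / pressure_kpa, Tleaf = 30,
             ppfd = ifelse(pre | post, 850, 150),
             pressure_kpa = pressure_kpa,
             Vcmax_true = vc, ci_pa = ci_vec, stringsAsFactors = FALSE)
}

#' Generate synthetic steady-state response curves
#'
#' Light curves at the 14-level PPFD assay sequence and CO2 curves at the
#' 15-level intercellular CO2 assay sequence, with Gaussian noise on A.
#' Light-curve truth is the non-rectangular hyperbola; CO2-curve truth is
#' the finite-g_m FvCB model (minimum of Rubisco- and RuBP-regeneration-
#' limited rates).
#'
#' @param light_params a [light_response_params()] (or NULL to skip).
#' @param fvcb_truth named list/vector with `Vcmax`, `J`, `R_d`, `g_m`
#'   (or NULL to skip the CO2 curve).
#' @param kinetics list with `K_C`, `K_O`, `Gamma_star` for the CO2 curve.
#' @param O oxygen partial pressure (kPa).
#' @param ppfd_levels,co2_levels design points (defaults: the assay
#'   sequences; 14 and 15 levels).
#' @param noise_sd Gaussian noise sd on A (umol m-2 s-1).
#' @param seed RNG seed (required).
#' @param pressure_kpa pressure for mole-fraction/partial-pressure
#'   conversion.
#' @return List with data.frames `light` and `co2` (columns `x`, `A`,
#'   `kind`), either possibly NULL.
#' @export
gen_response_curves <- function(light_params = NULL, fvcb_truth = NULL,
                                kinetics = tobacco_kinetics(30),
                                O = to_partial_pressure(209.5, 101.325),
                                ppfd_levels = c(1500, 2000, 1700, 1300,
                                                1100, 900, 700, 500, 400,
                                                300, 200, 100, 50, 0),
                                co2_levels = c(430, 375, 300, 225, 150, 75,
                                               30, 430, 500, 575, 625, 700,
                                               800, 900, 1000),
                                noise_sd = 0.5, seed,
                                pressure_kpa = 101.325) {
  if (missing(seed)) stop("gen_response_curves() requires a `seed`")
  set.seed(seed)
  out <- list(light = NULL, co2 = NULL)
  if (!is.null(light_params)) {
    A <- nrh_assimilation(ppfd_levels, light_params) +
      rnorm(length(ppfd_levels), 0, noise_sd)
    out$light <- data.frame(x = ppfd_levels, A = A, kind = "light",
                            stringsAsFactors = FALSE)
  }
  if (!is.null(fvcb_truth)) {
    ft <- as.list(fvcb_truth)
    Km <- kinetics$K_C * (1 + O / kinetics$K_O)
    ci_pa <- to_partial_pressure(co2_levels, pressure_kpa)
    A <- .aci_model(ci_pa, ft$Vcmax, ft$J, ft$R_d, ft$g_m, Km,
                    kinetics$Gamma_star) +
      rnorm(length(co2_levels), 0, noise_sd)
    out$co2 <- data.frame(x = co2_levels, A = A, kind = "co2",
                          stringsAsFactors = FALSE)
  }
  out
}

# ---- parameter-recovery harness -------------------------------------------

#' Recovery study for the piecewise activation-state fit
#'
#' Repeatedly generates a single-individual activation series (no
#' among-individual jitter), fits it, and collects the recovered
#' parameters — the harness used to verify that the sampling schedule and
#' noise level support unbiased time-constant estimation.
#'
#' @param n_seeds number of replicate worlds.
#' @param true_params a [piecewise_s_params()].
#' @param noise_sd measurement noise sd (percentage points).
#' @param schedule sampling schedule.
#' @param base_seed seeds used are `base_seed + 1:n_seeds`.
#' @param exclude_bound_hits drop replicates whose fit pinned a parameter
#'   at a box bound (default TRUE): such fits are flagged as unresolved,
#'   not estimates, and would otherwise contaminate the summary.
#' @return Data.frame with one row per usable replicate: `seed`,
#'   `S_H`, `S_L`, `tau_d`, `tau_a`.
#' @export
recovery_piecewise_S <- function(n_seeds, true_params, noise_sd = 3,
                                 schedule = default_schedule(),
                                 base_seed = 0,
                                 exclude_bound_hits = TRUE) {
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    ser <- gen_activation_series(true_params, schedule, noise_sd = noise_sd,
                                 n_individuals = 1, seed = base_seed + i,
                                 param_cv = 0)
    fit <- fit_piecewise_S(ser, t_L = true_params$t_L)
    if (!fit$convergence) next
    if (exclude_bound_hits && length(fit$bounds_hit)) next
    rows[[i]] <- data.frame(seed = base_seed + i, t(fit$params))
  }
  do.call(rbind, rows)
}

#' Recovery study for the gas-exchange tau_a pipeline
#'
#' Full-pipeline recovery: simulate a noisy gas-exchange trace, invert
#' one-point Vc,max in the 1-5 min Rubisco-limited window, fit the
#' induction model, and collect the recovered activation time constant.
#'
#' @param n_seeds number of replicate worlds.
#' @param true_kinetics a [vcmax_kinetics()] with `tau_d` set.
#' @param ctx an [fvcb_context()].
#' @param noise_sd Gaussian noise sd on A (umol m-2 s-1).
#' @param base_seed seeds used are `base_seed + 1:n_seeds`.
#' @param ci_pa intercellular CO2 (Pa) passed to [gen_gasex_series()].
#' @param exclude_bound_hits drop replicates whose fit pinned a parameter
#'   at a box bound (see [recovery_piecewise_S()]).
#' @return Data.frame with one row per usable replicate: `seed`,
#'   `Vcmax_H`, `Vcmax_L`, `tau_a`.
#' @export
recovery_vcmax_pipeline <- function(n_seeds, true_kinetics, ctx,
                                    noise_sd = 0.5, base_seed = 0,
                                    ci_pa = 27, exclude_bound_hits = TRUE) {
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    rec <- gen_gasex_series(true_kinetics, ctx, ci_pa = ci_pa,
                            noise_sd = noise_sd, seed = base_seed + i)
    win <- vcmax_window(rec, ctx)
    fit <- fit_vcmax_induction(data.frame(t_s = win$t_s, value = win$Vcmax))
    if (!fit$convergence) next
    if (exclude_bound_hits && length(fit$bounds_hit)) next
    rows[[i]] <- data.frame(seed = base_seed + i, t(fit$params))
  }
  do.call(rbind, rows)
}
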