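# Kinetic models of Rubisco regulation across sun-shade-sun transitions.
#
# Time convention: t is relative to the start of post-shade induction, so
# pre-shade is t <= -t_L, shade is -t_L < t <= 0, induction is t > 0.

.s_piecewise <- function(t, S_H, S_L, tau_d, tau_a, t_L) {
  S <- numeric(length(t))
  a <- t <= -t_L
  b <- t > -t_L & t <= 0
  cc <- t > 0
  S[a] <- S_H
  S[b] <- S_L - (S_L - S_H) * .decay(t[b] + t_L, tau_d)
  S[cc] <- S_H - (S_H - S_L) * .decay(t[cc], tau_a)
  S
}

#' Piecewise exponential model of Rubisco activation state
#'
#' Activation state through a sun-shade-sun sequence: constant at `S_H`
#' before shade; exponential relaxation from `S_H` towards `S_L` with time
#' constant `tau_d` during shade; exponential recovery from `S_L` towards
#' `S_H` with time constant `tau_a` after shade. The model is continuous
#' at shade onset; at the shade/sun boundary (t = 0) the recovery branch
#' starts from exactly `S_L`, so a discontinuity of magnitude
#' `(S_H - S_L) * exp(-t_L/tau_d)` remains unless the shade phase has
#' reached its asymptote — implemented as written, and reported as a fit
#' diagnostic by [fit_piecewise_S()].
#'
#' @param t time (s) relative to the start of induction (negative during
#'   pre-shade and shade); vectorized.
#' @param p a [piecewise_s_params()].
#' @return Activation state (%) at each `t`.
#' @export
#' @examples
#' p <- piecewise_s_params(S_H = 80, S_L = 59, tau_d = 108, tau_a = 144)
#' s_piecewise(c(-1200, -1092, 0.001, 1e6), p)
s_piecewise <- function(t, p) {
  stopifnot(inherits(p, "piecewise_s_params"))
  .s_piecewise(t, p$S_H, p$S_L, p$tau_d, p$tau_a, p$t_L)
}

.vcmax_induction <- function(t, Vcmax_H, Vcmax_L, tau_a) {
  Vcmax_H - (Vcmax_H - Vcmax_L) * .decay(t, tau_a)
}

#' Vc,max recovery during post-shade induction
#'
#' Exponential recovery of the maximum carboxylation rate from its shade
#' steady state `Vcmax_L` towards the high-light steady state `Vcmax_H`
#' with activation time constant `tau_a`.
#'
#' @param t time since end of shade (s), >= 0; vectorized.
#' @param k a [vcmax_kinetics()].
#' @return Vc,max (umol m-2 s-1) at each `t`.
#' @export
#' @examples
#' k <- vcmax_kinetics(239, 95, tau_a = 180)
#' vcmax_induction(c(0, 180, 1e6), k)
vcmax_induction <- function(t, k) {
  stopifnot(inherits(k, "vcmax_kinetics"))
  if (any(t < 0)) stop("vcmax_induction() applies post-shade only (t >= 0)")
  .vcmax_induction(t, k$Vcmax_H, k$Vcmax_L, k$tau_a)
}

#' Vc,max decline during shade
#'
#' Exponential decline from `Vcmax_H` towards `Vcmax_L` with deactivation
#' time constant `tau_d`; used to synthesize shade-phase trajectories and
#' as the forward model behind [tau_d_from_endpoints()].
#'
#' @param t time since start of shade (s), >= 0; vectorized.
#' @param k a [vcmax_kinetics()] with `tau_d` set.
#' @return Vc,max (umol m-2 s-1) at each `t`.
#' @export
vcmax_shade <- function(t, k) {
  stopifnot(inherits(k, "vcmax_kinetics"))
  if (any(t < 0)) stop("vcmax_shade() requires t >= 0 (time into shade)")
  if (is.na(k$tau_d)) stop("`k$tau_d` is not set")
  k$Vcmax_L - (k$Vcmax_L - k$Vcmax_H) * .decay(t, k$tau_d)
}

#' Closed-form deactivation time constant from shade endpoints
#'
#' Inverts the exponential shade decline of Vc,max to solve for the
#' deactivation time constant from its endpoints. With the convention that
#' Vc,max at the end of a shade period of length `t_L` has come to within
#' 1 umol m-2 s-1 of its asymptote (`Vcmax = Vcmax_L + 1`), the expression
#' simplifies to `tau_d = t_L / ln(Vcmax_H - Vcmax_L)`. Supplying
#' `vcmax_end_of_shade` uses the general form
#' `tau_d = -t_L / ln((Vcmax_L - Vcmax) / (Vcmax_L - Vcmax_H))` instead.
#'
#' Either way the result is an **upper limit** on the true deactivation
#' time constant (it shrinks as the assumed end-of-shade gap
#' `Vcmax - Vcmax_L` tends to 0); the return value carries attribute
#' `upper_bound = TRUE` to flag this.
#'
#' @param k a [vcmax_kinetics()]; requires `Vcmax_H - Vcmax_L > 1`.
#' @param vcmax_end_of_shade optional observed Vc,max at the end of shade,
#'   strictly between `Vcmax_L` and `Vcmax_H`.
#' @return Deactivation time constant (s) with attribute `upper_bound`.
#' @export
#' @examples
#' round(tau_d_from_endpoints(vcmax_kinetics(239, 95, tau_a = 180)))  # 241
tau_d_from_endpoints <- function(k, vcmax_end_of_shade = NULL) {
  stopifnot(inherits(k, "vcmax_kinetics"))
  gap <- k$Vcmax_H - k$Vcmax_L
  if (gap <= 1)
    stop("tau_d is undefined for Vcmax_H - Vcmax_L <= 1: the end-of-shade ",
         "convention Vcmax = Vcmax_L + 1 makes the log argument <= 0")
  tau <- if (is.null(vcmax_end_of_shade)) {
    k$t_L / log(gap)
  } else {
    v <- vcmax_end_of_shade
    if (v <= k$Vcmax_L || v >= k$Vcmax_H)
      stop("`vcmax_end_of_shade` must lie strictly between Vcmax_L and Vcmax_H")
    -k$t_L / log((k$Vcmax_L - v) / (k$Vcmax_L - k$Vcmax_H))
  }
  structure(tau, upper_bound = TRUE)
}

# ---- nonlinear least-squares machinery ------------------------------------

# run bounded Levenberg-Marquardt from several deterministic starts and
# keep the converged fit with the lowest deviance
.multistart_nls <- function(formula, data, starts, lower, upper) {
  best <- NULL
  best_start <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st,
                        lower = lower[names(st)], upper = upper[names(st)],
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(fit) && (is.null(best) || deviance(fit) < deviance(best))) {
      best <- fit
      best_start <- st
    }
  }
  list(fit = best, start = best_start)
}

.fit_report <- function(fit, start, model, n, lower, upper, extra = list()) {
  if (is.null(fit)) {
    return(structure(c(list(model = model, convergence = FALSE,
                            message = "no start converged", params = NULL,
                            se = NULL, sigma = NA_real_, residuals = NULL,
                            n = n), extra), class = "rubidyn_fit"))
  }
  params <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(params)))
  tol <- 1e-6
  at_lower <- names(params)[params <= lower[names(params)] + tol]
  at_upper <- names(params)[params >= upper[names(params)] - tol]
  structure(c(list(model = model, convergence = TRUE, message = "converged",
                   params = params, se = se,
                   sigma = sqrt(deviance(fit) / max(1, n - length(params))),
                   residuals = as.numeric(stats::residuals(fit)), n = n,
                   start_used = unlist(start),
                   bounds_hit = c(at_lower, at_upper)),
              extra),
            class = "rubidyn_fit")
}

#' @export
print.rubidyn_fit <- function(x, ...) {
  cat(sprintf("<rubidyn_fit: %s>\n", x$model))
  if (!x$convergence) {
    cat("  NOT converged:", x$message, "\n")
    return(invisible(x))
  }
  est <- format(signif(x$params, 5))
  se <- format(signif(x$se, 3))
  for (i in seq_along(x$params))
    cat(sprintf("  %-8s %s  (se %s)\n", names(x$params)[i], est[i], se[i]))
  cat(sprintf("  residual sd %.4g on %d points\n", x$sigma, x$n))
  if (length(x$bounds_hit))
    cat("  parameter(s) at bound:", paste(x$bounds_hit, collapse = ", "), "\n")
  if (!is.null(x$discontinuity))
    cat(sprintf("  shade/sun boundary discontinuity: %.3g\n",
                x$discontinuity))
  invisible(x)
}

#' Fit the piecewise activation-state model to one individual
#'
#' Bounded nonlinear least squares for `S_H`, `S_L`, `tau_d`, `tau_a` from
#' a sun-shade-sun time series of activation state. The optimizer is
#' Levenberg-Marquardt with box bounds (`0 <= S <= 100`,
#' `0 <= tau <= 5000` s) run from five deterministic starts (asymptote
#' guesses from the observed quartiles, `tau` starts spanning 30-480 s) to
#' guard against the flat-likelihood regime when a time constant
#' approaches 0; the lowest-deviance converged fit is kept. A `tau`
#' reported at the 0 bound means the transition was not resolvable from
#' instantaneous at this sampling density.
#'
#' @param series data.frame with columns `t_s` (s, relative to the start of
#'   induction; negative in pre-shade/shade) and `value` (activation
#'   state, %). Needs >= 2 pre-shade, >= 4 shade and >= 4 post-shade
#'   points.
#' @param t_L shade duration (s).
#' @param init optional named list/vector of starting values
#'   (`S_H`, `S_L`, `tau_d`, `tau_a`) replacing the multi-start.
#' @param lower,upper named box bounds.
#' @return A `rubidyn_fit`: estimates, approximate standard errors from the
#'   Jacobian, residuals, residual sd, convergence flag, bound diagnostics,
#'   and the magnitude of the model's shade/sun boundary discontinuity.
#' @export
#' @examples
#' p <- piecewise_s_params(80, 59, tau_d = 108, tau_a = 144)
#' sched <- default_schedule()
#' ser <- gen_activation_series(p, sched, noise_sd = 0, seed = 1,
#'                              param_cv = 0)
#' fit_piecewise_S(ser, t_L = 1200)
fit_piecewise_S <- function(series, t_L, init = NULL,
                            lower = c(S_H = 0, S_L = 0, tau_d = 0, tau_a = 0),
                            upper = c(S_H = 100, S_L = 100, tau_d = 5000,
                                      tau_a = 5000)) {
  .require_columns(series, c("t_s", "value"), "`series`")
  .check_scalar(t_L, "t_L", 0, Inf, open_lower = TRUE)
  t <- series$t_s
  n_pre <- sum(t <= -t_L)
  n_shade <- sum(t > -t_L & t <= 0)
  n_post <- sum(t > 0)
  if (n_pre < 2L || n_shade < 4L || n_post < 4L)
    stop(sprintf(paste0("series must span all three phases with >= 2 ",
                        "pre-shade, >= 4 shade and >= 4 post-shade points ",
                        "(got %d/%d/%d)"), n_pre, n_shade, n_post))
  v <- series$value
  q <- stats::quantile(v, c(0.1, 0.25, 0.75, 0.9), names = FALSE)
  starts <- if (!is.null(init)) list(as.list(init)) else list(
    list(S_H = q[4], S_L = q[1], tau_d = 30, tau_a = 30),
    list(S_H = q[4], S_L = q[1], tau_d = 120, tau_a = 120),
    list(S_H = q[4], S_L = q[1], tau_d = 480, tau_a = 480),
    list(S_H = q[3], S_L = q[2], tau_d = 30, tau_a = 480),
    list(S_H = q[3], S_L = q[2], tau_d = 480, tau_a = 30))
  ms <- .multistart_nls(
    value ~ .s_piecewise(t_s, S_H, S_L, tau_d, tau_a, t_L),
    data = list(t_s = t, value = v, t_L = t_L),
    starts = starts, lower = lower, upper = upper)
  disc <- if (!is.null(ms$fit)) {
    cf <- coef(ms$fit)
    abs((cf[["S_H"]] - cf[["S_L"]]) * .decay(t_L, cf[["tau_d"]]))
  } else NA_real_
  .fit_report(ms$fit, ms$start, "piecewise_S", length(v), lower, upper,
              extra = list(t_L = t_L, discontinuity = disc))
}

#' Fit the Vc,max induction model to a post-shade window
#'
#' Bounded nonlinear least squares for `Vcmax_H`, `Vcmax_L`, `tau_a` from
#' one-point Vc,max estimates in the window 1-5 min after shade — the
#' period when assimilation is consistently Rubisco-limited. Points
#' outside the window are rejected rather than silently dropped; use
#' [vcmax_window()] to subset first.
#'
#' @param series data.frame with columns `t_s` (s since end of shade) and
#'   `value` (Vc,max, umol m-2 s-1); all `t_s` within `window`, >= 6
#'   points.
#' @param init optional named starting values (`Vcmax_H`, `Vcmax_L`,
#'   `tau_a`).
#' @param window inclusive fitting window (s); default `c(60, 300)`.
#' @return A `rubidyn_fit` (same contract as [fit_piecewise_S()]).
#' @export
fit_vcmax_induction <- function(series, init = NULL, window = c(60, 300)) {
  .require_columns(series, c("t_s", "value"), "`series`")
  t <- series$t_s
  if (any(t < window[1L] | t > window[2L]))
    stop(sprintf("series contains points outside the %g-%g s fitting window",
                 window[1L], window[2L]))
  if (length(t) < 6L)
    stop("need >= 6 points in the fitting window")
  v <- series$value
  q <- stats::quantile(v, c(0.05, 0.25, 0.75, 0.95), names = FALSE)
  lower <- c(Vcmax_H = 1, Vcmax_L = 0, tau_a = 0)
  upper <- c(Vcmax_H = 1000, Vcmax_L = 1000, tau_a = 5000)
  starts <- if (!is.null(init)) list(as.list(init)) else list(
    list(Vcmax_H = q[4], Vcmax_L = q[1], tau_a = 30),
    list(Vcmax_H = q[4], Vcmax_L = q[1], tau_a = 120),
    list(Vcmax_H = q[4], Vcmax_L = q[1], tau_a = 480),
    list(Vcmax_H = max(v), Vcmax_L = max(min(v) / 2, 1), tau_a = 120),
    list(Vcmax_H = q[3], Vcmax_L = q[2], tau_a = 60))
  ms <- .multistart_nls(
    value ~ .vcmax_induction(t_s, Vcmax_H, Vcmax_L, tau_a),
    data = list(t_s = t, value = v),
    starts = starts, lower = lower, upper = upper)
  .fit_report(ms$fit, ms$start, "vcmax_induction", length(v), lower, upper)
}

#' Aggregate per-individual fits to accession means
#'
#' Arithmetic mean and t-distribution 95% confidence half-width of each
#' fitted parameter across the individuals of an accession — the
#' descriptive counterpart of a fixed-effects summary. Half-widths are
#' reported only for accessions with at least two individuals. Accessions
#' whose fits all failed to converge are dropped with a message.
#'
#' @param fits list of `rubidyn_fit` objects (or named numeric parameter
#'   vectors).
#' @param accessions character vector of accession labels, one per fit.
#' @return A data.frame with columns `accession`, `parameter`, `mean`,
#'   `ci95`, `n_individuals`.
#' @export
#' @examples
#' aggregate_accession(list(c(tau_d = 100), c(tau_d = 140)), c("a", "a"))
aggregate_accession <- function(fits, accessions) {
  stopifnot(length(fits) == length(accessions))
  params <- lapply(fits, function(f) {
    if (inherits(f, "rubidyn_fit")) {
      if (!isTRUE(f$convergence)) NULL else f$params
    } else {
      f
    }
  })
  keep <- !vapply(params, is.null, logical(1L))
  dropped <- setdiff(unique(accessions), unique(accessions[keep]))
  if (length(dropped))
    message("no converged fits for accession(s): ",
            paste(dropped, collapse = ", "), " - omitted from summary")
  params <- params[keep]
  accessions <- accessions[keep]
  out <- list()
  for (acc in unique(accessions)) {
    pp <- params[accessions == acc]
    pnames <- unique(unlist(lapply(pp, names)))
    for (pn in pnames) {
      x <- vapply(pp, function(p) if (pn %in% names(p)) p[[pn]] else NA_real_,
                  numeric(1L))
      s <- .mean_ci95(x)
      out[[length(out) + 1L]] <- data.frame(
        accession = acc, parameter = pn, mean = s[["mean"]],
        ci95 = s[["ci95"]], n_individuals = as.integer(s[["n"]]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
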