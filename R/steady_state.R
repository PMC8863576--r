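# Steady-state response-curve fits: the non-rectangular hyperbola light
# response (supplying phi, A_sat, theta, R_d for diurnal modelling) and an
# Ethier-type A/ci FvCB fit with finite mesophyll conductance (supplying
# R_d and g_m for one-point Vc,max inversion).

.nrh <- function(Q, phi, A_sat, theta, R_d) {
  if (theta >= 1) return(pmin(phi * Q, A_sat) - R_d)
  s <- phi * Q + A_sat
  disc <- s^2 - 4 * phi * theta * Q * A_sat
  disc[disc < 0] <- 0  # guard against rounding; exact disc is >= 0
  (s - sqrt(disc)) / (2 * theta) - R_d
}

#' Non-rectangular hyperbola light response
#'
#' Net assimilation as a saturating function of PPFD:
#' `A = (phi*Q + A_sat - sqrt((phi*Q + A_sat)^2 - 4*phi*theta*Q*A_sat)) /
#' (2*theta) - R_d`. At `theta = 1` this is evaluated as the algebraically
#' identical (and numerically safe) Blackman limit
#' `min(phi*Q, A_sat) - R_d`; as `theta -> 0` it tends to the rectangular
#' hyperbola.
#'
#' @param Q PPFD (umol m-2 s-1), >= 0; vectorized.
#' @param p a [light_response_params()].
#' @return Net assimilation (umol m-2 s-1).
#' @export
#' @examples
#' p <- light_response_params(phi = 0.063, A_sat = 36, theta = 0.77,
#'                            R_d = 1.85)
#' nrh_assimilation(850, p)
nrh_assimilation <- function(Q, p) {
  stopifnot(inherits(p, "light_response_params"))
  if (any(Q < 0)) stop("Q must be >= 0")
  .nrh(Q, p$phi, p$A_sat, p$theta, p$R_d)
}

#' Fit the non-rectangular hyperbola to an A/PPFD curve
#'
#' Bounded nonlinear least squares for `phi`, `A_sat`, `theta`, `R_d`.
#' The curve must include a dark or near-dark point (PPFD <= 50) so that
#' `R_d` is anchored by data rather than extrapolation. Multi-start as in
#' [fit_piecewise_S()]; `theta` pinned at a bound is reported in the
#' diagnostics.
#'
#' @param curve data.frame with columns `x` (PPFD, umol m-2 s-1) and `A`
#'   (umol m-2 s-1); >= 6 points.
#' @param init optional named starting values.
#' @return A `rubidyn_fit` whose `params` are `phi`, `A_sat`, `theta`,
#'   `R_d`.
#' @export
fit_light_response <- function(curve, init = NULL) {
  .require_columns(curve, c("x", "A"), "`curve`")
  if (nrow(curve) < 6L) stop("need >= 6 points to fit the light response")
  if (min(curve$x) > 50)
    stop("curve must include a PPFD <= 50 point to anchor R_d")
  Q <- curve$x
  A <- curve$A
  Rd0 <- max(0, -min(A))
  Amax <- max(A) + Rd0
  ilow <- order(Q)[1:3]
  slope <- stats::coef(stats::lm(A[ilow] ~ Q[ilow]))[[2L]]
  phi0 <- min(max(slope, 0.01), 0.15)
  lower <- c(phi = 1e-4, A_sat = 0.5, theta = 1e-3, R_d = 0)
  upper <- c(phi = 0.2, A_sat = 200, theta = 1, R_d = 20)
  starts <- if (!is.null(init)) list(as.list(init)) else list(
    list(phi = phi0, A_sat = Amax, theta = 0.8, R_d = Rd0),
    list(phi = phi0, A_sat = Amax, theta = 0.5, R_d = Rd0),
    list(phi = phi0, A_sat = Amax, theta = 0.95, R_d = Rd0),
    list(phi = 0.05, A_sat = 1.2 * Amax, theta = 0.7, R_d = 1),
    list(phi = 0.08, A_sat = 0.9 * Amax, theta = 0.9, R_d = 2))
  ms <- .multistart_nls(A ~ .nrh(Q, phi, A_sat, theta, R_d),
                        data = list(Q = Q, A = A),
                        starts = starts, lower = lower, upper = upper)
  .fit_report(ms$fit, ms$start, "light_response", length(A), lower, upper)
}

# smaller root of a*x^2 + b*x + c (a < 0 in the Ethier formulation);
# rounding can push the discriminant fractionally negative
.quad_min_root <- function(a, b, c) {
  disc <- b^2 - 4 * a * c
  disc[disc < 0] <- 0
  s <- sqrt(disc)
  pmin((-b + s) / (2 * a), (-b - s) / (2 * a))
}

# FvCB assimilation at given ci (Pa) with finite (or infinite) mesophyll
# conductance. The implicit c_c = ci - A/g_m makes each limitation state a
# quadratic in A (Ethier formulation); the smaller root is the physical
# one. J may be Inf to disable the RuBP-regeneration limitation.
.aci_model <- function(ci_pa, Vcmax, J, R_d, g_m, Km, Gamma_star) {
  if (is.infinite(g_m)) {
    Ac <- Vcmax * (ci_pa - Gamma_star) / (ci_pa + Km) - R_d
    Aj <- if (is.infinite(J)) Inf else
      J * (ci_pa - Gamma_star) / (4 * ci_pa + 8 * Gamma_star) - R_d
    return(pmin(Ac, Aj))
  }
  Ac <- .quad_min_root(
    a = -1 / g_m,
    b = ci_pa + Km - R_d / g_m + Vcmax / g_m,
    c = R_d * (ci_pa + Km) - Vcmax * (ci_pa - Gamma_star))
  if (is.infinite(J)) return(Ac)
  Aj <- .quad_min_root(
    a = -4 / g_m,
    b = 4 * ci_pa + 8 * Gamma_star - 4 * R_d / g_m + J / g_m,
    c = 4 * R_d * (ci_pa + 2 * Gamma_star) - J * (ci_pa - Gamma_star))
  pmin(Ac, Aj)
}

#' Fit the FvCB model to a steady-state A/ci curve
#'
#' Simultaneous nonlinear least squares for (`Vcmax`, `J`, `R_d`, `g_m`)
#' using the Ethier quadratic-in-A formulation: with finite mesophyll
#' conductance, `c_c = c_i - A/g_m` makes each limitation state (Rubisco-
#' or RuBP-regeneration-limited) a quadratic whose smaller root is the
#' physical assimilation rate; the realized rate at each point is the
#' minimum of the two (no smoothing hyperbola). Triose-phosphate-use
#' limitation is not modelled. This fit is the source of the `R_d` and
#' `g_m` held constant during induction by [one_point_vcmax()].
#'
#' The curve should span sub- and supra-ambient `c_i`; if every point lies
#' above the Rubisco/RuBP transition of the fitted model, `Vcmax` is
#' unidentifiable and the fit is flagged. A fitted `g_m` at its upper
#' bound is reported (`bounds_hit`) — prefer `gm_mode = "infinite"` then.
#'
#' @param curve data.frame with columns `x` (c_i, umol mol-1) and `A`
#'   (umol m-2 s-1); >= 6 points.
#' @param kinetics list with `K_C` (Pa), `K_O` (kPa), `Gamma_star` (Pa),
#'   e.g. from [tobacco_kinetics()] at the assay temperature.
#' @param O oxygen partial pressure (kPa).
#' @param pressure_kpa pressure used to convert `x` to Pa.
#' @param gm_mode `"fit"` (estimate g_m), `"fixed"` (use `g_m` as given),
#'   or `"infinite"` (c_c = c_i).
#' @param g_m fixed mesophyll conductance for `gm_mode = "fixed"`.
#' @param init optional named starting values.
#' @return A `rubidyn_fit` whose `params` are `Vcmax`, `J`, `R_d` and
#'   (unless infinite) `g_m`, plus a `limitation` vector ("rubisco"/
#'   "rubp") per point and `vcmax_identifiable` flag.
#' @export
fit_aci <- function(curve, kinetics = tobacco_kinetics(30),
                    O = to_partial_pressure(209.5, 101.325),
                    pressure_kpa = 101.325,
                    gm_mode = c("fit", "fixed", "infinite"), g_m = NULL,
                    init = NULL) {
  gm_mode <- match.arg(gm_mode)
  .require_columns(curve, c("x", "A"), "`curve`")
  if (nrow(curve) < 6L) stop("need >= 6 points to fit an A/ci curve")
  ci_pa <- to_partial_pressure(curve$x, pressure_kpa)
  A <- curve$A
  Km <- kinetics$K_C * (1 + O / kinetics$K_O)
  Gs <- kinetics$Gamma_star
  lower <- c(Vcmax = 5, J = 5, R_d = 0, g_m = 0.1)
  upper <- c(Vcmax = 500, J = 1000, R_d = 10, g_m = 50)
  base_starts <- list(
    list(Vcmax = 80, J = 160, R_d = 1.5, g_m = 2),
    list(Vcmax = 150, J = 300, R_d = 1.5, g_m = 2),
    list(Vcmax = 100, J = 200, R_d = 1, g_m = 8),
    list(Vcmax = 60, J = 120, R_d = 2, g_m = 4),
    list(Vcmax = 250, J = 400, R_d = 1, g_m = 1))
  if (gm_mode == "fit") {
    form <- A ~ .aci_model(ci_pa, Vcmax, J, R_d, g_m, Km, Gs)
    starts <- base_starts
    dat <- list(ci_pa = ci_pa, A = A, Km = Km, Gs = Gs)
  } else {
    gm_val <- if (gm_mode == "fixed") {
      if (is.null(g_m)) stop("gm_mode = \"fixed\" requires `g_m`")
      g_m
    } else {
      Inf
    }
    form <- A ~ .aci_model(ci_pa, Vcmax, J, R_d, gm_val, Km, Gs)
    starts <- lapply(base_starts, function(s) s[c("Vcmax", "J", "R_d")])
    dat <- list(ci_pa = ci_pa, A = A, Km = Km, Gs = Gs, gm_val = gm_val)
  }
  if (!is.null(init)) starts <- list(as.list(init))
  ms <- .multistart_nls(form, dat, starts, lower, upper)
  extra <- list(gm_mode = gm_mode)
  if (!is.null(ms$fit)) {
    cf <- coef(ms$fit)
    gm_used <- if (gm_mode == "fit") cf[["g_m"]]
               else if (gm_mode == "fixed") g_m else Inf
    Ac <- .aci_model(ci_pa, cf[["Vcmax"]], Inf, cf[["R_d"]], gm_used, Km, Gs)
    Aj <- .aci_model(ci_pa, 1e9, cf[["J"]], cf[["R_d"]], gm_used, Km, Gs)
    extra$limitation <- ifelse(Ac <= Aj, "rubisco", "rubp")
    extra$vcmax_identifiable <- any(extra$limitation == "rubisco")
    if (!extra$vcmax_identifiable)
      warning("no point is Rubisco-limited under the fitted model; ",
              "Vcmax is unidentifiable from this curve")
    if (gm_mode == "fixed") extra$g_m <- g_m
  }
  .fit_report(ms$fit, ms$start, "aci", length(A), lower, upper, extra)
}
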