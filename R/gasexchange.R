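# One-point Vc,max estimation from induction gas exchange: invert the
# Rubisco-limited Farquhar-von Caemmerer-Berry (FvCB) carboxylation rate
# point-by-point, with kinetic constants adjusted to leaf temperature and
# gas concentrations expressed as partial pressures.

#' Convert a mole fraction to a partial pressure
#'
#' `p = x * pressure / 1000`: a mole fraction in umol mol-1 at a pressure
#' in kPa yields Pa; a mole fraction in mmol mol-1 yields kPa. Pressure
#' must be applied consistently to every gas quantity in a calculation —
#' it then cancels from the FvCB rate ratio.
#'
#' @param x mole fraction (umol mol-1 or mmol mol-1); vectorized.
#' @param pressure_kpa atmospheric pressure (kPa).
#' @return Partial pressure (Pa per umol mol-1 input, kPa per mmol mol-1).
#' @export
#' @examples
#' to_partial_pressure(400, 100)       # 40 Pa
#' to_partial_pressure(209.5, 101.325) # 21.23 kPa (O2)
to_partial_pressure <- function(x, pressure_kpa) {
  if (any(x < 0) || any(pressure_kpa <= 0))
    stop("mole fractions must be >= 0 and pressure > 0")
  x * pressure_kpa / 1000
}

#' Reference Rubisco kinetic constants for tobacco (25 degrees C)
#'
#' The k25 values and Arrhenius activation energies used by
#' [tobacco_kinetics()]: `K_C` = 40.49 Pa, `K_O` = 27.84 kPa,
#' `Gamma_star` = 4.275 Pa, with activation energies 79.43, 36.38 and
#' 37.83 kJ mol-1 respectively — a standard tobacco parameterization in
#' partial-pressure units. All values are overridable so alternative
#' constant sets can be substituted.
#'
#' @param K_C25 Michaelis constant for CO2 at 25 C (Pa).
#' @param K_O25 Michaelis constant for O2 at 25 C (kPa).
#' @param Gamma_star25 CO2 compensation point without day respiration at
#'   25 C (Pa).
#' @param Ea_K_C,Ea_K_O,Ea_Gamma_star activation energies (J mol-1).
#' @return A named list of constants.
#' @export
tobacco_constants <- function(K_C25 = 40.49, K_O25 = 27.84,
                              Gamma_star25 = 4.275, Ea_K_C = 79430,
                              Ea_K_O = 36380, Ea_Gamma_star = 37830) {
  list(K_C25 = K_C25, K_O25 = K_O25, Gamma_star25 = Gamma_star25,
       Ea_K_C = Ea_K_C, Ea_K_O = Ea_K_O, Ea_Gamma_star = Ea_Gamma_star)
}

#' Temperature-adjusted Rubisco kinetic constants
#'
#' Arrhenius scaling of the tobacco constants to leaf temperature:
#' `k(T) = k25 * exp(Ea * (T - 25) / (298.15 * R * (T + 273.15)))` with
#' `R` = 8.314 J mol-1 K-1.
#'
#' @param T_leaf leaf temperature (degrees C), 0 < T < 50.
#' @param constants a [tobacco_constants()] list.
#' @return List with `K_C` (Pa), `K_O` (kPa), `Gamma_star` (Pa) at
#'   `T_leaf`.
#' @export
#' @examples
#' tobacco_kinetics(25)  # the k25 values themselves
#' tobacco_kinetics(30)
tobacco_kinetics <- function(T_leaf, constants = tobacco_constants()) {
  .check_scalar(T_leaf, "T_leaf", 0, 50, open_lower = TRUE,
                open_upper = TRUE)
  R <- 8.314
  arrh <- function(k25, Ea)
    k25 * exp(Ea * (T_leaf - 25) / (298.15 * R * (T_leaf + 273.15)))
  list(K_C = arrh(constants$K_C25, constants$Ea_K_C),
       K_O = arrh(constants$K_O25, constants$Ea_K_O),
       Gamma_star = arrh(constants$Gamma_star25, constants$Ea_Gamma_star))
}

#' FvCB context for Rubisco-limited calculations
#'
#' The constant inputs needed to invert or forward-run the Rubisco-limited
#' FvCB rate: kinetic constants, oxygen partial pressure, mesophyll
#' conductance and day respiration. `g_m` is held constant during
#' induction; `R_d` and `g_m` typically come from a steady-state A/ci fit
#' ([fit_aci()]) on the same leaf.
#'
#' @param K_C Michaelis constant for CO2 (Pa).
#' @param K_O Michaelis constant for O2 (kPa).
#' @param Gamma_star CO2 compensation point without R_d (Pa).
#' @param g_m mesophyll conductance (umol m-2 s-1 Pa-1).
#' @param R_d day respiration (umol m-2 s-1).
#' @param O oxygen partial pressure (kPa); default the 209.5 mmol mol-1
#'   atmospheric mole fraction at 101.325 kPa.
#' @return A list of class `fvcb_context`.
#' @export
fvcb_context <- function(K_C, K_O, Gamma_star, g_m, R_d,
                         O = to_partial_pressure(209.5, 101.325)) {
  for (nm in c("K_C", "K_O", "Gamma_star", "g_m", "R_d", "O"))
    .check_scalar(get(nm), nm, 0, Inf,
                  open_lower = nm != "R_d")
  structure(list(K_C = K_C, K_O = K_O, Gamma_star = Gamma_star, O = O,
                 g_m = g_m, R_d = R_d), class = "fvcb_context")
}

#' FvCB context at a leaf temperature
#'
#' Convenience wrapper building an [fvcb_context()] with tobacco kinetic
#' constants at `T_leaf` (one constant set per series, evaluated at the
#' mean leaf temperature, is the intended use).
#'
#' @param T_leaf leaf temperature (degrees C).
#' @param g_m mesophyll conductance (umol m-2 s-1 Pa-1).
#' @param R_d day respiration (umol m-2 s-1).
#' @param O_mmol oxygen mole fraction (mmol mol-1); default 209.5.
#' @param pressure_kpa atmospheric pressure (kPa).
#' @param constants a [tobacco_constants()] list.
#' @return An [fvcb_context()].
#' @export
fvcb_context_at <- function(T_leaf, g_m, R_d, O_mmol = 209.5,
                            pressure_kpa = 101.325,
                            constants = tobacco_constants()) {
  kin <- tobacco_kinetics(T_leaf, constants)
  fvcb_context(K_C = kin$K_C, K_O = kin$K_O, Gamma_star = kin$Gamma_star,
               g_m = g_m, R_d = R_d,
               O = to_partial_pressure(O_mmol, pressure_kpa))
}

# effective Michaelis constant K_C * (1 + O/K_O), Pa
.km_eff <- function(ctx) ctx$K_C * (1 + ctx$O / ctx$K_O)

#' Rubisco-limited FvCB assimilation (forward direction)
#'
#' `A = Vcmax * (c_c - Gamma_star) / (c_c + K_C * (1 + O/K_O)) - R_d`.
#' Used to synthesize gas-exchange traces and for round-trip checks of
#' [one_point_vcmax()].
#'
#' @param Vcmax maximum carboxylation rate (umol m-2 s-1); vectorized.
#' @param c_c chloroplastic CO2 partial pressure (Pa), > 0; vectorized.
#' @param ctx an [fvcb_context()].
#' @return Net assimilation (umol m-2 s-1).
#' @export
fvcb_forward <- function(Vcmax, c_c, ctx) {
  stopifnot(inherits(ctx, "fvcb_context"))
  if (any(c_c <= 0)) stop("c_c must be > 0")
  Vcmax * (c_c - ctx$Gamma_star) / (c_c + .km_eff(ctx)) - ctx$R_d
}

#' One-point Vc,max from induction gas-exchange records
#'
#' Inverts the Rubisco-limited FvCB rate per record:
#' `Vcmax = (A + R_d) / ((c_c - Gamma_star) / (c_c + K_C (1 + O/K_O)))`
#' with `c_c = c_i - A / g_m`. Records where `c_c <= Gamma_star` (the
#' inversion is not defined for positive Vc,max) or `A + R_d < 0` are
#' flagged invalid rather than dropped; [vcmax_window()] excludes them
#' downstream.
#'
#' @param records data.frame with columns `A` (umol m-2 s-1) and either
#'   `ci_pa` (Pa) or `ci` (umol mol-1) plus `pressure_kpa` (kPa; default
#'   101.325 applied with a message when absent).
#' @param ctx an [fvcb_context()].
#' @return `records` with added columns `c_c` (Pa), `Vcmax`
#'   (umol m-2 s-1; `NA` when invalid), `valid` (logical) and `reason`.
#' @export
#' @examples
#' ctx <- fvcb_context_at(30, g_m = 2, R_d = 1.5)
#' one_point_vcmax(data.frame(A = 20, ci_pa = 25), ctx)
one_point_vcmax <- function(records, ctx) {
  stopifnot(inherits(ctx, "fvcb_context"))
  .require_columns(records, "A", "`records`")
  if (!"ci_pa" %in% names(records)) {
    .require_columns(records, "ci", "`records`")
    p <- if ("pressure_kpa" %in% names(records)) {
      records$pressure_kpa
    } else {
      message("no `pressure_kpa` column; assuming 101.325 kPa")
      101.325
    }
    records$ci_pa <- to_partial_pressure(records$ci, p)
  }
  c_c <- records$ci_pa - records$A / ctx$g_m
  num <- records$A + ctx$R_d
  valid <- c_c > ctx$Gamma_star & num >= 0
  reason <- rep("", nrow(records))
  reason[c_c <= ctx$Gamma_star] <- "c_c <= Gamma_star"
  reason[num < 0] <- "A + R_d < 0"
  vc <- rep(NA_real_, nrow(records))
  vc[valid] <- num[valid] * (c_c[valid] + .km_eff(ctx)) /
    (c_c[valid] - ctx$Gamma_star)
  records$c_c <- c_c
  records$Vcmax <- vc
  records$valid <- valid
  records$reason <- reason
  records
}

#' Select the Rubisco-limited fitting window
#'
#' Keeps records 1-5 min after the end of shade (boundaries inclusive) —
#' the period after the fast RuBP-regeneration transient when net
#' assimilation is consistently limited by Rubisco activity — excluding
#' records flagged invalid by [one_point_vcmax()] when a context is
#' supplied.
#'
#' @param records gas-exchange data.frame with a `t_s` column (s since end
#'   of shade).
#' @param ctx optional [fvcb_context()]; when given, invalid records are
#'   computed and excluded, and `Vcmax` columns are attached.
#' @param window inclusive window (s); default `c(60, 300)`.
#' @return The subset data.frame; errors if it is empty.
#' @export
vcmax_window <- function(records, ctx = NULL, window = c(60, 300)) {
  .require_columns(records, "t_s", "`records`")
  out <- records[records$t_s >= window[1L] & records$t_s <= window[2L], ,
                 drop = FALSE]
  if (!is.null(ctx)) {
    out <- one_point_vcmax(out, ctx)
    out <- out[out$valid, , drop = FALSE]
  }
  if (nrow(out) == 0L)
    stop(sprintf("no valid records in the %g-%g s window",
                 window[1L], window[2L]))
  out
}
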