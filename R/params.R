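#' Parameters of the piecewise activation-state model
#'
#' Bundle of steady states and time constants for the sun-shade-sun
#' trajectory of Rubisco activation state `S` (percent of sites active):
#' `S` sits at `S_H` in sun, relaxes exponentially towards `S_L` during a
#' shade period of duration `t_L`, then recovers exponentially back to
#' `S_H` after the return to sun.
#'
#' @param S_H steady-state activation state in high light (%), 0-100.
#' @param S_L steady-state activation state in low light (%), `S_L <= S_H`.
#' @param tau_d deactivation time constant (s), e-folding constant of the
#'   decline in shade; 0 means instantaneous.
#' @param tau_a activation time constant (s) of the post-shade recovery.
#' @param t_L shade duration (s), > 0.
#' @return A list of class `piecewise_s_params`.
#' @seealso [s_piecewise()], [fit_piecewise_S()]
#' @export
#' @examples
#' piecewise_s_params(S_H = 80, S_L = 59, tau_d = 108, tau_a = 144)
piecewise_s_params <- function(S_H, S_L, tau_d, tau_a, t_L = 1200) {
  .check_scalar(S_H, "S_H", 0, 100)
  .check_scalar(S_L, "S_L", 0, S_H)
  .check_scalar(tau_d, "tau_d", 0, Inf)
  .check_scalar(tau_a, "tau_a", 0, Inf)
  .check_scalar(t_L, "t_L", 0, Inf, open_lower = TRUE)
  structure(list(S_H = S_H, S_L = S_L, tau_d = tau_d, tau_a = tau_a,
                 t_L = t_L), class = "piecewise_s_params")
}

#' Steady states and time constants for Vc,max regulation
#'
#' High- and low-light steady states of the maximum carboxylation rate and
#' the activation/deactivation time constants connecting them.
#'
#' @param Vcmax_H high-light steady state (umol m-2 s-1).
#' @param Vcmax_L shade steady state (umol m-2 s-1), `0 < Vcmax_L < Vcmax_H`.
#' @param tau_a activation time constant (s) of post-shade recovery.
#' @param tau_d deactivation time constant (s); may be `NA` when it is to
#'   be derived from endpoints via [tau_d_from_endpoints()].
#' @param t_L shade duration (s).
#' @return A list of class `vcmax_kinetics`.
#' @export
#' @examples
#' vcmax_kinetics(Vcmax_H = 239, Vcmax_L = 95, tau_a = 180)
vcmax_kinetics <- function(Vcmax_H, Vcmax_L, tau_a, tau_d = NA_real_,
                           t_L = 1200) {
  .check_scalar(Vcmax_H, "Vcmax_H", 0, Inf, open_lower = TRUE)
  .check_scalar(Vcmax_L, "Vcmax_L", 0, Vcmax_H, open_lower = TRUE,
                open_upper = TRUE)
  .check_scalar(tau_a, "tau_a", 0, Inf)
  if (!is.na(tau_d)) .check_scalar(tau_d, "tau_d", 0, Inf, open_lower = TRUE)
  .check_scalar(t_L, "t_L", 0, Inf, open_lower = TRUE)
  structure(list(Vcmax_H = Vcmax_H, Vcmax_L = Vcmax_L, tau_a = tau_a,
                 tau_d = tau_d, t_L = t_L), class = "vcmax_kinetics")
}

#' Parameters of the non-rectangular hyperbola light response
#'
#' @param phi initial quantum yield (mol CO2 mol-1 photons).
#' @param A_sat asymptotic light-saturated gross rate (umol m-2 s-1).
#' @param theta curvature, 0 < theta <= 1 (1 = Blackman limit).
#' @param R_d day respiration (umol m-2 s-1), >= 0.
#' @return A list of class `light_response_params`.
#' @seealso [nrh_assimilation()], [fit_light_response()]
#' @export
light_response_params <- function(phi, A_sat, theta, R_d) {
  .check_scalar(phi, "phi", 0, Inf, open_lower = TRUE)
  .check_scalar(A_sat, "A_sat", 0, Inf, open_lower = TRUE)
  .check_scalar(theta, "theta", 0, 1, open_lower = TRUE)
  .check_scalar(R_d, "R_d", 0, Inf)
  structure(list(phi = phi, A_sat = A_sat, theta = theta, R_d = R_d),
            class = "light_response_params")
}

#' A (tau_a, tau_d) scenario for diurnal simulation
#'
#' @param tau_a activation time constant (s).
#' @param tau_d deactivation time constant (s).
#' @param label scenario name used in output tables.
#' @return A list of class `tau_scenario`.
#' @export
tau_scenario <- function(tau_a, tau_d, label = sprintf("tau_a=%g,tau_d=%g",
                                                       tau_a, tau_d)) {
  .check_scalar(tau_a, "tau_a", 0, Inf)
  .check_scalar(tau_d, "tau_d", 0, Inf)
  structure(list(tau_a = tau_a, tau_d = tau_d, label = label),
            class = "tau_scenario")
}

#' Published induction and light-response parameters for four Vigna accessions
#'
#' Accession-mean parameters at 30 degrees C for two cowpea breeding lines
#' (IT86D-1010, IT82E-16), the wild relative *Vigna* sp. Savi and
#' *V. adenantha*: steady-state activation states (`S_H`, `S_L`, %),
#' activation-state time constants (`tau_d_S`, `tau_a_S`, s), gas-exchange
#' `Vc,max` steady states (umol m-2 s-1) and time constants (`tau_a_V`, s;
#' `tau_d_V` derivable from the endpoints), and the light-response
#' parameters (`phi`, `A_sat`, `theta`, `R_d`) used in diurnal modelling.
#' `tau_a_S` and `tau_a_V` did not differ among accessions and are shared
#' values.
#'
#' @return A data.frame with one row per accession.
#' @export
#' @examples
#' vp <- vigna_params()
#' tau_d_from_endpoints(vcmax_kinetics(vp$Vcmax_H[1], vp$Vcmax_L[1],
#'                                     tau_a = vp$tau_a_V[1]))
vigna_params <- function() {
  data.frame(
    accession = c("V. adenantha", "V. sp. Savi", "IT82E-16", "IT86D-1010"),
    S_H      = c(80, 65, 71, 80),
    S_L      = c(59, 53, 54, 58),
    tau_d_S  = c(108, 42, 132, 42),
    tau_a_S  = c(144, 144, 144, 144),
    Vcmax_H  = c(239, 239, 239, 239),
    Vcmax_L  = c(95, 96, 124, 113),
    tau_a_V  = c(180, 180, 180, 180),
    phi      = c(0.059, 0.058, 0.063, 0.063),
    A_sat    = c(32, 34, 39, 36),
    theta    = c(0.83, 0.80, 0.78, 0.77),
    R_d      = c(1.52, 1.58, 2.17, 1.85),
    stringsAsFactors = FALSE
  )
}
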