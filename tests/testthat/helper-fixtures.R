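# shared fixtures, all built in code

# accession-mean parameters used across tests (published means)
vp <- vigna_params()

adenantha_s <- function() piecewise_s_params(S_H = 80, S_L = 59,
                                             tau_d = 108, tau_a = 144)

adenantha_v <- function(tau_d = 241) vcmax_kinetics(239, 95, tau_a = 180,
                                                    tau_d = tau_d)

ctx30 <- function(g_m = 2, R_d = 1.52) fvcb_context_at(30, g_m = g_m,
                                                       R_d = R_d)

it86_light <- function() light_response_params(phi = 0.063, A_sat = 36,
                                               theta = 0.77, R_d = 1.85)

# small fluctuating regime for fast diurnal tests (4 h, 60 s steps)
small_regime <- function(seed = 7, event_rate = 12) {
  synth_canopy_light(day_length_s = 14400, peak_ppfd = 1500,
                     event_rate = event_rate, step_s = 60, seed = seed)
}
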