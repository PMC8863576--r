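# Pipeline entry points tying the stages together: read the CSV schemas,
# delegate to the fitting/simulation modules, and serialize results with a
# provenance header (package version, config fingerprint, seed).

.pkg_version <- function() {
  as.character(utils::packageVersion("rubidyn"))
}

.config_hash <- function(config) {
  .fnv1a32(paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), character(1L)),
    sep = "=", collapse = ";"))
}

# CSV with a provenance comment header; read back with comment.char = "#"
.write_output <- function(df, path, config, seed) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# rubidyn %s | config=%s | seed=%s", .pkg_version(),
                     .config_hash(config),
                     if (is.null(seed)) "none" else format(seed)), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_table_arg <- function(x, cols, what) {
  df <- if (is.character(x)) {
    if (!file.exists(x)) stop(sprintf("input file '%s' does not exist", x))
    read.csv(x, comment.char = "#", stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
  .require_columns(df, cols, what)
  df
}

#' Fit activation-state time series and summarize by accession
#'
#' Reads an activation time-series table (columns `individual_id`,
#' `accession`, `t_s`, `phase`, `value`), fits the piecewise model per
#' individual, and aggregates converged fits to accession means with 95%
#' CIs. Individuals whose fits fail are reported with a warning and
#' excluded from aggregation.
#'
#' @param activation path to a CSV or a data.frame in the activation
#'   schema.
#' @param t_L shade duration (s).
#' @param out_dir optional output directory; writes `activation_fits.csv`
#'   and `activation_summary.csv` with provenance headers.
#' @param seed seed recorded in outputs (the fit itself is deterministic).
#' @return List with `fits` (per-individual parameter data.frame),
#'   `summary` (accession aggregate), `failed` (ids).
#' @export
run_fit_activation <- function(activation, t_L = 1200, out_dir = NULL,
                               seed = NULL) {
  df <- .read_table_arg(activation,
                        c("individual_id", "accession", "t_s", "value"),
                        "activation table")
  ids <- unique(df$individual_id)
  fits <- list()
  accs <- character(0)
  rows <- list()
  failed <- character(0)
  for (id in ids) {
    sub <- df[df$individual_id == id, ]
    fit <- tryCatch(fit_piecewise_S(sub, t_L = t_L),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$convergence) {
      failed <- c(failed, id)
      next
    }
    fits[[length(fits) + 1L]] <- fit
    accs <- c(accs, sub$accession[1L])
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = id, accession = sub$accession[1L], t(fit$params),
      sigma = fit$sigma, stringsAsFactors = FALSE)
  }
  if (length(failed))
    warning("non-converged individual(s) excluded: ",
            paste(failed, collapse = ", "))
  if (!length(fits)) stop("no individual fit converged")
  fit_df <- do.call(rbind, rows)
  summary_df <- aggregate_accession(fits, accs)
  config <- list(t_L = t_L, n_individuals = length(ids))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_output(fit_df, file.path(out_dir, "activation_fits.csv"),
                  config, seed)
    .write_output(summary_df, file.path(out_dir, "activation_summary.csv"),
                  config, seed)
  }
  list(fits = fit_df, summary = summary_df, failed = failed)
}

#' Gas-exchange pipeline: one-point Vc,max, tau_a and tau_d per leaf
#'
#' For each individual in a gas-exchange table (columns `individual_id`,
#' `accession`, `t_s`, `A`, `ci`, `Tleaf`, `ppfd`, `pressure_kpa`):
#' build an FvCB context at the series-mean leaf temperature (one constant
#' set per series), estimate `R_d`/`g_m` from that leaf's A/ci curve when
#' one is supplied (otherwise use the provided defaults), invert one-point
#' Vc,max inside the 1-5 min Rubisco-limited window, fit the induction
#' model for `tau_a` and `Vcmax_H`, and derive the endpoint upper bound
#' `tau_d`.
#'
#' @param gasex path/data.frame in the gas-exchange schema.
#' @param aci optional path/data.frame of A/ci curves (columns
#'   `individual_id`, `x`, `A`) matched to leaves by `individual_id`.
#' @param g_m,R_d fallback mesophyll conductance (umol m-2 s-1 Pa-1) and
#'   day respiration (umol m-2 s-1) when no A/ci curve is available.
#' @param t_L shade duration (s).
#' @param out_dir optional output directory (`gasex_fits.csv`).
#' @param seed seed recorded in outputs.
#' @return Data.frame with one row per leaf: `individual_id`, `accession`,
#'   `R_d`, `g_m`, `Vcmax_H`, `Vcmax_L`, `tau_a`, `tau_d_upper`,
#'   `n_window`, `converged`.
#' @export
run_fit_gasex <- function(gasex, aci = NULL, g_m = 2, R_d = 1.5,
                          t_L = 1200, out_dir = NULL, seed = NULL) {
  df <- .read_table_arg(gasex, c("individual_id", "accession", "t_s", "A",
                                 "ci", "Tleaf", "pressure_kpa"),
                        "gas-exchange table")
  aci_df <- if (!is.null(aci))
    .read_table_arg(aci, c("individual_id", "x", "A"), "A/ci table")
  rows <- list()
  for (id in unique(df$individual_id)) {
    sub <- df[df$individual_id == id, ]
    T_mean <- mean(sub$Tleaf)
    p_kpa <- stats::median(sub$pressure_kpa)
    gm_i <- g_m
    rd_i <- R_d
    if (!is.null(aci_df) && id %in% aci_df$individual_id) {
      afit <- fit_aci(aci_df[aci_df$individual_id == id, c("x", "A")],
                      kinetics = tobacco_kinetics(T_mean),
                      pressure_kpa = p_kpa)
      if (afit$convergence) {
        rd_i <- afit$params[["R_d"]]
        gm_i <- afit$params[["g_m"]]
      }
    }
    ctx <- fvcb_context_at(T_mean, g_m = gm_i, R_d = rd_i,
                           pressure_kpa = p_kpa)
    win <- tryCatch(vcmax_window(sub, ctx), error = function(e) NULL)
    fit <- if (!is.null(win) && nrow(win) >= 6L)
      fit_vcmax_induction(data.frame(t_s = win$t_s, value = win$Vcmax))
    else NULL
    ok <- !is.null(fit) && fit$convergence
    H <- if (ok) fit$params[["Vcmax_H"]] else NA_real_
    L <- if (ok) fit$params[["Vcmax_L"]] else NA_real_
    tau_d <- if (ok && H - L > 1)
      as.numeric(tau_d_from_endpoints(vcmax_kinetics(H, L, tau_a = 0,
                                                     t_L = t_L)))
    else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = id, accession = sub$accession[1L], R_d = rd_i,
      g_m = gm_i, Vcmax_H = H, Vcmax_L = L,
      tau_a = if (ok) fit$params[["tau_a"]] else NA_real_,
      tau_d_upper = tau_d, n_window = if (is.null(win)) 0L else nrow(win),
      converged = ok, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    .write_output(out, file.path(out_dir, "gasex_fits.csv"),
                  list(t_L = t_L, g_m = g_m, R_d = R_d), seed)
  }
  out
}

#' Diurnal pipeline: scenario table and cumulative assimilation series
#'
#' Runs the diurnal scenario comparison on a light regime and writes a
#' flat scenario table (`accession,scenario,A_diel_mmol,A_f_mmol,A_f_pct`)
#' plus a per-timestep cumulative-assimilation series for each
#' accession x scenario.
#'
#' @param light path to a light-regime CSV or a [light_regime()].
#' @param params path/data.frame with `accession,phi,A_sat,theta,R_d`.
#' @param scenarios list of [tau_scenario()], or a data.frame with
#'   columns `label`, `tau_a`, `tau_d`.
#' @param out_dir optional output directory (`scenario_table.csv`,
#'   `scenario_means.csv`, `cumulative_assimilation.csv`).
#' @param seed seed recorded in outputs.
#' @return The [scenario_table()] result.
#' @export
run_diurnal <- function(light, params, scenarios, out_dir = NULL,
                        seed = NULL) {
  if (is.character(light)) light <- read_light_regime(light)
  pdf <- .read_table_arg(params,
                         c("accession", "phi", "A_sat", "theta", "R_d"),
                         "light-response parameter table")
  if (is.data.frame(scenarios)) {
    .require_columns(scenarios, c("label", "tau_a", "tau_d"),
                     "scenario table")
    scenarios <- lapply(seq_len(nrow(scenarios)), function(i)
      tau_scenario(scenarios$tau_a[i], scenarios$tau_d[i],
                   scenarios$label[i]))
  }
  tab <- scenario_table(pdf, scenarios, light)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    config <- list(n_scenarios = length(scenarios),
                   n_accessions = nrow(pdf), n_steps = nrow(light))
    .write_output(tab$by_accession,
                  file.path(out_dir, "scenario_table.csv"), config, seed)
    .write_output(tab$means, file.path(out_dir, "scenario_means.csv"),
                  config, seed)
    cum <- do.call(rbind, lapply(seq_len(nrow(pdf)), function(i) {
      p <- light_response_params(pdf$phi[i], pdf$A_sat[i], pdf$theta[i],
                                 pdf$R_d[i])
      do.call(rbind, lapply(scenarios, function(sc) {
        res <- simulate_diurnal(light, p, sc)
        data.frame(accession = pdf$accession[i], scenario = sc$label,
                   time_s = res$steps$time_s,
                   cumulative_mmol = cumsum(res$steps$realized) / 1000,
                   stringsAsFactors = FALSE)
      }))
    }))
    .write_output(cum, file.path(out_dir, "cumulative_assimilation.csv"),
                  config, seed)
  }
  tab
}

#' Generate a full synthetic input bundle
#'
#' Writes every CSV schema the pipeline consumes — activation series,
#' gas-exchange trace, response curves and a diurnal light regime — plus a
#' JSON sidecar of the true generating parameters for recovery scoring.
#'
#' @param out_dir output directory (created if needed).
#' @param seed RNG seed controlling every generator.
#' @param s_params a [piecewise_s_params()] truth.
#' @param v_kinetics a [vcmax_kinetics()] truth with `tau_d` set.
#' @param light_params a [light_response_params()] truth.
#' @param ctx an [fvcb_context()] for the gas-exchange forward model.
#' @param n_individuals individuals per accession in the activation file.
#' @return Invisibly, the named vector of file paths written.
#' @export
run_simulate <- function(out_dir, seed,
                         s_params = piecewise_s_params(80, 59, 108, 144),
                         v_kinetics = vcmax_kinetics(239, 95, tau_a = 180,
                                                     tau_d = 241),
                         light_params = light_response_params(0.063, 36,
                                                              0.77, 1.85),
                         ctx = fvcb_context_at(30, g_m = 2, R_d = 1.85),
                         n_individuals = 4) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(seed = seed, n_individuals = n_individuals)
  act <- gen_activation_series(s_params, n_individuals = n_individuals,
                               seed = seed)
  gx <- gen_gasex_series(v_kinetics, ctx, seed = seed + 1)
  rc <- gen_response_curves(light_params,
                            fvcb_truth = list(Vcmax = 120, J = 220,
                                              R_d = ctx$R_d, g_m = ctx$g_m),
                            seed = seed + 2)
  reg <- synth_canopy_light(seed = seed + 3)
  paths <- c(activation = file.path(out_dir, "activation.csv"),
             gasex = file.path(out_dir, "gasex.csv"),
             curves = file.path(out_dir, "response_curves.csv"),
             light = file.path(out_dir, "light_regime.csv"),
             truth = file.path(out_dir, "truth.json"))
  .write_output(act, paths[["activation"]], config, seed)
  .write_output(gx, paths[["gasex"]], config, seed)
  curves <- rbind(rc$light, rc$co2)
  .write_output(curves, paths[["curves"]], config, seed)
  write_light_regime(reg, paths[["light"]])
  truth <- list(seed = seed, s_params = unclass(s_params),
                v_kinetics = unclass(v_kinetics),
                light_params = unclass(light_params),
                fvcb_context = unclass(ctx))
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
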