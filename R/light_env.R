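#' Construct a chloroplast-level light regime
#'
#' A light regime is a strictly time-ordered series of photosynthetic
#' photon flux density (PPFD) values, the driving input of the diurnal
#' assimilation model. Stored as a data.frame with columns `time_s` and
#' `ppfd` plus a `step_s` attribute (nominal timestep, inferred from the
#' median spacing when not given). Irregular spacing is allowed.
#'
#' @param time_s times since regime start (s), strictly increasing.
#' @param ppfd PPFD at each timestep (umol m-2 s-1), >= 0.
#' @param step_s nominal timestep duration (s); default median spacing.
#' @return A data.frame of class `light_regime`.
#' @export
#' @examples
#' light_regime(c(0, 60, 120), c(0, 100, 200))
light_regime <- function(time_s, ppfd, step_s = NULL) {
  time_s <- as.numeric(time_s)
  ppfd <- as.numeric(ppfd)
  if (length(time_s) != length(ppfd))
    stop("time_s and ppfd must have the same length")
  if (length(time_s) < 2L)
    stop("a light regime needs at least two timesteps")
  if (anyNA(time_s) || anyNA(ppfd))
    stop("light regime contains missing values")
  d <- diff(time_s)
  if (any(d <= 0)) {
    i <- which(d <= 0)[1L]
    stop(sprintf("non-increasing time at row %d: t = %g follows t = %g",
                 i + 1L, time_s[i + 1L], time_s[i]))
  }
  if (any(ppfd < 0))
    stop(sprintf("negative PPFD at row %d", which(ppfd < 0)[1L]))
  step_s <- step_s %||% median(d)
  if (!is.finite(step_s) || step_s <= 0) stop("zero-length timestep")
  out <- data.frame(time_s = time_s, ppfd = ppfd)
  attr(out, "step_s") <- step_s
  class(out) <- c("light_regime", "data.frame")
  out
}

#' Read a light regime from CSV
#'
#' Expects comma-separated values with a header row and columns
#' `time_s,ppfd` ('.' decimal, UTF-8). Lines starting with `#` are
#' ignored, so files written by [write_light_regime()] round-trip.
#'
#' @param path path to a CSV file.
#' @return A [light_regime()].
#' @export
read_light_regime <- function(path) {
  df <- read.csv(path, comment.char = "#")
  .require_columns(df, c("time_s", "ppfd"), sprintf("'%s'", path))
  if (anyNA(df$time_s) || anyNA(df$ppfd))
    stop(sprintf("'%s' contains missing values", path))
  light_regime(df$time_s, df$ppfd)
}

#' Write a light regime to CSV
#'
#' @param x a [light_regime()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_light_regime <- function(x, path) {
  stopifnot(inherits(x, "light_regime"))
  write.csv(data.frame(time_s = x$time_s, ppfd = x$ppfd), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Square-wave sun-shade-sun experimental light protocol
#'
#' The laboratory protocol used for induction assays: steady high light,
#' a single shade period, then a return to high light. Defaults are
#' 40 min at 850, 20 min at 150, 20 min at 850 umol m-2 s-1.
#'
#' @param high_ppfd sun PPFD (umol m-2 s-1).
#' @param low_ppfd shade PPFD (umol m-2 s-1).
#' @param t_pre_s,t_shade_s,t_post_s phase durations (s), all > 0.
#' @param step_s timestep (s); default 10 (gas-exchange logging interval).
#' @return A [light_regime()] covering the three phases.
#' @export
#' @examples
#' prot <- sun_shade_protocol()
#' table(prot$ppfd)
sun_shade_protocol <- function(high_ppfd = 850, low_ppfd = 150,
                               t_pre_s = 2400, t_shade_s = 1200,
                               t_post_s = 1200, step_s = 10) {
  .check_scalar(t_pre_s, "t_pre_s", 0, Inf, open_lower = TRUE)
  .check_scalar(t_shade_s, "t_shade_s", 0, Inf, open_lower = TRUE)
  .check_scalar(t_post_s, "t_post_s", 0, Inf, open_lower = TRUE)
  .check_scalar(step_s, "step_s", 0, Inf, open_lower = TRUE)
  total <- t_pre_s + t_shade_s + t_post_s
  time_s <- seq(0, total - step_s, by = step_s)
  ppfd <- ifelse(time_s < t_pre_s, high_ppfd,
                 ifelse(time_s < t_pre_s + t_shade_s, low_ppfd, high_ppfd))
  light_regime(time_s, ppfd, step_s = step_s)
}

#' Synthesize a fluctuating diurnal canopy light regime
#'
#' Statistical stand-in for the light environment of a chloroplast in the
#' second layer of a legume canopy: a clear-sky half-sine envelope over the
#' photoperiod, punctuated by randomly placed square shade events during
#' which PPFD drops by `shade_fraction` (abrupt ~90% dips by default, the
#' signature of within-canopy shading). It emulates the statistical
#' character of a ray-traced canopy regime, not any particular day.
#'
#' Event placement is deterministic for a fixed `seed`, and at fixed seed a
#' higher `event_rate` produces a superset of the events of a lower rate,
#' so the daily light integral is non-increasing in `event_rate`.
#' Overlapping events do not stack.
#'
#' @param day_length_s photoperiod (s); default 16 h.
#' @param peak_ppfd mid-day clear-sky PPFD (umol m-2 s-1).
#' @param shade_fraction fractional PPFD reduction inside an event,
#'   0 < shade_fraction < 1.
#' @param event_rate mean shade events per hour; 0 gives the pure envelope.
#' @param event_duration_range min/max event duration (s); durations are
#'   drawn log-uniformly between the two, spanning sub- and supra-tau
#'   events.
#' @param step_s timestep (s); default 60.
#' @param seed RNG seed (required unless `events` is supplied).
#' @param events optional data.frame with columns `start`, `duration` (s)
#'   giving explicit events instead of random placement.
#' @return A [light_regime()].
#' @export
#' @examples
#' reg <- synth_canopy_light(seed = 1)
#' max(reg$ppfd)
synth_canopy_light <- function(day_length_s = 57600, peak_ppfd = 1800,
                               shade_fraction = 0.9, event_rate = 10,
                               event_duration_range = c(30, 600),
                               step_s = 60, seed = NULL, events = NULL) {
  .check_scalar(day_length_s, "day_length_s", 0, Inf, open_lower = TRUE)
  .check_scalar(shade_fraction, "shade_fraction", 0, 1,
                open_lower = TRUE, open_upper = TRUE)
  .check_scalar(peak_ppfd, "peak_ppfd", 0, Inf, open_lower = TRUE)
  .check_scalar(event_rate, "event_rate", 0, Inf)
  if (is.null(events)) {
    if (is.null(seed))
      stop("synth_canopy_light() needs a `seed` (or explicit `events`)")
    set.seed(seed)
    n_events <- round(event_rate * day_length_s / 3600)
    starts <- durs <- numeric(n_events)
    # one (start, duration) pair per event, drawn in order: the first k
    # events are identical for any rate that yields >= k events
    for (i in seq_len(n_events)) {
      starts[i] <- runif(1, 0, day_length_s)
      durs[i] <- exp(runif(1, log(event_duration_range[1L]),
                           log(event_duration_range[2L])))
    }
    events <- data.frame(start = starts, duration = durs)
  } else {
    .require_columns(events, c("start", "duration"), "`events`")
  }
  if (nrow(events) > 0L && sum(events$duration) >= day_length_s)
    warning("total shade-event duration covers the entire day; ",
            "regime is still valid but may be fully shaded")
  time_s <- seq(0, day_length_s - step_s, by = step_s)
  envelope <- peak_ppfd * sin(pi * time_s / day_length_s)
  shaded <- rep(FALSE, length(time_s))
  for (j in seq_len(nrow(events))) {
    shaded <- shaded | (time_s >= events$start[j] &
                        time_s < events$start[j] + events$duration[j])
  }
  ppfd <- envelope * ifelse(shaded, 1 - shade_fraction, 1)
  light_regime(time_s, pmax(ppfd, 0), step_s = step_s)
}
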