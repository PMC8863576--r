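# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# exp(-dt/tau) with tau = 0 treated as an instantaneous transition
# (limit tau -> 0+ for dt > 0), never a division error
.decay <- function(dt, tau) {
  if (is.infinite(tau)) return(rep(1, length(dt)))
  if (tau > 0) exp(-dt / tau) else as.numeric(dt <= 0)
}

.check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("`%s` = %g is outside the valid range %s%g, %g%s", name, x,
                 if (open_lower) "(" else "[", lower, upper,
                 if (open_upper) ")" else "]"), call. = FALSE)
  invisible(x)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

# 32-bit FNV-1a over a string, carried in doubles (no integer overflow);
# used to stamp output files with a config fingerprint
.fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(enc2utf8(s))) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- ((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# mean and t-distribution 95% CI half-width across individuals;
# half-width is NA for n = 1 (not estimable), 0 for identical values
.mean_ci95 <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0L) return(c(mean = NA_real_, ci95 = NA_real_, n = 0))
  ci <- if (n >= 2L) qt(0.975, n - 1L) * sd(x) / sqrt(n) else NA_real_
  c(mean = mean(x), ci95 = ci, n = n)
}
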