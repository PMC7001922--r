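# Internal validation and numeric helpers shared across modules.

stop_invalid <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "capno_validation_error")
}

stop_data <- function(msg) {
  abort(msg, class = "capno_data_error")
}

stop_domain <- function(msg) {
  abort(msg, class = "capno_domain_error")
}

check_scalar_number <- function(x, field, min = -Inf, max = Inf,
                                strict_min = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    stop_invalid(field, "must be provided")
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(field, "must be a single finite number")
  }
  if (strict_min && x <= min) {
    stop_invalid(field, sprintf("must be > %g", min))
  }
  if (!strict_min && x < min) {
    stop_invalid(field, sprintf("must be >= %g", min))
  }
  if (x > max) {
    stop_invalid(field, sprintf("must be <= %g", max))
  }
  invisible(x)
}

# Cubic smoothstep on [0, 1]; C1-continuous at both ends, used to render
# expiratory upstrokes and inspiratory downstrokes.
smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

# Linear interpolation of a uniformly sampled trace at arbitrary times.
interp_trace <- function(time_s, value, at) {
  if (any(at < time_s[1L] - 1e-9) || any(at > time_s[length(time_s)] + 1e-9)) {
    stop_data("annotation time falls outside the sampled trace")
  }
  approx(time_s, value, xout = at, rule = 2)$y
}

# Sampling interval of a uniform trace, with a uniformity check.
trace_dt <- function(time_s) {
  if (length(time_s) < 2L) stop_data("trace must contain at least 2 samples")
  dt <- diff(time_s)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop_data("trace is not uniformly sampled")
  }
  stats::median(dt)
}

# Centered moving-average smoother; ends fall back to the raw samples.
smooth_ma <- function(x, k) {
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  if (k <= 1L || k >= length(x)) return(x)
  sm <- stats::filter(x, rep(1 / k, k), sides = 2)
  out <- as.numeric(sm)
  out[is.na(out)] <- x[is.na(out)]
  out
}

# Maximal runs of TRUE in a logical vector -> integer start/end indices.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep])
}
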