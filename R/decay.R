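#' Fit the exponential decay of epCO2 with ventilation index
#'
#' Models the annotated epCO2 values of one segment as a geometric decay
#' `ep_n = a * k^n` (n = 0 ... N-1), where `a` estimates the initial epCO2
#' and `k` is the per-ventilation decay multiplier, and reports the decay
#' factor `D = 100 * (1 - k)` in percent together with the coefficient of
#' determination. Parameters minimize the sum of squared residuals by
#' Levenberg-Marquardt non-linear least squares, initialized from an
#' ordinary least-squares line through `log(ep_n)` vs `n` (closed form and
#' near-optimal under small multiplicative noise).
#'
#' Degenerate inputs have exact answers and bypass the optimizer: with
#' N = 2 the curve interpolates (`a = ep_0`, `k = ep_1/ep_0`, R-squared 1);
#' with all values equal, `a = ep_0`, `k = 1`, `D = 0`, R-squared defined
#' as 1. `k` is unconstrained above 0 during optimization so that mildly
#' rising series fit with `k > 1` (reported with negative `D` rather than
#' silently clipped); `a` must stay positive.
#'
#' @param series An `ep_series` tibble (or any data frame with column
#'   `ep_mmHg`, optionally `n` and `segment_id`), or a bare numeric vector
#'   of epCO2 values ordered by ventilation index.
#' @param max_iter Maximum optimizer iterations.
#' @param tol Relative convergence tolerance on the residual sum of squares.
#' @return An object of class `decay_fit`: a list with `segment_id`, `N`,
#'   `a`, `k`, `D` (percent), `r_squared`, `residuals`, `fitted`,
#'   `converged`, and the input `data`.
#' @examples
#' fit_decay(c(20, 18, 16.2))
#' @export
fit_decay <- function(series, max_iter = 500L, tol = 1e-12) {
  if (is.numeric(series)) {
    series <- tibble(n = seq_along(series) - 1L, ep_mmHg = as.numeric(series))
  }
  if (!is.data.frame(series) || !"ep_mmHg" %in% names(series)) {
    stop_data("`series` must contain an `ep_mmHg` column or be numeric")
  }
  ep <- series$ep_mmHg
  n <- if ("n" %in% names(series)) as.numeric(series$n) else seq_along(ep) - 1
  segment_id <- if ("segment_id" %in% names(series)) {
    as.character(series$segment_id[1L])
  } else "seg"
  N <- length(ep)
  if (N < 2L) stop_data("need at least 2 epCO2 values to fit the decay")
  if (any(!is.finite(ep)) || any(ep <= 0)) {
    stop_data("all epCO2 values must be positive and finite")
  }

  make_fit <- function(a, k, fitted, converged) {
    res <- ep - fitted
    ss_res <- sum(res^2)
    ss_tot <- sum((ep - mean(ep))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    structure(
      list(segment_id = segment_id, N = N, a = a, k = k,
           D = 100 * (1 - k), r_squared = r2,
           residuals = res, fitted = fitted, converged = converged,
           data = tibble(n = n, ep_mmHg = ep)),
      class = "decay_fit"
    )
  }

  if (all(abs(ep - ep[1L]) < 1e-12)) {
    f <- make_fit(ep[1L], 1, rep(ep[1L], N), TRUE)
    f$r_squared <- 1
    return(f)
  }
  if (N == 2L) {
    k <- ep[2L] / ep[1L]
    f <- make_fit(ep[1L], k, ep, TRUE)
    f$r_squared <- 1
    return(f)
  }

  # log-linear initialization: log(ep) = log(a) + n * log(k)
  init <- stats::lm.fit(cbind(1, n), log(ep))$coefficients
  start <- list(a = exp(init[[1L]]), k = exp(init[[2L]]))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      ep ~ a * k^n,
      data = data.frame(ep = ep, n = n),
      start = start,
      lower = c(a = 1e-12, k = 1e-12),
      control = minpack.lm::nls.lm.control(
        maxiter = as.integer(max_iter), ftol = tol, ptol = tol
      )
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warn(sprintf("decay fit did not converge for segment %s", segment_id))
    return(make_fit(start$a, start$k, start$a * start$k^n, FALSE))
  }
  cf <- coef(fit)
  info <- fit$convInfo
  converged <- is.null(info) || isTRUE(info$isConv)
  if (!converged) {
    warn(sprintf("decay fit did not converge for segment %s", segment_id))
  }
  make_fit(cf[["a"]], cf[["k"]], cf[["a"]] * cf[["k"]]^n, converged)
}

#' Fit the decay model to every annotated segment
#'
#' @param annotations Stacked epCO2 annotations from [annotate_segments()]
#'   (grouped by `segment_id`).
#' @param segments Optional segments table from [select_segments()]; when
#'   given, `airway_type` and `n_ventilations` are joined onto the output.
#' @param ... Passed on to [fit_decay()].
#' @return A tibble with one row per segment: `segment_id`, `N`, `a_mmHg`,
#'   `k`, `D_pct`, `r_squared`, `ep0_annotated_mmHg`, `converged`, plus
#'   `airway_type` when available.
#' @export
fit_decay_all <- function(annotations, segments = NULL, ...) {
  if (nrow(annotations) == 0L) {
    return(tibble(segment_id = character(), N = integer(), a_mmHg = numeric(),
                  k = numeric(), D_pct = numeric(), r_squared = numeric(),
                  ep0_annotated_mmHg = numeric(), converged = logical()))
  }
  fits <- annotations |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::group_map(function(df, key) {
      f <- fit_decay(dplyr::mutate(df, segment_id = key$segment_id), ...)
      tibble(
        segment_id = key$segment_id, N = f$N, a_mmHg = f$a, k = f$k,
        D_pct = f$D, r_squared = f$r_squared,
        ep0_annotated_mmHg = df$ep_mmHg[df$n == min(df$n)][1L],
        converged = f$converged
      )
    }) |>
    dplyr::bind_rows()
  if (!is.null(segments)) {
    fits <- dplyr::left_join(
      fits,
      dplyr::select(segments, "segment_id", "episode_id", "airway_type"),
      by = "segment_id"
    )
  }
  fits
}

#' Cumulative decay after a number of ventilations
#'
#' With per-ventilation decay multiplier `k`, the exhaled CO2 level after
#' `n` ventilations (absent any compression contribution) is `k^n` times the
#' initial level; the cumulative percent decrease is `100 * (1 - k^n)`. At
#' the cohort-median `k = 0.9`, ten ventilations remove about 65% of the
#' initial epCO2.
#'
#' @param k Decay multiplier per ventilation, in (0, 1].
#' @param n Number of ventilations (>= 0); vectorized.
#' @return Percent decrease, in `[0, 100)`.
#' @examples
#' decay_after_n(0.9, 10)
#' @export
decay_after_n <- function(k, n) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0) || any(k > 1)) {
    stop_domain("`k` must lie in (0, 1]")
  }
  if (!is.numeric(n) || any(n < 0)) {
    stop_domain("`n` must be >= 0")
  }
  100 * (1 - k^n)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Exponential epCO2 decay fit (segment %s, N = %d)\n", x$segment_id, x$N
  ))
  cat(sprintf("  a = %.2f mmHg, k = %.3f, D = %.1f%%, R^2 = %.3f%s\n",
              x$a, x$k, x$D, x$r_squared,
              if (x$converged) "" else "  [did not converge]"))
  invisible(x)
}

#' Broom-style accessors for decay fits
#'
#' `tidy()` returns the parameter estimates, `glance()` a one-row model
#' summary, `augment()` the data with fitted values and residuals.
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("a", "k"), estimate = c(x$a, x$k))
}

#' @rdname tidy.decay_fit
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(a_mmHg = x$a, k = x$k, D_pct = x$D, r_squared = x$r_squared,
         N = x$N, converged = x$converged)
}

#' @rdname tidy.decay_fit
#' @method augment decay_fit
#' @export
augment.decay_fit <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = x$residuals)
}

#' @describeIn fit_decay Plot the epCO2 series with the fitted decay curve.
#' @param object A `decay_fit`.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  grid <- tibble(
    n = seq(min(object$data$n), max(object$data$n), length.out = 101),
  )
  grid$ep <- object$a * object$k^grid$n
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$n, y = .data$ep_mmHg)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$ep),
                       linetype = "dashed") +
    ggplot2::geom_point(colour = "firebrick", size = 2) +
    ggplot2::labs(
      x = "ventilation index n",
      y = "epCO2 (mmHg)",
      title = sprintf("a = %.1f mmHg, D = %.1f%%, R² = %.2f",
                      object$a, object$D, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
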