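#' Cohort summary of decay fits, stratified by segment length
#'
#' Summarizes per-segment decay fits the way the study cohort is tabulated:
#' median and interquartile range of the decay factor `D` (%), the
#' coefficient of determination, and the initial epCO2, within strata of the
#' number of ventilations per segment (N = 2, 3, 4, 5, >= 6 pooled, and
#' total). Quantiles use linear interpolation between order statistics
#' (R's default type 7), so reported IQRs are reproducible.
#'
#' @param fits A fits tibble from [fit_decay_all()] (columns `N`, `D_pct`,
#'   `r_squared`, `ep0_annotated_mmHg`; optionally `vr_vpm`).
#' @param strata Integer cutoffs for the exact-N strata; larger N pool into
#'   one open-ended stratum.
#' @return A tibble of class `cohort_summary` with one row per stratum:
#'   `stratum`, `n_segments`, then `{median,q1,q3}` for `D_pct`,
#'   `r_squared`, and `ep0_mmHg` (plus `vr_vpm` when supplied).
#' @export
summarize_fits <- function(fits, strata = 2:5) {
  if (!is.data.frame(fits) || nrow(fits) == 0L) {
    stop_invalid("fits", "must contain at least one fit")
  }
  need <- c("N", "D_pct", "r_squared", "ep0_annotated_mmHg")
  missing_cols <- setdiff(need, names(fits))
  if (length(missing_cols)) {
    stop_invalid("fits", paste("missing columns:",
                               paste(missing_cols, collapse = ", ")))
  }
  top <- max(strata) + 1L
  lab <- function(N) ifelse(N >= top, sprintf(">=%d", top), as.character(N))
  levels <- c(as.character(strata), sprintf(">=%d", top), "total")

  one <- function(df, stratum) {
    q <- function(x, p) as.numeric(quantile(x, p, type = 7, names = FALSE))
    out <- tibble(
      stratum = stratum,
      n_segments = nrow(df),
      D_median = q(df$D_pct, 0.5), D_q1 = q(df$D_pct, 0.25),
      D_q3 = q(df$D_pct, 0.75),
      r2_median = q(df$r_squared, 0.5), r2_q1 = q(df$r_squared, 0.25),
      r2_q3 = q(df$r_squared, 0.75),
      ep0_median = q(df$ep0_annotated_mmHg, 0.5),
      ep0_q1 = q(df$ep0_annotated_mmHg, 0.25),
      ep0_q3 = q(df$ep0_annotated_mmHg, 0.75)
    )
    if ("vr_vpm" %in% names(df)) {
      out$vr_median <- q(df$vr_vpm, 0.5)
      out$vr_q1 <- q(df$vr_vpm, 0.25)
      out$vr_q3 <- q(df$vr_vpm, 0.75)
    }
    out
  }

  by_stratum <- fits |>
    dplyr::mutate(stratum = lab(.data$N)) |>
    dplyr::group_by(.data$stratum) |>
    dplyr::group_map(~ one(.x, .y$stratum)) |>
    dplyr::bind_rows()
  out <- dplyr::bind_rows(by_stratum, one(fits, "total"))
  out <- out[order(match(out$stratum, levels)), , drop = FALSE]
  stopifnot(sum(out$n_segments[out$stratum != "total"]) ==
              out$n_segments[out$stratum == "total"])
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Regress the decay factor on the initial epCO2
#'
#' Ordinary least squares of the per-segment decay factor `D` on the
#' annotated initial epCO2. A near-zero coefficient of determination means
#' the decay factor carries information independent of the segment's
#' starting CO2 level.
#'
#' @param fits A fits tibble with columns `D_pct` and `ep0_annotated_mmHg`.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
regress_decay_on_ep0 <- function(fits) {
  if (nrow(fits) < 3L) stop_invalid("fits", "need at least 3 fits")
  x <- fits$ep0_annotated_mmHg
  y <- fits$D_pct
  if (max(x) - min(x) < 1e-12) {
    stop_data("all initial epCO2 values identical: regression design degenerate")
  }
  m <- lm(y ~ x)
  tibble(
    slope = unname(coef(m)[2L]),
    intercept = unname(coef(m)[1L]),
    r_squared = summary(m)$r.squared,
    n = length(y)
  )
}

#' Compare decay factors between airway-management groups
#'
#' One-way fixed-effects analysis of variance of the decay factor `D`
#' across airway types (equal-variance F test), with group sizes and means
#' reported alongside the test.
#'
#' @param fits A fits tibble with columns `D_pct` and `airway_type`.
#' @param groups Optional subset of airway labels to compare; default all
#'   labels present.
#' @return A list of class `airway_anova`: `f_statistic`, `p_value`,
#'   `df_between`, `df_within`, and a `groups` tibble (label, n, mean D).
#' @export
compare_airway_groups <- function(fits, groups = NULL) {
  if (!all(c("D_pct", "airway_type") %in% names(fits))) {
    stop_invalid("fits", "must contain D_pct and airway_type columns")
  }
  if (!is.null(groups)) {
    fits <- dplyr::filter(fits, .data$airway_type %in% groups)
  }
  tab <- fits |>
    dplyr::group_by(.data$airway_type) |>
    dplyr::summarise(n = dplyr::n(), mean_D = mean(.data$D_pct),
                     .groups = "drop")
  tab_ok <- tab[tab$n >= 2L, , drop = FALSE]
  if (nrow(tab_ok) < 2L) {
    stop_invalid("fits", "need >= 2 airway groups with >= 2 segments each")
  }
  fits <- dplyr::filter(fits, .data$airway_type %in% tab_ok$airway_type)
  g <- factor(fits$airway_type)
  y <- fits$D_pct

  df_b <- nlevels(g) - 1L
  df_w <- length(y) - nlevels(g)
  within_var <- sum(tapply(y, g, function(v) sum((v - mean(v))^2))) / df_w
  between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - mean(y))^2))
  if (within_var < 1e-24) {
    # zero within-group variance: perfect separation (F infinite) unless the
    # group means also coincide (no effect at all)
    if (between < 1e-24) {
      f_stat <- 0
      p <- 1
    } else {
      f_stat <- Inf
      p <- 0
    }
  } else {
    ow <- oneway.test(y ~ g, var.equal = TRUE)
    f_stat <- unname(ow$statistic)
    p <- unname(ow$p.value)
  }
  structure(
    list(f_statistic = f_stat, p_value = p, df_between = df_b,
         df_within = df_w, groups = tab_ok),
    class = "airway_anova"
  )
}

#' @export
print.airway_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA of decay factor D by airway type\n"))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$f_statistic, x$p_value))
  print(x$groups)
  invisible(x)
}

#' @describeIn summarize_fits Boxplots of D, R-squared and initial epCO2
#'   across all fitted segments.
#' @param object A fits tibble from [fit_decay_all()].
#' @param ... Unused.
#' @export
plot_fit_distributions <- function(object, ...) {
  long <- object |>
    dplyr::select("segment_id", "D_pct", "r_squared",
                  "ep0_annotated_mmHg") |>
    tidyr::pivot_longer(-"segment_id", names_to = "measure") |>
    dplyr::mutate(measure = factor(
      .data$measure,
      levels = c("D_pct", "r_squared", "ep0_annotated_mmHg"),
      labels = c("decay factor D (%)", "R²", "initial epCO2 (mmHg)")
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = "", y = .data$value)) +
    ggplot2::geom_boxplot(width = 0.4, fill = "grey85") +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
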