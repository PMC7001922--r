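#' Chest-compression contribution to ETCO2 between consecutive ventilations
#'
#' With ongoing compressions, let `et1` be the end-tidal CO2 after one
#' ventilation and `et2` after the next. Absent compressions the decay model
#' predicts the second level would be `k * et1`; the surplus `et2 - k * et1`
#' is attributed to CO2 delivered to the lungs by compressions, and dividing
#' by the ventilation duration `t2 - t1` gives the contribution per unit
#' time. A negative value means net CO2 washout exceeded delivery.
#'
#' @param et1,et2 End-tidal CO2 levels of consecutive ventilations, mmHg.
#' @param k Decay multiplier per ventilation, in (0, 1).
#' @param t1,t2 Times (seconds) of the two ventilations; `t2 - t1` is the
#'   ventilation duration.
#' @return Contribution rate in mmHg/s (vectorized).
#' @examples
#' cc_contribution_rate(20, 20, k = 0.9, t1 = 0, t2 = 5)
#' @export
cc_contribution_rate <- function(et1, et2, k, t1, t2) {
  if (any(!is.finite(k)) || any(k <= 0) || any(k >= 1)) {
    stop_domain("`k` must lie in (0, 1)")
  }
  if (any(et1 <= 0) || any(et2 <= 0)) {
    stop_domain("ETCO2 levels must be positive")
  }
  if (any(t2 <= t1)) stop_domain("`t2` must exceed `t1`")
  (et2 - k * et1) / (t2 - t1)
}

#' Predicted ETCO2 ratio between two ventilation rates
#'
#' Under stable conditions, the per-minute compression contribution at
#' ventilation rate `vr` is proportional to `ET * (1 - k^vr)`. Equating the
#' compression contribution at two rates gives the model's predicted ratio
#' of steady ETCO2 levels:
#'
#'   ET2 / ET1 = (1 - k^vr1) / (1 - k^vr2)
#'
#' At `k = 0.9` and a 10 vpm reference, the predicted level at 5 vpm is 1.59
#' times the reference and the level at 15 vpm is 0.82 times it. Non-integer
#' rates are accepted (`k^vr` by real exponentiation).
#'
#' @param vr1,vr2 Ventilation rates in ventilations per minute (> 0);
#'   vectorized.
#' @param k Decay multiplier per ventilation, strictly inside (0, 1).
#' @return Dimensionless ratio ET2/ET1 (the level at `vr2` relative to the
#'   level at `vr1`).
#' @examples
#' etco2_ratio(10, 5, k = 0.9)
#' etco2_ratio(10, 15, k = 0.9)
#' @export
etco2_ratio <- function(vr1, vr2, k = 0.9) {
  if (any(!is.finite(k)) || any(k <= 0) || any(k >= 1)) {
    stop_domain("`k` must lie strictly inside (0, 1)")
  }
  if (any(vr1 <= 0) || any(vr2 <= 0)) {
    stop_domain("ventilation rates must be > 0")
  }
  (1 - k^vr1) / (1 - k^vr2)
}

#' Normalize a measured ETCO2 to a reference ventilation rate
#'
#' Converts an ETCO2 level measured while ventilating at `vr` into the level
#' the model predicts would have been observed at the reference rate
#' (default: the recommended 10 vpm), assuming equal chest-compression
#' performance. This removes ventilation rate as a confounder when comparing
#' ETCO2 across CPR intervals: the correction factor is the inverse of the
#' rate-ratio curve evaluated at `vr`.
#'
#' @param et Measured ETCO2, mmHg (vectorized).
#' @param vr Ventilation rate at which `et` was measured, vpm.
#' @param k Decay multiplier per ventilation, in (0, 1). The default 0.9 is
#'   the cohort-median value; per-patient values from [fit_decay()] can be
#'   substituted.
#' @param vr_ref Reference ventilation rate, vpm.
#' @return Normalized ETCO2 in mmHg.
#' @examples
#' normalize_etco2(31.8, vr = 5)   # ~20 mmHg at the 10 vpm reference
#' @export
normalize_etco2 <- function(et, vr, k = 0.9, vr_ref = 10) {
  if (any(et <= 0)) stop_domain("`et` must be positive")
  et / etco2_ratio(vr_ref, vr, k)
}

#' Tabulate the ETCO2 rate-ratio curve
#'
#' Evaluates [etco2_ratio()] over a grid of ventilation rates against the
#' reference rate, producing the curve relating relative ETCO2 level to
#' ventilation rate.
#'
#' @param vr Grid of ventilation rates, vpm (> 0).
#' @param k Decay multiplier per ventilation.
#' @param vr_ref Reference ventilation rate, vpm.
#' @return A tibble of class `ratio_curve` with columns `vr_vpm`, `ratio`.
#' @examples
#' ratio_curve(c(5, 10, 15))
#' @export
ratio_curve <- function(vr = seq(2, 30, by = 0.5), k = 0.9, vr_ref = 10) {
  if (any(vr <= 0)) stop_domain("grid ventilation rates must be > 0")
  out <- tibble(vr_vpm = as.numeric(vr),
                ratio = etco2_ratio(vr_ref, vr, k))
  attr(out, "k") <- k
  attr(out, "vr_ref") <- vr_ref
  class(out) <- c("ratio_curve", class(out))
  out
}

#' @describeIn ratio_curve Plot the ratio curve.
#' @param object A `ratio_curve`.
#' @param ... Unused.
#' @method autoplot ratio_curve
#' @export
autoplot.ratio_curve <- function(object, ...) {
  vr_ref <- attr(object, "vr_ref") %||% 10
  ggplot2::ggplot(object, ggplot2::aes(x = .data$vr_vpm, y = .data$ratio)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = vr_ref, linetype = "dotted") +
    ggplot2::labs(
      x = "ventilation rate (vpm)",
      y = sprintf("ETCO2 relative to level at %g vpm", vr_ref),
      title = sprintf("Predicted ETCO2 vs ventilation rate (k = %.2f)",
                      attr(object, "k") %||% 0.9)
    ) +
    ggplot2::theme_minimal()
}
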