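#' Reference delay for the epCO2 annotation
#'
#' The end-tidal value of a breath depends on how long its alveolar plateau
#' lasts, so breaths with unequal exhalation times are not directly
#' comparable. The epCO2 metric therefore samples every breath at the same
#' fixed delay from its expiratory upstroke onset; the delay is set by the
#' shortest plateau in the segment, so the annotation lands on or before
#' every breath's plateau end. Concretely the reference delay is
#' `min over breaths of (plateau_end_s - upstroke_onset_s)`.
#'
#' @param ventilations A tibble of breath landmarks with columns
#'   `upstroke_onset_s`, `plateau_start_s`, `plateau_end_s` (as produced by
#'   [detect_ventilations()]), or a one-row segment tibble from
#'   [select_segments()].
#' @return The reference delay in seconds (scalar, > 0).
#' @export
compute_reference_delay <- function(ventilations) {
  marks <- as_marks(ventilations)
  if (nrow(marks) < 2L) {
    stop_data("need at least 2 ventilations to define a reference delay")
  }
  durations <- marks$plateau_end_s - marks$plateau_start_s
  if (any(durations <= 0)) {
    stop_data("non-positive plateau duration in segment")
  }
  min(marks$plateau_end_s - marks$upstroke_onset_s)
}

as_marks <- function(x) {
  if (is.data.frame(x) && "ventilations" %in% names(x)) {
    if (nrow(x) != 1L) stop_data("pass one segment at a time")
    x <- x$ventilations[[1L]]
  }
  need <- c("upstroke_onset_s", "plateau_start_s", "plateau_end_s")
  if (!is.data.frame(x) || !all(need %in% names(x))) {
    stop_data("ventilation landmarks must contain upstroke/plateau columns")
  }
  bad <- !(x$upstroke_onset_s < x$plateau_start_s &
             x$plateau_start_s < x$plateau_end_s)
  if (any(bad)) stop_data("inconsistent breath landmarks (ordering violated)")
  x
}

#' Annotate the epCO2 series of a segment
#'
#' Samples the capnogram at `upstroke_onset + reference_delay` for every
#' ventilation in the segment, by linear interpolation between adjacent
#' samples. The resulting ordered values `ep_0 ... ep_{N-1}` are the input
#' to the exponential-decay fit.
#'
#' @param segment A one-row tibble from [select_segments()], or a tibble of
#'   breath landmarks.
#' @param co2 Capnogram trace (`time_s`, `co2_mmHg`) covering every
#'   annotation time.
#' @param segment_id Identifier recorded in the output (taken from `segment`
#'   when present).
#' @param reference_delay_s Optional override; computed from the segment's
#'   plateaus by default.
#' @return A tibble of class `ep_series`: `segment_id`, `n` (0-based breath
#'   index), `annotation_time_s`, `ep_mmHg`, `reference_delay_s`.
#' @export
annotate_epco2 <- function(segment, co2, segment_id = NULL,
                           reference_delay_s = NULL) {
  if (is.data.frame(segment) && "segment_id" %in% names(segment) &&
      is.null(segment_id)) {
    segment_id <- segment$segment_id[1L]
  }
  segment_id <- segment_id %||% "seg"
  marks <- as_marks(segment)
  if (nrow(marks) < 2L) stop_data("segment must contain >= 2 ventilations")
  delay <- reference_delay_s %||% compute_reference_delay(marks)
  check_scalar_number(delay, "reference_delay_s", min = 0, strict_min = TRUE)

  at <- marks$upstroke_onset_s + delay
  if (any(at > max(co2$time_s) + 1e-9)) {
    stop_data("annotation time beyond end of capnogram trace")
  }
  ep <- interp_trace(co2$time_s, co2$co2_mmHg, at)
  out <- tibble(
    segment_id = segment_id,
    n = seq_len(nrow(marks)) - 1L,
    annotation_time_s = at,
    ep_mmHg = ep,
    reference_delay_s = delay
  )
  class(out) <- c("ep_series", class(out))
  out
}

#' Annotate epCO2 for every selected segment
#'
#' Convenience wrapper applying [annotate_epco2()] across the segments table
#' of an episode. Segments where any annotated value is non-positive are
#' dropped (the log-linear initialization of the decay fit requires positive
#' values); the `skipped` attribute records their ids.
#'
#' @param segments Output of [select_segments()].
#' @param co2 The episode capnogram (`time_s`, `co2_mmHg`).
#' @return A tibble of stacked epCO2 annotations (class `ep_series`).
#' @export
annotate_segments <- function(segments, co2) {
  skipped <- character()
  rows <- vector("list", nrow(segments))
  for (i in seq_len(nrow(segments))) {
    ann <- annotate_epco2(segments[i, ], co2)
    if (any(ann$ep_mmHg <= 0)) {
      skipped <- c(skipped, segments$segment_id[i])
      next
    }
    rows[[i]] <- ann
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(segment_id = character(), n = integer(),
                  annotation_time_s = numeric(), ep_mmHg = numeric(),
                  reference_delay_s = numeric())
  }
  class(out) <- c("ep_series", class(out))
  attr(out, "skipped") <- skipped
  out
}
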