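#' Detection configuration
#'
#' Tuning knobs for ventilation and compression-pause detection. Breath
#' landmarks use thresholds expressed as fractions of each cycle's amplitude
#' (local maximum minus local baseline), which makes detection scale-free
#' across patients; absolute floors reject noise blips.
#'
#' @param min_amplitude_mmHg Minimum cycle amplitude for a candidate breath,
#'   mmHg.
#' @param min_plateau_s Minimum plateau duration, seconds.
#' @param onset_frac Fractional amplitude defining the upstroke onset
#'   crossing (last crossing before the rise).
#' @param plateau_frac Fractional amplitude defining the plateau bounds.
#' @param mid_frac Fractional amplitude marking the main rise/fall.
#' @param smooth_s Moving-average smoothing window applied before landmark
#'   search, seconds.
#' @param baseline_quantile Quantile of the smoothed trace taken as the local
#'   baseline (the capnogram rests at baseline between breaths).
#' @param activity_window_s Sliding window for the compression-activity
#'   criterion, seconds.
#' @param activity_p2p_mm Peak-to-peak depth above which a window counts as
#'   containing compressions, mm.
#' @param ti_crosscheck Require each CO2-detected breath to coincide (within
#'   `ti_tolerance_s`) with a slow fluctuation of the transthoracic impedance
#'   channel. Off by default.
#' @param ti_tolerance_s Coincidence tolerance for the impedance cross-check,
#'   seconds.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(min_amplitude_mmHg = 4,
                             min_plateau_s = 0.3,
                             onset_frac = 0.1,
                             plateau_frac = 0.9,
                             mid_frac = 0.5,
                             smooth_s = 0.15,
                             baseline_quantile = 0.05,
                             activity_window_s = 2,
                             activity_p2p_mm = 3,
                             ti_crosscheck = FALSE,
                             ti_tolerance_s = 1) {
  check_scalar_number(min_amplitude_mmHg, "min_amplitude_mmHg", min = 0,
                      strict_min = TRUE)
  check_scalar_number(min_plateau_s, "min_plateau_s", min = 0)
  check_scalar_number(activity_window_s, "activity_window_s", min = 0,
                      strict_min = TRUE)
  check_scalar_number(activity_p2p_mm, "activity_p2p_mm", min = 0,
                      strict_min = TRUE)
  stopifnot(onset_frac < mid_frac, mid_frac < plateau_frac, plateau_frac < 1)
  structure(
    list(min_amplitude_mmHg = min_amplitude_mmHg,
         min_plateau_s = min_plateau_s, onset_frac = onset_frac,
         plateau_frac = plateau_frac, mid_frac = mid_frac,
         smooth_s = smooth_s, baseline_quantile = baseline_quantile,
         activity_window_s = activity_window_s,
         activity_p2p_mm = activity_p2p_mm,
         ti_crosscheck = ti_crosscheck, ti_tolerance_s = ti_tolerance_s),
    class = "detection_config"
  )
}

# Interpolated time where the trace crosses `level` between samples i and
# i+1 (rising) or i-1 and i (falling handled by caller ordering).
cross_time <- function(time_s, x, i1, i2, level) {
  if (x[i2] == x[i1]) return(time_s[i1])
  time_s[i1] + (level - x[i1]) / (x[i2] - x[i1]) * (time_s[i2] - time_s[i1])
}

#' Detect ventilations in a capnogram
#'
#' Finds complete breath cycles (upstroke, plateau, downstroke) and returns
#' their timing landmarks. Per candidate cycle the amplitude `A` is the local
#' maximum minus the local baseline; the upstroke onset is the last crossing
#' of baseline + `onset_frac * A` before the rise, the plateau bounds are the
#' crossings of baseline + `plateau_frac * A`. Cycles smaller than
#' `min_amplitude_mmHg`, with plateaus shorter than `min_plateau_s`, or cut
#' off by the end of the trace (no completed downstroke) are dropped, so only
#' complete ventilations are reported.
#'
#' @param co2 A data frame with columns `time_s` and `co2_mmHg` (a segment or
#'   episode capnogram), uniformly sampled.
#' @param config A [detection_config()].
#' @param ti Optional impedance channel (`time_s`, `ti_ohm`) for the slow
#'   fluctuation cross-check; used only when `config$ti_crosscheck` is TRUE.
#' @return A tibble with one row per detected breath: `breath`,
#'   `upstroke_onset_s`, `plateau_start_s`, `plateau_end_s`.
#' @export
detect_ventilations <- function(co2, config = detection_config(), ti = NULL) {
  if (!is.data.frame(co2) || !all(c("time_s", "co2_mmHg") %in% names(co2))) {
    stop_data("`co2` must be a data frame with columns time_s and co2_mmHg")
  }
  if (nrow(co2) < 2L) stop_data("capnogram trace is degenerate (< 2 samples)")
  dt <- trace_dt(co2$time_s)
  fs <- 1 / dt
  time_s <- co2$time_s
  x <- smooth_ma(co2$co2_mmHg, round(config$smooth_s * fs))

  base <- as.numeric(quantile(x, config$baseline_quantile))
  cand_th <- base + config$mid_frac * config$min_amplitude_mmHg
  runs <- true_runs(x >= cand_th)
  if (nrow(runs) == 0L) {
    return(tibble(breath = integer(), upstroke_onset_s = numeric(),
                  plateau_start_s = numeric(), plateau_end_s = numeric()))
  }

  out <- vector("list", nrow(runs))
  prev_end <- 1L
  for (r in seq_len(nrow(runs))) {
    i1 <- runs$start[r]
    i2 <- runs$end[r]
    A <- max(x[i1:i2]) - base
    if (A < config$min_amplitude_mmHg) {
      prev_end <- i2
      next
    }
    th_on <- base + config$onset_frac * A
    th_hi <- base + config$plateau_frac * A

    # upstroke onset: last sample at/below th_on before the rise
    pre <- which(x[prev_end:i1] <= th_on)
    if (length(pre) == 0L) {
      prev_end <- i2
      next  # trace starts mid-breath: incomplete
    }
    oi <- prev_end + max(pre) - 1L
    onset <- cross_time(time_s, x, oi, oi + 1L, th_on)

    # plateau bounds: first/last crossing of th_hi within the run
    hi <- which(x[i1:i2] >= th_hi)
    if (length(hi) == 0L) {
      prev_end <- i2
      next
    }
    ps_i <- i1 + min(hi) - 1L
    pe_i <- i1 + max(hi) - 1L
    p_start <- if (ps_i > 1L) cross_time(time_s, x, ps_i - 1L, ps_i, th_hi) else time_s[ps_i]
    p_end <- if (pe_i < length(x)) cross_time(time_s, x, pe_i, pe_i + 1L, th_hi) else time_s[pe_i]

    # completeness: the downstroke must return to th_on before trace end
    post_lim <- if (r < nrow(runs)) runs$start[r + 1L] else length(x)
    post <- which(x[i2:post_lim] <= th_on)
    if (length(post) == 0L) {
      prev_end <- i2
      next  # truncated mid-plateau or mid-downstroke
    }
    if (p_end - p_start < config$min_plateau_s) {
      prev_end <- i2
      next
    }
    out[[r]] <- tibble(upstroke_onset_s = onset, plateau_start_s = p_start,
                       plateau_end_s = p_end)
    prev_end <- i2
  }
  marks <- dplyr::bind_rows(out)
  if (nrow(marks) == 0L) {
    return(tibble(breath = integer(), upstroke_onset_s = numeric(),
                  plateau_start_s = numeric(), plateau_end_s = numeric()))
  }
  marks <- dplyr::arrange(marks, .data$upstroke_onset_s)

  if (isTRUE(config$ti_crosscheck) && !is.null(ti)) {
    peaks <- ti_slow_peaks(ti)
    # the slow impedance bump peaks near mid-breath, so compare against the
    # plateau midpoint rather than the upstroke onset
    mid <- (marks$plateau_start_s + marks$plateau_end_s) / 2
    keep <- vapply(mid, function(t0) {
      length(peaks) > 0L && min(abs(peaks - t0)) <= config$ti_tolerance_s
    }, logical(1))
    marks <- marks[keep, , drop = FALSE]
  }

  dplyr::mutate(marks, breath = dplyr::row_number(), .before = 1L)
}

# Times of slow ventilation-synchronous impedance fluctuations: local maxima
# of the heavily smoothed, detrended TI channel.
ti_slow_peaks <- function(ti) {
  dt <- trace_dt(ti$time_s)
  fs <- 1 / dt
  x <- smooth_ma(ti$ti_ohm, round(1.0 * fs))
  x <- x - stats::median(x)
  up <- x > 0.2 * max(abs(x))
  runs <- true_runs(up)
  vapply(seq_len(nrow(runs)), function(r) {
    i <- runs$start[r]:runs$end[r]
    ti$time_s[i[which.max(x[i])]]
  }, numeric(1))
}

#' Detect pauses in chest compressions
#'
#' A sliding window of `activity_window_s` seconds counts as containing
#' compressions when its peak-to-peak depth exceeds `activity_p2p_mm`
#' millimetres; pauses are the maximal intervals free of any such window,
#' returned half-open `[start_s, end_s)`.
#'
#' @param depth A data frame with columns `time_s` and `depth_mm`.
#' @param config A [detection_config()].
#' @return A tibble with columns `pause_start_s`, `pause_end_s`.
#' @export
detect_compression_pauses <- function(depth, config = detection_config()) {
  if (!is.data.frame(depth) || !all(c("time_s", "depth_mm") %in% names(depth))) {
    stop_data("`depth` must be a data frame with columns time_s and depth_mm")
  }
  if (nrow(depth) < 2L) stop_data("depth trace is degenerate (< 2 samples)")
  dt <- trace_dt(depth$time_s)
  w <- max(2L, round(config$activity_window_s / dt))
  x <- depth$depth_mm
  n <- length(x)
  if (n <= w) {
    p2p <- max(x) - min(x)
    quiet_cov <- rep(p2p <= config$activity_p2p_mm, n)
  } else {
    hi <- zoo::rollmax(x, w, align = "left")
    lo <- -zoo::rollmax(-x, w, align = "left")
    # p2p[i] is the excursion of window [i, i + w - 1]; a pause is the union
    # of quiet windows, so its bounds sit at the true compression edges
    quiet <- (hi - lo) <= config$activity_p2p_mm
    cs <- cumsum(c(quiet, rep(0, w - 1L)))
    lag <- c(rep(0, w), head(cs, n - w))
    quiet_cov <- (cs - lag) > 0
  }
  runs <- true_runs(quiet_cov)
  if (nrow(runs) == 0L) {
    return(tibble(pause_start_s = numeric(), pause_end_s = numeric()))
  }
  tibble(
    pause_start_s = depth$time_s[runs$start],
    pause_end_s = depth$time_s[runs$end] + dt
  )
}

#' Select analysis segments from an episode
#'
#' Applies the inclusion criteria: a compression pause, at least
#' `min_ventilations` complete ventilations entirely after the post-pause
#' guard, and a non-perfusing rhythm (supplied as metadata). Each segment
#' starts exactly `guard_s` seconds after the interruption of chest
#' compressions, rejecting the interval where blood pressure is still
#' settling; ventilations whose upstroke begins before the guarded start are
#' excluded.
#'
#' @param episode A `capno_episode`, or a multichannel trace tibble (must
#'   contain at least `time_s`, `co2_mmHg` and `depth_mm`).
#' @param guard_s Guard after compression interruption, seconds.
#' @param min_ventilations Minimum complete ventilations per segment.
#' @param config A [detection_config()].
#' @param airway_type,rhythm_status,episode_id Metadata used when `episode`
#'   is a bare trace tibble; ignored for `capno_episode` input.
#' @return A tibble with one row per selected segment: `episode_id`,
#'   `segment_id`, `pause_start_s`, `start_s`, `end_s`, `n_ventilations`,
#'   `airway_type`, and a `ventilations` list-column of landmark tibbles.
#' @export
select_segments <- function(episode,
                            guard_s = 3.0,
                            min_ventilations = 2L,
                            config = detection_config(),
                            airway_type = "unknown",
                            rhythm_status = "non_perfusing",
                            episode_id = "ep001") {
  if (inherits(episode, "capno_episode")) {
    trace <- episode$trace
    airway_type <- episode$airway_type
    rhythm_status <- episode$rhythm_status
    episode_id <- episode$episode_id
  } else {
    trace <- episode
  }
  for (ch in c("time_s", "co2_mmHg", "depth_mm")) {
    if (!ch %in% names(trace)) {
      stop_data(sprintf("missing required channel `%s`", ch))
    }
  }
  check_scalar_number(guard_s, "guard_s", min = 0)

  if (identical(rhythm_status, "perfusing")) {
    return(empty_segments())
  }

  pauses <- detect_compression_pauses(
    dplyr::select(trace, "time_s", "depth_mm"), config
  )
  if (nrow(pauses) == 0L) return(empty_segments())

  ti <- if ("ti_ohm" %in% names(trace)) {
    dplyr::select(trace, "time_s", "ti_ohm")
  } else NULL

  segs <- vector("list", nrow(pauses))
  for (p in seq_len(nrow(pauses))) {
    ps <- pauses$pause_start_s[p]
    pe <- pauses$pause_end_s[p]
    start <- ps + guard_s
    if (start >= pe) next
    win <- dplyr::filter(trace, .data$time_s >= ps, .data$time_s < pe)
    if (nrow(win) < 2L) next
    marks <- detect_ventilations(
      dplyr::select(win, "time_s", "co2_mmHg"), config,
      ti = if (!is.null(ti)) dplyr::filter(ti, .data$time_s >= ps, .data$time_s < pe)
    )
    marks <- dplyr::filter(marks, .data$upstroke_onset_s >= start)
    if (nrow(marks) < min_ventilations) next
    marks$breath <- seq_len(nrow(marks))
    segs[[p]] <- tibble(
      episode_id = episode_id,
      segment_id = sprintf("%s-s%02d", episode_id, p),
      pause_start_s = ps,
      start_s = start,
      end_s = pe,
      n_ventilations = nrow(marks),
      airway_type = airway_type,
      ventilations = list(marks)
    )
  }
  res <- dplyr::bind_rows(segs)
  if (nrow(res) == 0L) empty_segments() else res
}

empty_segments <- function() {
  tibble(
    episode_id = character(), segment_id = character(),
    pause_start_s = numeric(), start_s = numeric(), end_s = numeric(),
    n_ventilations = integer(), airway_type = character(),
    ventilations = list()
  )
}
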