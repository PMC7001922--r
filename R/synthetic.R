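#' Describe one compression-pause capnogram segment to synthesize
#'
#' A segment scenario fixes everything needed to render the CO2 waveform of a
#' compression-free interval: the initial plateau level `ep0`, the
#' per-ventilation decay multiplier `k` (successive true plateau levels are
#' `ep0 * k^n`, n = 0 ... N-1), the number of ventilations, and the breath
#' morphology. Plateau durations deliberately vary between breaths (drawn
#' uniformly from `plateau_range` when not given) so that end-of-plateau
#' end-tidal CO2 and the fixed-delay epCO2 metric differ, which is the
#' situation the metric exists for.
#'
#' @param ep0 Initial plateau level in mmHg (> 0).
#' @param k Decay multiplier per ventilation, in (0, 1].
#' @param n_ventilations Number of complete breaths (>= 2).
#' @param plateau_durations Optional numeric vector of plateau durations in
#'   seconds, one per ventilation. Drawn from `plateau_range` if `NULL`.
#' @param ventilation_rate Breath onset rate in ventilations per minute.
#' @param noise_sd Additive Gaussian measurement noise on the CO2 channel,
#'   mmHg.
#' @param seed Integer seed making the segment reproducible.
#' @param baseline_level Inspiratory baseline in mmHg (>= 0).
#' @param plateau_slope Slope of the (slightly ascending) alveolar plateau,
#'   mmHg/s (>= 0).
#' @param upstroke_s,downstroke_s Durations of the sigmoidal expiratory
#'   upstroke and inspiratory downstroke, seconds.
#' @param plateau_range Range (seconds) that random plateau durations are
#'   drawn from.
#' @param lead_in_s,lead_out_s Baseline padding before the first breath and
#'   after the last, seconds.
#' @return A validated list of class `segment_scenario`.
#' @examples
#' sc <- segment_scenario(ep0 = 20, k = 0.9, n_ventilations = 4, seed = 1)
#' seg <- generate_segment(sc, fs = 100)
#' head(seg$trace)
#' @export
segment_scenario <- function(ep0,
                             k,
                             n_ventilations,
                             plateau_durations = NULL,
                             ventilation_rate = 12,
                             noise_sd = 0.3,
                             seed = 1L,
                             baseline_level = 0,
                             plateau_slope = 0.5,
                             upstroke_s = 0.4,
                             downstroke_s = 0.4,
                             plateau_range = c(1.0, 3.0),
                             lead_in_s = 2.0,
                             lead_out_s = 2.0) {
  check_scalar_number(ep0, "ep0", min = 0, strict_min = TRUE)
  check_scalar_number(k, "k", min = 0, max = 1, strict_min = TRUE)
  check_scalar_number(n_ventilations, "n_ventilations", min = 2)
  n_ventilations <- as.integer(n_ventilations)
  check_scalar_number(ventilation_rate, "ventilation_rate", min = 0, strict_min = TRUE)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  check_scalar_number(baseline_level, "baseline_level", min = 0)
  if (ep0 <= baseline_level) {
    stop_invalid("ep0", "plateau level must exceed baseline_level")
  }
  check_scalar_number(plateau_slope, "plateau_slope", min = 0)
  check_scalar_number(upstroke_s, "upstroke_s", min = 0, strict_min = TRUE)
  check_scalar_number(downstroke_s, "downstroke_s", min = 0, strict_min = TRUE)
  check_scalar_number(lead_in_s, "lead_in_s", min = 0)
  check_scalar_number(lead_out_s, "lead_out_s", min = 0)
  seed <- as.integer(seed)

  if (is.null(plateau_durations)) {
    plateau_durations <- withr::with_seed(
      seed,
      runif(n_ventilations, plateau_range[1L], plateau_range[2L])
    )
  }
  if (!is.numeric(plateau_durations) ||
      length(plateau_durations) != n_ventilations) {
    stop_invalid("plateau_durations",
                 "must be numeric with one duration per ventilation")
  }
  if (any(plateau_durations <= 0)) {
    stop_invalid("plateau_durations", "all durations must be > 0")
  }
  period <- 60 / ventilation_rate
  breath_len <- upstroke_s + plateau_durations + downstroke_s
  if (any(head(breath_len, -1L) > period - 0.1)) {
    stop_invalid("ventilation_rate",
                 "breaths overlap: period must exceed breath duration + 0.1 s")
  }

  structure(
    list(
      ep0 = ep0, k = k, n_ventilations = n_ventilations,
      plateau_durations = as.numeric(plateau_durations),
      ventilation_rate = ventilation_rate, noise_sd = noise_sd,
      seed = seed, baseline_level = baseline_level,
      plateau_slope = plateau_slope, upstroke_s = upstroke_s,
      downstroke_s = downstroke_s, lead_in_s = lead_in_s,
      lead_out_s = lead_out_s
    ),
    class = "segment_scenario"
  )
}

# Render breath waveforms onto a pre-allocated baseline vector.
# onsets/levels/plateaus are per-breath; returns the modified values.
render_breaths <- function(time_s, values, onsets, levels, plateaus,
                           baseline, slope, up, down) {
  for (i in seq_along(onsets)) {
    o <- onsets[i]
    L <- levels[i]
    p_start <- o + up
    p_end <- p_start + plateaus[i]
    end_level <- L + slope * plateaus[i]
    d_end <- p_end + down

    idx <- which(time_s >= o & time_s < p_start)
    values[idx] <- baseline +
      (L - baseline) * smoothstep((time_s[idx] - o) / up)
    idx <- which(time_s >= p_start & time_s < p_end)
    values[idx] <- L + slope * (time_s[idx] - p_start)
    idx <- which(time_s >= p_end & time_s < d_end)
    values[idx] <- baseline +
      (end_level - baseline) *
        (1 - smoothstep((time_s[idx] - p_end) / down))
  }
  values
}

breath_truth <- function(onsets, scenario) {
  nv <- scenario$n_ventilations
  tibble(
    n = seq_len(nv) - 1L,
    upstroke_onset_s = onsets,
    plateau_start_s = onsets + scenario$upstroke_s,
    plateau_end_s = onsets + scenario$upstroke_s + scenario$plateau_durations,
    true_plateau_level_mmHg = scenario$ep0 * scenario$k^(seq_len(nv) - 1L)
  )
}

#' Synthesize the capnogram of one compression-pause segment
#'
#' Renders a four-phase breath morphology (baseline, sigmoidal upstroke,
#' slightly ascending alveolar plateau, sigmoidal downstroke) for each
#' ventilation, with noiseless plateau onset levels following the geometric
#' law `ep0 * k^n` exactly, then adds Gaussian measurement noise. The trace
#' starts and ends at baseline.
#'
#' @param scenario A [segment_scenario()].
#' @param fs Sampling rate in Hz (>= 20 recommended; must be > 0).
#' @return A list of class `capno_segment` with elements `trace` (tibble
#'   `time_s`, `co2_mmHg`), `truth` (tibble of per-breath landmarks and true
#'   plateau levels, breath index `n` starting at 0), `fs`, and `scenario`.
#' @export
generate_segment <- function(scenario, fs = 100) {
  if (!inherits(scenario, "segment_scenario")) {
    scenario <- do.call(segment_scenario, as.list(scenario))
  }
  check_scalar_number(fs, "fs", min = 0, strict_min = TRUE)

  period <- 60 / scenario$ventilation_rate
  onsets <- scenario$lead_in_s + (seq_len(scenario$n_ventilations) - 1L) * period
  last_end <- onsets[length(onsets)] + scenario$upstroke_s +
    scenario$plateau_durations[scenario$n_ventilations] + scenario$downstroke_s
  total <- last_end + scenario$lead_out_s
  time_s <- seq(0, total, by = 1 / fs)

  levels <- scenario$ep0 * scenario$k^(seq_len(scenario$n_ventilations) - 1L)
  co2 <- rep(scenario$baseline_level, length(time_s))
  co2 <- render_breaths(time_s, co2, onsets, levels,
                        scenario$plateau_durations,
                        scenario$baseline_level, scenario$plateau_slope,
                        scenario$upstroke_s, scenario$downstroke_s)
  if (scenario$noise_sd > 0) {
    co2 <- co2 + withr::with_seed(
      scenario$seed + 1L,
      rnorm(length(co2), 0, scenario$noise_sd)
    )
  }

  structure(
    list(
      trace = tibble(time_s = time_s, co2_mmHg = co2),
      truth = breath_truth(onsets, scenario),
      fs = fs,
      scenario = scenario
    ),
    class = "capno_segment"
  )
}

#' Describe a full CPR episode to synthesize
#'
#' An episode alternates chest-compression blocks and compression pauses.
#' Blocks are appended in order; an explicit `start_s` earlier than the end
#' of the previous block is rejected as an overlap.
#'
#' @param blocks A list of blocks from [compression_block()] and
#'   [pause_block()].
#' @param fs Sampling rate in Hz.
#' @param airway_type One of `"endotracheal"`, `"supraglottic"`, `"unknown"`.
#' @param rhythm_status `"non_perfusing"` (eligible for analysis) or
#'   `"perfusing"`; supplied as metadata because rhythm interpretation is
#'   outside this pipeline.
#' @param ti_vent_amp_ohm,ti_comp_amp_ohm Amplitudes of the slow
#'   ventilation-synchronous and fast compression-synchronous components of
#'   the transthoracic impedance channel, Ohm.
#' @param ti_baseline_ohm Impedance baseline, Ohm.
#' @param seed Integer seed.
#' @param episode_id Identifier carried through all output tables.
#' @return A validated list of class `episode_scenario`.
#' @export
episode_scenario <- function(blocks,
                             fs = 100,
                             airway_type = c("endotracheal", "supraglottic",
                                             "unknown"),
                             rhythm_status = "non_perfusing",
                             ti_vent_amp_ohm = 1.5,
                             ti_comp_amp_ohm = 0.5,
                             ti_baseline_ohm = 500,
                             seed = 1L,
                             episode_id = "ep001") {
  airway_type <- match.arg(airway_type)
  if (!rhythm_status %in% c("non_perfusing", "perfusing")) {
    stop_invalid("rhythm_status", "must be 'non_perfusing' or 'perfusing'")
  }
  check_scalar_number(fs, "fs", min = 0, strict_min = TRUE)
  if (!is.list(blocks) || length(blocks) == 0L) {
    stop_invalid("blocks", "must be a non-empty list of blocks")
  }

  t0 <- 0
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    if (!inherits(b, "episode_block")) {
      stop_invalid("blocks",
                   "each element must come from compression_block() or pause_block()")
    }
    start <- b$start_s %||% t0
    if (start < t0 - 1e-9) {
      stop_invalid("blocks", sprintf("block %d overlaps the previous block", i))
    }
    blocks[[i]]$start_s <- start
    blocks[[i]]$end_s <- start + b$duration_s
    t0 <- blocks[[i]]$end_s
  }

  structure(
    list(
      blocks = blocks, fs = fs, airway_type = airway_type,
      rhythm_status = rhythm_status,
      ti_vent_amp_ohm = ti_vent_amp_ohm,
      ti_comp_amp_ohm = ti_comp_amp_ohm,
      ti_baseline_ohm = ti_baseline_ohm,
      seed = as.integer(seed), episode_id = episode_id,
      duration_s = t0
    ),
    class = "episode_scenario"
  )
}

#' @rdname episode_scenario
#' @param duration_s Block duration in seconds.
#' @param depth_mm Peak-to-peak compression depth, mm.
#' @param rate_cpm Compression rate, compressions per minute.
#' @param start_s Optional explicit start time; defaults to the end of the
#'   previous block.
#' @export
compression_block <- function(duration_s, depth_mm = 50, rate_cpm = 110,
                              start_s = NULL) {
  check_scalar_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_scalar_number(depth_mm, "depth_mm", min = 0, strict_min = TRUE)
  check_scalar_number(rate_cpm, "rate_cpm", min = 0, strict_min = TRUE)
  structure(
    list(type = "compressions", duration_s = duration_s, depth_mm = depth_mm,
         rate_cpm = rate_cpm, start_s = start_s),
    class = "episode_block"
  )
}

#' @rdname episode_scenario
#' @param scenario A [segment_scenario()] describing the breaths delivered
#'   during the pause.
#' @param first_breath_delay_s Delay from pause onset to the first expiratory
#'   upstroke, seconds. The default (3.5 s) places every breath after the
#'   3 s post-compression guard.
#' @export
pause_block <- function(duration_s, scenario, first_breath_delay_s = 3.5,
                        start_s = NULL) {
  check_scalar_number(duration_s, "duration_s", min = 0, strict_min = TRUE)
  check_scalar_number(first_breath_delay_s, "first_breath_delay_s", min = 0)
  if (!inherits(scenario, "segment_scenario")) {
    stop_invalid("scenario", "must be a segment_scenario")
  }
  period <- 60 / scenario$ventilation_rate
  need <- first_breath_delay_s +
    (scenario$n_ventilations - 1L) * period + scenario$upstroke_s +
    scenario$plateau_durations[scenario$n_ventilations] +
    scenario$downstroke_s + 0.5
  if (need > duration_s) {
    stop_invalid("duration_s",
                 sprintf("pause too short for %d breaths (needs >= %.1f s)",
                         scenario$n_ventilations, need))
  }
  structure(
    list(type = "pause", duration_s = duration_s, scenario = scenario,
         first_breath_delay_s = first_breath_delay_s, start_s = start_s),
    class = "episode_block"
  )
}

#' Synthesize a multichannel CPR episode with ground truth
#'
#' Renders four concurrent channels: the capnogram (breaths inside pauses,
#' baseline elsewhere), compression depth (flat zero inside pauses,
#' oscillatory at the stated rate and peak-to-peak depth inside compression
#' blocks), transthoracic impedance (slow ventilation-synchronous bumps plus
#' fast compression-synchronous oscillation on a constant baseline), and a
#' placeholder fibrillation-like ECG that the pipeline never analyses
#' (rhythm status travels as metadata).
#'
#' @param scenario An [episode_scenario()].
#' @return A list of class `capno_episode` with `trace` (tibble `time_s`,
#'   `co2_mmHg`, `depth_mm`, `ti_ohm`, `ecg_mv`), `truth` (per-breath
#'   landmarks with `pause_id`), `pauses` (per-pause ground truth: bounds,
#'   `ep0`, `k`, `n_ventilations`), `airway_type`, `rhythm_status`,
#'   `episode_id`, `fs`.
#' @export
generate_episode <- function(scenario) {
  if (!inherits(scenario, "episode_scenario")) {
    stop_invalid("scenario", "must be an episode_scenario")
  }
  fs <- scenario$fs
  time_s <- seq(0, scenario$duration_s, by = 1 / fs)
  n <- length(time_s)

  co2 <- rep(0, n)
  depth <- rep(0, n)
  ti_slow <- rep(0, n)
  ti_fast <- rep(0, n)

  truth <- list()
  pauses <- list()
  pause_i <- 0L

  for (b in scenario$blocks) {
    idx <- which(time_s >= b$start_s & time_s < b$end_s)
    if (b$type == "compressions") {
      f <- b$rate_cpm / 60
      # depth oscillates 0 .. depth_mm so peak-to-peak equals depth_mm
      depth[idx] <- b$depth_mm / 2 *
        (1 - cos(2 * pi * f * (time_s[idx] - b$start_s)))
      ti_fast[idx] <- scenario$ti_comp_amp_ohm *
        sin(2 * pi * f * (time_s[idx] - b$start_s))
    } else {
      pause_i <- pause_i + 1L
      sc <- b$scenario
      period <- 60 / sc$ventilation_rate
      onsets <- b$start_s + b$first_breath_delay_s +
        (seq_len(sc$n_ventilations) - 1L) * period
      levels <- sc$ep0 * sc$k^(seq_len(sc$n_ventilations) - 1L)
      co2 <- render_breaths(time_s, co2, onsets, levels,
                            sc$plateau_durations, sc$baseline_level,
                            sc$plateau_slope, sc$upstroke_s, sc$downstroke_s)
      co2[idx][co2[idx] == 0] <- sc$baseline_level
      # slow impedance bump spanning each breath
      for (j in seq_along(onsets)) {
        blen <- sc$upstroke_s + sc$plateau_durations[j] + sc$downstroke_s
        bi <- which(time_s >= onsets[j] & time_s < onsets[j] + blen)
        ti_slow[bi] <- ti_slow[bi] + scenario$ti_vent_amp_ohm *
          sin(pi * (time_s[bi] - onsets[j]) / blen)^2
      }
      bt <- breath_truth(onsets, sc)
      bt$pause_id <- pause_i
      truth[[pause_i]] <- bt
      pauses[[pause_i]] <- tibble(
        pause_id = pause_i, start_s = b$start_s, end_s = b$end_s,
        ep0 = sc$ep0, k = sc$k, n_ventilations = sc$n_ventilations
      )
    }
  }

  noise <- withr::with_seed(scenario$seed, {
    list(
      co2 = rnorm(n, 0, 0.3),
      ti = rnorm(n, 0, 0.05),
      ecg = as.numeric(stats::filter(rnorm(n, 0, 0.4), rep(0.2, 5),
                                     sides = 2))
    )
  })
  co2_noise_sd <- if (pause_i > 0L) {
    # keep the channel-wide noise level consistent with the pause scenarios
    max(vapply(scenario$blocks[vapply(scenario$blocks, function(b) b$type == "pause", logical(1))],
               function(b) b$scenario$noise_sd, numeric(1)))
  } else 0.3
  co2 <- co2 + noise$co2 / 0.3 * co2_noise_sd
  ti <- scenario$ti_baseline_ohm + ti_slow + ti_fast + noise$ti
  ecg <- noise$ecg
  ecg[is.na(ecg)] <- 0

  structure(
    list(
      trace = tibble(time_s = time_s, co2_mmHg = co2, depth_mm = depth,
                     ti_ohm = ti, ecg_mv = ecg),
      truth = dplyr::bind_rows(truth),
      pauses = dplyr::bind_rows(pauses),
      airway_type = scenario$airway_type,
      rhythm_status = scenario$rhythm_status,
      episode_id = scenario$episode_id,
      fs = fs
    ),
    class = "capno_episode"
  )
}

#' Read and write episode traces and ground-truth annotations
#'
#' Traces are plain comma-separated text with one header row and columns
#' `time_s`, `co2_mmHg`, `depth_mm`, `ti_ohm`, `ecg_mv` (single-channel
#' segment traces carry only the first two). Ground truth has one row per
#' ventilation. Episode metadata (airway type, rhythm status) travels in a
#' YAML sidecar.
#'
#' @param trace A trace tibble.
#' @param path Output file path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   a tibble.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(trace, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  if (!"time_s" %in% names(tr)) {
    stop_data(sprintf("%s: missing required column `time_s`", path))
  }
  trace_dt(tr$time_s)
  tr
}

#' @rdname write_trace
#' @param truth Ground-truth tibble from [generate_segment()] or
#'   [generate_episode()].
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(path)
}

#' @rdname write_trace
#' @param episode A `capno_episode`.
#' @export
write_episode_metadata <- function(episode, path) {
  yaml::write_yaml(
    list(episode_id = episode$episode_id,
         airway_type = episode$airway_type,
         rhythm_status = episode$rhythm_status),
    path
  )
  invisible(path)
}
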