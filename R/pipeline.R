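#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis, validated once.
#' Unknown keys are rejected so config files cannot silently misspell an
#' option.
#'
#' @param guard_s Guard after the interruption of chest compressions before
#'   a segment may start, seconds.
#' @param min_ventilations Minimum complete ventilations per segment.
#' @param detection A [detection_config()].
#' @param max_iter,tol Decay-fit optimizer controls.
#' @param k_default Decay multiplier used by the ventilation-rate
#'   normalization when no per-segment fit is supplied.
#' @param vr_ref Reference ventilation rate for normalization, vpm.
#' @param seed Seed threading all randomness in a pipeline run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(guard_s = 3.0,
                            min_ventilations = 2L,
                            detection = detection_config(),
                            max_iter = 500L,
                            tol = 1e-12,
                            k_default = 0.9,
                            vr_ref = 10,
                            seed = 1L) {
  check_scalar_number(guard_s, "guard_s", min = 0)
  check_scalar_number(min_ventilations, "min_ventilations", min = 1)
  check_scalar_number(k_default, "k_default", min = 0, max = 1,
                      strict_min = TRUE)
  check_scalar_number(vr_ref, "vr_ref", min = 0, strict_min = TRUE)
  if (!inherits(detection, "detection_config")) {
    stop_invalid("detection", "must come from detection_config()")
  }
  structure(
    list(guard_s = guard_s,
         min_ventilations = as.integer(min_ventilations),
         detection = detection, max_iter = as.integer(max_iter), tol = tol,
         k_default = k_default, vr_ref = vr_ref, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys map to [pipeline_config()] arguments; a nested `detection`
#' section maps to [detection_config()]. Unknown keys abort.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  det <- raw$detection
  raw$detection <- NULL
  known <- setdiff(names(formals(pipeline_config)), "detection")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_invalid("config", paste("unknown keys:", paste(unknown, collapse = ", ")))
  }
  if (!is.null(det)) {
    unknown <- setdiff(names(det), names(formals(detection_config)))
    if (length(unknown)) {
      stop_invalid("config detection",
                   paste("unknown keys:", paste(unknown, collapse = ", ")))
    }
    raw$detection <- do.call(detection_config, det)
  }
  do.call(pipeline_config, raw)
}

#' Read a directory of episode trace files
#'
#' Each episode is a `*_trace.csv` delimited trace (header `time_s`,
#' `co2_mmHg`, `depth_mm`, ...) with an optional `*_meta.yaml` sidecar
#' carrying `episode_id`, `airway_type` and `rhythm_status`.
#'
#' @param input_dir Directory containing the episode files.
#' @return A list of `capno_episode` objects.
#' @export
read_episode_dir <- function(input_dir) {
  trace_files <- sort(list.files(input_dir, pattern = "_trace\\.csv$",
                                 full.names = TRUE))
  if (length(trace_files) == 0L) {
    stop_data(sprintf("no episode trace files (*_trace.csv) found in %s",
                      input_dir))
  }
  lapply(trace_files, function(f) {
    meta_f <- sub("_trace\\.csv$", "_meta.yaml", f)
    meta <- if (file.exists(meta_f)) {
      yaml::read_yaml(meta_f)
    } else {
      list(episode_id = sub("_trace\\.csv$", "", basename(f)),
           airway_type = "unknown", rhythm_status = "non_perfusing")
    }
    structure(
      list(trace = read_trace(f),
           episode_id = meta$episode_id %||% basename(f),
           airway_type = meta$airway_type %||% "unknown",
           rhythm_status = meta$rhythm_status %||% "non_perfusing"),
      class = "capno_episode"
    )
  })
}

#' Run the full capnogram analysis pipeline
#'
#' Sequences segment selection, epCO2 annotation, decay fitting, and cohort
#' summary over a set of episodes, with a funnel log recording how many
#' episodes and candidate segments survive each stage (episodes in, pauses
#' detected, segments selected, segments annotated, segments fitted,
#' segments skipped). Per-segment annotation or fit failures are logged and
#' skipped; they never abort the run.
#'
#' @param episodes A list of `capno_episode` objects (from
#'   [generate_episode()] or [read_episode_dir] via `input_dir`), or a
#'   directory path containing `*_trace.csv` (+ optional `*_meta.yaml`)
#'   episode files.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, `segments.csv`,
#'   `annotations.csv`, `fits.csv`, `summary.csv` and `funnel.csv` are
#'   written there as comma-separated text.
#' @return A list of class `capno_results`: `segments`, `annotations`,
#'   `fits`, `summary` (NULL when nothing was fitted), `funnel`.
#' @export
run_pipeline <- function(episodes, config = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(episodes) && length(episodes) == 1L) {
    episodes <- read_episode_dir(episodes)
  }
  if (!is.list(episodes) || length(episodes) == 0L) {
    stop_data("no episodes to analyse")
  }

  seg_list <- list()
  ann_list <- list()
  skipped <- character()
  n_pauses <- 0L

  for (epi in episodes) {
    pauses <- detect_compression_pauses(
      dplyr::select(epi$trace, "time_s", "depth_mm"), config$detection
    )
    n_pauses <- n_pauses + nrow(pauses)
    segs <- select_segments(epi, guard_s = config$guard_s,
                            min_ventilations = config$min_ventilations,
                            config = config$detection)
    if (nrow(segs) == 0L) next
    ann <- annotate_segments(segs, dplyr::select(epi$trace, "time_s",
                                                 "co2_mmHg"))
    skipped <- c(skipped, attr(ann, "skipped"))
    seg_list[[length(seg_list) + 1L]] <- segs
    ann_list[[length(ann_list) + 1L]] <- ann
  }

  segments <- if (length(seg_list)) dplyr::bind_rows(seg_list) else empty_segments()
  annotations <- dplyr::bind_rows(ann_list)
  fits <- if (nrow(annotations) > 0L) {
    fit_decay_all(annotations, segments, max_iter = config$max_iter,
                  tol = config$tol)
  } else {
    fit_decay_all(tibble(segment_id = character(), n = integer(),
                         ep_mmHg = numeric()))
  }
  summary <- if (nrow(fits) > 0L) summarize_fits(fits) else NULL

  funnel <- tibble(
    stage = c("episodes_in", "pauses_detected", "segments_selected",
              "segments_annotated", "segments_fitted", "segments_skipped"),
    count = c(length(episodes), n_pauses, nrow(segments),
              nrow(segments) - length(skipped), nrow(fits), length(skipped))
  )

  results <- structure(
    list(segments = segments, annotations = annotations, fits = fits,
         summary = summary, funnel = funnel, skipped = skipped),
    class = "capno_results"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(dplyr::select(segments, -"ventilations"),
                     file.path(out_dir, "segments.csv"))
    readr::write_csv(annotations, file.path(out_dir, "annotations.csv"))
    readr::write_csv(fits, file.path(out_dir, "fits.csv"))
    if (!is.null(summary)) {
      readr::write_csv(summary, file.path(out_dir, "summary.csv"))
    }
    readr::write_csv(funnel, file.path(out_dir, "funnel.csv"))
  }
  results
}

#' @export
print.capno_results <- function(x, ...) {
  cat("Capnogram decay analysis\n")
  for (i in seq_len(nrow(x$funnel))) {
    cat(sprintf("  %-20s %d\n", x$funnel$stage[i], x$funnel$count[i]))
  }
  if (nrow(x$fits) > 0L) {
    cat(sprintf("  median D = %.1f%%, median R^2 = %.2f\n",
                stats::median(x$fits$D_pct),
                stats::median(x$fits$r_squared)))
  }
  invisible(x)
}
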