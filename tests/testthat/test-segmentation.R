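test_that("ventilation detection recovers known breaths within tolerance", {
  sc <- segment_scenario(16.7, 0.9, 5, seed = 3)  # default noise 0.3 mmHg
  seg <- generate_segment(sc, fs = 100)
  marks <- detect_ventilations(seg$trace)
  expect_identical(nrow(marks), 5L)
  expect_true(all(abs(marks$upstroke_onset_s - seg$truth$upstroke_onset_s)
                  <= 0.2))
})

test_that("degenerate and breath-free traces are handled", {
  flat <- tibble::tibble(time_s = seq(0, 10, by = 0.01),
                         co2_mmHg = 0)
  expect_identical(nrow(detect_ventilations(flat)), 0L)
  expect_error(detect_ventilations(flat[1, ]), "degenerate")
  expect_error(detect_ventilations(tibble::tibble(a = 1)), "time_s")
})

test_that("an incomplete trailing breath is dropped", {
  seg <- flat_segment(N = 4)
  # truncate mid-plateau of the last breath
  cut <- seg$truth$plateau_start_s[4] + 1.0
  trunc <- dplyr::filter(seg$trace, time_s <= cut)
  marks <- detect_ventilations(trunc)
  expect_identical(nrow(marks), 3L)
})

test_that("sub-threshold blips are not reported as breaths", {
  t <- seq(0, 20, by = 0.01)
  x <- 3 * exp(-((t - 10) / 0.5)^2)  # 3 mmHg bump, below the 4 mmHg floor
  marks <- detect_ventilations(tibble::tibble(time_s = t, co2_mmHg = x))
  expect_identical(nrow(marks), 0L)
})

test_that("compression pause detection finds maximal quiet intervals", {
  # all-quiet trace -> single pause spanning it
  t <- seq(0, 30, by = 0.01)
  quiet <- tibble::tibble(time_s = t, depth_mm = 0)
  p <- detect_compression_pauses(quiet)
  expect_identical(nrow(p), 1L)
  expect_equal(p$pause_start_s, 0)
  expect_equal(p$pause_end_s, 30, tolerance = 0.1)

  # continuous compressions -> no pause
  busy <- tibble::tibble(time_s = t,
                         depth_mm = 25 * (1 - cos(2 * pi * 110 / 60 * t)))
  expect_identical(nrow(detect_compression_pauses(busy)), 0L)

  # synthetic episode pause bounds recovered within 0.5 s
  sc <- segment_scenario(20, 0.9, 4, seed = 2)
  epi <- generate_episode(episode_scenario(
    list(compression_block(60), pause_block(30, sc), compression_block(20)),
    seed = 4
  ))
  p <- detect_compression_pauses(epi$trace)
  expect_identical(nrow(p), 1L)
  expect_lt(abs(p$pause_start_s - 60), 0.5)
  expect_lt(abs(p$pause_end_s - 90), 0.5)
})

test_that("segment selection enforces guard, breath count and rhythm", {
  epi <- demo_episode(seed = 6, ep0 = 30, k = 0.9, nv = 5)
  segs <- select_segments(epi)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$n_ventilations, 5L)
  # guard honored exactly
  expect_equal(segs$start_s - segs$pause_start_s, 3.0)
  marks <- segs$ventilations[[1]]
  expect_true(all(marks$upstroke_onset_s >= segs$start_s))

  # single-breath pause yields no segment: drop breaths by shrinking to 2
  # then demanding 3
  segs3 <- select_segments(epi, min_ventilations = 6L)
  expect_identical(nrow(segs3), 0L)

  # perfusing rhythm excludes the whole episode
  perf <- demo_episode(seed = 6, ep0 = 30, k = 0.9, nv = 5,
                       rhythm_status = "perfusing")
  expect_identical(nrow(select_segments(perf)), 0L)

  # missing channel errors name the channel
  expect_error(select_segments(epi$trace[, c("time_s", "co2_mmHg")]),
               "depth_mm")
})

test_that("breaths inside the guard window are excluded", {
  # both breaths start within 3 s of the pause onset: segment rejected
  sc <- segment_scenario(20, 0.9, 2, plateau_durations = c(0.5, 0.5),
                         ventilation_rate = 30, noise_sd = 0, seed = 1)
  epi <- generate_episode(episode_scenario(
    list(compression_block(30),
         pause_block(15, sc, first_breath_delay_s = 0.5)),
    seed = 2
  ))
  expect_identical(nrow(select_segments(epi)), 0L)
})

test_that("detection sensitivity and precision hold across random scenarios", {
  set.seed(202)
  n_scen <- 60
  truth_n <- 0L
  hits <- 0L
  false_pos <- 0L
  detected_n <- 0L
  for (i in seq_len(n_scen)) {
    ep0 <- runif(1, 10, 40)
    N <- sample(2:8, 1)
    sc <- segment_scenario(ep0, 0.9, N, seed = 1000L + i)
    seg <- generate_segment(sc, fs = 100)
    marks <- detect_ventilations(seg$trace)
    truth_n <- truth_n + N
    detected_n <- detected_n + nrow(marks)
    for (t0 in seg$truth$upstroke_onset_s) {
      if (nrow(marks) > 0 && min(abs(marks$upstroke_onset_s - t0)) <= 0.5) {
        hits <- hits + 1L
      }
    }
    matched <- vapply(marks$upstroke_onset_s, function(m) {
      min(abs(seg$truth$upstroke_onset_s - m)) <= 0.5
    }, logical(1))
    false_pos <- false_pos + sum(!matched)
  }
  expect_gte(hits / truth_n, 0.95)
  expect_lte(false_pos / max(detected_n, 1L), 0.05)
})

test_that("impedance cross-check keeps coincident breaths", {
  epi <- demo_episode(seed = 11, ep0 = 30, k = 0.9, nv = 4)
  cfg <- detection_config(ti_crosscheck = TRUE)
  segs <- select_segments(epi, config = cfg)
  expect_identical(nrow(segs), 1L)
  expect_identical(segs$n_ventilations, 4L)
})
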