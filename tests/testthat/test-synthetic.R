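test_that("noiseless plateau levels follow the geometric law exactly", {
  # k = 1 identity: all plateaus at ep0
  seg <- flat_segment(ep0 = 20, k = 1, N = 3)
  expect_equal(seg$truth$true_plateau_level_mmHg, rep(20, 3))
  at <- seg$truth$plateau_start_s + 0.5
  expect_equal(approx(seg$trace$time_s, seg$trace$co2_mmHg, at)$y,
               rep(20, 3), tolerance = 1e-9)

  # decaying case reproduces the geometric trajectory from a = 16.7, b = 0.90
  seg <- flat_segment(ep0 = 16.7, k = 0.90, N = 5)
  expect_equal(seg$truth$true_plateau_level_mmHg,
               16.7 * 0.9^(0:4), tolerance = 1e-12)
  expect_equal(round(seg$truth$true_plateau_level_mmHg, 2),
               c(16.7, 15.03, 13.53, 12.17, 10.96))
  lv <- approx(seg$trace$time_s, seg$trace$co2_mmHg,
               seg$truth$plateau_start_s + 0.5)$y
  expect_equal(lv, 16.7 * 0.9^(0:4), tolerance = 1e-9)
})

test_that("noisy plateau sample means stay near the true levels", {
  sc <- segment_scenario(20, 0.9, 4, plateau_durations = rep(2, 4),
                         plateau_slope = 0, noise_sd = 0.5, seed = 42)
  seg <- generate_segment(sc, fs = 100)
  for (i in 1:4) {
    idx <- seg$trace$time_s >= seg$truth$plateau_start_s[i] &
      seg$trace$time_s < seg$truth$plateau_end_s[i]
    m <- mean(seg$trace$co2_mmHg[idx])
    tol <- 3 * 0.5 / sqrt(sum(idx))
    expect_lt(abs(m - 20 * 0.9^(i - 1)), tol)
  }
})

test_that("segment traces are reproducible and start/end at baseline", {
  a <- generate_segment(segment_scenario(20, 0.9, 3, seed = 9), fs = 100)
  b <- generate_segment(segment_scenario(20, 0.9, 3, seed = 9), fs = 100)
  expect_identical(a$trace, b$trace)
  expect_identical(a$truth, b$truth)

  noiseless <- flat_segment(N = 3)
  expect_equal(noiseless$trace$co2_mmHg[1], 0)
  expect_equal(tail(noiseless$trace$co2_mmHg, 1), 0)

  # marks are internally consistent and non-overlapping
  tr <- noiseless$truth
  expect_true(all(tr$upstroke_onset_s < tr$plateau_start_s))
  expect_true(all(tr$plateau_start_s < tr$plateau_end_s))
  expect_true(all(diff(tr$upstroke_onset_s) >
                    (tr$plateau_end_s - tr$upstroke_onset_s)[-nrow(tr)]))
})

test_that("scenario validation names the offending field", {
  expect_error(segment_scenario(0, 0.9, 3), "ep0")
  expect_error(segment_scenario(20, 0, 3), "k")
  expect_error(segment_scenario(20, 1.2, 3), "k")
  expect_error(segment_scenario(20, 0.9, 1), "n_ventilations")
  expect_error(segment_scenario(20, 0.9, 3, noise_sd = -1), "noise_sd")
  expect_error(segment_scenario(20, 0.9, 3, plateau_durations = c(1, 2)),
               "plateau_durations")
})

test_that("episode channels honor the block structure", {
  sc <- segment_scenario(20, 0.9, 5, seed = 2)
  epi <- generate_episode(episode_scenario(
    list(compression_block(60), pause_block(30, sc, start_s = 60)),
    seed = 5
  ))
  # exactly 5 ground-truth marks inside the pause
  expect_identical(nrow(epi$truth), 5L)
  expect_true(all(epi$truth$upstroke_onset_s >= 60))
  # depth flat at 0 inside the pause, oscillatory outside
  pause_idx <- epi$trace$time_s >= 60 & epi$trace$time_s < 90
  expect_true(all(epi$trace$depth_mm[pause_idx] == 0))
  comp <- epi$trace$depth_mm[epi$trace$time_s < 60]
  expect_gt(max(comp) - min(comp), 45)
  # impedance carries slow bumps in the pause and fast ripple in compressions
  ti <- epi$trace$ti_ohm
  expect_gt(max(ti[pause_idx]) - min(ti[pause_idx]), 1)

  # determinism
  epi2 <- generate_episode(episode_scenario(
    list(compression_block(60), pause_block(30, sc, start_s = 60)),
    seed = 5
  ))
  expect_identical(epi$trace, epi2$trace)
})

test_that("overlapping episode blocks are rejected", {
  sc <- segment_scenario(20, 0.9, 2, seed = 1)
  expect_error(
    episode_scenario(list(compression_block(60),
                          pause_block(30, sc, start_s = 50))),
    "overlap"
  )
})

test_that("trace files round-trip through the delimited text format", {
  epi <- demo_episode(seed = 3)
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ep_trace.csv")
  write_trace(epi$trace, f)
  back <- read_trace(f)
  expect_equal(as.data.frame(back), as.data.frame(epi$trace),
               tolerance = 1e-12)
  expect_error(read_trace({
    g <- file.path(dir, "bad.csv")
    readr::write_csv(tibble::tibble(x = 1:3), g)
    g
  }), "time_s")
})
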