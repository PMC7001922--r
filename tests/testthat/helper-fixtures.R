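# Shared synthetic fixtures built in code at test time.

flat_segment <- function(ep0 = 20, k = 0.9, N = 3, fs = 100, seed = 1,
                         plateau = 2) {
  generate_segment(
    segment_scenario(ep0, k, N, plateau_durations = rep(plateau, N),
                     plateau_slope = 0, noise_sd = 0, seed = seed),
    fs = fs
  )
}

# A small two-pause episode with known per-pause decay parameters.
demo_episode <- function(seed = 1, episode_id = "ep001",
                         airway_type = "endotracheal",
                         ep0 = c(25, 18), k = c(0.9, 0.88),
                         nv = c(5, 4), noise_sd = 0.3,
                         rhythm_status = "non_perfusing") {
  blocks <- list(compression_block(45))
  for (i in seq_along(ep0)) {
    sc <- segment_scenario(ep0[i], k[i], nv[i], noise_sd = noise_sd,
                           seed = seed + i)
    need <- 3.5 + (nv[i] - 1) * 5 + 4.5
    blocks <- c(blocks, list(pause_block(ceiling(need + 2), sc),
                             compression_block(30)))
  }
  generate_episode(episode_scenario(
    blocks, airway_type = airway_type, rhythm_status = rhythm_status,
    seed = seed, episode_id = episode_id
  ))
}
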