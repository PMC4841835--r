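test_that("noise-free interpolation hits the key poses exactly at holds", {
  poses <- kick_key_poses()[1:2]
  sc <- key_pose_script(topology_k2(), poses, hold_times = 0.5,
                        transition_times = 0.5, repetitions = 1L,
                        noise_sigma_pos = 0, rate = 30, seed = 1L)
  gen <- generate_motion(sc)
  gt <- gen$ground_truth
  expect_equal(nrow(gt), 2L)
  # first held frame of each pose equals the pose exactly
  for (p in 1:2) {
    i <- which(gen$sequence$times >= gt$t_start[p] &
               gen$sequence$times < gt$t_end[p])
    expect_equal(gen$sequence$positions[i[1], , ],
                 unname(poses[[p]]), ignore_attr = TRUE)
    expect_equal(gen$sequence$positions[i[length(i)], , ],
                 unname(poses[[p]]), ignore_attr = TRUE)
  }
})

test_that("frame count equals rate times scripted duration within one frame", {
  sc <- builtin_kick_script(seed = 1, repetitions = 2)
  gen <- generate_motion(sc)
  dur <- sum(rep(sc$hold_times, 2)) + sum(sc$transition_times) +
    sum(sc$transition_times[1:2])
  expect_lte(abs(n_frames(gen$sequence) - sc$rate * dur), 1)
  # single-pose script
  sc2 <- builtin_stance_script(seed = 1)
  gen2 <- generate_motion(sc2)
  expect_lte(abs(n_frames(gen2$sequence) - sc2$rate * sc2$hold_times[1]), 1)
})

test_that("generation is reproducible given the seed", {
  g1 <- generate_motion(builtin_kick_script(seed = 42, repetitions = 2))
  g2 <- generate_motion(builtin_kick_script(seed = 42, repetitions = 2))
  g3 <- generate_motion(builtin_kick_script(seed = 43, repetitions = 2))
  expect_identical(g1$sequence$positions, g2$sequence$positions)
  expect_false(identical(g1$sequence$positions, g3$sequence$positions))
  # generation does not disturb the caller's RNG stream
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(generate_motion(builtin_kick_script(seed = 1)))
  expect_identical(rnorm(1), before)
})

test_that("noise-free features at held poses equal the closed-form angles", {
  fs <- builtin_hiza_geri_features()
  sc <- builtin_kick_script(seed = 1, repetitions = 1, noise_sigma_pos = 0)
  gen <- generate_motion(sc)
  tab <- evaluate_features_stream(gen$sequence, fs)
  planted <- kick_pose_angles()
  for (p in 1:3) {
    gt <- gen$ground_truth[p, ]
    i <- which(gen$sequence$times >= gt$t_start &
               gen$sequence$times < gt$t_end)
    for (j in 1:6)
      expect_equal(unname(tab$columns[[j]][i]),
                   rep(unname(planted[p, j]), length(i)),
                   tolerance = 1e-9)
  }
})

test_that("feature spread at held poses grows with positional noise", {
  fs <- builtin_hiza_geri_features()
  spread_at <- function(sigma) {
    gen <- generate_motion(builtin_kick_script(
      seed = 100, repetitions = 1, noise_sigma_pos = sigma,
      hold_times = 2))
    tab <- evaluate_features_stream(gen$sequence, fs)
    gt <- gen$ground_truth[1, ]
    i <- which(gen$sequence$times >= gt$t_start &
               gen$sequence$times < gt$t_end)
    stats::sd(tab$columns$A1[i])
  }
  s <- vapply(c(0, 0.005, 0.02), spread_at, numeric(1L))
  expect_true(all(diff(s) > 0))
})

test_that("zero-noise timelines label held intervals with their key frame", {
  fs <- builtin_hiza_geri_features()
  ad <- builtin_kick_action()
  gen <- generate_motion(builtin_kick_script(seed = 1, repetitions = 2,
                                             noise_sigma_pos = 0))
  res <- classify_stream(gen$sequence, fs, ad)
  kf_names <- ad$actions[[1]]$sequence
  for (r in seq_len(nrow(gen$ground_truth))) {
    gt <- gen$ground_truth[r, ]
    i <- which(gen$sequence$times >= gt$t_start &
               gen$sequence$times < gt$t_end)
    expect_true(all(res$timeline$hiza_geri[i] == kf_names[gt$pose]))
  }
})

test_that("key-pose scripts round-trip through YAML", {
  sc <- builtin_kick_script(seed = 3, repetitions = 2)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_script(sc, f)
  sc2 <- read_script(f)
  expect_equal(sc2$hold_times, sc$hold_times)
  expect_equal(sc2$transition_times, sc$transition_times)
  expect_equal(sc2$seed, sc$seed)
  g1 <- generate_motion(sc)
  g2 <- generate_motion(sc2)
  expect_equal(g2$sequence$positions, g1$sequence$positions,
               tolerance = 1e-12)
})
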