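test_that("the built-in knee-kick set has six numeric angle features", {
  fs <- builtin_hiza_geri_features()
  expect_length(fs$defs, 6L)
  expect_true(all(vapply(fs$defs, `[[`, character(1L), "kind") == "numeric"))
  expect_identical(names(fs$defs), paste0("A", 1:6))
  expect_identical(fs$topology$name, "K2")
})

test_that("constructed geometry gives the expected angles", {
  topo <- topology_k2()
  # head directly above neck -> angle with vertical = 0
  fs <- feature_set(
    feature_def("A", "numeric",
                "angle(sub(joint(Head), joint(Neck)), vec(0, 1, 0))"),
    topo)
  pose <- kick_key_poses()$neutral
  pose["Head", ] <- pose["Neck", ] + c(0, 0.2, 0)
  fv <- evaluate_features(skeleton_frame(0, pose, topo), fs)
  expect_equal(fv$values$A, 0)
  # thigh perpendicular to torso and shin parallel to torso
  hg <- builtin_hiza_geri_features()
  pose2 <- kick_key_poses()$neutral
  torso <- pose2["SpineShoulder", ] - pose2["SpineBase", ]
  torso <- torso / sqrt(sum(torso^2))
  perp <- c(0, -torso[3], torso[2])          # in-plane perpendicular
  pose2["KneeRight", ] <- pose2["HipRight", ] + 0.4 * perp
  pose2["AnkleRight", ] <- pose2["KneeRight", ] - 0.4 * torso
  fv2 <- evaluate_features(skeleton_frame(0, pose2, topo), hg)
  expect_equal(fv2$values$A1, 90, tolerance = 1e-9)
  expect_equal(fv2$values$A2, 180, tolerance = 1e-9)
})

test_that("each built-in angle matches a direct per-pair oracle on random frames", {
  fs <- builtin_hiza_geri_features()
  set.seed(5)
  pairs <- list(A1 = c("KneeRight", "HipRight", "torso"),
                A2 = c("AnkleRight", "KneeRight", "torso"),
                A3 = c("KneeLeft", "HipLeft", "torso"),
                A4 = c("KneeRight", "HipRight", "vert"),
                A5 = c("AnkleRight", "KneeRight", "vert"),
                A6 = c("KneeLeft", "HipLeft", "vert"))
  for (i in 1:25) {
    frame <- random_k2_frame()
    fv <- evaluate_features(frame, fs)
    p <- frame$positions
    torso <- p["SpineShoulder", ] - p["SpineBase", ]
    for (nm in names(pairs)) {
      spec <- pairs[[nm]]
      v <- p[spec[1], ] - p[spec[2], ]
      ref <- if (spec[3] == "torso") torso else c(0, 1, 0)
      expect_equal(fv$values[[nm]], oracle_angle_deg(v, ref),
                   tolerance = 1e-9)
    }
  }
})

test_that("angle features are invariant under rigid transformation", {
  fs <- builtin_hiza_geri_features()
  set.seed(8)
  vertical_only <- c("A4", "A5", "A6")   # reference the global vertical
  for (i in 1:30) {
    frame <- random_k2_frame()
    fv <- evaluate_features(frame, fs)
    # A1-A3 are internal angles: invariant under any rotation + translation
    rot <- random_rotation()
    fvr <- evaluate_features(transform_frame(frame, rot, rnorm(3)), fs)
    for (nm in c("A1", "A2", "A3"))
      expect_equal(fvr$values[[nm]], fv$values[[nm]], tolerance = 1e-9)
    # A4-A6 involve the vertical: invariant under rotations about +y
    th <- runif(1, 0, 2 * pi)
    roty <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0,
                     sin(th), 0, cos(th)), 3L)
    fvy <- evaluate_features(transform_frame(frame, roty, rnorm(3)), fs)
    for (nm in names(fs$defs))
      expect_equal(fvy$values[[nm]], fv$values[[nm]], tolerance = 1e-9)
  }
})

test_that("degenerate vectors error on single frames, NA + warn on streams", {
  topo <- topology_k2()
  fs <- builtin_hiza_geri_features()
  pose <- kick_key_poses()$neutral
  pose["KneeRight", ] <- pose["HipRight", ]   # zero-length thigh
  expect_error(evaluate_features(skeleton_frame(0.5, pose, topo), fs),
               "degenerate.*t=0.5")
  seq <- motion_sequence(topo, c(0, 0.1),
                         list(kick_key_poses()$neutral, pose))
  expect_warning(tab <- evaluate_features_stream(seq, fs), "degenerate")
  expect_true(is.na(tab$columns$A1[2]))
  expect_false(is.na(tab$columns$A1[1]))
})

test_that("stream evaluation equals frame-by-frame evaluation", {
  fs <- builtin_hiza_geri_features()
  gen <- generate_motion(builtin_kick_script(seed = 3, repetitions = 1))
  seq <- gen$sequence
  tab <- evaluate_features_stream(seq, fs)
  hist <- NULL
  for (i in seq_len(n_frames(seq))) {
    fv <- evaluate_features(get_frame(seq, i), fs, history = hist)
    for (nm in names(fs$defs))
      expect_equal(fv$values[[nm]], tab$columns[[nm]][i],
                   tolerance = 1e-12)
    hist <- fv
  }
})

test_that("feature definition files round-trip through YAML", {
  fs <- builtin_hiza_geri_features()
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_feature_defs(fs, f1)
  fs2 <- read_feature_defs(f1)
  expect_identical(names(fs2$defs), names(fs$defs))
  write_feature_defs(fs2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  frame <- random_k2_frame()
  expect_equal(evaluate_features(frame, fs2)$values,
               evaluate_features(frame, fs)$values)
})
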