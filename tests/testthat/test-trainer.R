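# shared training fixtures: distinct held poses, quick transitions
train_script <- function(seed, ...)
  builtin_kick_script(seed = seed, hold_times = 1, transition_times = 0.1,
                      ...)

make_exemplars <- function(n, seed0)
  lapply(seq_len(n), function(i)
    generate_motion(train_script(seed0 + i))$sequence)

test_that("the feature matrix pools frames with per-exemplar phase", {
  fs <- builtin_hiza_geri_features()
  ex <- make_exemplars(2, 500)
  m <- build_feature_matrix(ex, fs)
  expect_identical(m$feature_names, paste0("A", 1:6))
  expect_equal(nrow(m$values), sum(vapply(ex, n_frames, integer(1L))))
  expect_setequal(unique(m$meta$exemplar), 1:2)
  expect_equal(min(m$meta$phase), 0)
  expect_equal(max(m$meta$phase), 1)
  # rows equal per-frame evaluation
  tab <- evaluate_features_stream(ex[[1]], fs)
  for (nm in m$feature_names)
    expect_equal(m$values[m$meta$exemplar == 1, nm],
                 tab$columns[[nm]], ignore_attr = TRUE)
  # single-frame exemplar: phase defined as 0
  one <- motion_sequence(topology_k2(), 0.5,
                         list(kick_key_poses()$neutral))
  m1 <- build_feature_matrix(list(one), fs)
  expect_equal(m1$meta$phase, 0)
})

test_that("k = 1 clustering returns the column means", {
  fs <- builtin_hiza_geri_features()
  m <- build_feature_matrix(make_exemplars(1, 600), fs)
  mod <- cluster_keyframes(m, k = 1, seed = 1)
  expect_equal(as.numeric(mod$centroids[1, ]),
               unname(colMeans(m$values)), tolerance = 1e-9)
  expect_identical(mod$temporal_order, 1L)
})

test_that("clustering errors when rows < k", {
  fs <- builtin_hiza_geri_features()
  one <- motion_sequence(topology_k2(), 0.5,
                         list(kick_key_poses()$neutral))
  m <- build_feature_matrix(list(one), fs)
  expect_error(cluster_keyframes(m, k = 3, seed = 1), "insufficient")
})

test_that("two well-separated planted poses are recovered within tolerance", {
  fs <- builtin_hiza_geri_features()
  poses <- kick_key_poses()[c(1, 3)]
  ex <- lapply(1:10, function(i) {
    sc <- key_pose_script(topology_k2(), poses, hold_times = 1,
                          transition_times = 0.1, noise_sigma_pos = 0.005,
                          rate = 30, seed = 700 + i)
    generate_motion(sc)$sequence
  })
  m <- build_feature_matrix(ex, fs)
  mod <- cluster_keyframes(m, k = 2, seed = 1)
  planted <- kick_pose_angles()[c(1, 3), ]
  ord <- mod$temporal_order
  # centroids absorb a few interpolated transition frames per cluster, so
  # the bound is the same 2-degree envelope the k = 3 recovery obeys
  expect_lt(max(abs(mod$centroids[ord, ] - planted)), 2)
  expect_true(all(diff(mod$mean_phase[ord]) > 0))
})

test_that("small-instance k-means attains the exhaustive-partition optimum", {
  set.seed(88)
  fs <- builtin_hiza_geri_features()
  for (trial in 1:3) {
    n <- 9L; k <- 3L
    vals <- matrix(rnorm(n * 6, sd = 2), nrow = n,
                   dimnames = list(NULL, paste0("A", 1:6)))
    m <- structure(list(values = vals,
                        meta = data.frame(exemplar = 1L,
                                          timestamp = seq_len(n) / 10,
                                          phase = seq(0, 1, length.out = n)),
                        feature_names = paste0("A", 1:6)),
                   class = "feature_matrix")
    mod <- cluster_keyframes(m, k = k, seed = trial, nstart = 50)
    xs <- scale(vals)
    # exhaustive search over all 3^9 assignments
    best <- Inf
    grid <- as.matrix(expand.grid(rep(list(1:k), n)))
    for (r in seq_len(nrow(grid))) {
      a <- grid[r, ]
      if (length(unique(a)) < k) next
      ss <- 0
      for (c_i in 1:k) {
        rows <- xs[a == c_i, , drop = FALSE]
        ss <- ss + sum(sweep(rows, 2, colMeans(rows))^2)
      }
      best <- min(best, ss)
    }
    expect_equal(mod$tot_withinss, best, tolerance = 1e-8)
  }
})

test_that("synthesized rules form interval conjunctions per key frame", {
  fs <- builtin_hiza_geri_features()
  ex <- make_exemplars(5, 800)
  tr <- train_rgdl(ex, fs, k = 3, seed = 2, class_name = "kick")
  expect_length(tr$actions$rules, 3L)
  expect_identical(tr$actions$actions[[1]]$sequence,
                   c("kick_kf1", "kick_kf2", "kick_kf3"))
  # each rule: 6 features x 2 bounds = 12 comparisons
  for (r in tr$actions$rules) {
    txt <- format(r$expr)
    expect_equal(lengths(regmatches(txt, gregexpr(">=", txt))), 6L)
    expect_equal(lengths(regmatches(txt, gregexpr("<=", txt))), 6L)
  }
  # tolerances floored at 5 degrees
  expect_true(all(tr$model$tolerances >= 5))
})

test_that("the closed loop re-detects training exemplars exactly once", {
  fs <- builtin_hiza_geri_features()
  ex <- make_exemplars(10, 900)
  tr <- train_rgdl(ex, fs, k = 3, seed = 3, class_name = "kick")
  counts <- vapply(ex, function(s)
    nrow(classify_stream(s, fs, tr$actions)$events), integer(1L))
  expect_gte(mean(counts == 1L), 0.95)
})

test_that("widening tolerances never removes a detection", {
  fs <- builtin_hiza_geri_features()
  ex <- make_exemplars(8, 950)
  m <- build_feature_matrix(ex, fs)
  mod <- cluster_keyframes(m, k = 3, seed = 4)
  base <- synthesize_rules(mod, "kick")
  wide_mod <- mod
  wide_mod$tolerances <- mod$tolerances * 2
  wide <- synthesize_rules(wide_mod, "kick",
                           time_params = list(
                             max_gap = base$actions[[1]]$max_gap,
                             max_span = base$actions[[1]]$max_span))
  for (s in ex) {
    n_base <- nrow(classify_stream(s, fs, base)$events)
    n_wide <- nrow(classify_stream(s, fs, wide)$events)
    expect_gte(n_wide, min(n_base, 1L))
  }
})

test_that("training is deterministic given the seed", {
  fs <- builtin_hiza_geri_features()
  ex <- make_exemplars(5, 970)
  t1 <- train_rgdl(ex, fs, k = 3, seed = 11)
  t2 <- train_rgdl(ex, fs, k = 3, seed = 11)
  expect_identical(t1$model$centroids, t2$model$centroids)
  expect_identical(t1$model$assignments, t2$model$assignments)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_action_defs(t1$actions, f1)
  write_action_defs(t2$actions, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("PCA recovers planar structure and fixes signs deterministically", {
  set.seed(33)
  n <- 80L
  # rank-2 data embedded in 6-D
  basis <- matrix(rnorm(12), nrow = 2L)
  vals <- matrix(rnorm(2 * n), ncol = 2L) %*% basis
  vals <- sweep(vals, 2L, rnorm(6, sd = 5), "+")
  colnames(vals) <- paste0("A", 1:6)
  m <- structure(list(values = vals,
                      meta = data.frame(exemplar = 1L,
                                        timestamp = seq_len(n),
                                        phase = seq(0, 1, length.out = n)),
                      feature_names = colnames(vals)),
                 class = "feature_matrix")
  proj <- pca_project(m, dims = 2L)
  expect_equal(sum(proj$explained[1:2]), 1, tolerance = 1e-9)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(proj$loadings)))
    expect_gte(proj$loadings[which.max(abs(proj$loadings[, j])), j], 0)
  # linearity: the projection of a group centroid equals the mean of the
  # group's projected points
  half <- seq_len(n / 2)
  xs <- scale(vals)
  centroid_proj <- colMeans(xs[half, , drop = FALSE]) %*% proj$loadings
  expect_equal(as.numeric(centroid_proj[1, 1:2]),
               unname(colMeans(proj$scores[half, ])), tolerance = 1e-9)
  # reconstruction: retained variance + residual variance = total
  total_var <- sum(apply(scale(vals), 2L, stats::var))
  expect_equal(sum(proj$explained) * total_var, total_var,
               tolerance = 1e-9)
  # constant columns are dropped with a warning
  vals2 <- vals; vals2[, 3] <- 7
  m2 <- m; m2$values <- vals2
  expect_warning(p2 <- pca_project(m2, dims = 2L), "constant")
  expect_identical(p2$dropped, "A3")
})

test_that("models round-trip through YAML serialization", {
  fs <- builtin_hiza_geri_features()
  ex <- make_exemplars(4, 980)
  mod <- cluster_keyframes(build_feature_matrix(ex, fs), k = 3, seed = 5)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_model(mod, f)
  mod2 <- read_model(f)
  expect_equal(mod2$centroids, mod$centroids, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(mod2$tolerances, mod$tolerances, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(mod2$temporal_order, mod$temporal_order)
})
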