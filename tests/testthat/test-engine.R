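make_fv <- function(...) {
  structure(list(timestamp = 0, values = list(...),
                 conclusions = character()),
            class = "feature_vector")
}

test_that("key-frame rules evaluate independently per frame", {
  rules <- list(keyframe_rule("low", "A1 < 30 and A2 > 150"),
                keyframe_rule("any", "A1 < 30 or A2 < 30"))
  expect_setequal(evaluate_keyframes(make_fv(A1 = 10, A2 = 170), rules),
                  c("low", "any"))
  expect_identical(evaluate_keyframes(make_fv(A1 = 10, A2 = 10), rules),
                   "any")
  expect_length(evaluate_keyframes(make_fv(A1 = 50, A2 = 50), rules), 0L)
  expect_error(evaluate_keyframes(make_fv(A1 = 1), rules),
               "unresolved feature")
})

test_that("the memory stack evicts by time from the oldest end", {
  st <- memory_stack(10)
  st <- push_frame(st, 0, NULL, "a")
  expect_length(st$times, 1L)
  for (t in 1:5) st <- push_frame(st, t, NULL, character())
  st2 <- push_frame(st, 100, NULL, "b")
  expect_identical(st2$times, 100)
  expect_identical(st2$satisfied, list("b"))
  expect_error(push_frame(st, 2, NULL, character()), "ordering error")
  # brute-force retention window on a random push sequence
  set.seed(14)
  cap <- 3
  st <- memory_stack(cap)
  ts <- cumsum(runif(60, 0.05, 1.2))
  for (i in seq_along(ts)) {
    st <- push_frame(st, ts[i], NULL, character())
    expect_identical(st$times, ts[ts[i] - ts <= cap & ts <= ts[i]])
  }
})

test_that("match_sequence finds ordered witnesses within time limits", {
  a <- action_definition("X", c("KF1", "KF2", "KF3"),
                         max_gap = 0.5, max_span = 2)
  st <- memory_stack(10)
  st <- push_frame(st, 0.0, NULL, "KF1")
  st <- push_frame(st, 0.4, NULL, "KF2")
  st <- push_frame(st, 0.8, NULL, "KF3")
  ev <- match_sequence(st, a)
  expect_identical(ev$class_name, "X")
  expect_equal(ev$trigger_time, 0.8)
  expect_equal(ev$keyframe_times, c(0.0, 0.4, 0.8))
  # out-of-order satisfactions do not match
  st2 <- memory_stack(10)
  st2 <- push_frame(st2, 0.0, NULL, "KF2")
  st2 <- push_frame(st2, 0.4, NULL, "KF1")
  st2 <- push_frame(st2, 0.8, NULL, "KF3")
  expect_null(match_sequence(st2, a))
  # gap violation
  st3 <- memory_stack(10)
  st3 <- push_frame(st3, 0.0, NULL, "KF1")
  st3 <- push_frame(st3, 1.0, NULL, "KF2")
  st3 <- push_frame(st3, 1.4, NULL, "KF3")
  expect_null(match_sequence(st3, a))
  # non-decreasing default: one frame may serve two consecutive key frames
  a2 <- action_definition("X", c("KF1", "KF2"), max_gap = 0.6,
                          max_span = 2)
  st4 <- memory_stack(10)
  st4 <- push_frame(st4, 0.0, NULL, "KF1")
  st4 <- push_frame(st4, 0.5, NULL, c("KF1", "KF2"))
  ev4 <- match_sequence(st4, a2)
  expect_equal(ev4$keyframe_times, c(0.5, 0.5))
  # with strict increase the shared frame cannot serve both key frames
  expect_equal(match_sequence(st4, a2, strict = TRUE)$keyframe_times,
               c(0.0, 0.5))
  # backtracking: when the latest middle candidate is too far from the
  # first key frame, an earlier one still completes the match
  a3 <- action_definition("X", c("KF1", "KF2", "KF3"), max_gap = 0.6,
                          max_span = 2)
  st5 <- memory_stack(10)
  st5 <- push_frame(st5, 0.0, NULL, "KF1")
  st5 <- push_frame(st5, 0.4, NULL, "KF2")
  st5 <- push_frame(st5, 0.9, NULL, "KF2")
  st5 <- push_frame(st5, 1.0, NULL, "KF3")
  ev5 <- match_sequence(st5, a3)
  expect_equal(ev5$keyframe_times, c(0.0, 0.4, 1.0))
})

test_that("match_sequence agrees with exhaustive enumeration", {
  set.seed(1234)
  n_checked <- 0L
  for (i in 1:300) {
    inst <- random_match_instance(max_entries = 30L, max_kf = 4L)
    a <- action_definition("X", inst$kf_names, max_gap = inst$max_gap,
                           max_span = max(inst$max_span, inst$max_gap))
    st <- memory_stack(1e6)
    for (j in seq_along(inst$times))
      st <- push_frame(st, inst$times[j], NULL, inst$satisfied[[j]])
    got <- match_sequence(st, a)
    sat_idx <- lapply(seq_along(inst$kf_names), function(kf)
      which(inst$sat[, kf]))
    want <- oracle_match(inst$times, sat_idx, a$max_gap, a$max_span)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$keyframe_times, inst$times[want])
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 20L)   # the mix must include real matches
})

test_that("classification is deterministic and causal (online == offline)", {
  fs <- builtin_hiza_geri_features()
  ad <- builtin_kick_action()
  gen <- generate_motion(builtin_kick_script(seed = 4, repetitions = 3))
  seq <- gen$sequence
  res1 <- classify_stream(seq, fs, ad)
  res2 <- classify_stream(seq, fs, ad)
  expect_identical(res1$events, res2$events)
  expect_identical(res1$timeline, res2$timeline)
  # frame-by-frame stepping yields the identical result
  state <- gdl_engine(fs, ad)
  for (i in seq_len(n_frames(seq)))
    state <- engine_step(state, get_frame(seq, i))
  res3 <- engine_result(state)
  expect_equal(res3$events$trigger_time, res1$events$trigger_time)
  expect_equal(res3$timeline, res1$timeline)
})

test_that("a stream with no satisfied rules is all-N with no events", {
  fs <- builtin_hiza_geri_features()
  rules <- list(keyframe_rule("impossible", "A1 < -1"))
  ad <- gdl_actions(rules, action_definition("none", "impossible"))
  gen <- generate_motion(builtin_kick_script(seed = 6, repetitions = 1))
  res <- classify_stream(gen$sequence, fs, ad)
  expect_equal(nrow(res$events), 0L)
  expect_true(all(res$timeline$none == "N"))
})

test_that("each planted repetition triggers exactly one event", {
  fs <- builtin_hiza_geri_features()
  ad <- builtin_kick_action()
  gen <- generate_motion(builtin_kick_script(seed = 9, repetitions = 3))
  res <- classify_stream(gen$sequence, fs, ad)
  expect_equal(nrow(res$events), 3L)
  # events complete near each repetition's strike-hold onset
  strikes <- gen$ground_truth[gen$ground_truth$pose == 3L, ]
  expect_equal(order(res$events$trigger_time), 1:3)
  for (i in 1:3)
    expect_lt(abs(res$events$trigger_time[i] - strikes$t_start[i]), 0.4)
  # reversing the key-frame order detects nothing
  ad_rev <- gdl_actions(unname(ad$rules),
                        action_definition("rev",
                                          rev(ad$actions[[1]]$sequence),
                                          max_gap = 1, max_span = 3))
  expect_equal(nrow(classify_stream(gen$sequence, fs, ad_rev)$events), 0L)
})

test_that("inserting unlabelled frames between satisfactions never breaks a match", {
  a <- action_definition("X", c("KF1", "KF2"), max_gap = 1, max_span = 3)
  base_t <- c(0.0, 0.6)
  base_s <- list("KF1", "KF2")
  build <- function(times, sats) {
    st <- memory_stack(10)
    for (i in seq_along(times)) st <- push_frame(st, times[i], NULL, sats[[i]])
    st
  }
  ev0 <- match_sequence(build(base_t, base_s), a)
  expect_false(is.null(ev0))
  # add idle frames in between: outcome unchanged
  t2 <- c(0.0, 0.2, 0.4, 0.6)
  s2 <- list("KF1", character(), character(), "KF2")
  ev1 <- match_sequence(build(t2, s2), a)
  expect_equal(ev1$keyframe_times, ev0$keyframe_times)
})

test_that("action documents round-trip byte-identically through YAML", {
  ad <- builtin_kick_action()
  f1 <- withr::local_tempfile(fileext = ".yaml")
  f2 <- withr::local_tempfile(fileext = ".yaml")
  write_action_defs(ad, f1)
  ad2 <- read_action_defs(f1)
  write_action_defs(ad2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(names(ad2$rules), names(ad$rules))
  expect_equal(ad2$actions[[1]]$max_gap, ad$actions[[1]]$max_gap)
})
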