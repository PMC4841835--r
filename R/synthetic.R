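# Synthetic labelled skeleton streams: key-pose interpolation with tempo and
# noise controls.  The generator supplies ground truth for validating the
# feature system, the sequence classifier and the trainer.

# unit direction in the sagittal (y-z) plane: polar angle `deg` measured from
# the +y (vertical) axis toward +z (forward); z_sign = -1 tilts backward
.sagittal_dir <- function(deg, z_sign = 1) {
  r <- deg * pi / 180
  c(0, cos(r), z_sign * sin(r))
}

# Schematic upright K2 skeleton (metres, +y vertical, +z forward).  The right
# leg is re-posed by .k2_pose_legs(); all other joints are pose-invariant.
.k2_body_template <- function() {
  torso_dir <- .sagittal_dir(10)    # slight forward lean so the torso axis
                                    # is distinct from the global vertical
  spine_base <- c(0, 1.00, 0)
  spine_shoulder <- spine_base + 0.50 * torso_dir
  spine_mid <- spine_base + 0.25 * torso_dir
  neck <- spine_shoulder + 0.06 * torso_dir
  head <- spine_shoulder + 0.20 * torso_dir
  shoulder_off <- c(0.20, 0, 0)
  arm_hang <- c(0, -1, 0)
  pos <- rbind(
    SpineBase = spine_base, SpineMid = spine_mid,
    SpineShoulder = spine_shoulder, Neck = neck, Head = head,
    ShoulderLeft = spine_shoulder - shoulder_off,
    ElbowLeft = spine_shoulder - shoulder_off + 0.30 * arm_hang,
    WristLeft = spine_shoulder - shoulder_off + 0.55 * arm_hang,
    HandLeft = spine_shoulder - shoulder_off + 0.63 * arm_hang,
    HandTipLeft = spine_shoulder - shoulder_off + 0.71 * arm_hang,
    ThumbLeft = spine_shoulder - shoulder_off + 0.60 * arm_hang + c(0.05, 0, 0),
    ShoulderRight = spine_shoulder + shoulder_off,
    ElbowRight = spine_shoulder + shoulder_off + 0.30 * arm_hang,
    WristRight = spine_shoulder + shoulder_off + 0.55 * arm_hang,
    HandRight = spine_shoulder + shoulder_off + 0.63 * arm_hang,
    HandTipRight = spine_shoulder + shoulder_off + 0.71 * arm_hang,
    ThumbRight = spine_shoulder + shoulder_off + 0.60 * arm_hang + c(-0.05, 0, 0),
    HipLeft = c(-0.10, 0.95, 0),
    KneeLeft = c(0, 0, 0), AnkleLeft = c(0, 0, 0), FootLeft = c(0, 0, 0),
    HipRight = c(0.10, 0.95, 0),
    KneeRight = c(0, 0, 0), AnkleRight = c(0, 0, 0), FootRight = c(0, 0, 0))
  colnames(pos) <- c("x", "y", "z")
  pos
}

# Pose the legs by sagittal polar angles (degrees from vertical-up, so a
# straight standing leg is near 180).  Bone lengths: thigh and shin 0.4 m.
.k2_pose_legs <- function(pos, thigh_r, shin_r, thigh_l = 160, shin_l = 160,
                          left_z_sign = -1) {
  dir_tr <- .sagittal_dir(thigh_r)
  dir_sr <- .sagittal_dir(shin_r)
  pos["KneeRight", ] <- pos["HipRight", ] + 0.4 * dir_tr
  pos["AnkleRight", ] <- pos["KneeRight", ] + 0.4 * dir_sr
  pos["FootRight", ] <- pos["AnkleRight", ] +
    0.15 * .sagittal_dir(max(shin_r - 75, 5))
  dir_tl <- .sagittal_dir(thigh_l, left_z_sign)
  dir_sl <- .sagittal_dir(shin_l, left_z_sign)
  pos["KneeLeft", ] <- pos["HipLeft", ] + 0.4 * dir_tl
  pos["AnkleLeft", ] <- pos["KneeLeft", ] + 0.4 * dir_sl
  pos["FootLeft", ] <- pos["AnkleLeft", ] +
    0.15 * .sagittal_dir(max(shin_l - 75, 5), left_z_sign)
  pos
}

#' Key poses of the synthetic knee kick
#'
#' Three K2 poses — neutral stance, knee raised, strike — given as explicit
#' joint coordinates.  Right-leg polar angles (degrees from vertical) are:
#' pose 1 thigh 165 / shin 165 (straight standing leg, slight forward tilt),
#' pose 2 thigh 80 / shin 160 (knee lifted, shin hanging), pose 3 thigh 40 /
#' shin 100 (knee driven high, shin forward).  The torso leans 10 degrees
#' forward and the left leg tilts 20 degrees backward, so no planted angle
#' sits at the 0/180 degeneracy where unsigned angles fold noise.
#'
#' With the [builtin_hiza_geri_features()] set the planted feature values
#' (degrees) are, by construction:
#' pose 1 (155, 155, 170, 165, 165, 160); pose 2 (70, 150, 170, 80, 160,
#' 160); pose 3 (30, 90, 170, 40, 100, 160).
#'
#' @return List of three `25 x 3` joint-position matrices.
#' @export
kick_key_poses <- function() {
  base <- .k2_body_template()
  list(
    neutral = .k2_pose_legs(base, thigh_r = 165, shin_r = 165),
    knee_up = .k2_pose_legs(base, thigh_r = 80, shin_r = 160),
    strike  = .k2_pose_legs(base, thigh_r = 40, shin_r = 100))
}

#' Planted feature values of the kick key poses
#'
#' Closed-form angles of [kick_key_poses()] under the built-in six-angle
#' feature set (all directions lie in the sagittal plane, so each angle is a
#' difference of polar angles).
#'
#' @return `3 x 6` matrix (poses x features A1..A6), degrees.
#' @export
kick_pose_angles <- function() {
  torso <- 10; thigh_l <- 160
  pose <- function(thigh_r, shin_r)
    c(A1 = thigh_r - torso, A2 = shin_r - torso, A3 = thigh_l + torso,
      A4 = thigh_r, A5 = shin_r, A6 = thigh_l)
  m <- rbind(pose(165, 165), pose(80, 160), pose(40, 100))
  rownames(m) <- c("neutral", "knee_up", "strike")
  m
}

#' Key-pose script for synthetic motion generation
#'
#' A script describes a repeated exercise: an ordered list of full-body key
#' poses, per-pose hold times, transition times between consecutive poses
#' (the last transition returns to the first pose between repetitions), a
#' repetition count, i.i.d. Gaussian positional noise, the frame rate and a
#' seed.
#'
#' @param topology Topology of the poses.
#' @param key_poses List of `joints x 3` position matrices.
#' @param hold_times Seconds each pose is held (recycled to pose count; > 0).
#' @param transition_times Seconds per transition (recycled; > 0).
#' @param repetitions Number of repetitions (>= 1).
#' @param noise_sigma_pos Positional noise standard deviation in metres per
#'   joint coordinate.  The default 0 disables noise; 0.015 m corresponds to
#'   roughly 3 degrees of angular noise on a 0.4 m limb.
#' @param rate Frame rate in Hz.
#' @param seed Integer RNG seed (generation is deterministic given the seed).
#' @return An object of class `key_pose_script`.
#' @export
key_pose_script <- function(topology, key_poses, hold_times,
                            transition_times, repetitions = 1L,
                            noise_sigma_pos = 0, rate = 30, seed = 1L) {
  topology <- get_topology(topology)
  stopifnot(length(key_poses) >= 1L, rate > 0, repetitions >= 1L,
            noise_sigma_pos >= 0)
  k <- length(key_poses)
  hold_times <- rep_len(as.numeric(hold_times), k)
  transition_times <- rep_len(as.numeric(transition_times), k)
  if (any(hold_times <= 0) || any(transition_times <= 0))
    stop("all durations must be > 0")
  key_poses <- lapply(key_poses, function(p) {
    p <- as.matrix(p)
    if (nrow(p) != length(topology$joint_names))
      stop("pose joint count does not match topology")
    if (!is.null(rownames(p))) p <- p[topology$joint_names, , drop = FALSE]
    p
  })
  structure(list(topology = topology, key_poses = key_poses,
                 hold_times = hold_times,
                 transition_times = transition_times,
                 repetitions = as.integer(repetitions),
                 noise_sigma_pos = noise_sigma_pos,
                 rate = rate, seed = as.integer(seed)),
            class = "key_pose_script")
}

# run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a labelled synthetic motion stream
#'
#' Frames are linear interpolations between consecutive key poses sampled at
#' the scripted rate, with i.i.d. Gaussian positional noise added per joint
#' coordinate.  The ground truth records, per repetition and key pose, the
#' timestamp interval during which the pose is held.  Deterministic given
#' the script's seed.
#'
#' @param script A [key_pose_script()].
#' @return List with `sequence` (a `motion_sequence`) and `ground_truth`
#'   (data frame: `repetition`, `pose`, `t_start`, `t_end`).
#' @export
generate_motion <- function(script) {
  stopifnot(inherits(script, "key_pose_script"))
  k <- length(script$key_poses)
  reps <- script$repetitions
  # segment table: type (hold/transition), pose indices, duration
  segs <- list()
  for (r in seq_len(reps)) {
    for (p in seq_len(k)) {
      segs[[length(segs) + 1L]] <- list(type = "hold", rep = r,
                                        from = p, to = p,
                                        dur = script$hold_times[p])
      last_seg <- r == reps && p == k
      if (!last_seg) {
        to <- if (p < k) p + 1L else 1L
        segs[[length(segs) + 1L]] <- list(type = "transition", rep = r,
                                          from = p, to = to,
                                          dur = script$transition_times[p])
      }
    }
  }
  durs <- vapply(segs, `[[`, numeric(1L), "dur")
  starts <- cumsum(c(0, durs))
  total <- starts[length(starts)]
  n <- max(1L, round(total * script$rate))
  times <- (seq_len(n) - 1L) / script$rate
  seg_of <- findInterval(times, starts, rightmost.closed = FALSE)
  seg_of[seg_of > length(segs)] <- length(segs)
  jn <- script$topology$joint_names
  J <- length(jn)
  positions <- array(NA_real_, dim = c(n, J, 3L),
                     dimnames = list(NULL, jn, c("x", "y", "z")))
  for (i in seq_len(n)) {
    s <- segs[[seg_of[i]]]
    if (s$type == "hold") {
      positions[i, , ] <- script$key_poses[[s$from]]
    } else {
      frac <- (times[i] - starts[seg_of[i]]) / s$dur
      positions[i, , ] <- (1 - frac) * script$key_poses[[s$from]] +
        frac * script$key_poses[[s$to]]
    }
  }
  if (script$noise_sigma_pos > 0) {
    noise <- .with_seed(script$seed,
                        array(stats::rnorm(n * J * 3L,
                                           sd = script$noise_sigma_pos),
                              dim = c(n, J, 3L)))
    positions <- positions + noise
  }
  holds <- Filter(function(s) s$type == "hold", segs)
  hold_idx <- which(vapply(segs, `[[`, character(1L), "type") == "hold")
  ground_truth <- data.frame(
    repetition = vapply(holds, `[[`, numeric(1L), "rep"),
    pose = vapply(holds, `[[`, numeric(1L), "from"),
    t_start = starts[hold_idx],
    t_end = starts[hold_idx] + durs[hold_idx])
  list(sequence = motion_sequence(script$topology, times, positions,
                                  nominal_rate = script$rate),
       ground_truth = ground_truth)
}

#' Built-in synthetic scripts
#'
#' `builtin_kick_script()` emulates a repeated knee kick: the three
#' [kick_key_poses()] with 0.5 s holds and 0.5 s transitions at 30 Hz,
#' followed by a 6 s reset back to the neutral stance between repetitions
#' (athletes re-set between kicks; the slow return also means the backward
#' pass through the pose space happens far slower than the kick itself).
#' `builtin_stance_script()` emulates a held wide horse stance (single key
#' pose: feet wide, knees bent).
#'
#' @param seed RNG seed for the positional noise.
#' @param repetitions Repetition count.
#' @param noise_sigma_pos Metres; the default 0.015 corresponds to roughly
#'   3 degrees of angular noise on the 0.4 m limb segments.
#' @param rate Frame rate, Hz.
#' @param hold_times,transition_times Seconds (see [key_pose_script()]).
#' @return A `key_pose_script`.
#' @export
builtin_kick_script <- function(seed = 1L, repetitions = 1L,
                                noise_sigma_pos = 0.015, rate = 30,
                                hold_times = 0.5,
                                transition_times = c(0.5, 0.5, 6)) {
  key_pose_script(topology_k2(), kick_key_poses(),
                  hold_times = hold_times,
                  transition_times = transition_times,
                  repetitions = repetitions,
                  noise_sigma_pos = noise_sigma_pos,
                  rate = rate, seed = seed)
}

#' @rdname builtin_kick_script
#' @export
builtin_stance_script <- function(seed = 1L, repetitions = 1L,
                                  noise_sigma_pos = 0.015, rate = 30,
                                  hold_times = 2, transition_times = 0.5) {
  base <- .k2_body_template()
  # wide stance: both thighs splayed laterally, knees bent, shins vertical
  stance <- base
  stance["KneeRight", ] <- stance["HipRight", ] + 0.4 * c(sin(pi / 5), -cos(pi / 5), 0)
  stance["AnkleRight", ] <- stance["KneeRight", ] + 0.4 * c(0, -1, 0) + c(0, 0, 0.02)
  stance["FootRight", ] <- stance["AnkleRight", ] + c(0.02, -0.03, 0.14)
  stance["KneeLeft", ] <- stance["HipLeft", ] + 0.4 * c(-sin(pi / 5), -cos(pi / 5), 0)
  stance["AnkleLeft", ] <- stance["KneeLeft", ] + 0.4 * c(0, -1, 0) + c(0, 0, 0.02)
  stance["FootLeft", ] <- stance["AnkleLeft", ] + c(-0.02, -0.03, 0.14)
  key_pose_script(topology_k2(), list(stance = stance),
                  hold_times = hold_times,
                  transition_times = transition_times,
                  repetitions = repetitions,
                  noise_sigma_pos = noise_sigma_pos,
                  rate = rate, seed = seed)
}

# ---- script serialization (YAML) ----------------------------------------

#' Read / write key-pose scripts
#'
#' Scripts serialize to YAML with poses as per-joint coordinate rows.
#'
#' @param path File path.
#' @return `read_script()` returns a `key_pose_script`.
#' @export
read_script <- function(path) {
  doc <- yaml::read_yaml(path)
  topo <- .topology_from_list(doc$topology)
  poses <- lapply(doc$key_poses, function(p) {
    m <- do.call(rbind, lapply(p, as.numeric))
    rownames(m) <- names(p)
    m
  })
  key_pose_script(topo, poses, doc$hold_times, doc$transition_times,
                  repetitions = doc$repetitions,
                  noise_sigma_pos = doc$noise_sigma_pos,
                  rate = doc$rate, seed = doc$seed)
}

#' @rdname read_script
#' @param script A `key_pose_script`.
#' @export
write_script <- function(script, path) {
  doc <- list(
    topology = .topology_to_list(script$topology),
    key_poses = lapply(script$key_poses, function(p) {
      rows <- lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ]))
      names(rows) <- rownames(p)
      rows
    }),
    hold_times = script$hold_times,
    transition_times = script$transition_times,
    repetitions = script$repetitions,
    noise_sigma_pos = script$noise_sigma_pos,
    rate = script$rate, seed = script$seed)
  .write_yaml_canonical(doc, path)
  invisible(path)
}

#' Write generator ground truth to a text file
#' @param ground_truth Ground-truth data frame from [generate_motion()].
#' @param path Output path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  utils::write.csv(ground_truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
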