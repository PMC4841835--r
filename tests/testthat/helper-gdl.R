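# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately coded from scratch (different formulas/code paths
# than the package) so agreement is evidence, not tautology.

# independent angle oracle: clamped arccos of the normalized dot product,
# cross-checked through atan2 on components computed with base determinants
oracle_angle_deg <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  cross <- c(det(rbind(c(1, 0, 0), a, b)),
             det(rbind(c(0, 1, 0), a, b)),
             det(rbind(c(0, 0, 1), a, b)))
  atan2(sqrt(sum(cross^2)), sum(a * b)) * 180 / pi
}

# uniform random rotation matrix (QR of a Gaussian matrix, sign-fixed to a
# proper rotation)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3L))
  q <- qr.Q(qr_d)
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}

# random valid K2 frame: template pose plus positional jitter
random_k2_frame <- function(timestamp = 0, jitter = 0.2) {
  pos <- kick_key_poses()$neutral
  pos <- pos + matrix(rnorm(length(pos), sd = jitter), nrow = nrow(pos))
  skeleton_frame(timestamp, pos, topology_k2())
}

# apply a rigid transform (rotation + translation) to a skeleton frame
transform_frame <- function(frame, rot, shift) {
  skeleton_frame(frame$timestamp,
                 t(rot %*% t(frame$positions)) +
                   matrix(shift, nrow = nrow(frame$positions),
                          ncol = 3L, byrow = TRUE),
                 frame$topology)
}

# brute-force witness enumeration for the sequence matcher: all candidate
# index tuples (non-decreasing), filtered by order/gap/span, reporting the
# witness whose earlier key-frame indices are lexicographically latest
# (compared from the second-to-last key frame backwards)
oracle_match <- function(times, sat_idx, max_gap, max_span,
                         strict = FALSE) {
  k <- length(sat_idx)
  n <- length(times)
  if (!(n %in% sat_idx[[k]])) return(NULL)
  if (k == 1L) return(n)
  grids <- c(sat_idx[seq_len(k - 1L)], list(n))
  tuples <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  ok <- rep(TRUE, nrow(tuples))
  for (j in seq_len(k - 1L)) {
    inc <- if (strict) tuples[, j] < tuples[, j + 1L]
           else tuples[, j] <= tuples[, j + 1L]
    gap <- times[tuples[, j + 1L]] - times[tuples[, j]] <= max_gap
    ok <- ok & inc & gap
  }
  ok <- ok & (times[tuples[, k]] - times[tuples[, 1L]] <= max_span)
  if (!any(ok)) return(NULL)
  valid <- tuples[ok, , drop = FALSE]
  # lexicographic max over (i_{k-1}, i_{k-2}, ..., i_1)
  o <- do.call(order, c(lapply(rev(seq_len(k - 1L)), function(j)
    valid[, j]), list(decreasing = TRUE)))
  as.integer(valid[o[1L], ])
}

# random matcher instance: entries with random times and random rule
# satisfaction; returns pieces for both match_sequence and the oracle
random_match_instance <- function(max_entries = 50L, max_kf = 5L,
                                  p_sat = 0.2) {
  n <- sample(3:max_entries, 1L)
  k <- sample(1:max_kf, 1L)
  times <- cumsum(runif(n, 0.01, 0.3))
  kf_names <- paste0("KF", seq_len(k))
  sat <- matrix(runif(n * k) < p_sat, nrow = n)
  # ensure a case mix: sometimes force the newest entry to satisfy KF_k
  if (runif(1) < 0.5) sat[n, k] <- TRUE
  satisfied <- lapply(seq_len(n), function(i) kf_names[sat[i, ]])
  list(times = times, kf_names = kf_names,
       sat = sat,
       satisfied = satisfied,
       max_gap = runif(1, 0.1, 1.5),
       max_span = runif(1, 0.5, 4))
}

# tiny BVH document builder (text), used for import tests
bvh_text <- function(hierarchy, frames_mat, frame_time = 0.1) {
  c("HIERARCHY", hierarchy, "MOTION",
    paste("Frames:", nrow(frames_mat)),
    paste("Frame Time:", frame_time),
    apply(frames_mat, 1L, paste, collapse = " "))
}

# independent forward kinematics: explicit 4x4 homogeneous matrix product
# along the path from the root for every joint separately
oracle_fk_positions <- function(joint_defs, channel_values) {
  rot4 <- function(axis, deg) {
    r <- deg * pi / 180; cs <- cos(r); sn <- sin(r)
    m <- diag(4)
    if (axis == "X") m[2:3, 2:3] <- matrix(c(cs, sn, -sn, cs), 2L)
    if (axis == "Y") m[c(1, 3), c(1, 3)] <- matrix(c(cs, -sn, sn, cs), 2L)
    if (axis == "Z") m[1:2, 1:2] <- matrix(c(cs, sn, -sn, cs), 2L)
    m
  }
  trans4 <- function(v) { m <- diag(4); m[1:3, 4] <- v; m }
  local_mat <- function(jd, vals) {
    m <- trans4(jd$offset)
    tv <- c(0, 0, 0)
    rm_ <- diag(4)
    for (i in seq_along(jd$channels)) {
      ch <- tolower(jd$channels[i]); v <- vals[i]
      if (ch == "xposition") tv[1] <- tv[1] + v
      else if (ch == "yposition") tv[2] <- tv[2] + v
      else if (ch == "zposition") tv[3] <- tv[3] + v
      else rm_ <- rm_ %*% rot4(toupper(substr(ch, 1, 1)), v)
    }
    m %*% trans4(tv) %*% rm_
  }
  out <- matrix(NA_real_, nrow = length(joint_defs), ncol = 3L,
                dimnames = list(names(joint_defs), NULL))
  for (nm in names(joint_defs)) {
    chain <- nm
    while (!is.na(joint_defs[[chain[1L]]]$parent))
      chain <- c(joint_defs[[chain[1L]]]$parent, chain)
    m <- diag(4)
    for (link in chain)
      m <- m %*% local_mat(joint_defs[[link]], channel_values[[link]])
    out[nm, ] <- m[1:3, 4]
  }
  out
}

# independent rule-expression oracle: textual translation to base R syntax
# evaluated with eval(parse(...)) in an environment of feature values
oracle_eval_rule <- function(expr_text, values) {
  r_text <- gsub("\\band\\b", "&", expr_text)
  r_text <- gsub("\\bor\\b", "|", r_text)
  r_text <- gsub("\\bnot\\b", "!", r_text)
  eval(parse(text = r_text), envir = as.list(values))
}
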