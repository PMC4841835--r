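#' Import a BVH motion-capture file
#'
#' Parses the standard BVH HIERARCHY/MOTION dialect and computes world joint
#' positions by forward kinematics (offset translations composed with Euler
#' rotations in the channel order declared in the file).  Supports input from
#' high-end optical capture systems that export BVH.
#'
#' @param path Path to a BVH file.
#' @param scale Multiplier applied to offsets and translation channels (BVH
#'   files are often in centimetres; use `scale = 0.01` for metres).
#' @return A `motion_sequence` whose topology is taken from the BVH
#'   hierarchy (End Sites are ignored).
#' @export
import_bvh <- function(path, scale = 1) {
  tokens <- scan(path, what = character(), quiet = TRUE)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  nxt <- function() {
    t <- peek()
    if (is.na(t)) stop("format error: unexpected end of BVH file")
    pos <<- pos + 1L
    t
  }
  expect <- function(what) {
    t <- nxt()
    if (toupper(t) != toupper(what))
      stop("format error: expected '", what, "' but found '", t, "'")
    t
  }

  joints <- list()   # name, parent, offset, channels, doc_idx
  doc_counter <- 0L
  parse_joint <- function(parent) {
    kw <- toupper(nxt())
    if (kw == "END") {            # End Site: consume block, record nothing
      expect("Site")
      expect("{")
      expect("OFFSET")
      nxt(); nxt(); nxt()
      expect("}")
      return(invisible(NULL))
    }
    if (!(kw %in% c("ROOT", "JOINT")))
      stop("format error: expected ROOT/JOINT/End, found '", kw, "'")
    name <- nxt()
    doc_counter <<- doc_counter + 1L
    my_doc_idx <- doc_counter   # channels appear in document (pre-) order
    expect("{")
    offset <- NULL
    channels <- character()
    repeat {
      t <- peek()
      if (is.na(t)) stop("format error: unterminated JOINT block")
      tu <- toupper(t)
      if (tu == "OFFSET") {
        nxt()
        offset <- as.numeric(c(nxt(), nxt(), nxt())) * scale
      } else if (tu == "CHANNELS") {
        nxt()
        k <- as.integer(nxt())
        channels <- vapply(seq_len(k), function(i) nxt(), character(1L))
      } else if (tu %in% c("JOINT", "END")) {
        parse_joint(name)
      } else if (t == "}") {
        nxt()
        break
      } else stop("format error: unexpected token '", t, "' in JOINT block")
    }
    if (is.null(offset)) stop("format error: joint ", name, " has no OFFSET")
    joints[[length(joints) + 1L]] <<- list(name = name, parent = parent,
                                           offset = offset,
                                           channels = channels,
                                           doc_idx = my_doc_idx)
    invisible(NULL)
  }

  expect("HIERARCHY")
  # parse_joint appends children before parents (post-order); reorder later
  parse_joint(NA_character_)
  if (toupper(peek()) %in% "ROOT")
    stop("format error: multiple ROOT joints are not supported")
  expect("MOTION")
  expect("Frames:")
  n_frames <- as.integer(nxt())
  expect("Frame")
  expect("Time:")
  frame_time <- as.numeric(nxt())
  total_channels <- sum(vapply(joints, function(j) length(j$channels),
                               integer(1L)))
  vals <- suppressWarnings(as.numeric(tokens[pos:length(tokens)]))
  if (length(vals) < n_frames * total_channels || anyNA(vals[seq_len(n_frames * total_channels)]))
    stop("format error: MOTION section has too few numeric values")
  motion <- matrix(vals[seq_len(n_frames * total_channels)],
                   nrow = n_frames, byrow = TRUE)

  # topological order: parents before children
  nm <- vapply(joints, `[[`, character(1L), "name")
  ord <- integer()
  remaining <- seq_along(joints)
  placed <- character()
  while (length(remaining) > 0L) {
    ready <- remaining[vapply(remaining, function(i) {
      p <- joints[[i]]$parent
      is.na(p) || p %in% placed
    }, logical(1L))]
    if (length(ready) == 0L) stop("format error: broken joint hierarchy")
    ord <- c(ord, ready)
    placed <- c(placed, nm[ready])
    remaining <- setdiff(remaining, ready)
  }
  joints <- joints[ord]
  nm <- nm[ord]
  # MOTION channels follow the HIERARCHY document (pre-) order
  doc_order <- order(vapply(joints, `[[`, integer(1L), "doc_idx"))
  starts_doc <- cumsum(c(0L, vapply(joints[doc_order], function(j)
    length(j$channels), integer(1L))))[seq_along(joints)]
  ch_start <- integer(length(joints))
  ch_start[doc_order] <- starts_doc

  parent_idx <- match(vapply(joints, `[[`, character(1L), "parent"), nm)

  rot_mat <- function(axis, deg) {
    r <- deg * pi / 180
    cs <- cos(r); sn <- sin(r)
    switch(axis,
           X = matrix(c(1, 0, 0, 0, cs, sn, 0, -sn, cs), 3L),
           Y = matrix(c(cs, 0, -sn, 0, 1, 0, sn, 0, cs), 3L),
           Z = matrix(c(cs, sn, 0, -sn, cs, 0, 0, 0, 1), 3L))
  }

  J <- length(joints)
  positions <- array(NA_real_, dim = c(n_frames, J, 3L),
                     dimnames = list(NULL, nm, c("x", "y", "z")))
  for (f in seq_len(n_frames)) {
    R_world <- vector("list", J)
    for (j in seq_len(J)) {
      jt <- joints[[j]]
      trans <- jt$offset
      R_local <- diag(3L)
      if (length(jt$channels) > 0L) {
        ch <- motion[f, ch_start[j] + seq_along(jt$channels)]
        for (c_i in seq_along(jt$channels)) {
          cname <- tolower(jt$channels[c_i])
          v <- ch[c_i]
          if (cname == "xposition") trans[1L] <- trans[1L] + v * scale
          else if (cname == "yposition") trans[2L] <- trans[2L] + v * scale
          else if (cname == "zposition") trans[3L] <- trans[3L] + v * scale
          else if (cname == "xrotation") R_local <- R_local %*% rot_mat("X", v)
          else if (cname == "yrotation") R_local <- R_local %*% rot_mat("Y", v)
          else if (cname == "zrotation") R_local <- R_local %*% rot_mat("Z", v)
          else stop("format error: unknown channel '", jt$channels[c_i], "'")
        }
      }
      if (is.na(parent_idx[j])) {
        positions[f, j, ] <- trans
        R_world[[j]] <- R_local
      } else {
        p <- parent_idx[j]
        positions[f, j, ] <- positions[f, p, ] + R_world[[p]] %*% trans
        R_world[[j]] <- R_world[[p]] %*% R_local
      }
    }
  }
  topo <- joint_topology(
    name = paste0("bvh:", basename(path)),
    joint_names = nm,
    parent_of = stats::setNames(
      vapply(joints, `[[`, character(1L), "parent"),
      nm)[!is.na(parent_idx)])
  times <- (seq_len(n_frames) - 1L) * frame_time
  motion_sequence(topo, times, positions, nominal_rate = 1 / frame_time)
}
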