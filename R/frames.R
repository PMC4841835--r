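#' Skeleton frame
#'
#' One time sample of a motion-capture stream: a timestamp plus a 3D position
#' (metres, right-handed frame, +y vertical) for every joint of a topology.
#'
#' @param timestamp Non-negative time in seconds.
#' @param positions Numeric matrix with one row per joint (rownames = joint
#'   names) and columns x, y, z; or a named list of length-3 vectors.
#' @param topology A `joint_topology` or preset name.
#' @return An object of class `skeleton_frame`.
#' @export
skeleton_frame <- function(timestamp, positions, topology) {
  topology <- get_topology(topology)
  if (is.list(positions))
    positions <- do.call(rbind, lapply(positions, as.numeric))
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must have 3 columns (x, y, z)")
  jn <- topology$joint_names
  if (is.null(rownames(positions))) {
    if (nrow(positions) != length(jn))
      stop("topology error: frame has ", nrow(positions),
           " joints, topology ", topology$name, " expects ", length(jn))
    rownames(positions) <- jn
  }
  missing <- setdiff(jn, rownames(positions))
  if (length(missing) > 0L)
    stop("topology error: frame is missing joints: ",
         paste(missing, collapse = ", "))
  positions <- positions[jn, , drop = FALSE]
  colnames(positions) <- c("x", "y", "z")
  if (!all(is.finite(positions))) stop("all coordinates must be finite")
  timestamp <- as.numeric(timestamp)
  if (length(timestamp) != 1L || !is.finite(timestamp) || timestamp < 0)
    stop("timestamp must be a single non-negative finite number")
  structure(list(timestamp = timestamp, positions = positions,
                 topology = topology),
            class = "skeleton_frame")
}

#' Motion sequence
#'
#' A time-ordered stream of skeleton frames sharing one topology.  Internally
#' positions are held as an `n x joints x 3` array for fast whole-stream
#' feature evaluation.
#'
#' @param topology A `joint_topology` or preset name.
#' @param times Strictly increasing numeric vector of timestamps (seconds).
#' @param positions Array `n x joints x 3` (joint order = topology order), or
#'   a list of per-frame `joints x 3` matrices.
#' @param nominal_rate Optional nominal capture rate in Hz (metadata only).
#' @return An object of class `motion_sequence`.
#' @export
motion_sequence <- function(topology, times, positions, nominal_rate = NULL) {
  topology <- get_topology(topology)
  times <- as.numeric(times)
  n <- length(times)
  jn <- topology$joint_names
  if (is.list(positions)) {
    arr <- array(NA_real_, dim = c(n, length(jn), 3L),
                 dimnames = list(NULL, jn, c("x", "y", "z")))
    for (i in seq_len(n)) {
      p <- positions[[i]]
      if (!is.null(rownames(p))) p <- p[jn, , drop = FALSE]
      arr[i, , ] <- as.matrix(p)
    }
    positions <- arr
  }
  if (n > 0L) {
    if (length(dim(positions)) != 3L ||
        dim(positions)[1L] != n || dim(positions)[3L] != 3L)
      stop("positions must be an n x joints x 3 array")
    if (dim(positions)[2L] != length(jn))
      stop("topology error: stream has ", dim(positions)[2L],
           " joints, topology ", topology$name, " expects ", length(jn))
    if (!all(is.finite(positions))) stop("all coordinates must be finite")
    if (any(!is.finite(times)) || any(times < 0))
      stop("timestamps must be finite and non-negative")
    if (n > 1L && any(diff(times) <= 0))
      stop("timestamps must be strictly increasing")
    dimnames(positions) <- list(NULL, jn, c("x", "y", "z"))
  } else {
    positions <- array(NA_real_, dim = c(0L, length(jn), 3L),
                       dimnames = list(NULL, jn, c("x", "y", "z")))
  }
  structure(list(topology = topology, times = times, positions = positions,
                 nominal_rate = nominal_rate),
            class = "motion_sequence")
}

#' Assemble a motion sequence from individual frames
#'
#' @param frames List of `skeleton_frame` objects in time order.
#' @param topology Topology (defaults to the first frame's).
#' @inheritParams motion_sequence
#' @return A `motion_sequence`.
#' @export
as_motion_sequence <- function(frames, topology = NULL, nominal_rate = NULL) {
  if (length(frames) == 0L) {
    if (is.null(topology)) stop("topology required for an empty sequence")
    return(motion_sequence(topology, numeric(), list(),
                           nominal_rate = nominal_rate))
  }
  if (is.null(topology)) topology <- frames[[1L]]$topology
  motion_sequence(topology,
                  vapply(frames, function(f) f$timestamp, numeric(1L)),
                  lapply(frames, function(f) f$positions),
                  nominal_rate = nominal_rate)
}

#' Number of frames in a motion sequence
#' @param seq A `motion_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) length(seq$times)

#' Extract one frame of a motion sequence
#' @param seq A `motion_sequence`.
#' @param i Frame index.
#' @return A `skeleton_frame`.
#' @export
get_frame <- function(seq, i) {
  p <- seq$positions[i, , , drop = TRUE]
  skeleton_frame(seq$times[i], p, seq$topology)
}

#' Take the first `n` frames of a sequence
#' @param seq A `motion_sequence`.
#' @param n Number of frames to keep.
#' @return A `motion_sequence`.
#' @export
head_frames <- function(seq, n) {
  n <- min(n, n_frames(seq))
  motion_sequence(seq$topology, seq$times[seq_len(n)],
                  seq$positions[seq_len(n), , , drop = FALSE],
                  nominal_rate = seq$nominal_rate)
}

#' @export
print.motion_sequence <- function(x, ...) {
  cat("<motion_sequence>", n_frames(x), "frames,",
      length(x$topology$joint_names), "joints (", x$topology$name, ")")
  if (n_frames(x) > 0L)
    cat(sprintf(", t = [%.3f, %.3f] s", x$times[1L],
                x$times[n_frames(x)]))
  cat("\n")
  invisible(x)
}

# ---- frame-stream text format -------------------------------------------
# UTF-8; '#' comment lines; header `time,<joint>.x,<joint>.y,<joint>.z,...`
# in topology order; one frame per row, row order = time order; '.' decimal
# point; coordinates written with %.17g so doubles round-trip exactly.

#' Read a motion-capture frame stream
#'
#' Reads the plain-text tabular frame-stream format: comment lines start
#' with `#`, the header names columns `time,<joint>.x,<joint>.y,<joint>.z,...`
#' and each subsequent row is one frame.  The set of joints in the header
#' must match the declared topology exactly.
#'
#' @param path File path.
#' @param topology Topology the stream must conform to (`joint_topology` or
#'   preset name).
#' @return A `motion_sequence`.
#' @export
read_stream <- function(path, topology) {
  topology <- get_topology(topology)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("parse error: no header row in ", path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  header <- trimws(header)
  jn <- topology$joint_names
  expected <- c("time", as.vector(t(outer(jn, c("x", "y", "z"),
                                          function(a, b) paste0(a, ".", b)))))
  if (header[1L] != "time")
    stop("parse error: first header column must be 'time' (line ",
         line_no[1L], ")")
  hdr_joints <- unique(sub("\\.[xyz]$", "", header[-1L]))
  if (!setequal(hdr_joints, jn) || length(header) != length(expected))
    stop("topology error: stream header has ", length(hdr_joints),
         " joints, topology ", topology$name, " expects ", length(jn))
  body <- lines[-1L]
  body_line_no <- line_no[-1L]
  n <- length(body)
  if (n == 0L)
    return(motion_sequence(topology, numeric(), list()))
  fields <- strsplit(body, ",", fixed = TRUE)
  counts <- lengths(fields)
  if (any(counts != length(expected))) {
    bad <- which(counts != length(expected))[1L]
    stop("parse error at record ", bad, " (line ", body_line_no[bad],
         "): expected ", length(expected), " fields, found ", counts[bad])
  }
  vals <- suppressWarnings(as.numeric(unlist(fields, use.names = FALSE)))
  if (anyNA(vals)) {
    bad <- (which(is.na(vals))[1L] - 1L) %/% length(expected) + 1L
    stop("parse error at record ", bad, " (line ", body_line_no[bad],
         "): non-numeric field")
  }
  m <- matrix(vals, nrow = n, byrow = TRUE)
  colnames(m) <- header
  # reorder columns to topology order
  m <- m[, expected, drop = FALSE]
  arr <- array(m[, -1L], dim = c(n, 3L, length(jn)))
  arr <- aperm(arr, c(1L, 3L, 2L))
  motion_sequence(topology, m[, 1L], arr)
}

#' Write a motion-capture frame stream
#'
#' Emits the plain-text frame-stream format at full double precision so that
#' `read_stream(write_stream(s))` reproduces `s` exactly and a second write
#' is byte-identical to the first.
#'
#' @param seq A `motion_sequence`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stream <- function(seq, path) {
  stopifnot(inherits(seq, "motion_sequence"))
  jn <- seq$topology$joint_names
  header <- paste(c("time", as.vector(t(outer(jn, c("x", "y", "z"),
                                              function(a, b) paste0(a, ".", b))))),
                  collapse = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste0("# gdlmotion frame stream, topology: ",
                      seq$topology$name),
               header), con, sep = "\n")
  n <- n_frames(seq)
  if (n > 0L) {
    flat <- aperm(seq$positions, c(3L, 2L, 1L))  # xyz fastest, then joint
    m <- rbind(seq$times, matrix(flat, nrow = 3L * length(jn)))
    rows <- apply(m, 2L, function(r) paste(sprintf("%.17g", r),
                                           collapse = ","))
    writeLines(rows, con, sep = "\n")
  }
  invisible(path)
}
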