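#' Declarative kinematic feature definition
#'
#' A feature is a named, typed expression evaluated on every frame of a
#' stream.  Three kinds exist: `numeric` (e.g. a joint angle in degrees),
#' `vector` (a 3D vector such as a limb direction), and `logical` (a truth
#' value; logical features that evaluate to `TRUE` on a frame are exposed as
#' that frame's "conclusions").  Features may reference features defined
#' earlier in the set; forward references are rejected.
#'
#' @param name Feature identifier.
#' @param kind One of `"logical"`, `"numeric"`, `"vector"`.
#' @param expr Expression text (see [parse_expr()]) or a parsed `gdl_expr`.
#' @return An object of class `feature_def`.
#' @export
#' @examples
#' feature_def("KneeAngle", "numeric",
#'   "angle(sub(joint(HipRight), joint(KneeRight)),
#'          sub(joint(AnkleRight), joint(KneeRight)))")
feature_def <- function(name, kind = c("numeric", "logical", "vector"), expr) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.character(expr)) expr <- parse_expr(expr)
  stopifnot(inherits(expr, "gdl_expr"))
  structure(list(name = name, kind = kind, expr = expr),
            class = "feature_def")
}

#' Validated, ordered feature set
#'
#' Binds an ordered list of [feature_def()]s to a topology and validates
#' every expression statically: joint references must exist in the topology,
#' feature references must point to earlier definitions, and each
#' expression's result type must match its declared kind.
#'
#' @param defs List of `feature_def` objects (evaluation order).
#' @param topology A `joint_topology` or preset name.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(defs, topology) {
  topology <- get_topology(topology)
  if (inherits(defs, "feature_def")) defs <- list(defs)
  stopifnot(all(vapply(defs, inherits, logical(1L), "feature_def")))
  nms <- vapply(defs, `[[`, character(1L), "name")
  if (anyDuplicated(nms)) stop("validation error: duplicate feature names")
  kinds <- character()
  for (d in defs) {
    t <- .infer_type(unclass(d$expr), stats::setNames(kinds, names(kinds)),
                     topology$joint_names)
    if (t != d$kind)
      stop("validation error: feature '", d$name, "' is declared ", d$kind,
           " but its expression evaluates to ", t)
    kinds[[d$name]] <- d$kind
  }
  structure(list(topology = topology,
                 defs = stats::setNames(defs, nms),
                 kinds = kinds),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set>", length(x$defs), "features on topology",
      x$topology$name, "\n")
  for (d in x$defs)
    cat(sprintf("  %-12s %-8s %s\n", d$name, d$kind, format(d$expr)))
  invisible(x)
}

# Core vectorised evaluation over an n-frame position array.
# Returns list(values = env-free named list of columns, n_degenerate).
.eval_feature_columns <- function(positions, n, features, history = NULL,
                                  on_degenerate = "error") {
  values <- new.env(parent = emptyenv())
  prev <- new.env(parent = emptyenv())
  ctx <- list(n = n, joints = positions, values = values, prev = prev,
              on_degenerate = on_degenerate)
  out <- vector("list", length(features$defs))
  names(out) <- names(features$defs)
  for (d in features$defs) {
    # previous-frame column: lag by one; first frame falls back to the
    # history value if supplied, else to the frame's own value
    col <- .eval_expr(unclass(d$expr), ctx)
    if (d$kind == "vector") {
      if (!is.matrix(col)) col <- matrix(rep_len(col, n * 3L), nrow = n)
      if (nrow(col) != n) col <- matrix(rep(col, each = n), nrow = n)
    } else {
      col <- rep_len(col, n)
    }
    assign(d$name, col, envir = values)
    lagged <- .lag_column(col, d$kind, history, d$name)
    assign(d$name, lagged, envir = prev)
    out[[d$name]] <- col
  }
  out
}

.lag_column <- function(col, kind, history, name) {
  if (kind == "vector") {
    n <- nrow(col)
    first <- if (!is.null(history) && !is.null(history$values[[name]]))
      history$values[[name]] else col[1L, ]
    rbind(matrix(first, nrow = 1L), col[-n, , drop = FALSE],
          deparse.level = 0L)
  } else {
    n <- length(col)
    first <- if (!is.null(history) && !is.null(history$values[[name]]))
      history$values[[name]] else col[1L]
    c(first, col[-n])
  }
}

#' Evaluate a feature set on a single frame
#'
#' Computes every feature in definition order on one frame.  Logical
#' features evaluating to `TRUE` are additionally listed as the frame's
#' `conclusions`.  A reference to a missing joint or feature fails
#' validation before any evaluation; a zero-length vector inside `angle()`
#' raises a degenerate-vector error tagged with the frame timestamp.
#'
#' @param frame A `skeleton_frame`.
#' @param features A `feature_set` (or list of `feature_def`s plus the
#'   frame's topology).
#' @param history Optional `feature_vector` of the previous frame, consumed
#'   by `prev()` expressions.
#' @return A `feature_vector`: list with `timestamp`, `values` (named list),
#'   and `conclusions` (character vector of true logical features).
#' @export
evaluate_features <- function(frame, features, history = NULL) {
  stopifnot(inherits(frame, "skeleton_frame"))
  if (!inherits(features, "feature_set"))
    features <- feature_set(features, frame$topology)
  pos <- array(frame$positions, dim = c(1L, nrow(frame$positions), 3L),
               dimnames = list(NULL, rownames(frame$positions), NULL))
  cols <- tryCatch(
    .eval_feature_columns(pos, 1L, features, history,
                          on_degenerate = "error"),
    error = function(e) {
      if (grepl("degenerate", conditionMessage(e)))
        stop(conditionMessage(e), " [frame t=", frame$timestamp, "]",
             call. = FALSE)
      stop(e)
    })
  values <- lapply(seq_along(cols), function(i) {
    if (features$kinds[[i]] == "vector") as.numeric(cols[[i]][1L, ])
    else cols[[i]][1L]
  })
  names(values) <- names(cols)
  concl <- names(values)[vapply(names(values), function(nm)
    features$kinds[[nm]] == "logical" && isTRUE(values[[nm]]),
    logical(1L))]
  structure(list(timestamp = frame$timestamp, values = values,
                 conclusions = concl),
            class = "feature_vector")
}

#' Evaluate a feature set over a whole motion sequence
#'
#' Vectorised equivalent of calling [evaluate_features()] frame by frame
#' (with the history argument chained); results are identical.  Degenerate
#' frames (zero-length vector inside `angle()`) yield `NA` values and a
#' warning instead of aborting the stream.
#'
#' @param seq A `motion_sequence`.
#' @param features A `feature_set`.
#' @param history Optional `feature_vector` preceding the first frame.
#' @param on_degenerate `"na"` (stream default) or `"error"`.
#' @return A `feature_table`: list with `times` and `columns` (named list of
#'   per-frame value columns; vector features are `n x 3` matrices).
#' @export
evaluate_features_stream <- function(seq, features, history = NULL,
                                     on_degenerate = "na") {
  stopifnot(inherits(seq, "motion_sequence"))
  if (!inherits(features, "feature_set"))
    features <- feature_set(features, seq$topology)
  n <- n_frames(seq)
  if (n == 0L)
    return(structure(list(times = numeric(),
                          columns = stats::setNames(
                            rep(list(numeric()), length(features$defs)),
                            names(features$defs)),
                          kinds = features$kinds),
                     class = "feature_table"))
  cols <- .eval_feature_columns(seq$positions, n, features, history,
                                on_degenerate = on_degenerate)
  n_bad <- sum(!stats::complete.cases(
    do.call(cbind, lapply(cols, function(c) if (is.matrix(c)) c else cbind(c)))))
  if (n_bad > 0L)
    warning(n_bad, " frame(s) had degenerate feature values (set to NA)")
  structure(list(times = seq$times, columns = cols, kinds = features$kinds),
            class = "feature_table")
}

#' Flatten a feature table to a data frame
#'
#' Vector features expand to `<name>.x/.y/.z` columns.
#'
#' @param x A `feature_table`.
#' @param row.names,optional,... Passed over for S3 compatibility (unused).
#' @return A `data.frame` with a `time` column plus one column per scalar
#'   feature component.
#' @export
as.data.frame.feature_table <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  out <- list(time = x$times)
  for (nm in names(x$columns)) {
    col <- x$columns[[nm]]
    if (is.matrix(col)) {
      out[[paste0(nm, ".x")]] <- col[, 1L]
      out[[paste0(nm, ".y")]] <- col[, 2L]
      out[[paste0(nm, ".z")]] <- col[, 3L]
    } else out[[nm]] <- col
  }
  as.data.frame(out, optional = TRUE)
}

#' Extract a single-frame feature vector from a feature table
#' @param tab A `feature_table`.
#' @param i Frame index.
#' @return A `feature_vector`.
#' @export
feature_vector_at <- function(tab, i) {
  values <- lapply(names(tab$columns), function(nm) {
    col <- tab$columns[[nm]]
    if (is.matrix(col)) as.numeric(col[i, ]) else col[i]
  })
  names(values) <- names(tab$columns)
  concl <- names(values)[vapply(names(values), function(nm)
    tab$kinds[[nm]] == "logical" && isTRUE(values[[nm]]), logical(1L))]
  structure(list(timestamp = tab$times[i], values = values,
                 conclusions = concl),
            class = "feature_vector")
}

# ---- built-in angle feature set -----------------------------------------

#' Six-angle feature set for knee-kick analysis
#'
#' The classic six angle-based features used to describe the Hiza-Geri
#' (knee kick) technique on the 25-joint K2 topology.  Five direction
#' vectors are built from tracked joints — v1 right thigh
#' (HipRight to KneeRight), v2 torso axis (SpineBase to SpineShoulder),
#' v3 right shin (KneeRight to AnkleRight), v4 left thigh (HipLeft to
#' KneeLeft), v5 the global vertical (0, 1, 0) — and the features are the
#' unsigned angles, in degrees:
#' A1 = angle(v1, v2), A2 = angle(v3, v2), A3 = angle(v4, v2),
#' A4 = angle(v1, v5), A5 = angle(v3, v5), A6 = angle(v4, v5).
#' All six are invariant under rigid transformation of the whole skeleton
#' (A4-A6 under rotations about the vertical plus any translation; A1-A3
#' under all rigid transforms).
#'
#' @return A `feature_set` of exactly six numeric features on topology K2.
#' @export
builtin_hiza_geri_features <- function() {
  v1 <- "sub(joint(KneeRight), joint(HipRight))"
  v2 <- "sub(joint(SpineShoulder), joint(SpineBase))"
  v3 <- "sub(joint(AnkleRight), joint(KneeRight))"
  v4 <- "sub(joint(KneeLeft), joint(HipLeft))"
  v5 <- "vec(0, 1, 0)"
  pair <- function(nm, a, b)
    feature_def(nm, "numeric", sprintf("angle(%s, %s)", a, b))
  feature_set(list(
    pair("A1", v1, v2), pair("A2", v3, v2), pair("A3", v4, v2),
    pair("A4", v1, v5), pair("A5", v3, v5), pair("A6", v4, v5)),
    topology_k2())
}

# ---- feature definition files (YAML) ------------------------------------

.topology_to_list <- function(topology) {
  if (topology$name %in% c("K1", "K2")) return(topology$name)
  list(name = topology$name,
       joints = lapply(topology$joint_names, function(j) {
         p <- if (j == topology$root) NULL else unname(topology$parent_of[[j]])
         c(list(name = j), if (!is.null(p)) list(parent = p))
       }))
}

.topology_from_list <- function(x) {
  if (is.character(x)) return(get_topology(x))
  jn <- vapply(x$joints, `[[`, character(1L), "name")
  parents <- vapply(x$joints, function(j)
    if (is.null(j$parent)) NA_character_ else j$parent, character(1L))
  joint_topology(x$name, jn,
                 stats::setNames(parents, jn)[!is.na(parents)])
}

#' Read / write feature-definition documents
#'
#' Feature definitions are stored as YAML: a `topology` entry (preset name
#' or inline joint list) and a `features` list of `{name, kind, expr}`
#' records, in evaluation order.
#'
#' @param path File path.
#' @return `read_feature_defs()` returns a validated `feature_set`.
#' @export
read_feature_defs <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$features)) stop("feature file has no 'features' list: ", path)
  topo <- .topology_from_list(doc$topology)
  defs <- lapply(doc$features, function(f)
    feature_def(f$name, f$kind, f$expr))
  feature_set(defs, topo)
}

#' @rdname read_feature_defs
#' @param features A `feature_set`.
#' @export
write_feature_defs <- function(features, path) {
  doc <- list(
    topology = .topology_to_list(features$topology),
    features = lapply(unname(features$defs), function(d)
      list(name = d$name, kind = d$kind, expr = format(d$expr))))
  .write_yaml_canonical(doc, path)
  invisible(path)
}

# deterministic YAML writer used for all config documents, so a
# write -> read -> write cycle is byte-identical
.write_yaml_canonical <- function(doc, path) {
  txt <- yaml::as.yaml(doc, precision = 15L, indent.mapping.sequence = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(txt, con, sep = "")
  invisible(path)
}
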