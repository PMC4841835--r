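#' Key-frame rule
#'
#' A key frame is a characteristic pose of an action, defined by a boolean
#' constraint over the current frame's feature values (conjunctions /
#' disjunctions of comparisons in the expression notation).
#'
#' @param name Rule identifier.
#' @param expr Logical expression text or parsed `gdl_expr`, e.g.
#'   `"A1 < 30 and A2 > 150"`.
#' @return An object of class `keyframe_rule`.
#' @export
keyframe_rule <- function(name, expr) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (is.character(expr)) expr <- parse_expr(expr)
  structure(list(name = name, expr = expr), class = "keyframe_rule")
}

#' Action definition
#'
#' An action class is an ordered sequence of key-frame rules with two
#' mandatory time restrictions: `max_gap`, the longest allowed time between
#' consecutive key-frame satisfactions, and `max_span`, the longest allowed
#' time from the first to the last key frame of one performance.  Either can
#' be set large to effectively disable it.
#'
#' @param class_name Action class identifier.
#' @param sequence Character vector of key-frame rule names, in temporal
#'   order (length >= 1).
#' @param max_gap Seconds; must be > 0.
#' @param max_span Seconds; must be >= `max_gap`.
#' @return An object of class `action_definition`.
#' @export
action_definition <- function(class_name, sequence, max_gap = 0.5,
                              max_span = 3) {
  stopifnot(is.character(class_name), length(class_name) == 1L)
  sequence <- as.character(sequence)
  if (length(sequence) < 1L) stop("action needs at least one key frame")
  if (!is.numeric(max_gap) || max_gap <= 0) stop("max_gap must be > 0")
  if (!is.numeric(max_span) || max_span < max_gap)
    stop("max_span must be >= max_gap")
  structure(list(class_name = class_name, sequence = sequence,
                 max_gap = max_gap, max_span = max_span),
            class = "action_definition")
}

#' Action document: rules plus actions
#'
#' Bundles named key-frame rules with the action definitions that reference
#' them; validates that every sequence entry resolves to a rule.
#'
#' @param rules List of [keyframe_rule()]s.
#' @param actions List of [action_definition()]s.
#' @return An object of class `gdl_actions`.
#' @export
gdl_actions <- function(rules, actions) {
  if (inherits(rules, "keyframe_rule")) rules <- list(rules)
  if (inherits(actions, "action_definition")) actions <- list(actions)
  stopifnot(all(vapply(rules, inherits, logical(1L), "keyframe_rule")),
            all(vapply(actions, inherits, logical(1L), "action_definition")))
  rn <- vapply(rules, `[[`, character(1L), "name")
  if (anyDuplicated(rn)) stop("duplicate key-frame rule names")
  for (a in actions) {
    missing <- setdiff(a$sequence, rn)
    if (length(missing) > 0L)
      stop("action '", a$class_name, "' references undefined key frames: ",
           paste(missing, collapse = ", "))
  }
  cn <- vapply(actions, `[[`, character(1L), "class_name")
  if (anyDuplicated(cn)) stop("duplicate action class names")
  structure(list(rules = stats::setNames(rules, rn),
                 actions = stats::setNames(actions, cn)),
            class = "gdl_actions")
}

# validate rule expressions against a feature set (logical type, known refs)
.validate_rules <- function(actions_doc, features) {
  for (r in actions_doc$rules) {
    t <- .infer_type(unclass(r$expr), features$kinds,
                     features$topology$joint_names)
    if (t != "logical")
      stop("validation error: rule '", r$name,
           "' must be a logical expression, got ", t)
  }
  invisible(TRUE)
}

#' Evaluate key-frame rules on one feature vector
#'
#' Each rule is evaluated independently; a frame may satisfy several key
#' frames at once.
#'
#' @param fv A `feature_vector` (from [evaluate_features()]).
#' @param rules List of `keyframe_rule`s (or a `gdl_actions` document).
#' @return Character vector of satisfied rule names.
#' @export
evaluate_keyframes <- function(fv, rules) {
  if (inherits(rules, "gdl_actions")) rules <- rules$rules
  if (inherits(rules, "keyframe_rule")) rules <- list(rules)
  values <- new.env(parent = emptyenv())
  for (nm in names(fv$values)) assign(nm, fv$values[[nm]], envir = values)
  ctx <- list(n = 1L, joints = NULL, values = values,
              prev = values, on_degenerate = "na")
  sat <- vapply(rules, function(r) {
    v <- tryCatch(.eval_expr(unclass(r$expr), ctx), error = function(e) {
      if (grepl("not found|undefined", conditionMessage(e)))
        stop("validation error: rule '", r$name,
             "' references an unresolved feature", call. = FALSE)
      stop(e)
    })
    isTRUE(v[1L])
  }, logical(1L))
  vapply(rules, `[[`, character(1L), "name")[sat]
}

# ---- memory stack --------------------------------------------------------

#' Bounded time-ordered memory stack
#'
#' The memory stack holds the recent history the sequence matcher queries:
#' per entry a timestamp, the frame's feature vector, the set of satisfied
#' key-frame names, and any emitted class names.  Capacity is expressed in
#' seconds of retained history; entries older than `newest - capacity` are
#' evicted from the oldest end.
#'
#' @param capacity Seconds of history to retain (> 0).
#' @return An object of class `memory_stack`.
#' @export
memory_stack <- function(capacity) {
  stopifnot(is.numeric(capacity), length(capacity) == 1L, capacity > 0)
  structure(list(capacity = capacity, times = numeric(),
                 fvs = list(), satisfied = list(), classes = list()),
            class = "memory_stack")
}

#' Push a frame onto the memory stack
#'
#' Appends an entry and evicts entries older than the capacity window.
#' Timestamps must be non-decreasing across pushes.
#'
#' @param stack A `memory_stack`.
#' @param timestamp Frame time in seconds.
#' @param fv The frame's `feature_vector` (may be `NULL` when only
#'   satisfaction sets are needed).
#' @param satisfied Character vector of satisfied key-frame rule names.
#' @return The updated `memory_stack`.
#' @export
push_frame <- function(stack, timestamp, fv = NULL, satisfied = character()) {
  stopifnot(inherits(stack, "memory_stack"))
  n <- length(stack$times)
  if (n > 0L && timestamp < stack$times[n])
    stop("ordering error: timestamp ", timestamp,
         " regresses behind newest entry ", stack$times[n])
  stack$times <- c(stack$times, timestamp)
  stack$fvs <- c(stack$fvs, list(fv))
  stack$satisfied <- c(stack$satisfied, list(as.character(satisfied)))
  stack$classes <- c(stack$classes, list(character()))
  keep <- timestamp - stack$times <= stack$capacity
  if (!all(keep)) {
    stack$times <- stack$times[keep]
    stack$fvs <- stack$fvs[keep]
    stack$satisfied <- stack$satisfied[keep]
    stack$classes <- stack$classes[keep]
  }
  stack
}

# ---- sequence matching ---------------------------------------------------

# Backtracking search for entries e_1 <= e_2 <= ... <= e_k (e_k = newest)
# with e_i satisfying key frame i, consecutive gaps <= max_gap and total
# span <= max_span.  Candidates are explored newest-first, so the first
# complete witness found carries the latest-possible earlier key-frame
# times (lexicographically latest in t_{k-1}, t_{k-2}, ..., t_1).
.match_indices <- function(times, sat_idx, max_gap, max_span, strict) {
  k <- length(sat_idx)
  n <- length(times)
  last <- n
  if (!(last %in% sat_idx[[k]])) return(NULL)
  t_last <- times[last]
  chosen <- integer(k)
  chosen[k] <- last
  dfs <- function(level, upper) {
    if (level == 0L) return(TRUE)
    cands <- sat_idx[[level]]
    cands <- cands[cands <= upper & (!strict | cands < upper)]
    if (length(cands) == 0L) return(FALSE)
    t_next <- times[chosen[level + 1L]]
    for (i in sort(cands, decreasing = TRUE)) {
      if (t_next - times[i] > max_gap) break        # older ones only worse
      if (t_last - times[i] > max_span) break
      chosen[level] <<- i
      if (level > 1L) {
        if (dfs(level - 1L, i)) return(TRUE)
      } else {
        return(TRUE)
      }
    }
    FALSE
  }
  if (k == 1L) return(chosen)
  if (dfs(k - 1L, last)) chosen else NULL
}

#' Match an action's key-frame sequence against the memory stack
#'
#' Returns a classification event iff the newest stack entry satisfies the
#' action's final key frame and there exist stack entries, in order, that
#' satisfy every key frame of the sequence with consecutive gaps at most
#' `max_gap` and total span at most `max_span`.  Among multiple witnesses
#' the latest-possible earlier key-frame times are reported.  By default a
#' single frame may satisfy two consecutive key frames (non-decreasing
#' key-frame times); set `strict = TRUE` to require strictly increasing
#' entries.
#'
#' @param stack A `memory_stack` with at least one entry.
#' @param action An `action_definition`.
#' @param strict Require strictly increasing entry indices.
#' @return A `classification_event` (list with `class_name`, `trigger_time`,
#'   `keyframe_times`) or `NULL` if no match.
#' @export
match_sequence <- function(stack, action, strict = FALSE) {
  stopifnot(inherits(stack, "memory_stack"),
            inherits(action, "action_definition"))
  n <- length(stack$times)
  if (n == 0L) stop("match_sequence needs a non-empty stack")
  sat_idx <- lapply(action$sequence, function(kf)
    which(vapply(stack$satisfied, function(s) kf %in% s, logical(1L))))
  idx <- .match_indices(stack$times, sat_idx, action$max_gap,
                        action$max_span, strict)
  if (is.null(idx)) return(NULL)
  structure(list(class_name = action$class_name,
                 trigger_time = stack$times[length(stack$times)],
                 keyframe_times = stack$times[idx]),
            class = "classification_event")
}

# ---- engine --------------------------------------------------------------

#' Create a GDL classification engine
#'
#' The engine wires features, rules and actions into a causal, online
#' classifier: each incoming frame is evaluated, the satisfied key frames
#' are pushed onto the memory stack, and every action's sequence is matched
#' against the stack.  After an event fires, a refractory period equal to
#' the action's `max_gap` suppresses immediate duplicate triggers from
#' consecutive frames satisfying the final key frame.
#'
#' @param features A `feature_set`.
#' @param actions A `gdl_actions` document.
#' @param capacity Memory-stack capacity in seconds; defaults to the largest
#'   action `max_span` plus one second, which guarantees no witness is
#'   evicted prematurely.
#' @param strict Passed to [match_sequence()].
#' @return An engine state object (class `gdl_engine`); feed it frames with
#'   [engine_step()] or classify whole sequences with [classify_stream()].
#' @export
gdl_engine <- function(features, actions, capacity = NULL, strict = FALSE) {
  stopifnot(inherits(features, "feature_set"),
            inherits(actions, "gdl_actions"))
  .validate_rules(actions, features)
  if (is.null(capacity))
    capacity <- max(vapply(actions$actions, `[[`, numeric(1L),
                           "max_span")) + 1
  acc <- new.env(parent = emptyenv())   # reference accumulators: appending
  acc$events <- list()                  # must not copy the whole history
  acc$timeline_time <- numeric()        # on every frame
  acc$timeline_labels <- list()
  structure(list(features = features, actions = actions,
                 stack = memory_stack(capacity),
                 strict = strict,
                 last_fv = NULL,
                 last_trigger = stats::setNames(
                   rep(-Inf, length(actions$actions)),
                   names(actions$actions)),
                 acc = acc),
            class = "gdl_engine")
}

# shared per-frame core: push + match + timeline label; `satisfied` is the
# character vector of satisfied rule names for this frame.  Pure: returns
# the updated state plus this frame's labels and events; accumulation is
# the caller's concern (classify_stream preallocates, engine_step appends).
.engine_advance <- function(state, timestamp, fv, satisfied) {
  state$stack <- push_frame(state$stack, timestamp, fv, satisfied)
  action_names <- names(state$actions$actions)
  labels <- character(length(action_names))
  names(labels) <- action_names
  new_events <- list()
  for (cn in action_names) {
    a <- state$actions$actions[[cn]]
    # timeline: highest-index satisfied key frame of this action, else "N"
    hit <- which(a$sequence %in% satisfied)
    labels[[cn]] <- if (length(hit) > 0L) a$sequence[max(hit)] else "N"
    last_kf <- a$sequence[length(a$sequence)]
    if (last_kf %in% satisfied) {
      ev <- match_sequence(state$stack, a, strict = state$strict)
      if (!is.null(ev) &&
          timestamp - state$last_trigger[[cn]] > a$max_gap) {
        state$last_trigger[[cn]] <- timestamp
        n <- length(state$stack$times)
        state$stack$classes[[n]] <- c(state$stack$classes[[n]], cn)
        new_events[[length(new_events) + 1L]] <- ev
      }
    }
  }
  state$new_events <- new_events
  state$new_labels <- labels
  state
}

#' Feed one frame to the engine
#'
#' Online counterpart of [classify_stream()]: evaluates features (chaining
#' the previous frame's values as history), evaluates key-frame rules,
#' pushes the frame and matches every action.  Events emitted for this
#' frame are in `$new_events` of the returned state.
#'
#' @param state A `gdl_engine`.
#' @param frame A `skeleton_frame`.
#' @return The updated engine state.
#' @export
engine_step <- function(state, frame) {
  stopifnot(inherits(state, "gdl_engine"))
  fv <- tryCatch(
    evaluate_features(frame, state$features, history = state$last_fv),
    error = function(e) {
      if (grepl("degenerate", conditionMessage(e))) {
        warning(conditionMessage(e), call. = FALSE)
        NULL
      } else stop(e)
    })
  if (is.null(fv)) {                   # degenerate frame: label "N", no rules
    satisfied <- character()
  } else {
    satisfied <- .satisfied_names(fv, state$actions)
    state$last_fv <- fv
  }
  state <- .engine_advance(state, frame$timestamp, fv, satisfied)
  acc <- state$acc
  i <- length(acc$timeline_time) + 1L
  acc$timeline_time[[i]] <- frame$timestamp
  acc$timeline_labels[[i]] <- state$new_labels
  for (ev in state$new_events)
    acc$events[[length(acc$events) + 1L]] <- ev
  state
}

.satisfied_names <- function(fv, actions_doc) {
  evaluate_keyframes(fv, actions_doc$rules)
}

#' Classify a whole motion sequence
#'
#' Processes frames strictly in time order through feature evaluation,
#' key-frame rule evaluation, the memory stack and sequence matching for
#' every action.  Identical to feeding the frames one by one through
#' [engine_step()] (the engine is causal: nothing depends on future
#' frames), but feature and rule evaluation are vectorised over the stream.
#'
#' @param seq A `motion_sequence`.
#' @param features A `feature_set`.
#' @param actions A `gdl_actions` document.
#' @param capacity,strict See [gdl_engine()].
#' @return A list of class `gdl_classification`:
#'   \describe{
#'     \item{timeline}{data frame, one row per frame: `time` plus one label
#'       column per action class (satisfied key-frame name or `"N"`).}
#'     \item{events}{data frame of classification events: `class`,
#'       `trigger_time`, `keyframe_times` (semicolon-joined) plus a
#'       list-column `kf_times`.}
#'   }
#' @export
classify_stream <- function(seq, features, actions, capacity = NULL,
                            strict = FALSE) {
  state <- gdl_engine(features, actions, capacity = capacity,
                      strict = strict)
  n <- n_frames(seq)
  action_names <- names(state$actions$actions)
  label_mat <- matrix("N", nrow = n, ncol = length(action_names),
                      dimnames = list(NULL, action_names))
  events <- vector("list", 64L)
  n_events <- 0L
  if (n > 0L) {
    tab <- evaluate_features_stream(seq, features, on_degenerate = "na")
    sat_mat <- .rule_matrix(tab, state$actions)
    rule_names <- names(state$actions$rules)
    for (i in seq_len(n)) {
      satisfied <- rule_names[sat_mat[i, ]]
      fv <- feature_vector_at(tab, i)
      state$last_fv <- fv
      state <- .engine_advance(state, seq$times[i], fv, satisfied)
      label_mat[i, ] <- state$new_labels
      for (ev in state$new_events) {
        n_events <- n_events + 1L
        if (n_events > length(events))
          length(events) <- 2L * length(events)
        events[[n_events]] <- ev
      }
    }
  }
  timeline <- as.data.frame(
    c(list(time = seq$times),
      stats::setNames(lapply(seq_len(ncol(label_mat)), function(j)
        label_mat[, j]), action_names)),
    optional = TRUE)
  structure(list(timeline = timeline,
                 events = .events_to_df(events[seq_len(n_events)]),
                 engine = state),
            class = "gdl_classification")
}

# n x n_rules logical matrix of rule satisfaction; NA (degenerate) => FALSE
.rule_matrix <- function(tab, actions_doc) {
  n <- length(tab$times)
  values <- new.env(parent = emptyenv())
  for (nm in names(tab$columns)) assign(nm, tab$columns[[nm]], envir = values)
  ctx <- list(n = n, joints = NULL, values = values, prev = values,
              on_degenerate = "na")
  cols <- lapply(actions_doc$rules, function(r) {
    v <- rep_len(.eval_expr(unclass(r$expr), ctx), n)
    v[is.na(v)] <- FALSE
    v
  })
  m <- do.call(cbind, cols)
  colnames(m) <- names(actions_doc$rules)
  m
}

.finish_classification <- function(state) {
  acc <- state$acc
  action_names <- names(state$actions$actions)
  label_cols <- lapply(seq_along(action_names), function(j)
    vapply(acc$timeline_labels, `[[`, character(1L), j))
  names(label_cols) <- action_names
  if (length(acc$timeline_time) == 0L)
    label_cols <- stats::setNames(rep(list(character()),
                                      length(action_names)), action_names)
  timeline <- as.data.frame(c(list(time = acc$timeline_time), label_cols),
                            optional = TRUE)
  events <- .events_to_df(acc$events)
  structure(list(timeline = timeline, events = events, engine = state),
            class = "gdl_classification")
}

.events_to_df <- function(events) {
  if (length(events) == 0L)
    return(data.frame(class = character(), trigger_time = numeric(),
                      keyframe_times = character(),
                      stringsAsFactors = FALSE))
  df <- data.frame(
    class = vapply(events, `[[`, character(1L), "class_name"),
    trigger_time = vapply(events, `[[`, numeric(1L), "trigger_time"),
    keyframe_times = vapply(events, function(e)
      paste(sprintf("%.17g", e$keyframe_times), collapse = ";"),
      character(1L)),
    stringsAsFactors = FALSE)
  df$kf_times <- lapply(events, `[[`, "keyframe_times")
  df
}

#' Finalise an engine run into timeline/event tables
#'
#' Use after a sequence of [engine_step()] calls to obtain the same result
#' structure [classify_stream()] returns.
#'
#' @param state A `gdl_engine`.
#' @return A `gdl_classification`.
#' @export
engine_result <- function(state) .finish_classification(state)

#' @export
print.gdl_classification <- function(x, ...) {
  cat("<gdl_classification>", nrow(x$timeline), "frames,",
      nrow(x$events), "event(s)\n")
  if (nrow(x$events) > 0L)
    print(x$events[, c("class", "trigger_time", "keyframe_times")])
  invisible(x)
}

# ---- action definition files (YAML) -------------------------------------

#' Read / write action-definition documents
#'
#' YAML layout: a `rules` list of `{name, expr}` and an `actions` list of
#' `{class, sequence, max_gap, max_span}`.
#'
#' @param path File path.
#' @return `read_action_defs()` returns a `gdl_actions`.
#' @export
read_action_defs <- function(path) {
  doc <- yaml::read_yaml(path)
  rules <- lapply(doc$rules, function(r) keyframe_rule(r$name, r$expr))
  actions <- lapply(doc$actions, function(a)
    action_definition(a$class, as.character(a$sequence),
                      max_gap = a$max_gap, max_span = a$max_span))
  gdl_actions(rules, actions)
}

#' @rdname read_action_defs
#' @param actions A `gdl_actions`.
#' @export
write_action_defs <- function(actions, path) {
  doc <- list(
    rules = lapply(unname(actions$rules), function(r)
      list(name = r$name, expr = format(r$expr))),
    actions = lapply(unname(actions$actions), function(a)
      list(class = a$class_name, sequence = as.list(a$sequence),
           max_gap = a$max_gap, max_span = a$max_span)))
  .write_yaml_canonical(doc, path)
  invisible(path)
}

#' Write classification events to a tabular text file
#'
#' Columns: `class`, `trigger_time`, `keyframe_times` (semicolon-joined
#' seconds).
#'
#' @param events Events data frame from [classify_stream()].
#' @param path Output path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events[, c("class", "trigger_time", "keyframe_times")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-frame key-frame timeline to a text file
#'
#' @param timeline Timeline data frame from [classify_stream()].
#' @param path Output path.
#' @export
write_timeline <- function(timeline, path) {
  utils::write.csv(timeline, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Hand-written Hiza-Geri action definition
#'
#' Three key frames over the built-in six-angle feature set
#' ([builtin_hiza_geri_features()]): neutral stance (thigh near the torso
#' line), knee raised (right thigh roughly perpendicular to the torso, shin
#' still hanging), and the strike (thigh high, shin driven forward).
#' The kf2 constraint `A2 > 135` separates the rising phase (shin still
#' hanging near the torso line) from the recovery phase after the strike,
#' in which thigh and shin drop together and A2 stays well below 120 while
#' A1 re-crosses the kf2 window.
#' Thresholds are documented tunables, not calibrated constants.  Adjacent
#' rules leave a small hysteresis band (kf2 ends at A1 = 50, kf3 begins at
#' A1 = 40) so that measurement noise cannot make a frame satisfy both
#' sides of a boundary.  The default `max_gap = 1` s accommodates the pose
#' hold + transition tempo of [builtin_kick_script()]: the single witness
#' frame for the middle key frame must sit within `max_gap` of both its
#' neighbours' satisfying frames.  The default `max_span = 2.5` s is set a
#' little above the observed first-to-last key-frame duration of one kick
#' (about 1.2 s), so isolated noise-tail satisfactions far apart in time
#' cannot be stitched into a spurious witness.
#'
#' @param max_gap,max_span Time restrictions in seconds.
#' @return A `gdl_actions` document with one action, class `"hiza_geri"`.
#' @export
builtin_kick_action <- function(max_gap = 1, max_span = 2.5) {
  rules <- list(
    keyframe_rule("hiza_geri_kf1", "A1 > 120 and A2 > 120"),
    keyframe_rule("hiza_geri_kf2", "A1 > 50 and A1 < 110 and A2 > 135"),
    keyframe_rule("hiza_geri_kf3", "A1 < 40 and A2 < 110"))
  gdl_actions(rules, action_definition(
    "hiza_geri", c("hiza_geri_kf1", "hiza_geri_kf2", "hiza_geri_kf3"),
    max_gap = max_gap, max_span = max_span))
}
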