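# R-GDL: automatic key-frame discovery.  Exemplar recordings are moved to
# feature space, pooled frames are clustered with k-means, clusters are
# ordered by the phase at which their members occur, and interval rules are
# synthesized around each cluster centroid.

#' Build a pooled feature matrix from exemplar recordings
#'
#' Evaluates every numeric feature on every frame of every exemplar and
#' pools the rows.  Row metadata records the exemplar id, the timestamp and
#' the normalized phase `(t - t_first) / (t_last - t_first)` within the
#' exemplar (0 for a single-frame exemplar).  Logical and vector features do
#' not participate in training.  Degenerate frames (NA feature values) are
#' dropped with a warning reporting the count.
#'
#' @param exemplars List of `motion_sequence`s (or a single one).
#' @param features A `feature_set`.
#' @return An object of class `feature_matrix`: list with `values`
#'   (rows x numeric features), `meta` (data frame: exemplar, timestamp,
#'   phase) and `feature_names`.
#' @export
build_feature_matrix <- function(exemplars, features) {
  if (inherits(exemplars, "motion_sequence")) exemplars <- list(exemplars)
  stopifnot(length(exemplars) >= 1L)
  numeric_feats <- names(features$kinds)[features$kinds == "numeric"]
  if (length(numeric_feats) == 0L)
    stop("no numeric features to train on")
  vals <- list()
  meta <- list()
  for (e in seq_along(exemplars)) {
    seq_e <- exemplars[[e]]
    tab <- suppressWarnings(
      evaluate_features_stream(seq_e, features, on_degenerate = "na"))
    m <- do.call(cbind, tab$columns[numeric_feats])
    colnames(m) <- numeric_feats
    tt <- tab$times
    span <- tt[length(tt)] - tt[1L]
    phase <- if (length(tt) <= 1L || span == 0) rep(0, length(tt))
             else (tt - tt[1L]) / span
    vals[[e]] <- m
    meta[[e]] <- data.frame(exemplar = e, timestamp = tt, phase = phase)
  }
  values <- do.call(rbind, vals)
  meta <- do.call(rbind, meta)
  ok <- stats::complete.cases(values)
  if (!all(ok)) {
    warning(sum(!ok), " degenerate frame row(s) dropped from feature matrix")
    values <- values[ok, , drop = FALSE]
    meta <- meta[ok, , drop = FALSE]
  }
  structure(list(values = values, meta = meta,
                 feature_names = numeric_feats),
            class = "feature_matrix")
}

# per-column standardization; zero-spread columns get unit scale so they
# pass through unchanged
.fit_scaler <- function(x) {
  center <- colMeans(x)
  spread <- apply(x, 2L, stats::sd)
  spread[!is.finite(spread) | spread == 0] <- 1
  list(center = center, spread = spread)
}

.apply_scaler <- function(x, scaler)
  sweep(sweep(x, 2L, scaler$center), 2L, scaler$spread, "/")

.invert_scaler <- function(x, scaler)
  sweep(sweep(x, 2L, scaler$spread, "*"), 2L, scaler$center, "+")

#' Discover key frames by k-means clustering
#'
#' Standardizes the feature columns (zero mean, unit spread), runs k-means
#' with a fixed seed and multiple restarts, and derives: de-standardized
#' centroids, per-cluster per-feature tolerances (`tol_c` standard
#' deviations of member rows, floored at `tol_floor` degrees), and the
#' temporal order of clusters (sorted by mean phase of member rows).
#'
#' @param m A [build_feature_matrix()] result.
#' @param k Number of key frames (>= 1; the classic knee-kick definition
#'   uses 3).
#' @param seed Integer seed; given identical inputs and seed the model is
#'   identical.
#' @param nstart Number of k-means restarts.
#' @param tol_c Tolerance multiplier in standard deviations (default 3).
#' @param tol_floor Minimum tolerance half-width, in the feature's unit
#'   (default 5, i.e. 5 degrees for angle features).
#' @return An object of class `trained_model`: `k`, `centroids` (k x p,
#'   original scale, cluster-indexed), `tolerances` (k x p),
#'   `temporal_order` (cluster indices sorted by phase), `scaler`,
#'   `assignments`, `meta`, `feature_names`.
#' @export
cluster_keyframes <- function(m, k, seed = 1L, nstart = 10L, tol_c = 3,
                              tol_floor = 5) {
  stopifnot(inherits(m, "feature_matrix"), k >= 1L)
  n <- nrow(m$values)
  if (n < k) stop("insufficient data: ", n, " rows for k = ", k)
  scaler <- .fit_scaler(m$values)
  xs <- .apply_scaler(m$values, scaler)
  fit <- .with_seed(seed,
                    stats::kmeans(xs, centers = k, nstart = nstart,
                                  iter.max = 100L))
  # additional deterministic start stratified by phase: key frames are
  # temporal by nature, so bin means along the normalized phase are strong
  # initial centroids and guard against poor random restarts
  bins <- cut(m$meta$phase, breaks = seq(0, 1, length.out = k + 1L),
              include.lowest = TRUE)
  if (nlevels(droplevels(bins)) == k) {
    centers0 <- do.call(rbind, lapply(levels(bins), function(b)
      colMeans(xs[bins == b, , drop = FALSE])))
    if (!anyNA(centers0) && nrow(unique(centers0)) == k) {
      fit2 <- tryCatch(stats::kmeans(xs, centers = centers0,
                                     iter.max = 100L),
                       error = function(e) NULL)
      if (!is.null(fit2) && fit2$tot.withinss < fit$tot.withinss)
        fit <- fit2
    }
  }
  assignments <- fit$cluster
  centroids <- .invert_scaler(fit$centers, scaler)
  p <- ncol(m$values)
  tolerances <- matrix(NA_real_, nrow = k, ncol = p,
                       dimnames = list(NULL, m$feature_names))
  mean_phase <- numeric(k)
  for (c_i in seq_len(k)) {
    rows <- m$values[assignments == c_i, , drop = FALSE]
    sds <- if (nrow(rows) > 1L) apply(rows, 2L, stats::sd) else rep(0, p)
    sds[!is.finite(sds)] <- 0
    tolerances[c_i, ] <- pmax(tol_c * sds, tol_floor)
    mean_phase[c_i] <- mean(m$meta$phase[assignments == c_i])
  }
  structure(list(k = as.integer(k), feature_names = m$feature_names,
                 centroids = centroids, tolerances = tolerances,
                 temporal_order = order(mean_phase),
                 mean_phase = mean_phase,
                 scaler = scaler, assignments = assignments,
                 meta = m$meta, tot_withinss = fit$tot.withinss),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat("<trained_model> k =", x$k, "key frames over",
      length(x$feature_names), "features\n")
  ord <- x$temporal_order
  for (i in seq_len(x$k)) {
    c_i <- ord[i]
    cat(sprintf("  kf%d (cluster %d, phase %.2f): %s\n", i, c_i,
                x$mean_phase[c_i],
                paste(sprintf("%s=%.1f±%.1f", x$feature_names,
                              x$centroids[c_i, ], x$tolerances[c_i, ]),
                      collapse = " ")))
  }
  invisible(x)
}

#' Synthesize an executable action definition from a trained model
#'
#' Key frame `i` (in temporal order) becomes the rule
#' "for every feature f: |f - centroid_i\[f\]| <= tolerance_i\[f\]",
#' written as a conjunction of interval constraints.  Time restrictions are
#' taken from `time_params` or estimated from the exemplars' key-frame
#' timing: the 95th percentile of observed consecutive-cluster gaps and of
#' observed first-to-last spans, times a safety factor.
#'
#' @param model A `trained_model`.
#' @param class_name Action class name for the generated definition.
#' @param time_params Optional list with `max_gap` and/or `max_span`
#'   (seconds); missing entries are estimated.
#' @param safety_factor Multiplier on the timing percentiles (default 1.5).
#' @return A `gdl_actions` document whose single action has `model$k` key
#'   frames named `<class_name>_kf1 ... _kfk`.
#' @export
synthesize_rules <- function(model, class_name, time_params = NULL,
                             safety_factor = 1.5) {
  stopifnot(inherits(model, "trained_model"))
  ord <- model$temporal_order
  fmt <- function(x) sprintf("%.6g", x)
  rules <- vector("list", model$k)
  for (i in seq_len(model$k)) {
    c_i <- ord[i]
    lo <- model$centroids[c_i, ] - model$tolerances[c_i, ]
    hi <- model$centroids[c_i, ] + model$tolerances[c_i, ]
    terms <- paste0(model$feature_names, " >= ", fmt(lo), " and ",
                    model$feature_names, " <= ", fmt(hi))
    rules[[i]] <- keyframe_rule(sprintf("%s_kf%d", class_name, i),
                                paste(terms, collapse = " and "))
  }
  est <- .estimate_timing(model)
  max_gap <- time_params$max_gap
  max_span <- time_params$max_span
  if (is.null(max_gap)) max_gap <- est$max_gap * safety_factor
  if (is.null(max_span)) max_span <- est$max_span * safety_factor
  max_span <- max(max_span, max_gap)
  action <- action_definition(class_name,
                              vapply(rules, `[[`, character(1L), "name"),
                              max_gap = max_gap, max_span = max_span)
  gdl_actions(rules, action)
}

# observed timing: per exemplar, mean member timestamp per cluster in
# temporal order; gaps between consecutive clusters and first-to-last spans
.estimate_timing <- function(model) {
  ord <- model$temporal_order
  gaps <- numeric()
  spans <- numeric()
  for (e in unique(model$meta$exemplar)) {
    sel <- model$meta$exemplar == e
    tmean <- vapply(ord, function(c_i) {
      rows <- sel & model$assignments == c_i
      if (!any(rows)) return(NA_real_)
      mean(model$meta$timestamp[rows])
    }, numeric(1L))
    if (anyNA(tmean)) next
    if (length(tmean) > 1L) gaps <- c(gaps, diff(tmean))
    spans <- c(spans, tmean[length(tmean)] - tmean[1L])
  }
  if (length(gaps) == 0L) gaps <- 1
  if (length(spans) == 0L) spans <- 1
  list(max_gap = max(stats::quantile(gaps, 0.95), 1e-3),
       max_span = max(stats::quantile(spans, 0.95), 1e-3))
}

#' Train a key-frame model and synthesize its action in one call
#'
#' Convenience wrapper: [build_feature_matrix()], [cluster_keyframes()] and
#' [synthesize_rules()].
#'
#' @inheritParams build_feature_matrix
#' @inheritParams cluster_keyframes
#' @inheritParams synthesize_rules
#' @return List with `model` (`trained_model`) and `actions`
#'   (`gdl_actions`).
#' @export
train_rgdl <- function(exemplars, features, k = 3L, seed = 1L,
                       class_name = "action", time_params = NULL) {
  m <- build_feature_matrix(exemplars, features)
  model <- cluster_keyframes(m, k = k, seed = seed)
  actions <- synthesize_rules(model, class_name, time_params = time_params)
  list(model = model, actions = actions)
}

#' PCA projection of a feature matrix
#'
#' Standard principal component analysis on the standardized feature
#' columns, for inspecting the key-frame structure of pooled exemplar
#' frames (each point is one frame).  Constant columns are dropped with a
#' warning.  Component signs follow a deterministic convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param m A `feature_matrix`.
#' @param dims 2 or 3 output dimensions.
#' @return List with `scores` (rows x dims), `explained` (variance ratio of
#'   every component), `loadings`, and `dropped` (names of constant
#'   columns).
#' @export
pca_project <- function(m, dims = 3L) {
  stopifnot(inherits(m, "feature_matrix"), dims %in% c(2L, 3L))
  if (nrow(m$values) <= dims)
    stop("need more rows than output dimensions")
  spread <- apply(m$values, 2L, stats::sd)
  constant <- !is.finite(spread) | spread == 0
  dropped <- colnames(m$values)[constant]
  if (length(dropped) > 0L)
    warning("dropping constant feature column(s): ",
            paste(dropped, collapse = ", "))
  x <- m$values[, !constant, drop = FALSE]
  scaler <- .fit_scaler(x)
  xs <- .apply_scaler(x, scaler)
  fit <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  rot <- fit$rotation
  for (j in seq_len(ncol(rot))) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- xs %*% rot
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  list(scores = scores[, seq_len(min(dims, ncol(scores))), drop = FALSE],
       explained = explained, loadings = rot, dropped = dropped)
}

# ---- model serialization (YAML) -----------------------------------------

#' Read / write trained models
#'
#' Models serialize to YAML (centroids, tolerances, temporal order, scaler).
#' The generated action definition is written separately with
#' [write_action_defs()] so it is directly loadable by the classifier.
#'
#' @param path File path.
#' @return `read_model()` returns a `trained_model` (without per-row
#'   assignments/metadata, which are training artefacts).
#' @export
read_model <- function(path) {
  doc <- yaml::read_yaml(path)
  structure(list(
    k = as.integer(doc$k),
    feature_names = as.character(doc$feature_names),
    centroids = matrix(unlist(doc$centroids), nrow = doc$k, byrow = TRUE,
                       dimnames = list(NULL, doc$feature_names)),
    tolerances = matrix(unlist(doc$tolerances), nrow = doc$k, byrow = TRUE,
                        dimnames = list(NULL, doc$feature_names)),
    temporal_order = as.integer(doc$temporal_order),
    mean_phase = as.numeric(doc$mean_phase),
    scaler = list(center = stats::setNames(as.numeric(doc$scaler$center),
                                           doc$feature_names),
                  spread = stats::setNames(as.numeric(doc$scaler$spread),
                                           doc$feature_names)),
    assignments = NULL, meta = NULL, tot_withinss = doc$tot_withinss),
    class = "trained_model")
}

#' @rdname read_model
#' @param model A `trained_model`.
#' @export
write_model <- function(model, path) {
  doc <- list(
    k = model$k,
    feature_names = as.list(model$feature_names),
    centroids = lapply(seq_len(model$k), function(i)
      as.numeric(model$centroids[i, ])),
    tolerances = lapply(seq_len(model$k), function(i)
      as.numeric(model$tolerances[i, ])),
    temporal_order = as.list(model$temporal_order),
    mean_phase = as.numeric(model$mean_phase),
    scaler = list(center = as.numeric(model$scaler$center),
                  spread = as.numeric(model$scaler$spread)),
    tot_withinss = model$tot_withinss)
  .write_yaml_canonical(doc, path)
  invisible(path)
}
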