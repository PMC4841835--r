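#' 3D vector constructor
#'
#' Creates a length-3 numeric vector representing a point or displacement in
#' a right-handed Cartesian frame (x, y, z; vertical axis = +y).  Used both
#' for joint positions (metres) and for dimensionless direction vectors.
#'
#' @param x,y,z Finite numeric scalars.
#' @return Named numeric vector of length 3.
#' @export
#' @examples
#' vec3(0, 1, 0)  # global vertical
vec3 <- function(x, y, z) {
  v <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (!all(is.finite(v))) stop("vec3 components must be finite")
  v
}

#' Vector algebra on 3D vectors
#'
#' Standard Euclidean operations: sum, difference, scaling, dot product,
#' cross product and norm.  These are the primitives from which kinematic
#' features (limb direction vectors, joint angles) are built.
#'
#' @param a,b Numeric vectors of length 3.
#' @param s Numeric scalar.
#' @return `v3_add`, `v3_sub`, `v3_scale`, `v3_cross` return a length-3
#'   vector; `v3_dot` and `v3_norm` return a scalar.
#' @name vec3-ops
NULL

#' @rdname vec3-ops
#' @export
v3_add <- function(a, b) a + b

#' @rdname vec3-ops
#' @export
v3_sub <- function(a, b) a - b

#' @rdname vec3-ops
#' @export
v3_scale <- function(a, s) a * s

#' @rdname vec3-ops
#' @export
v3_dot <- function(a, b) sum(a * b)

#' @rdname vec3-ops
#' @export
v3_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' @rdname vec3-ops
#' @export
v3_norm <- function(a) sqrt(sum(a * a))

#' Unsigned angle between two vectors, in degrees
#'
#' Returns the angle on the plane designated by the two vectors,
#' `acos(dot(a, b) / (|a| |b|))` expressed in degrees and bounded in
#' \[0, 180\].  Computed internally as `atan2(|a x b|, a . b)`, which is
#' identical mathematically but better conditioned near 0 and 180 degrees.
#' The result is symmetric in its arguments and invariant under positive
#' scaling of either one.
#'
#' @param a,b Nonzero numeric vectors of length 3.
#' @return Angle in degrees in \[0, 180\].
#' @export
#' @examples
#' v3_angle(vec3(1, 0, 0), vec3(0, 1, 0))  # 90
v3_angle <- function(a, b) {
  if (v3_norm(a) == 0) stop("degenerate (zero-length) vector: first operand of angle()")
  if (v3_norm(b) == 0) stop("degenerate (zero-length) vector: second operand of angle()")
  atan2(v3_norm(v3_cross(a, b)), v3_dot(a, b)) * 180 / pi
}

# Row-wise counterparts on n x 3 matrices; the expression evaluator uses these
# so whole streams evaluate in one pass.
.rw_dot <- function(a, b) rowSums(a * b)

.rw_norm <- function(a) sqrt(rowSums(a * a))

.rw_cross <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L],
        deparse.level = 0L)
}

# angle with selectable handling of zero-length rows: "error" (single-frame
# contract) or "na" (stream mode: degenerate frames become NA and are labelled
# "N" downstream).
.rw_angle <- function(a, b, on_degenerate = c("error", "na")) {
  on_degenerate <- match.arg(on_degenerate)
  na <- .rw_norm(a)
  nb <- .rw_norm(b)
  bad <- na == 0 | nb == 0
  if (any(bad)) {
    if (on_degenerate == "error") {
      operand <- if (any(na == 0)) "first" else "second"
      stop("degenerate (zero-length) vector: ", operand, " operand of angle()")
    }
  }
  out <- atan2(.rw_norm(.rw_cross(a, b)), .rw_dot(a, b)) * 180 / pi
  out[bad] <- NA_real_
  out
}
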