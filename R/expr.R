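# Declarative expression language for features and key-frame rules.
#
# Grammar (infix, case-sensitive identifiers):
#   or_expr  := and_expr ( 'or' and_expr )*
#   and_expr := not_expr ( 'and' not_expr )*
#   not_expr := 'not' not_expr | cmp
#   cmp      := sum ( ('<'|'<='|'>'|'>='|'=='|'!=') sum )?
#   sum      := term ( ('+'|'-') term )*
#   term     := unary ( ('*'|'/') unary )*
#   unary    := '-' unary | primary
#   primary  := number | 'true' | 'false' | ident | ident '(' args ')'
#              | '(' or_expr ')'
#
# Values are typed: numeric, logical, or vector (3D).  Functions:
#   joint(Name)           -> vector   position of a topology joint
#   vec(x, y, z)          -> vector   literal / componentwise construction
#   add(v,v) sub(v,v)     -> vector   (also defined on numerics)
#   scale(v, s)           -> vector
#   dot(v,v) norm(v)      -> numeric
#   cross(v,v)            -> vector
#   angle(v,v)            -> numeric  unsigned, degrees, [0, 180]
#   x(v) y(v) z(v)        -> numeric  component access
#   abs sqrt min max      -> numeric
#   sin cos tan           -> numeric  argument in DEGREES
#   asin acos atan        -> numeric  result in DEGREES
#   atan2(y, x)           -> numeric  result in DEGREES
#   prev(Feature)         -> feature's value on the previous frame (equals the
#                            current value on the first frame); the basis for
#                            finite-difference velocity features
# Bare identifiers refer to previously defined features (no forward
# references).

.token_pattern <- paste0(
  "[A-Za-z_][A-Za-z0-9_]*",
  "|[0-9]+\\.?[0-9]*(?:[eE][+-]?[0-9]+)?",
  "|\\.[0-9]+(?:[eE][+-]?[0-9]+)?",
  "|<=|>=|==|!=|[-+*/(),<>]")

.tokenize <- function(text) {
  m <- gregexpr(.token_pattern, text)[[1L]]
  toks <- regmatches(text, gregexpr(.token_pattern, text))[[1L]]
  residue <- text
  regmatches(residue, gregexpr(.token_pattern, residue)) <- list(rep("", length(toks)))
  if (grepl("[^[:space:]]", residue))
    stop("expression syntax error: unexpected character(s) in: ", text)
  toks
}

#' Parse a feature/rule expression
#'
#' Parses the package's declarative expression notation (see the package
#' vignette) into an expression tree usable in [feature_def()] and
#' [keyframe_rule()].  Expressions are data, not code: only the documented
#' vector-algebra, arithmetic, comparison, boolean and trigonometric
#' operations are available.
#'
#' @param text A single character string, e.g.
#'   `"angle(sub(joint(KneeRight), joint(HipRight)), vec(0, 1, 0))"`.
#' @return An expression tree (nested list), class `gdl_expr`.
#' @export
parse_expr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- .tokenize(text)
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[i] else NA_character_
  advance <- function() {
    t <- peek()
    if (is.na(t)) stop("expression syntax error: unexpected end of: ", text)
    i <<- i + 1L
    t
  }
  expect <- function(what) {
    t <- advance()
    if (t != what)
      stop("expression syntax error: expected '", what, "' near '", t,
           "' in: ", text)
  }
  p_or <- function() {
    e <- p_and()
    while (!is.na(peek()) && peek() == "or") {
      advance()
      e <- list(k = "op", op = "or", lhs = e, rhs = p_and())
    }
    e
  }
  p_and <- function() {
    e <- p_not()
    while (!is.na(peek()) && peek() == "and") {
      advance()
      e <- list(k = "op", op = "and", lhs = e, rhs = p_not())
    }
    e
  }
  p_not <- function() {
    if (!is.na(peek()) && peek() == "not") {
      advance()
      return(list(k = "not", arg = p_not()))
    }
    p_cmp()
  }
  p_cmp <- function() {
    e <- p_sum()
    if (!is.na(peek()) && peek() %in% c("<", "<=", ">", ">=", "==", "!=")) {
      op <- advance()
      e <- list(k = "op", op = op, lhs = e, rhs = p_sum())
    }
    e
  }
  p_sum <- function() {
    e <- p_term()
    while (!is.na(peek()) && peek() %in% c("+", "-")) {
      op <- advance()
      e <- list(k = "op", op = op, lhs = e, rhs = p_term())
    }
    e
  }
  p_term <- function() {
    e <- p_unary()
    while (!is.na(peek()) && peek() %in% c("*", "/")) {
      op <- advance()
      e <- list(k = "op", op = op, lhs = e, rhs = p_unary())
    }
    e
  }
  p_unary <- function() {
    if (!is.na(peek()) && peek() == "-") {
      advance()
      return(list(k = "neg", arg = p_unary()))
    }
    p_primary()
  }
  p_primary <- function() {
    t <- advance()
    if (grepl("^[0-9.]", t)) return(list(k = "num", v = as.numeric(t)))
    if (t == "(") {
      e <- p_or()
      expect(")")
      return(e)
    }
    if (t %in% c("true", "TRUE")) return(list(k = "bool", v = TRUE))
    if (t %in% c("false", "FALSE")) return(list(k = "bool", v = FALSE))
    if (!grepl("^[A-Za-z_]", t))
      stop("expression syntax error: unexpected '", t, "' in: ", text)
    if (!is.na(peek()) && peek() == "(") {
      advance()
      args <- list()
      if (peek() != ")") {
        repeat {
          args[[length(args) + 1L]] <- p_or()
          if (peek() == ",") { advance(); next }
          break
        }
      }
      expect(")")
      return(list(k = "call", fn = t, args = args))
    }
    list(k = "id", name = t)
  }
  e <- p_or()
  if (!is.na(peek()))
    stop("expression syntax error: trailing tokens near '", peek(),
         "' in: ", text)
  structure(e, class = "gdl_expr")
}

# function signatures: list(arg types, return type); "J" = joint identifier
.fn_sigs <- list(
  joint = list(args = "J", ret = "vector"),
  vec   = list(args = c("numeric", "numeric", "numeric"), ret = "vector"),
  add   = list(args = c("same", "same"), ret = "same"),
  sub   = list(args = c("same", "same"), ret = "same"),
  scale = list(args = c("vector", "numeric"), ret = "vector"),
  dot   = list(args = c("vector", "vector"), ret = "numeric"),
  cross = list(args = c("vector", "vector"), ret = "vector"),
  norm  = list(args = "vector", ret = "numeric"),
  angle = list(args = c("vector", "vector"), ret = "numeric"),
  x = list(args = "vector", ret = "numeric"),
  y = list(args = "vector", ret = "numeric"),
  z = list(args = "vector", ret = "numeric"),
  abs = list(args = "numeric", ret = "numeric"),
  sqrt = list(args = "numeric", ret = "numeric"),
  min = list(args = c("numeric", "numeric"), ret = "numeric"),
  max = list(args = c("numeric", "numeric"), ret = "numeric"),
  sin = list(args = "numeric", ret = "numeric"),
  cos = list(args = "numeric", ret = "numeric"),
  tan = list(args = "numeric", ret = "numeric"),
  asin = list(args = "numeric", ret = "numeric"),
  acos = list(args = "numeric", ret = "numeric"),
  atan = list(args = "numeric", ret = "numeric"),
  atan2 = list(args = c("numeric", "numeric"), ret = "numeric"),
  prev = list(args = "F", ret = "featuretype")
)

# Static type inference + reference validation.  `feature_kinds` is a named
# character vector (name -> logical/numeric/vector) of features defined
# EARLIER; forward references are rejected by construction.
.infer_type <- function(ast, feature_kinds, joint_names) {
  k <- ast$k
  if (k == "num") return("numeric")
  if (k == "bool") return("logical")
  if (k == "id") {
    if (!ast$name %in% names(feature_kinds))
      stop("validation error: reference to undefined feature '", ast$name,
           "' (features may only reference features defined earlier)")
    return(unname(feature_kinds[[ast$name]]))
  }
  if (k == "neg") {
    t <- .infer_type(ast$arg, feature_kinds, joint_names)
    if (t == "logical") stop("validation error: '-' is not defined on logical values")
    return(t)
  }
  if (k == "not") {
    t <- .infer_type(ast$arg, feature_kinds, joint_names)
    if (t != "logical") stop("validation error: 'not' needs a logical operand")
    return("logical")
  }
  if (k == "op") {
    lt <- .infer_type(ast$lhs, feature_kinds, joint_names)
    rt <- .infer_type(ast$rhs, feature_kinds, joint_names)
    op <- ast$op
    if (op %in% c("and", "or")) {
      if (lt != "logical" || rt != "logical")
        stop("validation error: '", op, "' needs logical operands")
      return("logical")
    }
    if (op %in% c("<", "<=", ">", ">=", "==", "!=")) {
      if (lt != "numeric" || rt != "numeric")
        stop("validation error: comparison '", op, "' needs numeric operands")
      return("logical")
    }
    if (op %in% c("+", "-")) {
      if (lt == "vector" && rt == "vector") return("vector")
      if (lt == "numeric" && rt == "numeric") return("numeric")
      stop("validation error: '", op, "' needs two numerics or two vectors")
    }
    if (op == "*") {
      if (lt == "numeric" && rt == "numeric") return("numeric")
      if ((lt == "vector" && rt == "numeric") ||
          (lt == "numeric" && rt == "vector")) return("vector")
      stop("validation error: '*' needs numeric x numeric or vector x scalar")
    }
    if (op == "/") {
      if (lt == "numeric" && rt == "numeric") return("numeric")
      if (lt == "vector" && rt == "numeric") return("vector")
      stop("validation error: '/' needs numeric or vector/scalar operands")
    }
    stop("validation error: unknown operator '", op, "'")
  }
  if (k == "call") {
    sig <- .fn_sigs[[ast$fn]]
    if (is.null(sig))
      stop("validation error: unknown function '", ast$fn, "'")
    if (length(ast$args) != length(sig$args))
      stop("validation error: ", ast$fn, "() takes ", length(sig$args),
           " argument(s), got ", length(ast$args))
    if (identical(sig$args, "J")) {
      a <- ast$args[[1L]]
      if (a$k != "id")
        stop("validation error: joint() needs a bare joint name")
      if (!a$name %in% joint_names)
        stop("validation error: unknown joint '", a$name,
             "' for the active topology")
      return("vector")
    }
    if (identical(sig$args, "F")) {       # prev(Feature)
      a <- ast$args[[1L]]
      if (a$k != "id")
        stop("validation error: prev() needs a bare feature name")
      if (!a$name %in% names(feature_kinds))
        stop("validation error: prev() references undefined feature '",
             a$name, "'")
      return(unname(feature_kinds[[a$name]]))
    }
    types <- vapply(ast$args, .infer_type, character(1L),
                    feature_kinds, joint_names)
    if (identical(sig$args, c("same", "same"))) {
      if (types[1L] != types[2L] || types[1L] == "logical")
        stop("validation error: ", ast$fn,
             "() needs two numerics or two vectors")
      return(types[1L])
    }
    for (ii in seq_along(sig$args))
      if (types[ii] != sig$args[ii])
        stop("validation error: argument ", ii, " of ", ast$fn,
             "() must be ", sig$args[ii], ", got ", types[ii])
    return(sig$ret)
  }
  stop("internal error: unknown expression node kind '", k, "'")
}

# Vectorised evaluation over n frames.  Context `ctx`:
#   $n          frame count
#   $joints     n x J x 3 array (dimnames on joints), or NULL
#   $values     environment: feature name -> column (numeric[n] / logical[n]
#               / n x 3 matrix)
#   $prev       environment of previous-frame columns (lagged), same shapes
#   $on_degenerate  "error" or "na"
.eval_expr <- function(ast, ctx) {
  k <- ast$k
  if (k == "num") return(ast$v)
  if (k == "bool") return(ast$v)
  if (k == "id") return(get(ast$name, envir = ctx$values))
  if (k == "neg") return(-.eval_expr(ast$arg, ctx))
  if (k == "not") return(!.eval_expr(ast$arg, ctx))
  if (k == "op") {
    l <- .eval_expr(ast$lhs, ctx)
    r <- .eval_expr(ast$rhs, ctx)
    return(switch(ast$op,
      "and" = l & r, "or" = l | r,
      "<" = l < r, "<=" = l <= r, ">" = l > r, ">=" = l >= r,
      "==" = l == r, "!=" = l != r,
      "+" = l + r, "-" = l - r,
      "*" = if (is.matrix(l) && !is.matrix(r)) l * r
            else if (!is.matrix(l) && is.matrix(r)) r * l
            else l * r,
      "/" = l / r))
  }
  # call
  fn <- ast$fn
  if (fn == "joint") {
    jm <- ctx$joints[, ast$args[[1L]]$name, , drop = FALSE]
    return(matrix(jm, nrow = ctx$n, ncol = 3L))
  }
  if (fn == "prev") return(get(ast$args[[1L]]$name, envir = ctx$prev))
  a <- lapply(ast$args, .eval_expr, ctx)
  switch(fn,
    vec = {
      n <- ctx$n
      cbind(rep_len(a[[1L]], n), rep_len(a[[2L]], n), rep_len(a[[3L]], n),
            deparse.level = 0L)
    },
    add = a[[1L]] + a[[2L]],
    sub = a[[1L]] - a[[2L]],
    scale = a[[1L]] * a[[2L]],
    dot = .rw_dot(a[[1L]], a[[2L]]),
    cross = .rw_cross(a[[1L]], a[[2L]]),
    norm = .rw_norm(a[[1L]]),
    angle = .rw_angle(a[[1L]], a[[2L]], ctx$on_degenerate),
    x = a[[1L]][, 1L],
    y = a[[1L]][, 2L],
    z = a[[1L]][, 3L],
    abs = abs(a[[1L]]),
    sqrt = sqrt(a[[1L]]),
    min = pmin(a[[1L]], a[[2L]]),
    max = pmax(a[[1L]], a[[2L]]),
    sin = sin(a[[1L]] * pi / 180),
    cos = cos(a[[1L]] * pi / 180),
    tan = tan(a[[1L]] * pi / 180),
    asin = asin(a[[1L]]) * 180 / pi,
    acos = acos(a[[1L]]) * 180 / pi,
    atan = atan(a[[1L]]) * 180 / pi,
    atan2 = atan2(a[[1L]], a[[2L]]) * 180 / pi,
    stop("internal error: unhandled function '", fn, "'"))
}

# scale(v, s) above: matrix * numeric recycles columnwise, correct when s is
# length 1 or length n.

#' Render an expression tree back to its text notation
#' @param x A `gdl_expr` (or raw tree).
#' @param ... Unused.
#' @return Character string.
#' @export
format.gdl_expr <- function(x, ...) .deparse_expr(unclass(x))

.deparse_expr <- function(ast) {
  k <- ast$k
  if (k == "num") return(format(ast$v, digits = 15L))
  if (k == "bool") return(if (ast$v) "true" else "false")
  if (k == "id") return(ast$name)
  if (k == "neg") return(paste0("-", .deparse_expr(ast$arg)))
  if (k == "not") return(paste0("not (", .deparse_expr(ast$arg), ")"))
  if (k == "op")
    return(paste0("(", .deparse_expr(ast$lhs), " ", ast$op, " ",
                  .deparse_expr(ast$rhs), ")"))
  paste0(ast$fn, "(", paste(vapply(ast$args, .deparse_expr, character(1L)),
                            collapse = ", "), ")")
}

#' @export
print.gdl_expr <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
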