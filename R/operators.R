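# Operator inventory for the equation-learner network.
#
# Unary units consume one linear output g_k; binary units consume two
# consecutive linear outputs.  Each operator carries its forward map and its
# partial derivatives; the compiled training core mirrors these definitions
# exactly (tested), so the R side is the reference semantics.

.fl_unary_ops <- list(
  id     = list(fn = function(x) x,            grad = function(x) rep(1, length(x))),
  square = list(fn = function(x) x * x,        grad = function(x) 2 * x),
  exp    = list(fn = function(x) sexp(x),      grad = function(x) ifelse(x <= .fl_exp_cap, exp(x), 0)),
  sin    = list(fn = sin,                      grad = cos),
  cos    = list(fn = cos,                      grad = function(x) -sin(x)),
  relu   = list(fn = function(x) pmax(x, 0),   grad = function(x) as.numeric(x > 0)),
  logabs = list(fn = function(x) logabs(x),
                grad = function(x) ifelse(abs(x) > .fl_eps_log, 1 / x, 0))
)

.fl_binary_ops <- list(
  sum  = list(fn = function(u, v) u + v,
              du = function(u, v) rep(1, length(u)),
              dv = function(u, v) rep(1, length(u))),
  diff = list(fn = function(u, v) u - v,
              du = function(u, v) rep(1, length(u)),
              dv = function(u, v) rep(-1, length(u))),
  prod = list(fn = function(u, v) u * v,
              du = function(u, v) v,
              dv = function(u, v) u),
  quot = list(fn = function(u, v) sdiv(u, v),
              du = function(u, v) {
                s <- ifelse(v < 0, -1, 1)
                1 / (s * pmax(abs(v), .fl_eps_div))
              },
              dv = function(u, v) ifelse(abs(v) > .fl_eps_div, -u / (v * v), 0))
)

# Integer codes shared with the compiled training core.
.fl_unary_codes  <- c(id = 0L, square = 1L, exp = 2L, sin = 3L, cos = 4L,
                      relu = 5L, logabs = 6L)
.fl_binary_codes <- c(sum = 0L, diff = 1L, prod = 2L, quot = 3L)

#' Declare the operator inventory of an equation-learner network
#'
#' The hidden units of an equation-learner apply elementary mathematical
#' operators to linear combinations of their inputs.  This constructor fixes
#' which operators are available: unary operators take one linear output,
#' binary operators take two consecutive linear outputs.  The quotient and
#' log-magnitude operators are safeguarded (see [sdiv()], [logabs()]) so that
#' every operator is total on the reals.  The inventory is extensible: the
#' network only ever sees operator names, so restricting or reordering the
#' set here changes the hypothesis space of extractable formulas.
#'
#' @param unary character vector of unary operator names; any of
#'   `"id"`, `"square"`, `"exp"`, `"sin"`, `"cos"`, `"relu"`, `"logabs"`.
#' @param binary character vector of binary operator names; any of
#'   `"sum"`, `"diff"`, `"prod"`, `"quot"`.
#' @param use_derivative logical; expose the precomputed first-difference
#'   feature `dy` (when present in the dataset) as an additional input.
#' @return An object of class `"operator_set"`.
#' @seealso [build_network()]
#' @export
operator_set <- function(unary = c("id", "square", "exp", "sin", "cos",
                                   "relu", "logabs"),
                         binary = c("sum", "diff", "prod", "quot"),
                         use_derivative = FALSE) {
  if (length(unary) + length(binary) == 0L) {
    stop("operator_set needs at least one operator", call. = FALSE)
  }
  unary <- if (length(unary)) {
    match.arg(unary, names(.fl_unary_ops), several.ok = TRUE)
  } else {
    character(0)
  }
  binary <- if (length(binary)) {
    match.arg(binary, names(.fl_binary_ops), several.ok = TRUE)
  } else {
    character(0)
  }
  structure(list(unary = unary, binary = binary,
                 use_derivative = isTRUE(use_derivative)),
            class = "operator_set")
}

#' @export
print.operator_set <- function(x, ...) {
  cat("<operator_set>\n",
      " unary : ", paste(x$unary, collapse = ", "), "\n",
      " binary: ", if (length(x$binary)) paste(x$binary, collapse = ", ") else "(none)", "\n",
      " derivative feature: ", x$use_derivative, "\n", sep = "")
  invisible(x)
}

#' Smoothed L1/2 sparsity penalty
#'
#' Piecewise regularizer used during equation-learner training: the exact
#' square-root norm `|w|^(1/2)` for `|w| >= a`, and the smooth quartic
#' surrogate `|-w^4/(8 a^3) + 3 w^2/(4 a) + 3 a / 8|^(1/2)` for `|w| < a`.
#' The surrogate removes the singular gradient at `w = 0` while agreeing with
#' the square-root branch (value `sqrt(a)`) at the joint `|w| = a`.  The
#' penalty is even, non-negative, and non-decreasing in `|w|`.
#'
#' @param w numeric vector of weights.
#' @param a positive smoothing constant below which the surrogate branch is
#'   used (default 0.01).
#' @return Numeric vector of penalty values, same length as `w`.
#' @examples
#' l12_star_penalty(1, 0.01)        # exactly 1
#' l12_star_penalty(0.01, 0.01)     # sqrt(0.01) = 0.1 on both branches
#' l12_star_penalty(0, 0.01)        # sqrt(3 * 0.01 / 8)
#' @export
l12_star_penalty <- function(w, a = 0.01) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    stop("`a` must be a single positive number", call. = FALSE)
  }
  aw <- abs(w)
  inner <- -w^4 / (8 * a^3) + 3 * w^2 / (4 * a) + 3 * a / 8
  ifelse(aw >= a, sqrt(aw), sqrt(abs(inner)))
}

# Derivative of the penalty wrt w (used by the R reference gradient; the
# compiled core re-implements it).  Smooth branch: p'(w) / (2 sqrt(p)).
.l12_star_grad <- function(w, a = 0.01) {
  aw <- abs(w)
  outer_branch <- sign(w) / (2 * sqrt(pmax(aw, .Machine$double.eps)))
  inner <- -w^4 / (8 * a^3) + 3 * w^2 / (4 * a) + 3 * a / 8
  dinner <- -w^3 / (2 * a^3) + 3 * w / (2 * a)
  smooth_branch <- dinner / (2 * sqrt(inner))
  ifelse(aw >= a, outer_branch, smooth_branch)
}
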