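# Formula extraction: coefficients below the threshold are treated as exact
# zeros, the surviving structure is composed layer by layer into an R
# expression, and constants are folded.  Only conservative rewrites are
# applied (0 * e -> 0, 1 * e -> e, dropped zero terms), so evaluating the
# expression reproduces the pruned network's forward pass to floating
# tolerance.  Safeguarded operators appear in the tree as the exported
# functions logabs(), sdiv(), sexp(), relu().

.is_const <- function(e) is.numeric(e) && length(e) == 1L

# Evaluation environment for formula trees (safeguarded operators visible,
# everything else from base).  Built lazily so file collation order does not
# matter at load time.
.fold_env_holder <- new.env(parent = emptyenv())
.fold_env <- function() {
  if (is.null(.fold_env_holder$env)) {
    e <- new.env(parent = baseenv())
    e$logabs <- logabs; e$sdiv <- sdiv; e$sexp <- sexp; e$relu <- relu
    .fold_env_holder$env <- e
  }
  .fold_env_holder$env
}

.mk_call <- function(fn, ...) {
  args <- list(...)
  e <- as.call(c(as.name(fn), args))
  if (all(vapply(args, .is_const, logical(1)))) {
    return(eval(e, .fold_env()))
  }
  e
}

.mk_prod <- function(a, b) {
  if (.is_const(a) && a == 0) return(0)
  if (.is_const(b) && b == 0) return(0)
  if (.is_const(a) && a == 1) return(b)
  if (.is_const(b) && b == 1) return(a)
  .mk_call("*", a, b)
}

.mk_sum <- function(a, b) {
  if (.is_const(a) && a == 0) return(b)
  if (.is_const(b) && b == 0) return(a)
  .mk_call("+", a, b)
}

# Linear combination sum_k w_k * e_k + b with zero coefficients dropped and
# negative coefficients rendered as subtractions.
.lin_comb <- function(w, exprs, b) {
  out <- NULL
  const_acc <- b
  for (k in seq_along(w)) {
    if (w[k] == 0) next
    ek <- exprs[[k]]
    if (.is_const(ek)) { const_acc <- const_acc + w[k] * ek; next }
    coef <- abs(w[k])
    term <- if (coef == 1) ek else .mk_call("*", coef, ek)
    if (is.null(out)) {
      out <- if (w[k] < 0) .mk_call("-", term) else term
    } else {
      out <- .mk_call(if (w[k] < 0) "-" else "+", out, term)
    }
  }
  if (is.null(out)) return(const_acc)
  if (const_acc != 0) out <- .mk_call(if (const_acc < 0) "-" else "+",
                                      out, abs(const_acc))
  out
}

.apply_unary <- function(op, g) {
  if (.is_const(g)) return(.fl_unary_ops[[op]]$fn(g))
  switch(op,
         id = g,
         square = .mk_call("^", g, 2),
         exp = .mk_call("sexp", g),
         sin = .mk_call("sin", g),
         cos = .mk_call("cos", g),
         relu = .mk_call("relu", g),
         logabs = .mk_call("logabs", g))
}

.apply_binary <- function(op, u, v) {
  if (.is_const(u) && .is_const(v)) return(.fl_binary_ops[[op]]$fn(u, v))
  switch(op,
         sum = .mk_sum(u, v),
         diff = if (.is_const(v) && v == 0) u else .mk_call("-", u, v),
         prod = .mk_prod(u, v),
         quot = .mk_call("sdiv", u, v))
}

#' Extract a closed-form formula from a trained network
#'
#' Treats every weight and bias with magnitude strictly below `theta` as
#' exactly zero (magnitudes `>= theta` are retained), composes the surviving
#' structure layer by layer into an expression tree over `X1`, `X2` (and
#' `dy` when the derivative feature is enabled), folds constants, and drops
#' sub-expressions multiplied by zero.  No aggressive algebraic rewriting is
#' performed, so evaluating the formula reproduces the pruned network's
#' forward pass to floating tolerance.
#'
#' @param network a (typically trained) `eql_network`.
#' @param theta coefficient threshold; defaults to the threshold stored in
#'   the network (0.01 unless overridden at construction).
#' @return An object of class `"symbolic_formula"`: the expression (`expr`),
#'   the variables and operators it uses, its numeric coefficients, the
#'   threshold, and `constant = TRUE` when pruning removed every variable
#'   (the formula is then the surviving constant).
#' @examples
#' ops <- operator_set(unary = c("id", "sin"), binary = NULL)
#' net <- build_network(ops, depth = 1, units = c(id = 1, sin = 1), seed = 1)
#' # hand-wire y = sin(X1)
#' net$layers[[1]]$W[] <- 0; net$layers[[1]]$b[] <- 0
#' net$layers[[1]]$W[2, 1] <- 1
#' net$W_out[] <- c(0, 1); net$b_out <- 0
#' formula_text(extract_formula(net))
#' @export
extract_formula <- function(network, theta = network$theta) {
  stopifnot(inherits(network, "eql_network"))
  if (theta < 0) stop("`theta` must be >= 0", call. = FALSE)
  net <- prune_network(network, theta)
  vars <- c("X1", "X2", if (net$operators$use_derivative) "dy")
  exprs <- lapply(vars, as.name)
  for (layer in net$layers) {
    nu <- length(layer$unary)
    g <- lapply(seq_len(nrow(layer$W)), function(k) {
      .lin_comb(layer$W[k, ], exprs, layer$b[k])
    })
    h <- vector("list", nu + length(layer$binary))
    for (k in seq_len(nu)) h[[k]] <- .apply_unary(layer$unary[k], g[[k]])
    for (m in seq_along(layer$binary)) {
      h[[nu + m]] <- .apply_binary(layer$binary[m],
                                   g[[nu + 2L * m - 1L]], g[[nu + 2L * m]])
    }
    exprs <- h
  }
  expr <- .lin_comb(as.vector(net$W_out), exprs, net$b_out)
  if (!is.null(net$y_scale) &&
      (net$y_scale$sd != 1 || net$y_scale$mu != 0)) {
    # undo target standardization outside the pruned coefficients
    expr <- .lin_comb(net$y_scale$sd, list(expr), net$y_scale$mu)
  }
  structure(list(expr = expr,
                 vars = intersect(vars, all.vars(as.expression(expr))),
                 operators_used = .collect_operators(expr),
                 coefficients = .collect_coefficients(expr),
                 theta = theta,
                 constant = .is_const(expr),
                 use_derivative = net$operators$use_derivative),
            class = "symbolic_formula")
}

.collect_operators <- function(e) {
  map <- c("sin" = "sin", "cos" = "cos", "sexp" = "exp", "logabs" = "logabs",
           "sdiv" = "quot", "relu" = "relu", "^" = "square",
           "+" = "sum", "-" = "diff", "*" = "prod")
  found <- character(0)
  walk <- function(x) {
    if (is.call(x)) {
      fn <- as.character(x[[1]])
      if (fn %in% names(map)) found <<- union(found, map[[fn]])
      for (i in seq_along(x)[-1]) walk(x[[i]])
    }
  }
  walk(e)
  unname(found)
}

.collect_coefficients <- function(e) {
  found <- numeric(0)
  walk <- function(x) {
    if (is.numeric(x)) found <<- c(found, x)
    else if (is.call(x)) for (i in seq_along(x)[-1]) walk(x[[i]])
  }
  walk(e)
  found
}

#' @export
print.symbolic_formula <- function(x, ...) {
  cat("<symbolic_formula> y =", formula_text(x), "\n")
  if (x$constant) cat("  (pruning removed every variable: constant formula)\n")
  invisible(x)
}

#' Plain-text rendering of an extracted formula
#' @param formula a `symbolic_formula`.
#' @return A single string.
#' @export
formula_text <- function(formula) {
  stopifnot(inherits(formula, "symbolic_formula"))
  paste(deparse(formula$expr, width.cutoff = 500L), collapse = " ")
}

#' Evaluate an extracted formula
#'
#' @param object a `symbolic_formula`.
#' @param newdata a `triplet_dataset`, or a data frame / matrix with columns
#'   `X1`, `X2` and (if the formula uses it) `dy`.
#' @param ... unused.
#' @return Numeric vector of predicted values.
#' @export
predict.symbolic_formula <- function(object, newdata, ...) {
  df <- if (inherits(newdata, "triplet_dataset")) newdata$records
        else as.data.frame(newdata)
  missing_vars <- setdiff(object$vars, names(df))
  if (length(missing_vars)) {
    stop("newdata lacks variables: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(df)
  env <- list2env(df[, intersect(names(df), c("X1", "X2", "dy")), drop = FALSE],
                  parent = .fold_env())
  val <- eval(object$expr, env)
  if (length(val) == 1L) val <- rep(val, n)
  val
}

#' Write a formula record to JSON
#'
#' Serializes the expression string, operators used, numeric coefficients,
#' the pruning threshold, and (optionally) an accuracy report.
#'
#' @param formula a `symbolic_formula`.
#' @param path output file path.
#' @param accuracy optional `accuracy_report` to embed.
#' @return `path`, invisibly.
#' @export
write_formula_json <- function(formula, path, accuracy = NULL) {
  stopifnot(inherits(formula, "symbolic_formula"))
  rec <- list(expression = formula_text(formula),
              variables = formula$vars,
              operators_used = formula$operators_used,
              coefficients = formula$coefficients,
              threshold = formula$theta,
              constant = formula$constant)
  if (!is.null(accuracy)) rec$accuracy <- unclass(accuracy)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Tolerance-band verification accuracy
#'
#' Fraction (as a percentage) of test records whose prediction falls within
#' `tau` times the observed target range of the true value; the boundary
#' counts as within.  This maps a continuous regression fit to the
#' percentage scale used when reporting how faithfully a distilled formula
#' reproduces a factor matrix, and is invariant to target scaling.
#'
#' @param predictor an `eql_network` or `symbolic_formula`.
#' @param testset a nonempty `triplet_dataset` whose `y` values are not all
#'   identical (the band is a fraction of the observed range).
#' @param tau relative tolerance (default 0.05).
#' @return An object of class `"accuracy_report"`: `accuracy` (percent),
#'   `tau`, `n`, `mae`, and `nrmse` (RMSE over the target range).
#' @export
verification_accuracy <- function(predictor, testset, tau = 0.05) {
  stopifnot(inherits(testset, "triplet_dataset"))
  y <- testset$records$y
  if (length(y) == 0L) stop("test set is empty", call. = FALSE)
  rng <- max(y) - min(y)
  if (rng == 0) {
    stop("target values are constant: the tolerance band is undefined",
         call. = FALSE)
  }
  y_hat <- predict(predictor, testset)
  err <- abs(y_hat - y)
  structure(list(accuracy = 100 * mean(err <= tau * rng),
                 tau = tau, n = length(y),
                 mae = mean(err),
                 nrmse = sqrt(mean(err^2)) / rng),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> %.2f%% within %.3g of range (n = %d, MAE %.4g, NRMSE %.4g)\n",
              x$accuracy, x$tau, x$n, x$mae, x$nrmse))
  invisible(x)
}
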