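# Equation-learner network: each hidden layer is a linear stage g = W x + b
# followed by a fixed block of operator units.  Unary unit k consumes g_k;
# binary unit m consumes the next two linear outputs.  The unit-to-operator
# assignment is frozen at construction; training only moves W, b and the
# final linear read-out.

.layer_widths <- function(unary, binary) {
  list(n_h = length(unary) + length(binary),
       n_g = length(unary) + 2L * length(binary))
}

#' Build an equation-learner network
#'
#' Constructs a network of `depth` hidden operator layers followed by a
#' linear read-out.  Every hidden layer carries `units[op]` copies of each
#' enabled operator; unary units consume one linear output each and binary
#' units two consecutive outputs, so the linear stage of a layer has
#' `n_unary + 2 * n_binary` outputs.  Weights are initialized reproducibly
#' from `seed` with standard deviation `1/sqrt(fan_in)`; rows feeding sine
#' and cosine units are additionally scaled by `osc_scale`, which seeds the
#' network with higher random frequencies when fitting oscillatory surfaces
#' (phases for those units are drawn uniformly on `[-pi, pi]`).
#'
#' @param operators an [operator_set()].
#' @param depth number of hidden layers (>= 1).
#' @param units named integer vector of unit counts per operator per layer;
#'   names must belong to the operator set.  Operators omitted from `units`
#'   get no units.
#' @param theta coefficient threshold used later at formula extraction
#'   (stored with the network; >= 0).
#' @param a smoothing constant of the L1/2* penalty (> 0, default 0.01).
#' @param seed integer seed for weight initialization.
#' @param osc_scale multiplier on the initial scale of weights feeding
#'   sin/cos units (default 1).
#' @return An object of class `"eql_network"`.
#' @examples
#' ops <- operator_set(unary = c("id", "sin"), binary = "prod")
#' net <- build_network(ops, depth = 1, units = c(id = 1, sin = 1, prod = 1),
#'                      seed = 1)
#' net$layers[[1]]$unary
#' @export
build_network <- function(operators = operator_set(), depth = 2L,
                          units = c(id = 2L, square = 1L, sin = 2L, cos = 2L,
                                    prod = 2L),
                          theta = 0.01, a = 0.01, seed = 1L, osc_scale = 1) {
  stopifnot(inherits(operators, "operator_set"))
  depth <- as.integer(depth)
  if (depth < 1L) stop("`depth` must be >= 1", call. = FALSE)
  if (theta < 0) stop("`theta` must be >= 0", call. = FALSE)
  if (a <= 0) stop("`a` must be > 0", call. = FALSE)
  if (is.null(names(units)) || any(names(units) == "")) {
    stop("`units` must be a named count vector", call. = FALSE)
  }
  enabled <- c(operators$unary, operators$binary)
  unknown <- setdiff(names(units), enabled)
  if (length(unknown)) {
    stop("units requested for operators outside the set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  units <- units[units > 0]
  unary <- rep(intersect(names(units), operators$unary),
               times = units[intersect(names(units), operators$unary)])
  binary <- rep(intersect(names(units), operators$binary),
                times = units[intersect(names(units), operators$binary)])
  if (length(unary) + length(binary) == 0L) {
    stop("network must have at least one hidden unit", call. = FALSE)
  }

  n_in0 <- 2L + as.integer(operators$use_derivative)
  layers <- vector("list", depth)
  with_seed(seed, {
    n_in <- n_in0
    for (l in seq_len(depth)) {
      w <- .layer_widths(unary, binary)
      sd0 <- 1 / sqrt(n_in)
      W <- matrix(rnorm(w$n_g * n_in, sd = sd0), w$n_g, n_in)
      b <- rnorm(w$n_g, sd = 0.1)
      osc_rows <- which(unary %in% c("sin", "cos"))
      if (length(osc_rows) && osc_scale != 1) {
        W[osc_rows, ] <- W[osc_rows, , drop = FALSE] * osc_scale
        b[osc_rows] <- runif(length(osc_rows), -pi, pi)
      }
      layers[[l]] <- list(W = W, b = b, unary = unary, binary = binary)
      n_in <- w$n_h
    }
    W_out <- matrix(rnorm(n_in, sd = 1 / sqrt(n_in)), 1L, n_in)
    b_out <- 0
    structure(list(layers = layers, W_out = W_out, b_out = b_out,
                   operators = operators, depth = depth, theta = theta,
                   a = a, seed = seed, n_inputs = n_in0,
                   trained = FALSE),
              class = "eql_network")
  })
}

#' @export
print.eql_network <- function(x, ...) {
  l1 <- x$layers[[1L]]
  cat(sprintf("<eql_network> depth %d, %d inputs, units/layer: %s%s\n",
              x$depth, x$n_inputs,
              paste(c(l1$unary, l1$binary), collapse = " "),
              if (isTRUE(x$trained)) " [trained]" else ""))
  invisible(x)
}

# Forward pass of one layer on a batch (rows = samples).  Returns h and,
# when cache = TRUE, the linear outputs g for backprop.
.layer_forward <- function(layer, x, cache = FALSE) {
  g <- x %*% t(layer$W) + matrix(layer$b, nrow(x), length(layer$b), byrow = TRUE)
  nu <- length(layer$unary)
  nb <- length(layer$binary)
  h <- matrix(0, nrow(x), nu + nb)
  for (k in seq_len(nu)) {
    h[, k] <- .fl_unary_ops[[layer$unary[k]]]$fn(g[, k])
  }
  for (m in seq_len(nb)) {
    u <- g[, nu + 2L * m - 1L]
    v <- g[, nu + 2L * m]
    h[, nu + m] <- .fl_binary_ops[[layer$binary[m]]]$fn(u, v)
  }
  if (cache) list(h = h, g = g) else h
}

# Full forward pass; X is the feature matrix (columns X1, X2[, dy]).  The
# optional target scale (set by standardized training) is applied last.
.eql_forward_matrix <- function(network, X) {
  h <- X
  for (layer in network$layers) h <- .layer_forward(layer, h)
  out <- as.vector(h %*% t(network$W_out)) + network$b_out
  if (!is.null(network$y_scale)) {
    out <- out * network$y_scale$sd + network$y_scale$mu
  }
  out
}

#' Predictions of an equation-learner network
#'
#' Runs the forward pass on a triplet dataset (or a raw feature matrix with
#' columns `X1`, `X2` and optionally `dy`).  Safeguarded operators guarantee
#' one finite prediction per record.
#'
#' @param object an `eql_network`.
#' @param newdata a `triplet_dataset` or numeric feature matrix.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.eql_network <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "triplet_dataset")) {
    .triplet_features(newdata, use_derivative = object$operators$use_derivative)
  } else {
    as.matrix(newdata)
  }
  if (ncol(X) != object$n_inputs) {
    stop(sprintf("network expects %d input features, got %d",
                 object$n_inputs, ncol(X)), call. = FALSE)
  }
  .eql_forward_matrix(object, X)
}

#' Training loss of the equation learner
#'
#' Squared-error fit term plus `lambda` times the summed L1/2* penalty over
#' every weight and bias of the network (hidden layers and read-out).  With
#' `lambda = 0` this is plain least squares.
#'
#' @param y observed values.
#' @param y_hat predictions, same length as `y`.
#' @param network the `eql_network` whose parameters are penalized.
#' @param lambda non-negative penalty weight.
#' @return A single number.
#' @export
eql_loss <- function(y, y_hat, network, lambda = 0) {
  if (length(y) != length(y_hat)) stop("`y` and `y_hat` lengths differ", call. = FALSE)
  fit <- sum((y - y_hat)^2)
  if (lambda == 0) return(fit)
  fit + lambda * .network_penalty(network)
}

.network_penalty <- function(network) {
  a <- network$a
  tot <- 0
  for (layer in network$layers) {
    tot <- tot + sum(l12_star_penalty(layer$W, a)) + sum(l12_star_penalty(layer$b, a))
  }
  tot + sum(l12_star_penalty(network$W_out, a)) + sum(l12_star_penalty(network$b_out, a))
}

#' Prune an equation-learner network
#'
#' Zeroes every weight and bias with magnitude strictly below `theta`
#' (magnitude exactly `theta` is retained).  [extract_formula()] applies
#' this first; evaluating the extracted formula reproduces the pruned
#' network's forward pass to floating tolerance.
#'
#' @param network an `eql_network`.
#' @param theta threshold (defaults to the network's stored threshold).
#' @return The pruned `eql_network`.
#' @export
prune_network <- function(network, theta = network$theta) {
  zap <- function(x) ifelse(abs(x) < theta, 0, x)
  network$layers <- lapply(network$layers, function(l) {
    l$W <- zap(l$W); l$b <- zap(l$b); l
  })
  network$W_out <- zap(network$W_out)
  network$b_out <- zap(network$b_out)
  network
}
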