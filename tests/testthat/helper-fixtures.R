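# Shared fixtures built in code at test time.

# A network hand-wired to compute y = f(op applied to w1*X1 + w2*X2 + b),
# with all other coefficients set to `distractor`.
wire_unary_net <- function(op, w1 = 1, w2 = 0, b = 0, distractor = 0) {
  ops <- operator_set(unary = unique(c("id", op)), binary = NULL)
  units <- stats::setNames(c(1L, 1L), c("id", op))
  if (op == "id") units <- c(id = 2L)
  net <- build_network(ops, depth = 1L, units = units, seed = 1)
  net$layers[[1]]$W[] <- distractor
  net$layers[[1]]$b[] <- distractor
  k <- which(net$layers[[1]]$unary == op)[if (op == "id") 2 else 1]
  net$layers[[1]]$W[k, 1] <- w1
  net$layers[[1]]$W[k, 2] <- w2
  net$layers[[1]]$b[k] <- b
  net$W_out[] <- distractor
  net$W_out[1, k] <- 1
  net$b_out <- distractor
  net
}

# Small deterministic grid dataset from a function of (X1, X2).
grid_dataset <- function(f, n = 20L, with_derivative = FALSE) {
  x <- seq(-1, 1, length.out = n)
  matrix_to_triplets(outer(x, x, f), with_derivative = with_derivative)
}

# Brute-force mode-n product by explicit summation (independent oracle).
naive_mode_product <- function(x, m, mode) {
  d <- dim(x)
  out_dim <- d
  out_dim[mode] <- nrow(m)
  out <- array(0, out_dim)
  idx_out <- as.matrix(expand.grid(lapply(out_dim, seq_len)))
  for (r in seq_len(nrow(idx_out))) {
    io <- idx_out[r, ]
    acc <- 0
    for (k in seq_len(d[mode])) {
      ii <- io
      ii[mode] <- k
      acc <- acc + m[io[mode], k] * x[matrix(ii, 1)]
    }
    out[matrix(io, 1)] <- acc
  }
  out
}

# Plug-in entropy of a vector of outcomes (independent oracle using table()).
oracle_entropy <- function(codes) {
  p <- as.numeric(table(codes))
  p <- p / sum(p)
  -sum(p * log2(p))
}
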