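# Coordinate-encoded matrix samples: every matrix element becomes one record
# (i, j, y) with indices mapped affinely to model coordinates X1, X2 in
# [-1, 1].  The optional dy column is the first difference of y along the row
# axis, taken with respect to the *normalized* row coordinate.

.normalize_index <- function(i, n) {
  if (n < 2L) stop("cannot normalize an axis of extent < 2", call. = FALSE)
  -1 + 2 * (i - 1) / (n - 1)
}

#' Convert a matrix into a coordinate-encoded triplet dataset
#'
#' Re-encodes a 2D factor matrix as records `(i, j, value)` plus normalized
#' model coordinates `X1` (row) and `X2` (column) in `[-1, 1]`, the form the
#' equation-learner network regresses on.  With `with_derivative = TRUE` a
#' fourth feature `dy` is attached: the finite difference of the value along
#' the row axis with respect to the normalized row coordinate (central in the
#' interior, one-sided at the edges), computed per column.
#'
#' @param matrix a numeric matrix with at least 2 rows and 2 columns and all
#'   entries finite.
#' @param with_derivative logical; attach the `dy` feature (default `FALSE`).
#' @return An object of class `"triplet_dataset"`: a list with a data frame
#'   `records` (columns `i`, `j`, `X1`, `X2`, `y` and optionally `dy`),
#'   extents `n_rows`, `n_cols`, and `has_derivative`.
#' @examples
#' ds <- matrix_to_triplets(matrix(1:6, 2, 3))
#' head(ds$records)
#' @export
matrix_to_triplets <- function(matrix, with_derivative = FALSE) {
  m <- as.matrix(matrix)
  if (!is.numeric(m)) stop("`matrix` must be numeric", call. = FALSE)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("`matrix` must have at least 2 rows and 2 columns ",
         "(a single index cannot be normalized to a range)", call. = FALSE)
  }
  bad <- which(!is.finite(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    show <- utils::head(bad, 5L)
    stop("non-finite entries at positions: ",
         paste(sprintf("(%d,%d)", show[, 1], show[, 2]), collapse = " "),
         if (nrow(bad) > 5L) sprintf(" ... and %d more", nrow(bad) - 5L),
         call. = FALSE)
  }
  nr <- nrow(m); nc <- ncol(m)
  idx <- expand.grid(i = seq_len(nr), j = seq_len(nc))
  rec <- data.frame(
    i = idx$i, j = idx$j,
    X1 = .normalize_index(idx$i, nr),
    X2 = .normalize_index(idx$j, nc),
    y = as.vector(m)
  )
  if (isTRUE(with_derivative)) {
    rec$dy <- as.vector(row_derivative(m))
  }
  structure(list(records = rec, n_rows = nr, n_cols = nc,
                 has_derivative = isTRUE(with_derivative)),
            class = "triplet_dataset")
}

#' Row-wise finite difference of a matrix
#'
#' First derivative of each column with respect to the normalized row
#' coordinate (spacing `2 / (n_rows - 1)`): central differences in the
#' interior, forward/backward at the first/last row.
#'
#' @param m numeric matrix with at least 2 rows.
#' @return A matrix of the same shape as `m`.
#' @export
row_derivative <- function(m) {
  m <- as.matrix(m)
  nr <- nrow(m)
  if (nr < 2L) stop("need at least 2 rows for a row derivative", call. = FALSE)
  h <- 2 / (nr - 1)
  d <- m
  if (nr == 2L) {
    d[1L, ] <- (m[2L, ] - m[1L, ]) / h
    d[2L, ] <- d[1L, ]
  } else {
    d[1L, ] <- (m[2L, ] - m[1L, ]) / h
    d[nr, ] <- (m[nr, ] - m[nr - 1L, ]) / h
    d[2:(nr - 1L), ] <- (m[3:nr, , drop = FALSE] - m[1:(nr - 2L), , drop = FALSE]) / (2 * h)
  }
  d
}

#' @export
print.triplet_dataset <- function(x, ...) {
  cat(sprintf("<triplet_dataset> %d records from a %d x %d matrix%s\n",
              nrow(x$records), x$n_rows, x$n_cols,
              if (x$has_derivative) " (with dy feature)" else ""))
  invisible(x)
}

# Feature matrix fed to the network: columns X1, X2 and, if the dataset
# carries it, dy.
.triplet_features <- function(dataset, use_derivative = dataset$has_derivative) {
  rec <- dataset$records
  if (use_derivative && is.null(rec$dy)) {
    stop("dataset has no `dy` feature; rebuild with with_derivative = TRUE",
         call. = FALSE)
  }
  cols <- c("X1", "X2", if (use_derivative) "dy")
  as.matrix(rec[, cols, drop = FALSE])
}

.subset_triplets <- function(dataset, idx) {
  out <- dataset
  out$records <- dataset$records[idx, , drop = FALSE]
  rownames(out$records) <- NULL
  out
}

#' Split a triplet dataset into training and test portions
#'
#' Seeded uniform shuffle followed by an 80/20 (by default) split, the
#' protocol used when learning formulas from factor matrices.
#'
#' @param dataset a `triplet_dataset`.
#' @param train_frac fraction assigned to the training portion, strictly
#'   between 0 and 1 (default 0.8).
#' @param seed integer seed for the shuffle (required, for reproducibility).
#' @return A list with elements `train` and `test`, both `triplet_dataset`s.
#' @export
split_triplets <- function(dataset, train_frac = 0.8, seed) {
  stopifnot(inherits(dataset, "triplet_dataset"))
  if (missing(seed)) stop("`seed` is required for a reproducible split", call. = FALSE)
  if (!(train_frac > 0 && train_frac < 1)) {
    stop("`train_frac` must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- nrow(dataset$records)
  ord <- with_seed(seed, sample.int(n))
  n_train <- max(1L, min(n - 1L, floor(n * train_frac)))
  list(train = .subset_triplets(dataset, sort(ord[seq_len(n_train)])),
       test  = .subset_triplets(dataset, sort(ord[(n_train + 1L):n])))
}

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
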