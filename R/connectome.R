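# Entropy-based functional connectivity.  Signals are discretized into
# equal-width bins over each series' observed range; marginal and joint
# entropies are plug-in (histogram) estimates in bits, and the mutual
# information between two regions is H(R1) + H(R2) - H(R1, R2).  Because the
# joint histogram reuses the per-axis marginal edges, its marginals coincide
# with the marginal histograms and the plug-in MI is non-negative.

# Bin codes 1..bins; a constant series occupies a single bin.
.bin_series <- function(x, bins) {
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(rep(1L, length(x)))
  edges <- seq(lo, hi, length.out = bins + 1L)
  findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
}

.entropy_from_counts <- function(counts) {
  p <- counts[counts > 0]
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Plug-in Shannon entropy of a signal (bits)
#'
#' Histogram entropy over `bins` equal-width bins spanning the observed
#' range of the series; empty bins contribute nothing and a constant series
#' has entropy 0 by convention (a single occupied bin).
#'
#' @param series numeric vector, length >= 2.
#' @param bins number of bins (>= 2, default 16).
#' @return Entropy in bits, between 0 and `log2(bins)`.
#' @export
marginal_entropy <- function(series, bins = 16L) {
  if (length(series) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  if (any(!is.finite(series))) stop("series contains non-finite values", call. = FALSE)
  .entropy_from_counts(tabulate(.bin_series(series, bins), nbins = bins))
}

#' Plug-in joint entropy of two signals (bits)
#'
#' Entropy of the 2D equal-width histogram (`bins x bins`), with each axis
#' binned over its own observed range exactly as in [marginal_entropy()].
#'
#' @param s1,s2 numeric vectors of equal length.
#' @param bins bins per axis (default 16).
#' @return Joint entropy in bits.
#' @export
joint_entropy <- function(s1, s2, bins = 16L) {
  if (length(s1) != length(s2)) stop("series lengths differ", call. = FALSE)
  if (length(s1) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (bins < 2L) stop("`bins` must be >= 2", call. = FALSE)
  if (any(!is.finite(s1)) || any(!is.finite(s2))) {
    stop("series contain non-finite values", call. = FALSE)
  }
  b1 <- .bin_series(s1, bins)
  b2 <- .bin_series(s2, bins)
  .entropy_from_counts(tabulate((b1 - 1L) * bins + b2, nbins = bins * bins))
}

#' Histogram mutual information between two signals (bits)
#'
#' `MI = H(s1) + H(s2) - H(s1, s2)` with plug-in entropies on matched
#' equal-width bins.  Symmetric in its arguments and non-negative (tiny
#' negative floating-point residue is clamped to zero); `MI(x, x) = H(x)`.
#'
#' @inheritParams joint_entropy
#' @return Mutual information in bits.
#' @export
mutual_information <- function(s1, s2, bins = 16L) {
  mi <- marginal_entropy(s1, bins) + marginal_entropy(s2, bins) -
    joint_entropy(s1, s2, bins)
  max(mi, 0)
}

#' Mean regional time series from a labeled 4D tensor
#'
#' Averages each frame of a `(d1, d2, d3, T)` tensor over the voxels of each
#' ROI of an integer label volume.  Entry `(r, t)` of the result is the mean
#' of frame `t` over the voxels labeled `r`.
#'
#' @param tensor4d a 4-way array (original or reference tensor; the
#'   downstream comparison is agnostic to the source).
#' @param parcellation a parcellation as produced by
#'   [phantom_parcellation()] or assembled from a label volume and an
#'   ROI-to-subnetwork map (list with `labels`, `map`, `n_rois`).
#' @param subject optional subject identifier stored on the result.
#' @param group optional group label stored on the result.
#' @return An object of class `"roi_timeseries"`: a list with the `R x T`
#'   matrix `series`, `subject` and `group`.
#' @export
extract_roi_timeseries <- function(tensor4d, parcellation, subject = NA_character_,
                                   group = NA_character_) {
  d <- dim(tensor4d)
  if (length(d) != 4L) stop("`tensor4d` must be a 4-way array", call. = FALSE)
  labels <- parcellation$labels
  if (!identical(dim(labels), d[1:3])) {
    stop("spatial extents of the tensor and the label volume differ", call. = FALSE)
  }
  R <- parcellation$n_rois
  lab <- as.vector(labels)
  counts <- tabulate(lab[lab > 0L], nbins = R)
  if (any(counts == 0L)) {
    stop("ROI(s) with zero voxels: ", paste(which(counts == 0L), collapse = ", "),
         call. = FALSE)
  }
  vox <- matrix(tensor4d, prod(d[1:3]), d[4])
  keep <- lab > 0L
  sums <- rowsum(vox[keep, , drop = FALSE], group = lab[keep], reorder = TRUE)
  series <- sums / counts
  rownames(series) <- seq_len(R)
  structure(list(series = unname(series), n_rois = R, n_time = d[4],
                 subject = subject, group = group),
            class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d ROIs x %d frames (subject %s, group %s)\n",
              x$n_rois, x$n_time, x$subject, x$group))
  invisible(x)
}

#' Mutual-information connectivity matrix
#'
#' Computes the histogram mutual information for every unordered ROI pair of
#' a regional time-series set and mirrors it into a symmetric `R x R`
#' matrix.  The diagonal holds each ROI's marginal entropy (it is excluded
#' from thresholding and testing).
#'
#' @param ts an `roi_timeseries` (or a plain `R x T` matrix).
#' @param bins histogram bins (default 16).
#' @return A symmetric matrix of class `"connectivity_matrix"` with a
#'   `"bins"` attribute.
#' @export
build_connectivity <- function(ts, bins = 16L) {
  series <- if (inherits(ts, "roi_timeseries")) ts$series else as.matrix(ts)
  R <- nrow(series)
  if (R < 2L) stop("need at least 2 ROIs", call. = FALSE)
  codes <- t(apply(series, 1L, .bin_series, bins = bins))
  h_marg <- apply(codes, 1L, function(b) .entropy_from_counts(tabulate(b, nbins = bins)))
  M <- diag(h_marg)
  nb2 <- bins * bins
  for (p in seq_len(R - 1L)) {
    base <- (codes[p, ] - 1L) * bins
    for (q in (p + 1L):R) {
      hj <- .entropy_from_counts(tabulate(base + codes[q, ], nbins = nb2))
      M[p, q] <- M[q, p] <- max(h_marg[p] + h_marg[q] - hj, 0)
    }
  }
  attr(M, "bins") <- bins
  class(M) <- c("connectivity_matrix", class(M))
  M
}

#' Threshold a connectivity matrix into a binary adjacency
#'
#' An edge is present iff its mutual information strictly exceeds the
#' threshold; the diagonal is excluded.  Thresholding affects only graph
#' rendering and summary counts — group statistics operate on the
#' unthresholded matrices.
#'
#' @param matrix a `connectivity_matrix` (or symmetric numeric matrix).
#' @param threshold finite numeric cut; defaults to the median off-diagonal
#'   value of the matrix.
#' @return An integer 0/1 adjacency matrix with zero diagonal.
#' @export
apply_threshold <- function(matrix, threshold = NULL) {
  M <- unclass(matrix)
  if (is.null(threshold)) threshold <- median(M[upper.tri(M)])
  if (!is.finite(threshold)) stop("`threshold` must be finite", call. = FALSE)
  A <- (M > threshold) * 1L
  diag(A) <- 0L
  storage.mode(A) <- "integer"
  A
}
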