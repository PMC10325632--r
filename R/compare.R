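# Edgewise two-group comparison of connectivity matrices: at every unordered
# ROI pair a linear model of the edge value on a group indicator plus
# optional covariates (ANCOVA); with no covariates this is exactly one-way
# ANOVA, whose F equals the square of the pooled-variance two-sample t.
# Multiple testing over the R(R-1)/2 edges is controlled by the
# Benjamini-Hochberg step-up.

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of a p-value vector with the significance mask at the
#' requested level.  Adjusted values are monotone (enforced by the step-up)
#' and never smaller than the raw p-values.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return A list with `q_values` (BH-adjusted) and `mask`
#'   (`q_values <= q`).
#' @export
fdr_correct <- function(pvalues, q = 0.05) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  qv <- p.adjust(pvalues, method = "BH")
  list(q_values = qv, mask = qv <= q)
}

.stack_edges <- function(mats) {
  R <- nrow(mats[[1]])
  ut <- upper.tri(matrix(0, R, R))
  t(vapply(mats, function(m) unclass(m)[ut], numeric(sum(ut))))
}

#' Edgewise group comparison with FDR control
#'
#' For every unordered edge, fits a linear model of the per-subject edge
#' value on a group indicator plus optional covariates and records the
#' partial F-test p-value for the group effect (ANCOVA).  With no covariates
#' this reduces exactly to one-way ANOVA / the two-sample pooled-variance
#' t-test.  P-values are then Benjamini-Hochberg adjusted over all
#' `R(R-1)/2` edges and the significance mask is taken at `q_values <= q`.
#'
#' @param groupA,groupB lists of per-subject `connectivity_matrix` objects
#'   (at least 2 subjects per group, all sharing the ROI count).
#' @param covariates optional data frame of per-subject covariates, rows
#'   ordered as `c(groupA, groupB)`; the design must be full rank.
#' @param q FDR level (default 0.05).
#' @return An object of class `"edge_comparison"`: a data frame `edges` with
#'   columns `roi_a`, `roi_b`, `diff_mean` (B minus A), `statistic` (F),
#'   `p_value`, `q_value`, `significant`; plus `n_rois`, `q`,
#'   `covariate_names`, and a symmetric logical matrix `significant_matrix`.
#' @export
edgewise_group_comparison <- function(groupA, groupB, covariates = NULL,
                                      q = 0.05) {
  if (length(groupA) < 2L || length(groupB) < 2L) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  R <- nrow(groupA[[1]])
  all_mats <- c(groupA, groupB)
  if (!all(vapply(all_mats, function(m) nrow(m) == R, logical(1)))) {
    stop("connectivity matrices do not share one ROI count", call. = FALSE)
  }
  Y <- .stack_edges(all_mats)                       # subjects x edges
  n <- nrow(Y)
  grp <- factor(rep(c("A", "B"), c(length(groupA), length(groupB))))

  if (is.null(covariates)) {
    X0 <- matrix(1, n, 1)
    cov_names <- character(0)
  } else {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) {
      stop("covariate table must have one row per subject", call. = FALSE)
    }
    X0 <- stats::model.matrix(~ ., data = covariates)
    cov_names <- colnames(covariates)
  }
  X1 <- cbind(X0, group = as.numeric(grp == "B"))
  if (qr(X1)$rank < ncol(X1)) {
    stop("rank-deficient design: covariates are collinear with the intercept or group",
         call. = FALSE)
  }
  df_res <- n - ncol(X1)
  if (df_res < 1L) stop("too few subjects for the covariate design", call. = FALSE)

  rss <- function(X) {
    res <- qr.resid(qr(X), Y)
    colSums(res^2)
  }
  rss0 <- rss(X0)
  rss1 <- rss(X1)
  Fstat <- (rss0 - rss1) / (rss1 / df_res)
  pval <- pf(Fstat, 1, df_res, lower.tail = FALSE)
  adj <- fdr_correct(pval, q = q)

  ut <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  mA <- colMeans(Y[seq_along(groupA), , drop = FALSE])
  mB <- colMeans(Y[length(groupA) + seq_along(groupB), , drop = FALSE])
  edges <- data.frame(roi_a = ut[, 1], roi_b = ut[, 2],
                      diff_mean = mB - mA,
                      statistic = Fstat, p_value = pval,
                      q_value = adj$q_values, significant = adj$mask)
  sig <- matrix(FALSE, R, R)
  sig[cbind(edges$roi_a, edges$roi_b)] <- edges$significant
  sig <- sig | t(sig)
  structure(list(edges = edges, n_rois = R, q = q,
                 covariate_names = cov_names,
                 significant_matrix = sig),
            class = "edge_comparison")
}

#' @export
print.edge_comparison <- function(x, ...) {
  cat(sprintf("<edge_comparison> %d ROIs, %d edges, %d significant at FDR q = %g%s\n",
              x$n_rois, nrow(x$edges), sum(x$edges$significant), x$q,
              if (length(x$covariate_names))
                paste0(" (covariates: ", paste(x$covariate_names, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Subnetwork block summary (8 x 8 by default)
#'
#' Aggregates edgewise results over the subnetwork partition of the
#' parcellation: for an `edge_comparison`, the count of significant edges
#' within and between each subnetwork pair; for a `connectivity_matrix`, the
#' mean mutual information per block (diagonal blocks average distinct pairs
#' only).  The returned matrix is symmetric, with subnetworks ordered as in
#' the parcellation map.
#'
#' @param x an `edge_comparison` or `connectivity_matrix`.
#' @param parcellation a parcellation whose `map` assigns every ROI to a
#'   subnetwork.
#' @return A symmetric `S x S` matrix (S = number of subnetworks) with
#'   dimnames.
#' @export
subnetwork_summary <- function(x, parcellation) {
  map <- parcellation$map
  R <- parcellation$n_rois
  if (nrow(map) != R || anyNA(map$subnetwork)) {
    stop("every ROI must have exactly one subnetwork assignment", call. = FALSE)
  }
  sub <- map$subnetwork[order(map$roi_id)]
  nets <- unique(sub)
  S <- length(nets)
  net_of <- match(sub, nets)

  if (inherits(x, "edge_comparison")) {
    if (x$n_rois != R) stop("ROI counts differ between result and parcellation", call. = FALSE)
    out <- matrix(0, S, S, dimnames = list(nets, nets))
    sig <- x$edges[x$edges$significant, , drop = FALSE]
    for (k in seq_len(nrow(sig))) {
      a <- net_of[sig$roi_a[k]]; b <- net_of[sig$roi_b[k]]
      out[a, b] <- out[a, b] + 1
      if (a != b) out[b, a] <- out[b, a] + 1
    }
    return(out)
  }
  M <- unclass(x)
  if (nrow(M) != R) stop("ROI counts differ between matrix and parcellation", call. = FALSE)
  out <- matrix(NA_real_, S, S, dimnames = list(nets, nets))
  for (a in seq_len(S)) {
    for (b in a:S) {
      ia <- which(net_of == a); ib <- which(net_of == b)
      block <- M[ia, ib, drop = FALSE]
      vals <- if (a == b) block[upper.tri(block)] else as.vector(block)
      out[a, b] <- out[b, a] <- if (length(vals)) mean(vals) else NA_real_
    }
  }
  out
}
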