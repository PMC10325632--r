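# Seeded synthetic generators: factor surfaces from the six built-in
# closed-form equations (coronal/sagittal/axial plane x autism/control
# group), random factorized tensors, phantom parcellations, and two-group
# regional time series with planted connectivity differences.  Every
# generator is a pure function of its arguments including the seed.

# The six built-in factor-surface equations.  The printed sources lost their
# typography, so juxtaposition is read as multiplication and a bare leading
# "1" before a delimited expression as a reciprocal; the transcriptions are
# documented in the methods vignette.  All evaluations go through the same
# safeguarded operators as the equation learner, so every surface is finite.
.surface_grid_fns <- list(
  "coronal-autism" = function(X1, X2) {
    0.14 * cos(sin(logabs(-0.165 * cos(0.05 * X1))) - 0.11 * X2)
  },
  "coronal-normal" = function(X1, X2) {
    sdiv(1, abs(relu(sin((1 / 0.624) * X2))^0.568 + X1 - 5.29))
  },
  "sagittal-autism" = function(X1, X2) {
    cos(abs(27.709 + relu(sin(X1 + cos(abs(4.71 * X2))))))
  },
  "sagittal-normal" = function(X1, X2) {
    cos(sexp(0.017 * logabs(X1 * X2 - 4.2 * X2)))
  },
  "axial-normal" = function(X1, X2) {
    sin(cos(17.65 * abs(logabs(X1))) * sin(X2))
  }
)

# The axial/autism equation is implicit in y (it contains the first-order
# differential y').  It is generated as a forward recursion in the row
# index: with y' ~ (y[i+1] - y[i]) / h in normalized row coordinates
# (h = 2 / (n_rows - 1)) and y = 0.431 y' - 0.055 g(X1, X2), rearranging
# gives y[i+1] = y[i] + (h / 0.431) (y[i] + 0.055 g[i]); the first row is
# the non-derivative part -0.055 g[1].
.axial_autism_surface <- function(n_rows, n_cols) {
  X1 <- .normalize_index(seq_len(n_rows), n_rows)
  X2 <- .normalize_index(seq_len(n_cols), n_cols)
  g <- outer(X1, X2, function(a, b) {
    cos(sdiv(1, a) * sexp(cos(sdiv(1, a))) + b)
  })
  h <- 2 / (n_rows - 1)
  y <- matrix(0, n_rows, n_cols)
  y[1L, ] <- -0.055 * g[1L, ]
  for (i in seq_len(n_rows - 1L)) {
    y[i + 1L, ] <- y[i, ] + (h / 0.431) * (y[i, ] + 0.055 * g[i, ])
  }
  y
}

#' Names of the built-in factor-surface equations
#' @return Character vector of the six built-in identifiers.
#' @export
surface_builtins <- function() {
  c(names(.surface_grid_fns)[1:4], "axial-autism", "axial-normal")
}

#' Generate a factor surface from a closed-form equation
#'
#' Evaluates one of the six built-in factor-matrix equations (or a user
#' expression over `X1` and `X2`) on the normalized `[-1, 1]` coordinate
#' grid, optionally adds seeded Gaussian noise, and returns both the matrix
#' and its coordinate-encoded triplet form.  The derivative-bearing built-in
#' (`"axial-autism"`) is generated by the forward row recursion documented
#' in the package vignette.
#'
#' @param formula a built-in identifier (see [surface_builtins()]) or a
#'   string expression over `X1`, `X2` (safeguarded operators `logabs`,
#'   `sdiv`, `sexp`, `relu` are available).
#' @param n_rows,n_cols grid shape (default 100 x 100; at least 10 rows
#'   recommended for the derivative-bearing equation).
#' @param noise_sd absolute standard deviation of additive Gaussian noise
#'   (default 0).
#' @param noise_frac if given, overrides `noise_sd` with this fraction of
#'   the noise-free value range.
#' @param seed integer seed for the noise (default 1).
#' @param with_derivative attach the `dy` feature to the triplets
#'   (default `FALSE`).
#' @return An object of class `"formula_surface"`: `values` (the matrix),
#'   `triplets` (a `triplet_dataset`), `formula`, `noise_sd` (the absolute
#'   SD actually used), and `seed`.
#' @examples
#' s <- formula_surface("X1 + X2", n_rows = 3, n_cols = 3)
#' s$values
#' @export
formula_surface <- function(formula, n_rows = 100L, n_cols = 100L,
                            noise_sd = 0, noise_frac = NULL, seed = 1L,
                            with_derivative = FALSE) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 2L || n_cols < 2L) stop("grid must be at least 2 x 2", call. = FALSE)
  if (formula %in% names(.surface_grid_fns)) {
    X1 <- .normalize_index(seq_len(n_rows), n_rows)
    X2 <- .normalize_index(seq_len(n_cols), n_cols)
    values <- outer(X1, X2, .surface_grid_fns[[formula]])
  } else if (formula == "axial-autism") {
    values <- .axial_autism_surface(n_rows, n_cols)
  } else if (grepl("X1|X2", formula)) {
    expr <- tryCatch(str2lang(formula),
                     error = function(e) stop("cannot parse expression: ",
                                              formula, call. = FALSE))
    X1g <- matrix(.normalize_index(seq_len(n_rows), n_rows), n_rows, n_cols)
    X2g <- matrix(.normalize_index(seq_len(n_cols), n_cols), n_rows, n_cols,
                  byrow = TRUE)
    env <- list2env(list(X1 = X1g, X2 = X2g), parent = .fold_env())
    values <- eval(expr, env)
    if (length(values) == 1L) values <- matrix(values, n_rows, n_cols)
    values <- matrix(values, n_rows, n_cols)
  } else {
    stop("unknown surface '", formula, "'; built-ins are: ",
         paste(surface_builtins(), collapse = ", "), call. = FALSE)
  }
  if (!is.null(noise_frac)) noise_sd <- noise_frac * (max(values) - min(values))
  if (noise_sd > 0) {
    values <- values + with_seed(seed, matrix(rnorm(length(values), sd = noise_sd),
                                              n_rows, n_cols))
  }
  structure(list(values = values,
                 triplets = matrix_to_triplets(values, with_derivative = with_derivative),
                 formula = formula, noise_sd = noise_sd, seed = seed),
            class = "formula_surface")
}

#' @export
print.formula_surface <- function(x, ...) {
  cat(sprintf("<formula_surface> '%s' on %d x %d grid (noise sd %.4g, seed %d)\n",
              x$formula, nrow(x$values), ncol(x$values), x$noise_sd, x$seed))
  invisible(x)
}

#' Random factorized tensor fixture
#'
#' Draws a seeded random core tensor and three seeded factor matrices and
#' returns them together with the volume they reconstruct, so round-trip
#' properties of the factor fitter can be tested without any data.
#'
#' @param dims volume extents `(d1, d2, d3)`.
#' @param ranks mode ranks, each at most the matching extent.
#' @param seed integer seed.
#' @return A list with `core`, `factors` (list of three matrices), and
#'   `volume` (exactly `reconstruct_frame(core, factors)`).
#' @export
random_factor_tensor <- function(dims, ranks, seed = 1L) {
  dims <- as.integer(dims); ranks <- as.integer(ranks)
  if (length(dims) != 3L || length(ranks) != 3L) {
    stop("`dims` and `ranks` must have length 3", call. = FALSE)
  }
  if (any(ranks > dims)) stop("ranks must not exceed dims", call. = FALSE)
  with_seed(seed, {
    core <- array(rnorm(prod(ranks)), ranks)
    factors <- lapply(1:3, function(m) matrix(rnorm(dims[m] * ranks[m]),
                                              dims[m], ranks[m]))
    list(core = core, factors = factors,
         volume = reconstruct_frame(core, factors))
  })
}

#' Phantom parcellation (synthetic label volume)
#'
#' Seeded Voronoi-style parcellation of a voxel grid into `n_rois` regions:
#' `n_rois` distinct centroid voxels are drawn and every voxel is assigned
#' to its nearest centroid, so every label occupies at least one voxel.  The
#' ROI-to-subnetwork map partitions the ROI ids into (up to) eight
#' contiguous blocks named DMN, AN, VN, SMN, BiN, SCN, CCN, and Cerebellum.
#' This is a synthetic stand-in for an anatomical parcellation, not an
#' anatomical atlas.
#'
#' @param dims voxel grid extents `(d1, d2, d3)`.
#' @param n_rois number of regions (default 116); must not exceed the voxel
#'   count.
#' @param seed integer seed.
#' @return An object of class `"parcellation"`: integer `labels` array,
#'   data frame `map` (`roi_id`, `roi_name`, `subnetwork`), and `n_rois`.
#' @export
phantom_parcellation <- function(dims, n_rois = 116L, seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L) stop("`dims` must have length 3", call. = FALSE)
  n_vox <- prod(dims)
  n_rois <- as.integer(n_rois)
  if (n_rois < 1L || n_rois > n_vox) {
    stop(sprintf("need at least %d voxels for %d ROIs", n_rois, n_rois),
         call. = FALSE)
  }
  coords <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                                  z = seq_len(dims[3])))
  centroid_idx <- with_seed(seed, sample.int(n_vox, n_rois))
  cen <- coords[centroid_idx, , drop = FALSE]
  # nearest centroid per voxel (squared Euclidean, ties to the lower id)
  d2 <- outer(rowSums(coords^2), rep(1, n_rois)) -
    2 * coords %*% t(cen) +
    outer(rep(1, n_vox), rowSums(cen^2))
  labels <- array(max.col(-d2, ties.method = "first"), dims)
  nets <- c("DMN", "AN", "VN", "SMN", "BiN", "SCN", "CCN", "Cerebellum")
  n_nets <- min(length(nets), n_rois)
  block <- sort(rep_len(seq_len(n_nets), n_rois))
  map <- data.frame(roi_id = seq_len(n_rois),
                    roi_name = sprintf("ROI_%03d", seq_len(n_rois)),
                    subnetwork = nets[block],
                    stringsAsFactors = FALSE)
  structure(list(labels = labels, map = map, n_rois = n_rois, seed = seed),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d ROIs on a %s grid, %d subnetworks\n",
              x$n_rois, paste(dim(x$labels), collapse = " x "),
              length(unique(x$map$subnetwork))))
  invisible(x)
}

#' Specification of a two-group simulation with planted edges
#'
#' @param n_rois number of regions.
#' @param n_time frames per subject (>= 50 recommended for stable MI
#'   estimates).
#' @param n_per_group subjects per group.
#' @param edges two-column matrix of ROI pairs whose dependence is
#'   strengthened in group B (`NULL` for none).
#' @param effect_size planted MI shift in pooled-SD units of the null MI
#'   sampling distribution (>= 0).
#' @param base_cor weight of a common latent signal mixed into every ROI of
#'   both groups (default 0 = independent baseline).
#' @param bins histogram bins assumed downstream (used when calibrating the
#'   planted effect; default 16).
#' @param seed integer seed.
#' @return An object of class `"planted_difference_spec"`.
#' @export
planted_difference_spec <- function(n_rois, n_time = 100L, n_per_group = 20L,
                                    edges = NULL, effect_size = 0,
                                    base_cor = 0, bins = 16L, seed = 1L) {
  if (effect_size < 0) stop("`effect_size` must be >= 0", call. = FALSE)
  if (!is.null(edges)) {
    edges <- matrix(as.integer(edges), ncol = 2L)
    bad <- edges[, 1] == edges[, 2] |
      edges < 1L | edges > as.integer(n_rois)
    if (any(bad)) stop("invalid planted edge list", call. = FALSE)
  }
  structure(list(n_rois = as.integer(n_rois), n_time = as.integer(n_time),
                 n_per_group = as.integer(n_per_group), edges = edges,
                 effect_size = effect_size, base_cor = base_cor,
                 bins = as.integer(bins), seed = as.integer(seed)),
            class = "planted_difference_spec")
}

# Monte-Carlo calibration: find the latent-mixing weight whose expected
# plug-in MI sits `effect` null-SDs above the null mean for this (T, bins).
.calibrate_mixing <- function(n_time, bins, effect, seed) {
  with_seed(seed, {
    null_mi <- replicate(150, mutual_information(rnorm(n_time), rnorm(n_time),
                                                 bins = bins))
    m0 <- mean(null_mi); s0 <- sd(null_mi)
    target <- m0 + effect * s0
    ws <- seq(0.1, 0.95, by = 0.05)
    means <- vapply(ws, function(w) {
      mean(replicate(30, {
        z <- rnorm(n_time)
        a <- sqrt(1 - w) * rnorm(n_time) + sqrt(w) * z
        b <- sqrt(1 - w) * rnorm(n_time) + sqrt(w) * z
        mutual_information(a, b, bins = bins)
      }))
    }, numeric(1))
    if (target >= max(means)) return(max(ws))
    if (target <= means[1]) return(ws[1])
    stats::approx(means, ws, xout = target, ties = mean)$y
  })
}

#' Simulate two groups of regional time series with planted edges
#'
#' Both groups share the base structure (independent standard-normal ROI
#' series, optionally mixed with a common latent signal).  In group B, each
#' planted edge additionally mixes a shared latent source into its two ROIs
#' with a weight calibrated by Monte Carlo so that the expected plug-in MI
#' of the edge sits `effect_size` null-SDs above the null MI mean for the
#' spec's `n_time` and `bins`.  With `effect_size = 0` the two groups are
#' exchangeable.  Fully deterministic given the spec (seed included).
#'
#' @param spec a [planted_difference_spec()].
#' @return A list with `groupA` and `groupB` (lists of `roi_timeseries`),
#'   and the calibrated `mixing_weight`.
#' @export
group_timeseries <- function(spec) {
  stopifnot(inherits(spec, "planted_difference_spec"))
  w <- if (is.null(spec$edges) || spec$effect_size == 0) 0 else {
    .calibrate_mixing(spec$n_time, spec$bins, spec$effect_size,
                      seed = spec$seed + 424243L)
  }
  gen_subject <- function(planted) {
    x <- matrix(rnorm(spec$n_rois * spec$n_time), spec$n_rois, spec$n_time)
    if (spec$base_cor > 0) {
      zg <- rnorm(spec$n_time)
      x <- sqrt(1 - spec$base_cor) * x +
        sqrt(spec$base_cor) * matrix(zg, spec$n_rois, spec$n_time, byrow = TRUE)
    }
    if (planted && w > 0) {
      for (k in seq_len(nrow(spec$edges))) {
        z <- rnorm(spec$n_time)
        for (roi in spec$edges[k, ]) {
          x[roi, ] <- sqrt(1 - w) * x[roi, ] + sqrt(w) * z
        }
      }
    }
    x
  }
  with_seed(spec$seed, {
    groupA <- lapply(seq_len(spec$n_per_group), function(s) {
      structure(list(series = gen_subject(FALSE), n_rois = spec$n_rois,
                     n_time = spec$n_time, subject = sprintf("A%02d", s),
                     group = "A"), class = "roi_timeseries")
    })
    groupB <- lapply(seq_len(spec$n_per_group), function(s) {
      structure(list(series = gen_subject(TRUE), n_rois = spec$n_rois,
                     n_time = spec$n_time, subject = sprintf("B%02d", s),
                     group = "B"), class = "roi_timeseries")
    })
    list(groupA = groupA, groupB = groupB, mixing_weight = w)
  })
}
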