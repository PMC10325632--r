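# Synthetic generators: factor surfaces, phantom parcellations, and
# two-group time series with planted dependence.

test_that("surfaces are pure functions of their spec", {
  a <- formula_surface("sagittal-normal", 20, 20, noise_frac = 0.01, seed = 3)
  b <- formula_surface("sagittal-normal", 20, 20, noise_frac = 0.01, seed = 3)
  expect_identical(a$values, b$values)
  c <- formula_surface("sagittal-normal", 20, 20, noise_frac = 0.01, seed = 4)
  expect_false(identical(a$values, c$values))
  expect_error(formula_surface("no-such-surface", 10, 10), "built-ins")
})

test_that("noise-free surfaces match direct expression evaluation", {
  # mid-grid point of the safeguarded sagittal/control equation: at
  # (X1, X2) = (0, 0) the log floor makes it cos(exp(0.017 * log(1e-3)))
  s <- formula_surface("sagittal-normal", 21, 21)
  expect_equal(s$values[11, 11], cos(exp(0.017 * log(1e-3))), tolerance = 1e-12)
  expect_true(all(is.finite(s$values)))
  # all six built-ins are finite and reproducible at small sizes
  for (f in surface_builtins()) {
    v <- formula_surface(f, 15, 15)$values
    expect_true(all(is.finite(v)))
  }
  # spot-check another equation against a hand evaluation
  s2 <- formula_surface("coronal-autism", 21, 21)
  x1 <- 0; x2 <- 0
  expect_equal(s2$values[11, 11],
               0.14 * cos(sin(log(abs(-0.165 * cos(0.05 * x1)))) - 0.11 * x2),
               tolerance = 1e-12)
})

test_that("user expressions evaluate on the normalized grid", {
  s <- formula_surface("X1 + X2", 3, 3)
  expect_equal(s$values, outer(c(-1, 0, 1), c(-1, 0, 1), `+`))
  expect_equal(nrow(s$triplets$records), 9L)
})

test_that("derivative-bearing surface satisfies its implicit equation", {
  s <- formula_surface("axial-autism", 60, 40)
  y <- s$values
  h <- 2 / (nrow(y) - 1)
  X1 <- seq(-1, 1, length.out = nrow(y))
  X2 <- seq(-1, 1, length.out = ncol(y))
  g <- outer(X1, X2, function(a, b) cos(sdiv(1, a) * sexp(cos(sdiv(1, a))) + b))
  # forward-difference derivative satisfies y = 0.431 y' - 0.055 g row-wise
  fwd <- (y[-1, ] - y[-nrow(y), ]) / h
  lhs <- y[-nrow(y), ]
  expect_equal(lhs, 0.431 * fwd - 0.055 * g[-nrow(y), ], tolerance = 1e-9)
})

test_that("phantom parcellations cover every ROI and are seeded", {
  parc <- phantom_parcellation(c(10, 10, 10), n_rois = 116, seed = 2)
  counts <- tabulate(parc$labels, nbins = 116)
  expect_equal(sum(counts > 0), 116L)
  expect_equal(nrow(parc$map), 116L)
  expect_equal(sort(unique(parc$map$subnetwork)),
               sort(c("DMN", "AN", "VN", "SMN", "BiN", "SCN", "CCN",
                      "Cerebellum")))
  again <- phantom_parcellation(c(10, 10, 10), n_rois = 116, seed = 2)
  expect_identical(parc$labels, again$labels)
  one <- phantom_parcellation(c(3, 3, 3), n_rois = 1, seed = 1)
  expect_true(all(one$labels == 1L))
  expect_error(phantom_parcellation(c(2, 2, 2), n_rois = 9, seed = 1),
               "voxels")
})

test_that("parcellations round-trip through NIfTI + TSV", {
  parc <- phantom_parcellation(c(6, 5, 4), n_rois = 10, seed = 3)
  labs <- withr::local_tempfile(fileext = ".nii.gz")
  mapp <- withr::local_tempfile(fileext = ".tsv")
  write_parcellation(parc, labs, mapp)
  back <- read_parcellation(labs, mapp)
  expect_identical(back$labels, parc$labels)
  expect_equal(back$map$subnetwork, parc$map$subnetwork)
})

test_that("group simulation is reproducible and exchangeable at effect 0", {
  spec <- planted_difference_spec(n_rois = 6, n_time = 80, n_per_group = 4,
                                  effect_size = 0, seed = 5)
  g1 <- group_timeseries(spec)
  g2 <- group_timeseries(spec)
  expect_identical(g1$groupA[[2]]$series, g2$groupA[[2]]$series)
  expect_identical(g1$groupB[[3]]$series, g2$groupB[[3]]$series)
  expect_equal(g1$mixing_weight, 0)
  expect_error(planted_difference_spec(n_rois = 4, edges = cbind(1, 5),
                                       effect_size = 2, seed = 1),
               "edge")
})

test_that("a large planted effect raises the target edge's MI", {
  spec <- planted_difference_spec(n_rois = 5, n_time = 120, n_per_group = 8,
                                  edges = cbind(2, 4), effect_size = 5,
                                  seed = 6)
  g <- group_timeseries(spec)
  expect_gt(g$mixing_weight, 0.1)
  mi_edge <- function(subjects) {
    mean(vapply(subjects, function(s) {
      mutual_information(s$series[2, ], s$series[4, ], bins = 16)
    }, numeric(1)))
  }
  # the planted edge separates the groups; an unplanted edge does not
  expect_gt(mi_edge(g$groupB) - mi_edge(g$groupA), 0.05)
  mi_other <- function(subjects) {
    mean(vapply(subjects, function(s) {
      mutual_information(s$series[1, ], s$series[3, ], bins = 16)
    }, numeric(1)))
  }
  expect_lt(abs(mi_other(g$groupB) - mi_other(g$groupA)), 0.05)
})
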