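# Histogram entropies, mutual information, and connectivity matrices.

test_that("marginal entropy matches hand-computed histograms", {
  expect_equal(marginal_entropy(rep(c(0, 1), 10), bins = 2), 1.0)
  expect_equal(marginal_entropy(rep(5, 10)), 0)
  expect_equal(marginal_entropy(rep(c(1, 2, 3, 4), 25), bins = 4), 2.0)
  expect_true(marginal_entropy(rnorm(100), bins = 8) <= log2(8))
  expect_error(marginal_entropy(1), "at least 2")
  expect_error(marginal_entropy(c(1, 2), bins = 1), "bins")
})

test_that("joint entropy is symmetric and collapses on identical series", {
  x <- rnorm(200)
  expect_equal(joint_entropy(x, x, 8), marginal_entropy(x, 8), tolerance = 1e-12)
  y <- rnorm(200)
  expect_equal(joint_entropy(x, y, 8), joint_entropy(y, x, 8), tolerance = 1e-12)
  # jointly uniform over a 2x2 grid: 2 bits
  s1 <- rep(c(0, 0, 1, 1), 25)
  s2 <- rep(c(0, 1, 0, 1), 25)
  expect_equal(joint_entropy(s1, s2, bins = 2), 2.0)
  expect_lte(joint_entropy(x, y, 8),
             marginal_entropy(x, 8) + marginal_entropy(y, 8) + 1e-12)
  expect_error(joint_entropy(x, y[-1], 8), "lengths differ")
})

test_that("mutual information: self-information, symmetry, non-negativity", {
  x <- rnorm(300)
  expect_equal(mutual_information(x, x, 16), marginal_entropy(x, 16),
               tolerance = 1e-12)
  # strictly monotone transform with matched binning preserves MI = H
  expect_equal(mutual_information(x, -x, 16), marginal_entropy(x, 16),
               tolerance = 1e-12)
  set.seed(8)
  for (rep in 1:20) {
    a <- rnorm(60); b <- runif(60)
    bins <- sample(2:16, 1)
    mi <- mutual_information(a, b, bins = bins)
    expect_gte(mi, 0)
    expect_equal(mi, mutual_information(b, a, bins = bins), tolerance = 1e-12)
  }
})

test_that("independent series have near-zero MI at large samples", {
  set.seed(10)
  mi <- mutual_information(runif(1e5), runif(1e5), bins = 8)
  expect_lt(mi, 0.01)
})

test_that("ROI extraction averages voxels per region", {
  # two-voxel ROI with traces (1,3) and (3,5) -> series (2,4)
  labels <- array(0L, c(2, 2, 1))
  labels[1, 1, 1] <- 1L; labels[2, 1, 1] <- 1L; labels[1, 2, 1] <- 2L
  labels[2, 2, 1] <- 2L
  x4 <- array(0, c(2, 2, 1, 2))
  x4[1, 1, 1, ] <- c(1, 3); x4[2, 1, 1, ] <- c(3, 5)   # ROI 1
  x4[1, 2, 1, ] <- c(7, 7); x4[2, 2, 1, ] <- c(9, 9)   # ROI 2
  parc <- list(labels = labels, n_rois = 2L,
               map = data.frame(roi_id = 1:2, roi_name = c("a", "b"),
                                subnetwork = c("DMN", "VN")))
  ts <- extract_roi_timeseries(x4, parc)
  expect_equal(ts$series[1, ], c(2, 4))
  expect_equal(ts$series[2, ], c(8, 8))
  # constant volume -> constant series
  x4c <- array(3.5, c(2, 2, 1, 4))
  expect_true(all(extract_roi_timeseries(x4c, parc)$series == 3.5))
  # missing ROI voxels are reported by id
  parc3 <- parc; parc3$n_rois <- 3L
  expect_error(extract_roi_timeseries(x4, parc3), "3")
  expect_error(extract_roi_timeseries(array(0, c(3, 2, 1, 2)), parc),
               "extents")
})

test_that("connectivity matrices are symmetric with entropies on the diagonal", {
  set.seed(11)
  series <- matrix(rnorm(5 * 120), 5, 120)
  series[2, ] <- series[1, ]  # duplicate ROI rows
  M <- build_connectivity(series, bins = 8)
  expect_equal(dim(M), c(5L, 5L))
  expect_equal(unclass(M), t(unclass(M)), tolerance = 1e-12)
  expect_true(all(M[upper.tri(M)] >= 0))
  for (r in 1:5) {
    expect_equal(M[r, r], marginal_entropy(series[r, ], 8), tolerance = 1e-12)
  }
  # the duplicated pair carries its full marginal entropy off-diagonal
  expect_equal(M[1, 2], M[1, 1], tolerance = 1e-12)
  expect_error(build_connectivity(series[1, , drop = FALSE]), "at least 2")
})

test_that("thresholding is strict and excludes the diagonal", {
  M <- matrix(c(1, 0.4, 0.2, 0.4, 1, 0.6, 0.2, 0.6, 1), 3, 3)
  A <- apply_threshold(M, 0.1)
  expect_equal(diag(A), rep(0L, 3))
  expect_equal(sum(A) / 2, 3)          # all edges pass
  expect_equal(sum(apply_threshold(M, 0.9)), 0)  # none pass
  # boundary: an edge exactly at the threshold is absent
  expect_equal(apply_threshold(M, 0.4)[1, 2], 0L)
  expect_equal(apply_threshold(M, 0.4)[2, 3], 1L)
})

test_that("connectivity matrices round-trip through TSV", {
  M <- build_connectivity(matrix(rnorm(3 * 50), 3, 50), bins = 6)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity(M, p)
  back <- read_connectivity(p)
  expect_equal(unclass(back), unclass(M), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "bins"), 6L)
})
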