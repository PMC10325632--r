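# Mode-product algebra, frame splitting/merging, and the factor fitter.

test_that("mode products agree with the brute-force oracle", {
  set.seed(3)
  for (rep in 1:4) {
    d <- sample(2:5, 3, replace = TRUE)
    x <- array(rnorm(prod(d)), d)
    mode <- sample(1:3, 1)
    m <- matrix(rnorm(4 * d[mode]), 4, d[mode])
    expect_lt(max(abs(mode_product(x, m, mode) -
                        naive_mode_product(x, m, mode))), 1e-10)
  }
})

test_that("identity matrices and commuting modes behave algebraically", {
  set.seed(4)
  x <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
  for (mode in 1:3) {
    expect_equal(mode_product(x, diag(dim(x)[mode]), mode), x,
                 tolerance = 1e-14)
  }
  a <- matrix(rnorm(4), 2, 2)
  b <- matrix(rnorm(9), 3, 3)
  expect_equal(mode_product(mode_product(x, a, 1), b, 2),
               mode_product(mode_product(x, b, 2), a, 1), tolerance = 1e-12)
  # doubling along mode 1 of an all-ones core doubles every entry
  g <- array(1, c(2, 2, 2))
  expect_equal(mode_product(g, 2 * diag(2), 1), 2 * g, tolerance = 1e-14)
  expect_error(mode_product(x, matrix(1, 2, 5), 1), "mode 1")
})

test_that("rank-one reconstruction is the outer product", {
  u <- rnorm(4); v <- rnorm(5); w <- rnorm(6)
  g <- core_tensor(c(1, 1, 1))
  x <- reconstruct_frame(g, list(cbind(u), cbind(v), cbind(w)))
  expect_equal(x, outer(outer(u, v), w), tolerance = 1e-12)
})

test_that("reconstruction is deterministic and multilinear in each factor", {
  rt <- random_factor_tensor(c(4, 5, 6), c(2, 2, 2), seed = 9)
  again <- random_factor_tensor(c(4, 5, 6), c(2, 2, 2), seed = 9)
  expect_identical(rt$volume, again$volume)
  scaled <- rt$factors
  scaled[[2]] <- 3 * scaled[[2]]
  expect_equal(reconstruct_frame(rt$core, scaled), 3 * rt$volume,
               tolerance = 1e-12)
})

test_that("split and merge are exact inverses", {
  set.seed(5)
  x4 <- array(rnorm(4 * 4 * 4 * 3), c(4, 4, 4, 3))
  frames <- split_frames(x4)
  expect_length(frames, 3L)
  expect_equal(dim(frames[[1]]), c(4, 4, 4))
  expect_identical(merge_frames(frames), x4)
  one <- array(rnorm(8), c(2, 2, 2, 1))
  expect_identical(merge_frames(split_frames(one)), one)
  expect_error(split_frames(array(0, c(2, 2, 2))), "4-way")
})

test_that("factor fitting recovers the reconstruction on synthetic frames", {
  rt <- random_factor_tensor(c(7, 8, 6), c(2, 2, 2), seed = 21)
  fit <- fit_factors(rt$volume, rt$core, seed = 2, max_iter = 400)
  expect_lt(fit$relative_error, 1e-3)
  expect_true(all(diff(fit$loss_history) <= 1e-12))
  # reproducibility of the whole trajectory
  fit2 <- fit_factors(rt$volume, rt$core, seed = 2, max_iter = 400)
  expect_identical(fit$loss_history, fit2$loss_history)
})

test_that("full-rank frames inside the core's orbit factor to ~zero loss", {
  # with ranks equal to the extents the factorization is unconstrained on
  # the core's orbit; build the frame from invertible square factors
  rt <- random_factor_tensor(c(3, 4, 3), c(3, 4, 3), seed = 31)
  fit <- fit_factors(rt$volume, rt$core, seed = 1, n_starts = 10, max_iter = 300)
  expect_lt(fit$relative_error, 1e-3)
  expect_error(fit_factors(rt$volume, core_tensor(c(4, 3, 3))), "ranks")
})

test_that("tensors round-trip through NIfTI", {
  x4 <- array(rnorm(2 * 3 * 4 * 2), c(2, 3, 4, 2))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_tensor_nifti(x4, p)
  expect_equal(read_tensor_nifti(p), x4, tolerance = 1e-6)
})
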