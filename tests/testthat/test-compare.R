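# Edgewise group comparison, BH correction, and subnetwork summaries.

make_group <- function(n, R = 4, T = 60, shift_edge = NULL, shift = 0) {
  lapply(seq_len(n), function(s) {
    x <- matrix(rnorm(R * T), R, T)
    M <- build_connectivity(x, bins = 8)
    if (!is.null(shift_edge)) {
      M[shift_edge[1], shift_edge[2]] <- M[shift_edge[1], shift_edge[2]] + shift
      M[shift_edge[2], shift_edge[1]] <- M[shift_edge[1], shift_edge[2]]
    }
    M
  })
}

test_that("BH step-up matches the hand-computed example", {
  # step-up: largest k with p_(k) <= k q / m; here k = 2 (0.04 > 3/4 * 0.05)
  res <- fdr_correct(c(0.01, 0.02, 0.04, 0.8), q = 0.05)
  expect_equal(res$mask, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$q_values, c(0.04, 0.04, 0.04 * 4 / 3, 0.8),
               tolerance = 1e-12)
  expect_true(all(res$q_values >= c(0.01, 0.02, 0.04, 0.8)))
  all_small <- fdr_correct(rep(0.001, 10), q = 0.05)
  expect_true(all(all_small$mask))
  expect_error(fdr_correct(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("BH on uniform nulls keeps the rejection rate near the level", {
  set.seed(12)
  any_rej <- replicate(200, any(fdr_correct(runif(500), q = 0.05)$mask))
  # under the global null the false-discovery proportion is 1{any rejection};
  # its mean should sit at ~q for independent uniforms
  expect_lt(mean(any_rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("edgewise p-values equal the two-sample t-test without covariates", {
  set.seed(13)
  gA <- make_group(6); gB <- make_group(7)
  cmp <- edgewise_group_comparison(gA, gB)
  ut <- which(upper.tri(matrix(0, 4, 4)), arr.ind = TRUE)
  for (k in seq_len(nrow(ut))) {
    a <- vapply(gA, function(m) m[ut[k, 1], ut[k, 2]], numeric(1))
    b <- vapply(gB, function(m) m[ut[k, 1], ut[k, 2]], numeric(1))
    tt <- t.test(b, a, var.equal = TRUE)
    expect_lt(abs(cmp$edges$p_value[k] - tt$p.value), 1e-10)
    expect_lt(abs(cmp$edges$statistic[k] - tt$statistic^2), 1e-8)
  }
})

test_that("identical groups produce no significant edges", {
  set.seed(14)
  g <- make_group(5)
  cmp <- edgewise_group_comparison(g, g)
  expect_false(any(cmp$edges$significant))
  expect_true(all(cmp$edges$q_value >= cmp$edges$p_value - 1e-15))
})

test_that("covariates enter the design and rank deficiency is an error", {
  set.seed(15)
  gA <- make_group(6); gB <- make_group(6)
  cov_ok <- data.frame(age = rnorm(12), sex = rep(c(0, 1), 6))
  cmp <- edgewise_group_comparison(gA, gB, covariates = cov_ok)
  expect_equal(cmp$covariate_names, c("age", "sex"))
  expect_true(all(is.finite(cmp$edges$p_value)))
  # a covariate identical to the group indicator is collinear
  cov_bad <- data.frame(dup = rep(c(0, 1), each = 6))
  expect_error(edgewise_group_comparison(gA, gB, covariates = cov_bad),
               "rank-deficient")
  expect_error(edgewise_group_comparison(gA[1], gB), "at least 2")
})

test_that("a strongly shifted edge is detected and localized", {
  set.seed(16)
  gA <- make_group(10, R = 5)
  gB <- make_group(10, R = 5, shift_edge = c(2, 4), shift = 1.5)
  cmp <- edgewise_group_comparison(gA, gB)
  hit <- cmp$edges[cmp$edges$roi_a == 2 & cmp$edges$roi_b == 4, ]
  expect_true(hit$significant)
  expect_gt(hit$diff_mean, 1)
  expect_true(cmp$significant_matrix[2, 4] && cmp$significant_matrix[4, 2])
})

test_that("subnetwork summaries aggregate blocks correctly", {
  parc <- phantom_parcellation(c(6, 6, 6), n_rois = 8, seed = 1)
  expect_equal(length(unique(parc$map$subnetwork)), 8L)
  # connectivity block means: single subnetwork collapses to one cell
  parc1 <- parc
  parc1$map$subnetwork <- "DMN"
  M <- build_connectivity(matrix(rnorm(8 * 60), 8, 60), bins = 8)
  s1 <- subnetwork_summary(M, parc1)
  expect_equal(dim(s1), c(1L, 1L))
  expect_equal(s1[1, 1], mean(M[upper.tri(M)]), tolerance = 1e-12)
  # significance counts land in the right block
  set.seed(17)
  gA <- make_group(8, R = 8); gB <- make_group(8, R = 8,
                                               shift_edge = c(1, 2), shift = 2)
  cmp <- edgewise_group_comparison(gA, gB)
  s2 <- subnetwork_summary(cmp, parc)
  expect_equal(dim(s2), c(8L, 8L))
  expect_equal(s2, t(s2))
  nets <- unique(parc$map$subnetwork)
  n1 <- match(parc$map$subnetwork[1], nets)
  n2 <- match(parc$map$subnetwork[2], nets)
  expect_gte(s2[n1, n2], 1)
})
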