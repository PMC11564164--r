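test_that("the voxel GLM t matches the pooled-variance two-sample t", {
  f <- glm_t_map(matrix(c(1, 2, 3), 1), matrix(c(4, 5, 6), 1))
  expect_equal(f$t, -3.674235, tolerance = 1e-6)
  expect_equal(f$df, 4L)
  # identical data in both groups -> t = 0 everywhere
  set.seed(1)
  Y <- matrix(rnorm(20), 4, 5)
  f0 <- glm_t_map(Y, Y)
  expect_equal(f0$t, rep(0, 4))
  # n = 83 vs 83 with a gender covariate -> df = 163
  set.seed(2)
  f1 <- glm_t_map(matrix(rnorm(83), 1), matrix(rnorm(83), 1),
                  covariates = rep(0:1, 83))
  expect_equal(f1$df, 163L)
  expect_error(glm_t_map(matrix(1:3, 1), matrix(4:6, 1),
                         covariates = rep(1, 6)), "rank-deficient")
})

test_that("swapping groups negates t and constants are absorbed", {
  co <- small_cohort(seed = 11, n = 6, grid = c(14L, 14L, 14L))
  ab <- voxelwise_glm_t(co, "A", "B")
  ba <- voxelwise_glm_t(co, "B", "A")
  expect_equal(ab$t_map$values, -ba$t_map$values, tolerance = 1e-10)
  co2 <- co
  co2$data <- co2$data + 5
  ab2 <- voxelwise_glm_t(co2, "A", "B", mask_rel_threshold = -Inf)
  ab1 <- voxelwise_glm_t(co, "A", "B", mask_rel_threshold = -Inf)
  expect_equal(ab2$t_map$values, ab1$t_map$values, tolerance = 1e-8)
})

test_that("smoothness estimates track the applied smoothing", {
  set.seed(3)
  gs <- c(26L, 26L, 26L)
  mask <- array(TRUE, gs)
  gen <- function(fwhm) {
    r <- sapply(1:16, function(i) {
      x <- array(rnorm(prod(gs)), gs)
      if (fwhm > 0) x <- gaussian_smooth(x, fwhm, 1.5)
      as.numeric(x)
    })
    r
  }
  est8 <- estimate_smoothness(gen(8), mask, 1.5)
  expect_true(all(abs(est8 - 8) / 8 < 0.15))
  est0 <- estimate_smoothness(gen(0), mask, 1.5)
  est4 <- estimate_smoothness(gen(4), mask, 1.5)
  expect_true(all(est0 < est4))              # unsmoothed floor sits lowest
  expect_true(all(est4 < est8))              # doubling smoothing increases it
  expect_error(estimate_smoothness(matrix(0, sum(mask), 3), mask, 1.5), "flat")
})

test_that("cluster labeling respects connectivity and sizes", {
  a <- array(FALSE, c(6L, 6L, 6L))
  a[1:2, 1, 1] <- TRUE                        # size-2 component
  a[4, 4, 4] <- TRUE                          # isolated voxel
  a[5, 5, 5] <- TRUE                          # diagonal neighbor of (4,4,4)
  lab26 <- label_clusters(a, 26)
  expect_equal(max(lab26), 2L)                # diagonal pair joins under 26
  expect_equal(lab26[1, 1, 1], lab26[2, 1, 1])
  lab6 <- label_clusters(a, 6)
  expect_equal(max(lab6), 3L)                 # but not under face connectivity
  expect_equal(sum(lab6 == 1L), 2L)           # labels ordered by size
})

test_that("GRF correction returns empty masks under threshold and nests in cluster_p", {
  co <- small_cohort(seed = 13, n = 12, d = NA, grid = c(16L, 16L, 16L))
  cr <- voxelwise_glm_t(co, "A", "B")
  sub <- cr
  sub$t_map$values <- sub$t_map$values * 0.1  # everything below threshold
  out <- grf_cluster_correct(sub, fwhm_mm = 8)
  expect_false(any(out$mask_pos) || any(out$mask_neg))
  expect_equal(nrow(out$cluster_table), 0L)

  co2 <- small_cohort(seed = 13, n = 40, d = -2)
  cr2 <- voxelwise_glm_t(co2, "B", "A")     # B carries the planted decrease
  strict <- grf_cluster_correct(cr2, cluster_p = 0.01)
  loose <- grf_cluster_correct(cr2, cluster_p = 0.20)
  expect_true(all(loose$mask_neg[strict$mask_neg]))   # strict subset of loose
  expect_true(any(strict$mask_neg))                   # planted cluster found
  expect_equal(formals(grf_cluster_correct)$voxel_p, 0.001)
  expect_equal(formals(grf_cluster_correct)$cluster_p, 0.05)
  expect_warning(grf_cluster_correct(cr2, fwhm_mm = 0.5), "clamping")
})

test_that("a planted d = 1.5 cluster survives correction across seeds", {
  hits <- 0L
  for (s in 1:5) {
    co <- small_cohort(seed = 20 + s, n = 83, d = -1.5)
    cr <- grf_cluster_correct(voxelwise_glm_t(co, "B", "A"))
    ctr <- co$spec$effect_clusters[[1]]$center
    if (cr$mask_neg[ctr[1], ctr[2], ctr[3]]) hits <- hits + 1L
  }
  expect_equal(hits, 5L)
})

test_that("mask overlap is an idempotent intersection", {
  m <- array(c(TRUE, FALSE), c(4L, 4L, 4L))
  expect_equal(overlap_maps(list(m, m, m)), m)
  expect_false(any(overlap_maps(list(m, array(FALSE, c(4L, 4L, 4L))))))
  expect_error(overlap_maps(list(m, array(TRUE, c(3L, 3L, 3L)))), "mismatched")
})
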