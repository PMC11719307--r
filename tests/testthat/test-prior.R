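test_that("an axis-aligned single-pixel mask backprojects to a full y column", {
  d <- c(12, 9, 6)
  P <- ceiling(sqrt(d[1]^2 + d[2]^2))
  v <- array(0, dim = d); v[5, 4, 3] <- 1
  msk <- mip_at_angle(volume_grid(v), 0, "mask")
  expect_equal(sum(msk), 1)
  bp <- backproject_mask(msk, 0, d)
  expect_true(all(bp$values[5, , 3] == 1))       # the column through the voxel
  expect_equal(sum(bp$values), d[2])             # and nothing else

  empty <- matrix(0, d[3], P)
  expect_equal(sum(backproject_mask(empty, 40, d)$values), 0)

  expect_error(backproject_mask(matrix(0, 2, 2), 0, d), "geometry")
})

test_that("backprojection of a projected mask contains the source voxels", {
  ph <- generate_phantom(phantom_config(n_lesions = 2, seed = 18))
  truth_ix <- which(ph$truth$values == 1)
  for (a in c(-90, -70, -15, 0, 35, 80)) {
    msk <- mip_at_angle(ph$truth, a, "mask")
    bp <- backproject_mask(msk, a, dim(ph$truth$values))
    expect_true(all(bp$values[truth_ix] == 1), info = sprintf("angle %g", a))
  }
})

test_that("fusion sums overlap counts and weights by SUV", {
  ph <- generate_phantom(phantom_config(n_lesions = 1, seed = 19))
  d <- dim(ph$suv$values)
  zeros <- replicate(18, volume_grid(array(0, dim = d)), simplify = FALSE)
  expect_equal(sum(fuse_backprojections(zeros, ph$suv)$values), 0)

  ones <- replicate(18, volume_grid(array(1, dim = d)), simplify = FALSE)
  suv2 <- volume_grid(array(2, dim = d))
  expect_true(all(fuse_backprojections(ones, suv2)$values == 36))

  bad <- volume_grid(array(0, dim = c(3, 3, 3)))
  expect_error(fuse_backprojections(list(bad), ph$suv), "shape")
})

test_that("with the oracle segmenter every truth voxel reaches full overlap", {
  ph <- generate_phantom(hard_case_config(seed = 20))
  sch <- enumerate_angles()
  bp <- lapply(sch$angles, function(a)
    backproject_mask(mip_at_angle(ph$truth, a, "mask"), a, dim(ph$truth$values)))
  counts <- Reduce(`+`, lapply(bp, function(v) v$values))
  expect_true(all(counts[ph$truth$values == 1] == 18))
  expect_true(all(counts <= 18))
})

test_that("prior finalization normalizes, denoises and survives degenerate input", {
  # max normalization
  d <- c(6, 6, 4)
  f <- array(0, dim = d); f[2, 2, 2] <- 36; f[3, 3, 3] <- 9
  p <- finalize_prior(volume_grid(f), percentile = 5)
  expect_equal(max(p$values), 1)
  expect_equal(p$values[2, 2, 2], 1)

  # all-zero input: no NaNs, all-zero prior
  z <- finalize_prior(volume_grid(array(0, dim = d)))
  expect_true(all(z$values == 0))
  expect_false(any(is.nan(z$values)))

  # 100 distinct positive voxels: exactly the 5 smallest are zeroed
  set.seed(30)
  vals <- sample(seq(1, 100), 100)
  f2 <- array(0, dim = c(10, 10, 2))
  f2[, , 1] <- vals
  p2 <- finalize_prior(volume_grid(f2), percentile = 5)
  zeroed <- which(p2$values[, , 1] == 0)
  expect_length(zeroed, 5)
  expect_setequal(vals[zeroed], 1:5)

  expect_error(finalize_prior(volume_grid(array(-1, dim = d))), "non-negative")
})

test_that("equal-SUV voxels with more overlap never get a lower prior value", {
  d <- c(8, 8, 4)
  suv <- volume_grid(array(1.7, dim = d))
  set.seed(31)
  counts <- array(sample(0:18, prod(d), replace = TRUE), dim = d)
  vols <- lapply(1:18, function(k) volume_grid((counts >= k) * 1))
  prior <- finalize_prior(fuse_backprojections(vols, suv), percentile = 0)
  ord <- order(as.vector(counts))
  expect_true(all(diff(prior$values[ord]) >= -1e-12))
})

test_that("the localization score is rank-based and handles edge cases", {
  ph <- generate_phantom(phantom_config(n_lesions = 2, seed = 22))
  stack <- build_projection_stack(ph$suv, truth = ph$truth)
  prior <- build_segmentation_prior(stack, oracle_segmenter(stack), ph$suv)
  expect_equal(prior_localization_score(prior, ph$truth), 1)

  # invariant to monotone rescaling
  resc <- prior
  resc$values <- sqrt(prior$values)
  expect_equal(prior_localization_score(resc, ph$truth), 1)

  zero_prior <- volume_grid(array(0, dim = dim(ph$truth$values)))
  expect_equal(prior_localization_score(zero_prior, ph$truth), 0)

  empty_truth <- volume_grid(array(0, dim = dim(ph$truth$values)))
  expect_error(prior_localization_score(prior, empty_truth), "undefined")
})

test_that("prior values stay in [0,1] on the source grid regardless of backend", {
  ph <- generate_phantom(phantom_config(n_lesions = 2, seed = 23))
  stack <- build_projection_stack(ph$suv, truth = ph$truth)
  for (seg in list(oracle_segmenter(stack), threshold_segmenter(2.5))) {
    prior <- build_segmentation_prior(stack, seg, ph$suv)
    expect_true(all(prior$values >= 0 & prior$values <= 1))
    expect_false(any(is.nan(prior$values)))
    expect_identical(dim(prior$values), dim(ph$suv$values))
    expect_equal(prior$spacing_mm, ph$suv$spacing_mm)
    expect_equal(prior$n_angles_used, 18)
  }
})
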