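test_that("angle schedules enumerate half-open ranges", {
  sch <- enumerate_angles(-90, 90, 10)
  expect_length(sch$angles, 18)
  expect_equal(sch$angles, seq(-90, 80, by = 10))
  expect_equal(enumerate_angles(-90, 90, 90)$angles, c(-90, 0))
  expect_equal(enumerate_angles(0, 10, 10)$angles, 0)
  expect_error(enumerate_angles(0, 90, 0), "positive")
  expect_error(enumerate_angles(90, 0, 10), "less")
})

test_that("the cohort manifest counts scans times angles", {
  man <- projection_manifest(501)
  expect_equal(nrow(man), 9018)
  expect_equal(length(unique(man$scan)), 501)
  expect_equal(nrow(projection_manifest(3, enumerate_angles(-90, 90, 90))), 6)
})

test_that("a constant volume projects to its constant on the covered columns", {
  vol <- volume_grid(array(3, dim = c(10, 10, 6)))
  for (a in c(0, -90, 30, 55)) {
    img <- mip_at_angle(vol, a, "max")
    expect_equal(max(img), 3)                     # interior rays see the constant
    expect_true(all(img >= 0 & img <= 3 + 1e-12)) # pad/edge pixels interpolate to less
    expect_equal(nrow(img), 6)
  }
})

test_that("an axis-aligned projection reduces to the plain coronal MIP", {
  set.seed(4)
  vol <- volume_grid(array(stats::runif(10 * 8 * 5), dim = c(10, 8, 5)))
  img <- mip_at_angle(vol, 0, "max")
  plain <- t(apply(vol$values, c(1, 3), max))
  # the plain MIP appears exactly, embedded at some offset of the padded frame
  P <- ncol(img); nx <- 10
  hits <- vapply(0:(P - nx), function(off)
    isTRUE(all.equal(img[, (off + 1):(off + nx)], plain, check.attributes = FALSE)),
    logical(1))
  expect_equal(sum(hits), 1)
  expect_true(all(img[, !seq_len(P) %in% (which(hits) - 1 + 1:nx)] == 0))
})

test_that("a single hot voxel lands at its rotated in-plane coordinate", {
  d <- c(15, 15, 7)
  v <- array(0, dim = d); v[4, 11, 3] <- 1
  vol <- volume_grid(v)
  P <- ceiling(sqrt(d[1]^2 + d[2]^2))
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cp <- (P + 1) / 2
  for (a in c(0, 30, -50, 80)) {
    th <- a * pi / 180
    expected_col <- floor(cp + (4 - cx) * cos(th) - (11 - cy) * sin(th) + 0.5)
    # mask mode: exactly one pixel, at the rounded rotated coordinate
    msk <- mip_at_angle(vol, a, "mask")
    expect_equal(sum(msk), 1)
    expect_equal(which(msk[3, ] == 1), expected_col)
    # max mode: the brightest pixel within one column of it (bilinear halo)
    img <- mip_at_angle(vol, a, "max")
    expect_lte(abs(which.max(img[3, ]) - expected_col), 1)
    expect_true(all(img[-3, ] == 0))
  }
})

test_that("the vectorized MIP matches the per-pixel rotation oracle", {
  set.seed(5)
  vol <- volume_grid(array(stats::runif(12 * 9 * 6), dim = c(12, 9, 6)))
  for (a in c(-90, -40, 0, 25, 80)) {
    expect_equal(mip_at_angle(vol, a, "max"), oracle_mip(vol, a),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("adding uptake never decreases any MIP pixel", {
  set.seed(6)
  v <- array(stats::runif(10 * 10 * 5), dim = c(10, 10, 5))
  vol <- volume_grid(v)
  before <- lapply(c(-30, 0, 60), function(a) mip_at_angle(vol, a, "max"))
  v2 <- v
  bump <- sample(length(v), 20)
  v2[bump] <- v2[bump] + stats::runif(20, 0.5, 2)
  vol2 <- volume_grid(v2)
  after <- lapply(c(-30, 0, 60), function(a) mip_at_angle(vol2, a, "max"))
  for (i in seq_along(before))
    expect_true(all(after[[i]] - before[[i]] >= -1e-12))
})

test_that("mask-mode projections stay binary and reject non-binary input", {
  ph <- generate_phantom(phantom_config(n_lesions = 2, seed = 8))
  for (a in c(-90, -10, 0, 40))
    expect_true(all(mip_at_angle(ph$truth, a, "mask") %in% c(0, 1)))
  expect_error(mip_at_angle(ph$suv, 0, "mask"), "binary")
})

test_that("stacks hold one image per angle and channel plus truth masks", {
  ph <- generate_phantom(phantom_config(n_lesions = 1, seed = 9))
  tc <- make_tissue_channels(ph$ct, ph$suv)
  stack <- build_projection_stack(ph$suv, tissue = tc, truth = ph$truth)
  expect_equal(length(stack$channels), 5)
  expect_equal(sum(lengths(stack$images)), 90)   # 18 angles x 5 channels
  expect_length(stack$gt_masks, 18)
  # a present lesion is visible from every angle
  expect_true(all(vapply(stack$gt_masks, sum, numeric(1)) > 0))

  no_truth <- build_projection_stack(ph$suv, tissue = tc)
  expect_null(no_truth$gt_masks)
  expect_equal(sum(lengths(no_truth$images)), 90)

  suv_bad <- volume_grid(ph$suv$values[1:10, , ], spacing_mm = ph$suv$spacing_mm)
  expect_error(build_projection_stack(suv_bad, truth = ph$truth), "shape")
})
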