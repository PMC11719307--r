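vg3 <- function(arr, spacing = c(1, 1, 1)) volume_grid(arr, spacing_mm = spacing)

test_that("dice follows the overlap formula with the empty-mask conventions", {
  d <- c(6, 6, 6)
  a <- array(0, dim = d); a[1:2, 1, 1] <- 1; a[3:4, 2, 1] <- 1   # |A| = 4
  b <- array(0, dim = d); b[1:2, 1, 1] <- 1; b[5:6, 3, 1] <- 1   # |B| = 4, overlap 2
  expect_equal(dice(vg3(a), vg3(b)), 0.5)
  expect_equal(dice(vg3(a), vg3(a)), 1)
  disj <- array(0, dim = d); disj[6, 6, 6] <- 1
  expect_equal(dice(vg3(a), vg3(disj)), 0)
  z <- array(0, dim = d)
  expect_equal(dice(vg3(z), vg3(z)), 1)   # both empty
  expect_equal(dice(vg3(a), vg3(z)), 0)   # one empty
})

test_that("surface distances match hand values and scale with spacing", {
  d <- c(8, 8, 8)
  a <- array(0, dim = d); a[4, 4, 2] <- 1
  b <- array(0, dim = d); b[4, 4, 5] <- 1   # 3 voxels apart along z
  sp <- c(2.04, 2.04, 3.00)
  expect_equal(hd95(vg3(a, sp), vg3(b, sp)), 9)
  expect_equal(asd(vg3(a, sp), vg3(b, sp)), 9)
  expect_equal(hd95(vg3(a, sp * 2), vg3(b, sp * 2)), 18)  # linear in spacing
  expect_equal(hd95(vg3(a, sp), vg3(a, sp)), 0)
  expect_equal(asd(vg3(a, sp), vg3(a, sp)), 0)
  expect_warning(out <- hd95(vg3(a, sp), vg3(array(0, dim = d), sp)), "empty")
  expect_true(is.na(out))
})

test_that("hd95 and asd agree with the brute-force pairwise oracle", {
  set.seed(50)
  for (rep in 1:12) {
    d <- sample(6:12, 3, replace = TRUE)
    sp <- runif(3, 0.8, 3)
    a <- random_blob_mask(d); b <- random_blob_mask(d)
    ds <- oracle_distance_sets(a, b, sp)
    pooled <- c(ds$a2b, ds$b2a)
    expect_equal(hd95(vg3(a, sp), vg3(b, sp)),
                 stats::quantile(pooled, 0.95, names = FALSE), tolerance = 1e-9)
    expect_equal(asd(vg3(a, sp), vg3(b, sp)), mean(pooled), tolerance = 1e-9)
  }
})

test_that("lesion extraction uses 27-connectivity and the 0.3 ml filter", {
  d <- c(10, 10, 10)
  m <- array(0, dim = d)
  m[2, 2, 2] <- 1; m[3, 3, 3] <- 1      # touch only at a corner
  expect_length(extract_lesions(vg3(m, c(2.04, 2.04, 3)), 0), 1)

  # 24 voxels = 0.2996 ml <= 0.3 are discarded; 25 voxels = 0.3121 ml kept
  m24 <- array(0, dim = d); m24[1:4, 1:3, 1:2] <- 1
  m25 <- m24; m25[5, 1, 1] <- 1
  expect_length(extract_lesions(vg3(m24, c(2.04, 2.04, 3))), 0)
  expect_length(extract_lesions(vg3(m25, c(2.04, 2.04, 3))), 1)

  expect_length(extract_lesions(vg3(array(0, dim = d))), 0)

  # raising the filter never increases the number of retained lesions
  set.seed(51)
  blobs <- random_blob_mask(c(14, 14, 14), n_blobs = 4)
  counts <- vapply(c(0, 0.05, 0.15, 0.5), function(mv)
    length(extract_lesions(vg3(blobs), mv)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("lesion precision and recall follow the detection counts", {
  d <- c(24, 8, 8)
  truth <- array(0, dim = d)
  truth[1:3, 1:3, 1:3] <- 1; truth[9:11, 1:3, 1:3] <- 1; truth[17:19, 1:3, 1:3] <- 1
  pred <- array(0, dim = d)
  pred[1:3, 1:3, 1:3] <- 1; pred[9:10, 1:2, 1:2] <- 1   # hits lesions 1 and 2
  pred[22:24, 6:8, 6:8] <- 1                            # pure false positive
  sp <- c(5, 5, 5)   # large voxels so nothing is filtered
  tl <- extract_lesions(vg3(truth, sp), 0.3)
  pl <- extract_lesions(vg3(pred, sp), 0.3)
  pr <- lesion_precision_recall(pl, tl)
  expect_equal(pr$recall, 2 / 3)
  expect_equal(pr$tp, 2); expect_equal(pr$fn, 1); expect_equal(pr$fp, 1)
  expect_equal(pr$precision, 2 / 3)
  # conservation
  expect_equal(pr$tp + pr$fn, length(tl))
  expect_equal(sum(pr$pred_matched) + pr$fp, length(pl))

  perfect <- lesion_precision_recall(tl, tl)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
})

test_that("detection metrics are invariant to uniform spacing changes", {
  set.seed(52)
  a <- random_blob_mask(c(12, 12, 12), 3)
  b <- random_blob_mask(c(12, 12, 12), 3)
  for (sc in c(1, 2.5)) {
    sp <- c(1, 1, 1) * sc
    expect_equal(dice(vg3(a, sp), vg3(b, sp)), dice(vg3(a), vg3(b)))
    pr1 <- lesion_precision_recall(extract_lesions(vg3(a, sp), 0),
                                   extract_lesions(vg3(b, sp), 0))
    pr2 <- lesion_precision_recall(extract_lesions(vg3(a), 0),
                                   extract_lesions(vg3(b), 0))
    expect_equal(pr1$recall, pr2$recall)
    expect_equal(pr1$precision, pr2$precision)
  }
})

test_that("MTV groups follow the disease presets", {
  lym <- mtv_group_boundaries("lymphoma")
  expect_equal(as.character(mtv_group(0.8, lym)), "V1")
  expect_equal(as.character(mtv_group(14, lym)), "V5")
  expect_equal(as.character(mtv_group(c(1, 1.5, 2, 4.2, 20), lym)),
               c("V1", "V2", "V2", "V4", "V5"))
  expect_equal(mtv_group_boundaries("lung"), c(2, 3.5, 7.3, 23))
  expect_equal(mtv_group_boundaries("melanoma"), c(1, 1.5, 3, 8))

  rec <- data.frame(volume_ml = c(0.5, 0.9), mean_suv = c(3, 4),
                    dice = c(0.8, 0.6))
  tab <- stratified_dice(rec, lym, by = "volume_ml")
  expect_equal(tab$n, c(2, 0, 0, 0, 0))
  expect_equal(tab$mean_dice[1], 0.7)
  expect_true(all(is.na(tab$mean_dice[-1])))
})

test_that("the FN confusion matrix cross-tabulates detections and conserves lesions", {
  d <- c(24, 8, 8)
  sp <- c(5, 5, 5)
  truth <- array(0, dim = d)
  truth[1:3, 1:3, 1:3] <- 1; truth[9:11, 1:3, 1:3] <- 1; truth[17:19, 1:3, 1:3] <- 1
  pa <- array(0, dim = d); pa[1:3, 1:3, 1:3] <- 1; pa[9:11, 1:3, 1:3] <- 1   # {1,2}
  pb <- array(0, dim = d); pb[9:11, 1:3, 1:3] <- 1; pb[17:19, 1:3, 1:3] <- 1 # {2,3}
  m <- fn_confusion_matrix(vg3(pa, sp), vg3(pb, sp), vg3(truth, sp))
  expect_equal(m["Yes", "Yes"], 1)
  expect_equal(m["Yes", "No"], 1)
  expect_equal(m["No", "Yes"], 1)
  expect_equal(m["No", "No"], 0)
  expect_equal(sum(m), 3)

  both <- fn_confusion_matrix(vg3(truth, sp), vg3(truth, sp), vg3(truth, sp))
  expect_equal(both["Yes", "Yes"], 3)
  expect_equal(sum(both) - both["Yes", "Yes"], 0)
})

test_that("the paired Wilcoxon test matches the exact sign-flip distribution", {
  a <- c(0.52, 0.61, 0.47, 0.70, 0.66, 0.58, 0.71, 0.49, 0.63, 0.55)
  b <- a + 0.04                     # constant shift, all signs positive
  expect_equal(paired_wilcoxon(a, b), 2 / 2^10)
  expect_equal(paired_wilcoxon(a, b), paired_wilcoxon(b, a))   # symmetry
  expect_warning(out <- paired_wilcoxon(a, a), "zero")
  expect_true(is.na(out))

  # tie-free data agrees with the reference implementation's exact p-value
  set.seed(53)
  x <- stats::rnorm(12); y <- x + stats::rnorm(12, 0.3, 0.6)
  expect_equal(paired_wilcoxon(x, y),
               stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)$p.value)
})

test_that("evaluate_segmentation assembles a consistent report", {
  ph <- generate_phantom(phantom_config(n_lesions = 2, seed = 28,
                                        lesion_suv_range = c(4, 8),
                                        n_hotspots = 0))
  pred <- reference_segmenter3d(model3d_spec("baseline"), ph$ct, ph$suv)
  rep <- evaluate_segmentation(pred, ph$truth, suv = ph$suv)
  expect_true(rep$dice >= 0 && rep$dice <= 1)
  expect_equal(rep$tp + rep$fn, rep$n_truth_lesions)
  expect_equal(nrow(rep$per_lesion), rep$n_truth_lesions)
  expect_true(all(rep$per_lesion$dice >= 0 & rep$per_lesion$dice <= 1))
  expect_true(all(rep$per_lesion$volume_ml > 0.3))
})
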