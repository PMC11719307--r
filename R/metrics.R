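## 3D connected-component labelling. connectivity 26 links voxels sharing a
## face, edge or corner (the 27-connected neighborhood); 6 links faces only.
## Adjacency is built by shifting the foreground index set by each
## half-neighborhood offset and the components come from igraph.
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  idx <- which(mask > 0)
  n_fg <- length(idx)
  if (n_fg == 0L) return(list(labels = labels, n = 0L))
  offsets <- if (connectivity == 26) {
    gr <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    gr <- gr[order(gr$dz, gr$dy, gr$dx), ]
    as.matrix(gr[(nrow(gr) + 1) %/% 2 + seq_len(nrow(gr) %/% 2), ])
  } else if (connectivity == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else stop("connectivity must be 6 or 26")

  fg_rank <- integer(prod(d))
  fg_rank[idx] <- seq_len(n_fg)
  co <- arrayInd(idx, d)
  edges <- vector("list", nrow(offsets))
  for (k in seq_len(nrow(offsets))) {
    o <- offsets[k, ]
    ok <- co[, 1] + o[1] >= 1 & co[, 1] + o[1] <= d[1] &
          co[, 2] + o[2] >= 1 & co[, 2] + o[2] <= d[2] &
          co[, 3] + o[3] >= 1 & co[, 3] + o[3] <= d[3]
    nb <- idx[ok] + o[1] + o[2] * d[1] + o[3] * d[1] * d[2]
    hit <- fg_rank[nb] > 0L
    edges[[k]] <- cbind(fg_rank[idx[ok]][hit], fg_rank[nb][hit])
  }
  em <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = n_fg, directed = FALSE)
  if (!is.null(em) && nrow(em) > 0)
    g <- igraph::add_edges(g, t(em))
  comp <- igraph::components(g)
  labels[idx] <- comp$membership
  list(labels = labels, n = comp$no)
}

#' Extract lesions as connected components
#'
#' Labels a binary tumor mask with 27-connected components (voxels sharing a
#' face, edge or corner belong together) and discards components with volume
#' not greater than `min_volume_ml` (default 0.3 ml). Volumes are voxel
#' counts times the voxel volume from the spacing.
#'
#' @param mask binary [volume_grid].
#' @param min_volume_ml minimum retained lesion volume, ml; components with
#'   volume `<= min_volume_ml` are dropped. Use 0 to keep everything.
#' @param suv optional [volume_grid] to record each lesion's mean SUV.
#' @return A list of class `lesion_set`: `components` (list of linear voxel
#'   index vectors), `volumes_ml`, `mean_suv`, `min_volume_ml`, `dim`,
#'   `spacing_mm`, `n_raw` (component count before the volume filter).
#' @export
extract_lesions <- function(mask, min_volume_ml = 0.3, suv = NULL) {
  stopifnot(is_volume_grid(mask))
  if (!is_binary(mask)) stop("'mask' must be binary")
  if (!is.null(suv)) stop_unless_same_grid(mask, suv, "mask and suv")
  lab <- label_components(mask$values, connectivity = 26)
  vml <- voxel_volume_ml(mask$spacing_mm)
  comps <- if (lab$n > 0) split(which(lab$labels > 0), lab$labels[lab$labels > 0]) else list()
  vols <- vapply(comps, length, 1L) * vml
  keep <- vols > min_volume_ml
  comps <- unname(comps[keep]); vols <- unname(vols[keep])
  means <- if (!is.null(suv))
    vapply(comps, function(ix) mean(suv$values[ix]), numeric(1))
  else rep(NA_real_, length(comps))
  structure(list(components = comps, volumes_ml = vols, mean_suv = means,
                 min_volume_ml = min_volume_ml, dim = dim(mask$values),
                 spacing_mm = mask$spacing_mm, n_raw = lab$n),
            class = "lesion_set")
}

#' @export
length.lesion_set <- function(x) length(x$components)

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("<lesion_set> %d lesions (> %.2g ml) of %d raw components\n",
              length(x$components), x$min_volume_ml, x$n_raw))
  invisible(x)
}

## binary array covering the union of retained lesions
lesion_mask_array <- function(ls) {
  out <- array(0, dim = ls$dim)
  for (ix in ls$components) out[ix] <- 1
  out
}

#' Dice coefficient
#'
#' `2|A intersect B| / (|A| + |B|)`. Two empty masks give 1 by convention
#' (so degenerate cases do not crash cohort loops); one empty mask gives 0.
#'
#' @param pred,truth binary [volume_grid]s (or plain arrays of equal shape).
#' @return Scalar in [0, 1].
#' @export
dice <- function(pred, truth) {
  if (is_volume_grid(pred) && is_volume_grid(truth))
    stop_unless_same_grid(pred, truth, "pred and truth")
  a <- if (is_volume_grid(pred)) pred$values else pred
  b <- if (is_volume_grid(truth)) truth$values else truth
  if (!identical(dim(a), dim(b))) stop("masks must share the same shape")
  na <- sum(a > 0); nb <- sum(b > 0)
  if (na + nb == 0) return(1)
  2 * sum(a > 0 & b > 0) / (na + nb)
}

## surface voxels: mask voxels with at least one face-adjacent (6-neighbor)
## background voxel; the volume border counts as background
surface_voxels <- function(mask) {
  d <- dim(mask)
  fg <- mask > 0
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- fg
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb_all <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
            pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
            pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
            pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
            pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
            pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  which(core & !nb_all)
}

## directed surface distances a -> b in mm, chunked pairwise Euclidean
directed_surface_distances <- function(ca, cb) {
  na <- nrow(ca)
  out <- numeric(na)
  chunk <- max(1L, floor(2e6 / nrow(cb)))
  for (s in seq.int(1L, na, by = chunk)) {
    e <- min(s + chunk - 1L, na)
    block <- ca[s:e, , drop = FALSE]
    d2 <- outer(block[, 1], cb[, 1], `-`)^2 +
          outer(block[, 2], cb[, 2], `-`)^2 +
          outer(block[, 3], cb[, 3], `-`)^2
    out[s:e] <- sqrt(apply(d2, 1, min))
  }
  out
}

## both directed surface-distance multisets between two masks, mm
surface_distance_sets <- function(pred, truth) {
  stop_unless_same_grid(pred, truth, "pred and truth")
  sp <- pred$spacing_mm
  ia <- surface_voxels(pred$values)
  ib <- surface_voxels(truth$values)
  if (length(ia) == 0L || length(ib) == 0L) return(NULL)
  ca <- sweep(arrayInd(ia, dim(pred$values)), 2, sp, `*`)
  cb <- sweep(arrayInd(ib, dim(truth$values)), 2, sp, `*`)
  list(a2b = directed_surface_distances(ca, cb),
       b2a = directed_surface_distances(cb, ca))
}

#' 95th-percentile Hausdorff distance (HD95)
#'
#' Robust Hausdorff variant: the 95th percentile of the pooled directed
#' surface-to-surface distances in both directions, in physical mm. Surfaces
#' are mask voxels with a face-adjacent background voxel. Undefined (NA with
#' a warning) when either mask is empty.
#'
#' @param pred,truth binary [volume_grid]s.
#' @param percentile percentile of the pooled distances, default 95.
#' @return Distance in mm, or NA.
#' @export
hd95 <- function(pred, truth, percentile = 95) {
  ds <- surface_distance_sets(pred, truth)
  if (is.null(ds)) {
    warning("HD95 is undefined when either mask is empty")
    return(NA_real_)
  }
  stats::quantile(c(ds$a2b, ds$b2a), percentile / 100, names = FALSE, type = 7)
}

#' Average symmetric surface distance (ASD)
#'
#' Mean of the pooled directed surface distances pred-to-truth and
#' truth-to-pred, in mm. Undefined (NA with a warning) when either mask is
#' empty.
#'
#' @param pred,truth binary [volume_grid]s.
#' @return Distance in mm, or NA.
#' @export
asd <- function(pred, truth) {
  ds <- surface_distance_sets(pred, truth)
  if (is.null(ds)) {
    warning("ASD is undefined when either mask is empty")
    return(NA_real_)
  }
  mean(c(ds$a2b, ds$b2a))
}

#' Lesion-wise precision and recall
#'
#' A truth lesion is detected (TP) when it overlaps the predicted lesion
#' mask in at least `min_overlap_voxels` voxels; a predicted lesion with no
#' truth overlap is a false positive. Recall = TP / (TP + FN) over truth
#' lesions, precision = TP' / (TP' + FP) over predicted lesions. Both lesion
#' sets should come from [extract_lesions()] on the same grid (so the 0.3 ml
#' volume filter has been applied to both sides).
#'
#' @param pred_lesions,truth_lesions `lesion_set` objects on one grid.
#' @param min_overlap_voxels detection criterion, default 1 voxel.
#' @return List: `precision`, `recall` (NA when the denominator set is
#'   empty), `tp`, `fn`, `fp`, `detected` (logical per truth lesion),
#'   `pred_matched` (logical per predicted lesion).
#' @export
lesion_precision_recall <- function(pred_lesions, truth_lesions,
                                    min_overlap_voxels = 1) {
  stopifnot(inherits(pred_lesions, "lesion_set"),
            inherits(truth_lesions, "lesion_set"))
  if (!identical(pred_lesions$dim, truth_lesions$dim))
    stop("lesion sets must come from the same grid")
  pred_mask <- lesion_mask_array(pred_lesions)
  truth_mask <- lesion_mask_array(truth_lesions)
  detected <- vapply(truth_lesions$components,
                     function(ix) sum(pred_mask[ix]) >= min_overlap_voxels,
                     logical(1))
  pred_matched <- vapply(pred_lesions$components,
                         function(ix) sum(truth_mask[ix]) >= min_overlap_voxels,
                         logical(1))
  tp <- sum(detected); fn <- sum(!detected); fp <- sum(!pred_matched)
  list(precision = if (length(pred_matched)) mean(pred_matched) else NA_real_,
       recall = if (length(detected)) mean(detected) else NA_real_,
       tp = tp, fn = fn, fp = fp,
       detected = detected, pred_matched = pred_matched)
}

#' Per-lesion evaluation records
#'
#' One row per truth lesion: volume (ml), mean SUV (when an SUV volume is
#' supplied), detection flag, and a lesion-level Dice computed inside the
#' lesion's bounding box padded by `margin` voxels, with only that lesion as
#' truth.
#'
#' @param pred,truth binary [volume_grid]s.
#' @param suv optional [volume_grid] for per-lesion mean SUV.
#' @param min_volume_ml lesion volume filter (applied to both masks).
#' @param margin bounding-box padding in voxels for the local Dice.
#' @return data.frame with columns `lesion`, `volume_ml`, `mean_suv`,
#'   `detected`, `dice`.
#' @export
per_lesion_records <- function(pred, truth, suv = NULL, min_volume_ml = 0.3,
                               margin = 2) {
  tl <- extract_lesions(truth, min_volume_ml, suv = suv)
  pl <- extract_lesions(pred, min_volume_ml)
  pr <- if (length(tl)) lesion_precision_recall(pl, tl) else
    list(detected = logical(0))
  pred_mask <- lesion_mask_array(pl)
  d <- tl$dim
  dice_k <- vapply(seq_along(tl$components), function(k) {
    co <- arrayInd(tl$components[[k]], d)
    lo <- pmax(apply(co, 2, min) - margin, 1)
    hi <- pmin(apply(co, 2, max) + margin, d)
    tr <- array(0, dim = hi - lo + 1)
    tr[sweep(co, 2, lo - 1L, `-`)] <- 1
    pd <- pred_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    dice(pd, tr)
  }, numeric(1))
  data.frame(lesion = seq_along(tl$components),
             volume_ml = tl$volumes_ml,
             mean_suv = tl$mean_suv,
             detected = pr$detected,
             dice = dice_k)
}

#' Metabolic-tumor-volume group boundaries
#'
#' Disease presets for the five MTV groups V1..V5 used to stratify
#' lesion-level Dice: lymphoma (1, 2, 4, 14 ml), lung cancer (2, 3.5, 7.3,
#' 23 ml), melanoma (1, 1.5, 3, 8 ml). A volume `<= b1` falls in V1 and a
#' volume `>= b4` in V5; interior boundaries are closed on the right.
#'
#' @param preset `"lymphoma"`, `"lung"` or `"melanoma"`.
#' @return Numeric 4-vector of group boundaries, ml.
#' @export
mtv_group_boundaries <- function(preset = c("lymphoma", "lung", "melanoma")) {
  switch(match.arg(preset),
         lymphoma = c(1, 2, 4, 14),
         lung = c(2, 3.5, 7.3, 23),
         melanoma = c(1, 1.5, 3, 8))
}

#' Assign lesions to volume groups
#'
#' @param volumes_ml lesion volumes, ml.
#' @param boundaries 4 boundaries from [mtv_group_boundaries()] (or custom,
#'   any length k giving k+1 groups).
#' @param labels group labels, default `V1..V5`.
#' @return Factor of group labels.
#' @export
mtv_group <- function(volumes_ml, boundaries = mtv_group_boundaries("lymphoma"),
                      labels = paste0("V", seq_len(length(boundaries) + 1))) {
  k <- length(boundaries)
  stopifnot(length(labels) == k + 1, !is.unsorted(boundaries))
  g <- integer(length(volumes_ml))
  for (i in seq_along(volumes_ml)) {
    v <- volumes_ml[i]
    g[i] <- if (v >= boundaries[k]) k + 1L
            else if (v <= boundaries[1]) 1L
            else findInterval(v, boundaries, left.open = TRUE) + 1L
  }
  factor(labels[g], levels = labels)
}

#' Stratified lesion-level Dice
#'
#' Summarizes per-lesion Dice within volume (or SUVmean) groups.
#'
#' @param records data.frame from [per_lesion_records()].
#' @param boundaries group boundaries (ml for MTV groups, SUV for SUVmean
#'   groups).
#' @param by column of `records` to group on, `"volume_ml"` or `"mean_suv"`.
#' @param labels group labels.
#' @return data.frame with one row per group: `group`, `n`, `mean_dice`,
#'   `median_dice`. Empty groups appear with `n = 0` and NA summaries.
#' @export
stratified_dice <- function(records, boundaries = mtv_group_boundaries("lymphoma"),
                            by = c("volume_ml", "mean_suv"),
                            labels = if (match.arg(by) == "volume_ml")
                              paste0("V", seq_len(length(boundaries) + 1))
                            else paste0("S", seq_len(length(boundaries) + 1))) {
  by <- match.arg(by)
  grp <- mtv_group(records[[by]], boundaries, labels)
  out <- do.call(rbind, lapply(levels(grp), function(g) {
    dsub <- records$dice[grp == g]
    data.frame(group = g, n = length(dsub),
               mean_dice = if (length(dsub)) mean(dsub) else NA_real_,
               median_dice = if (length(dsub)) stats::median(dsub) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' False-negative confusion matrix between two methods
#'
#' Cross-tabulates, over the truth lesions, detection ("Yes") versus miss
#' ("No") by method A against method B. The matrix total equals the number
#' of truth lesions.
#'
#' @param pred_a,pred_b binary [volume_grid] predictions of the two methods.
#' @param truth binary [volume_grid] ground truth.
#' @param min_volume_ml lesion volume filter.
#' @param min_overlap_voxels detection criterion.
#' @return 2x2 matrix with dimnames `method_a`/`method_b` in ("Yes", "No").
#' @export
fn_confusion_matrix <- function(pred_a, pred_b, truth, min_volume_ml = 0.3,
                                min_overlap_voxels = 1) {
  tl <- extract_lesions(truth, min_volume_ml)
  det <- function(pred) {
    pl <- extract_lesions(pred, min_volume_ml)
    lesion_precision_recall(pl, tl, min_overlap_voxels)$detected
  }
  da <- factor(ifelse(det(pred_a), "Yes", "No"), levels = c("Yes", "No"))
  db <- factor(ifelse(det(pred_b), "Yes", "No"), levels = c("Yes", "No"))
  m <- table(method_a = da, method_b = db)
  matrix(as.integer(m), 2, 2,
         dimnames = list(method_a = c("Yes", "No"), method_b = c("Yes", "No")))
}

## exact null distribution of the Wilcoxon signed-rank statistic under sign
## flips, with midranks for tied |differences|: dynamic programming over
## doubled ranks (so midranks stay integral)
signed_rank_exact_p <- function(d) {
  r2 <- as.integer(round(2 * rank(abs(d))))
  total <- sum(r2)
  dist <- numeric(total + 1); dist[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(total + 1 - r)])
    dist <- (dist + shifted) / 2
  }
  v2 <- sum(r2[d > 0])          # doubled observed statistic
  dev <- abs(v2 - total / 2)
  support <- seq_len(total + 1) - 1
  sum(dist[abs(support - total / 2) >= dev - 1e-9])
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Compares two equal-length paired samples (e.g. per-patient scores of two
#' methods). Zero differences are dropped before ranking. For n <= 30
#' retained pairs the two-sided p-value comes from the exact sign-flip
#' distribution of the signed-rank statistic (with midranks when |d| ties),
#' so tied differences are handled exactly; larger samples use the normal
#' approximation of [stats::wilcox.test()]. All-zero differences give NA
#' with a warning.
#'
#' @param sample_a,sample_b paired numeric vectors.
#' @return Two-sided p-value, or NA.
#' @export
paired_wilcoxon <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) == length(sample_b))
  d <- sample_b - sample_a
  d <- d[is.finite(d) & d != 0]
  if (length(d) == 0L) {
    warning("all paired differences are zero; p-value undefined")
    return(NA_real_)
  }
  if (length(d) <= 30L) {
    min(1, signed_rank_exact_p(d))
  } else {
    stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
  }
}

#' Full voxel-level and lesion-level evaluation
#'
#' Computes Dice, HD95 and ASD at the voxel level and lesion-wise precision
#' and recall (27-connected components, volume filter) plus per-lesion
#' records for stratified analysis.
#'
#' @param pred,truth binary [volume_grid]s.
#' @param suv optional [volume_grid] for per-lesion mean SUV.
#' @param min_volume_ml lesion volume filter, ml.
#' @return A list of class `eval_report`.
#' @export
evaluate_segmentation <- function(pred, truth, suv = NULL, min_volume_ml = 0.3) {
  stop_unless_same_grid(pred, truth, "pred and truth")
  tl <- extract_lesions(truth, min_volume_ml, suv = suv)
  pl <- extract_lesions(pred, min_volume_ml)
  pr <- if (length(tl) || length(pl))
    lesion_precision_recall(pl, tl)
  else list(precision = NA_real_, recall = NA_real_, tp = 0L, fn = 0L, fp = 0L)
  structure(list(dice = dice(pred, truth),
                 hd95_mm = suppressWarnings(hd95(pred, truth)),
                 asd_mm = suppressWarnings(asd(pred, truth)),
                 lesion_precision = pr$precision,
                 lesion_recall = pr$recall,
                 tp = pr$tp, fn = pr$fn, fp = pr$fp,
                 n_truth_lesions = length(tl),
                 n_pred_lesions = length(pl),
                 per_lesion = per_lesion_records(pred, truth, suv, min_volume_ml)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> Dice %.3f | HD95 %s mm | ASD %s mm\n",
              x$dice,
              ifelse(is.na(x$hd95_mm), "NA", sprintf("%.2f", x$hd95_mm)),
              ifelse(is.na(x$asd_mm), "NA", sprintf("%.2f", x$asd_mm))))
  cat(sprintf("  lesions: %d truth, %d predicted; TP %d FN %d FP %d; recall %s precision %s\n",
              x$n_truth_lesions, x$n_pred_lesions, x$tp, x$fn, x$fp,
              ifelse(is.na(x$lesion_recall), "NA", sprintf("%.2f", x$lesion_recall)),
              ifelse(is.na(x$lesion_precision), "NA", sprintf("%.2f", x$lesion_precision))))
  invisible(x)
}
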