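#' Backproject a 2D projection-domain mask into 3D
#'
#' Extrudes the mask along the projection ray direction and inverse-rotates
#' it into the source frame: voxel (x, y, z) is foreground exactly when the
#' mask is set at row z and the padded column that (x, y) rotates to under
#' the forward projection geometry. Nearest-neighbour (rounded-column)
#' assignment keeps the output binary and makes the operation the exact
#' adjoint of mask-mode [mip_at_angle()]: the backprojection of a projected
#' mask contains every voxel that produced it.
#'
#' @param mask2d binary matrix (nz x padded extent), e.g. a predicted or
#'   projected lesion mask.
#' @param angle viewing angle, degrees (same angle the mask was produced at).
#' @param source_shape integer 3-vector, the original volume shape. Taken
#'   from the mask's `mip_geometry` attribute when omitted.
#' @param spacing_mm voxel spacing of the output volume.
#' @return A binary [volume_grid] of shape `source_shape`.
#' @export
backproject_mask <- function(mask2d, angle = NULL, source_shape = NULL,
                             spacing_mm = c(2.04, 2.04, 3.00)) {
  geom <- attr(mask2d, "mip_geometry")
  if (is.null(angle)) {
    if (is.null(geom)) stop("'angle' missing and mask carries no geometry")
    angle <- geom$angle
  }
  if (is.null(source_shape)) {
    if (is.null(geom)) stop("'source_shape' missing and mask carries no geometry")
    source_shape <- geom$source_shape
  }
  if (!is.null(geom) && !is.null(geom$spacing_mm)) spacing_mm <- geom$spacing_mm
  if (!all(mask2d %in% c(0, 1))) stop("'mask2d' must be binary")
  g <- rot_geometry(source_shape)
  if (!all(dim(mask2d) == c(g$nz, g$P)))
    stop(sprintf("mask is %s but the recorded geometry requires %d x %d",
                 paste(dim(mask2d), collapse = "x"), g$nz, g$P))
  th <- angle * pi / 180
  X <- rep(seq_len(g$nx), times = g$ny)
  Y <- rep(seq_len(g$ny), each = g$nx)
  col <- rnd(g$cp + (X - g$cx) * cos(th) - (Y - g$cy) * sin(th))
  ok <- col >= 1 & col <= g$P
  maskT <- t(mask2d)                       # (P, nz)
  out <- matrix(0, g$nx * g$ny, g$nz)
  out[ok, ] <- maskT[col[ok], , drop = FALSE]
  dim(out) <- c(g$nx, g$ny, g$nz)
  volume_grid(out, spacing_mm = spacing_mm)
}

#' Fuse per-angle backprojections with SUV weighting
#'
#' Sums the binary backprojected volumes voxel-wise (the overlap count, 0 to
#' the number of angles) and multiplies the sum by the SUV volume, so regions
#' where many viewing angles agree — and that show high uptake — dominate.
#'
#' @param volumes list of binary [volume_grid]s, one per angle.
#' @param suv [volume_grid] of SUV values on the same grid.
#' @return A non-negative [volume_grid]; attribute `n_angles` records the
#'   number of fused volumes.
#' @export
fuse_backprojections <- function(volumes, suv) {
  stopifnot(length(volumes) >= 1, is_volume_grid(suv))
  acc <- array(0, dim = dim(suv$values))
  for (v in volumes) {
    stop_unless_same_grid(v, suv, "backprojections and suv")
    acc <- acc + v$values
  }
  out <- vg_like(suv, acc * suv$values)
  attr(out, "n_angles") <- length(volumes)
  out
}

#' Normalize and denoise a fused backprojection into a segmentation prior
#'
#' Scales the fused volume by its global maximum to [0, 1], then removes the
#' noise floor: voxels at or below the given percentile of the strictly
#' positive values are set to zero. The percentile is taken over positive
#' voxels only because the vast majority of voxels lie outside every
#' extrusion and are exact zeros already (`positive_only = FALSE` restores
#' an all-voxel percentile). An all-zero input returns an all-zero prior.
#'
#' @param fused non-negative [volume_grid] from [fuse_backprojections()].
#' @param percentile noise-floor percentile, default 5.
#' @param positive_only compute the percentile over positive voxels only.
#' @param provenance channel mode label, `"prior_1"` (SUVorgMIP-only 2D
#'   stage) or `"prior_2"` (5-channel 2D stage).
#' @return A [volume_grid] of class `segmentation_prior` with values in
#'   [0, 1] and fields `n_angles_used`, `provenance`,
#'   `noise_floor_percentile`.
#' @export
finalize_prior <- function(fused, percentile = 5, positive_only = TRUE,
                           provenance = c("prior_2", "prior_1")) {
  stopifnot(is_volume_grid(fused))
  provenance <- match.arg(provenance)
  v <- fused$values
  if (any(v < 0)) stop("fused volume must be non-negative")
  mx <- max(v)
  if (mx > 0) {
    v <- v / mx
    pos <- v[v > 0]
    ref <- if (positive_only) pos else as.vector(v)
    thr <- stats::quantile(ref, percentile / 100, names = FALSE, type = 7)
    v[v <= thr] <- 0
  }
  out <- vg_like(fused, v)
  out$n_angles_used <- attr(fused, "n_angles") %||% NA_integer_
  out$provenance <- provenance
  out$noise_floor_percentile <- percentile
  class(out) <- c("segmentation_prior", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a segmentation prior from a stack and a 2D segmenter
#'
#' Convenience wrapper running the full chain: predict per-angle 2D masks,
#' backproject each, fuse with SUV weighting, normalize and remove the noise
#' floor.
#'
#' @param stack a [build_projection_stack()] result.
#' @param segmenter a `segmenter2d`, or a pre-computed list of per-angle
#'   binary masks from [predict_stack()].
#' @param suv [volume_grid] of SUV values on the source grid.
#' @param percentile,positive_only,provenance passed to [finalize_prior()].
#' @return A `segmentation_prior`.
#' @export
build_segmentation_prior <- function(stack, segmenter, suv, percentile = 5,
                                     positive_only = TRUE,
                                     provenance = c("prior_2", "prior_1")) {
  masks <- if (inherits(segmenter, "segmenter2d"))
    predict_stack(segmenter, stack) else segmenter
  stopifnot(length(masks) == length(stack$angles$angles))
  bp <- lapply(seq_along(masks), function(i)
    backproject_mask(masks[[i]], angle = stack$angles$angles[i],
                     source_shape = stack$source_shape,
                     spacing_mm = stack$spacing_mm))
  finalize_prior(fuse_backprojections(bp, suv), percentile = percentile,
                 positive_only = positive_only, provenance = provenance)
}

#' Fraction of lesions highlighted by a prior
#'
#' A truth lesion (27-connected component) counts as highlighted when the
#' prior value at its centroid voxel is strictly above the prior's
#' background median (the median over non-tumor voxels). Rank-based, so the
#' score is invariant to any monotone rescaling of the prior.
#'
#' @param prior a `segmentation_prior` (or any [volume_grid]).
#' @param truth binary [volume_grid] of ground-truth lesions.
#' @return Scalar in [0, 1].
#' @export
prior_localization_score <- function(prior, truth) {
  stopifnot(is_volume_grid(prior), is_volume_grid(truth))
  stop_unless_same_grid(prior, truth, "prior and truth")
  if (!is_binary(truth)) stop("'truth' must be binary")
  lab <- label_components(truth$values, connectivity = 26)
  if (lab$n == 0L) stop("localization score is undefined for empty truth")
  bg_median <- stats::median(prior$values[truth$values == 0])
  hits <- vapply(seq_len(lab$n), function(k) {
    co <- arrayInd(which(lab$labels == k), dim(truth$values))
    cen <- rnd(colMeans(co))
    prior$values[cen[1], cen[2], cen[3]] > bg_median
  }, logical(1))
  mean(hits)
}
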