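#' 3D segmentation model specification
#'
#' Declares the input-channel mode and patching scheme of the 3D stage:
#' `baseline` consumes (CT, SUV); `prior_1` and `prior_2` add the
#' segmentation prior built from single-channel or 5-channel 2D projections
#' as a third input channel. Inference runs over sliding-window patches of
#' (160, 160, 160) voxels with 0.25 overlap by default.
#'
#' The `reference` backend is a deterministic rule-based segmenter (see
#' [reference_segmenter3d()]): it thresholds SUV at `suv_threshold`, and in
#' prior modes lowers the threshold to `prior_suv_threshold` wherever the
#' prior is positive. The two thresholds are test instruments calibrated for
#' the synthetic phantoms, not clinical settings.
#'
#' @param mode `"baseline"`, `"prior_1"` or `"prior_2"`.
#' @param patch_size integer 3-vector, voxels.
#' @param patch_overlap fractional overlap between consecutive patches,
#'   `0 <= overlap < 1`.
#' @param backend backend name (only `"reference"` ships with the package;
#'   neural backends can be registered behind the same contract).
#' @param suv_threshold SUV threshold for candidate voxels.
#' @param prior_suv_threshold lowered SUV threshold where the prior is
#'   positive (prior modes only).
#' @return A list of class `model3d_spec`.
#' @export
model3d_spec <- function(mode = c("baseline", "prior_1", "prior_2"),
                         patch_size = c(160, 160, 160),
                         patch_overlap = 0.25,
                         backend = "reference",
                         suv_threshold = 2.5,
                         prior_suv_threshold = 1.5) {
  mode <- match.arg(mode)
  if (patch_overlap < 0 || patch_overlap >= 1)
    stop("'patch_overlap' must be in [0, 1)")
  structure(list(mode = mode,
                 n_channels = if (mode == "baseline") 2L else 3L,
                 patch_size = as.integer(patch_size),
                 patch_overlap = patch_overlap,
                 backend = backend,
                 suv_threshold = suv_threshold,
                 prior_suv_threshold = prior_suv_threshold),
            class = "model3d_spec")
}

## sliding offsets along one axis: stride = patch * (1 - overlap), final
## window clamped to end at the boundary so every voxel is covered
axis_offsets <- function(n, patch, overlap) {
  if (patch >= n) return(0L)
  stride <- max(1L, as.integer(round(patch * (1 - overlap))))
  off <- seq.int(0L, n - patch, by = stride)
  if (off[length(off)] + patch < n) off <- c(off, n - patch)
  off
}

#' Sliding-window patch grid
#'
#' Enumerates the patch windows tiling a volume with the given overlap.
#' Stride is `patch_size * (1 - overlap)`; the final window along each axis
#' is clamped to the boundary, so the union of windows covers every voxel.
#' A patch larger than the volume yields a single window clamped to the
#' volume.
#'
#' @param shape integer 3-vector, volume shape.
#' @param patch_size integer 3-vector, window shape.
#' @param overlap fractional overlap, `0 <= overlap < 1`.
#' @return data.frame with 1-based inclusive window bounds `x0,x1,y0,y1,z0,z1`.
#' @export
sliding_window_patches <- function(shape, patch_size = c(160, 160, 160),
                                   overlap = 0.25) {
  if (overlap < 0 || overlap >= 1) stop("'overlap' must be in [0, 1)")
  shape <- as.integer(shape); patch_size <- as.integer(patch_size)
  eff <- pmin(patch_size, shape)
  offs <- lapply(1:3, function(a) axis_offsets(shape[a], eff[a], overlap))
  gr <- expand.grid(x = offs[[1]], y = offs[[2]], z = offs[[3]])
  data.frame(x0 = gr$x + 1L, x1 = gr$x + eff[1],
             y0 = gr$y + 1L, y1 = gr$y + eff[2],
             z0 = gr$z + 1L, z1 = gr$z + eff[3])
}

#' Deterministic reference 3D segmenter
#'
#' A rule-based stand-in for a trained 3D network, used to demonstrate and
#' test the prior-channel plumbing and the evaluation suite end to end. In
#' `baseline` mode a voxel is tumor when `SUV > suv_threshold`. In prior
#' modes the prior gates a second, lower threshold: voxels with positive
#' prior support are tumor already at `SUV > prior_suv_threshold`, so
#' low-uptake lesions highlighted by the prior are recovered while
#' unsupported background still needs the full threshold. Inference runs
#' patch-wise over the sliding-window grid and combines patches by union.
#'
#' @param spec a [model3d_spec()].
#' @param ct [volume_grid] of CT values (part of the channel contract;
#'   unused by the reference rules).
#' @param suv [volume_grid] of SUV values.
#' @param prior a `segmentation_prior` (required in prior modes).
#' @return A binary [volume_grid] prediction.
#' @export
reference_segmenter3d <- function(spec, ct, suv, prior = NULL) {
  stopifnot(inherits(spec, "model3d_spec"), is_volume_grid(ct), is_volume_grid(suv))
  stop_unless_same_grid(ct, suv, "ct and suv")
  if (spec$mode != "baseline") {
    if (is.null(prior))
      stop(sprintf("mode '%s' requires a segmentation prior", spec$mode))
    stop_unless_same_grid(suv, prior, "suv and prior")
  }
  out <- array(0, dim = dim(suv$values))
  win <- sliding_window_patches(dim(suv$values), spec$patch_size, spec$patch_overlap)
  for (i in seq_len(nrow(win))) {
    xs <- win$x0[i]:win$x1[i]; ys <- win$y0[i]:win$y1[i]; zs <- win$z0[i]:win$z1[i]
    s <- suv$values[xs, ys, zs, drop = FALSE]
    m <- s > spec$suv_threshold
    if (spec$mode != "baseline") {
      p <- prior$values[xs, ys, zs, drop = FALSE]
      m <- m | (p > 0 & s > spec$prior_suv_threshold)
    }
    out[xs, ys, zs] <- pmax(out[xs, ys, zs], m * 1)
  }
  vg_like(suv, out)
}
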