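#' Preprocessing specification
#'
#' Bundles the target grid and intensity windows used to condition raw CT and
#' PET volumes before modelling: a common voxel spacing, a CT window of
#' [-100, 250] HU, an SUV window of [0, 15], and affine normalization of both
#' windows to [0, 1].
#'
#' @param target_spacing_mm common voxel spacing, mm.
#' @param ct_clip CT clip window `(low, high)`, HU.
#' @param suv_clip SUV clip window `(low, high)`.
#' @return A list of class `preprocess_spec`.
#' @export
preprocess_spec <- function(target_spacing_mm = c(2.04, 2.04, 3.00),
                            ct_clip = c(-100, 250),
                            suv_clip = c(0, 15)) {
  if (ct_clip[1] >= ct_clip[2]) stop("ct_clip must satisfy low < high")
  if (suv_clip[1] >= suv_clip[2]) stop("suv_clip must satisfy low < high")
  structure(list(target_spacing_mm = as.numeric(target_spacing_mm),
                 ct_clip = as.numeric(ct_clip),
                 suv_clip = as.numeric(suv_clip)),
            class = "preprocess_spec")
}

#' Convert PET activity concentration to body-weight SUV
#'
#' Standard body-weight SUV: voxel activity concentration (Bq/ml) divided by
#' injected dose per gram of body weight, i.e. `activity * weight_g / dose`.
#' The result is dimensionless and linear in body weight.
#'
#' @param pet_activity [volume_grid] of activity concentration, Bq/ml.
#' @param injected_dose_bq injected dose, Bq (positive scalar).
#' @param body_weight_kg body weight, kg (positive scalar).
#' @return A [volume_grid] of SUV values on the same grid.
#' @export
compute_suv <- function(pet_activity, injected_dose_bq, body_weight_kg) {
  stopifnot(is_volume_grid(pet_activity))
  if (!is.numeric(injected_dose_bq) || length(injected_dose_bq) != 1L ||
      !is.finite(injected_dose_bq) || injected_dose_bq <= 0)
    stop("'injected_dose_bq' must be a positive scalar")
  if (!is.numeric(body_weight_kg) || length(body_weight_kg) != 1L ||
      !is.finite(body_weight_kg) || body_weight_kg <= 0)
    stop("'body_weight_kg' must be a positive scalar")
  vg_like(pet_activity, pet_activity$values * (body_weight_kg * 1000) / injected_dose_bq)
}

## 1D linear interpolation of a 3D array along one axis at continuous
## (1-based) source indices `pos`; out-of-range positions clamp to the edge.
interp_axis <- function(arr, axis, pos, nearest = FALSE) {
  n <- dim(arr)[axis]
  pos <- pmin(pmax(pos, 1), n)
  if (nearest) {
    idx <- floor(pos + 0.5)
    return(switch(axis,
                  arr[idx, , , drop = FALSE],
                  arr[, idx, , drop = FALSE],
                  arr[, , idx, drop = FALSE]))
  }
  lo <- pmin(floor(pos), n - 1L)
  lo <- pmax(lo, 1L)
  f <- pos - lo
  hi <- lo + 1L
  take <- function(i) switch(axis,
                             arr[i, , , drop = FALSE],
                             arr[, i, , drop = FALSE],
                             arr[, , i, drop = FALSE])
  a <- take(lo)
  b <- take(hi)
  ## broadcast the per-position weight along the other two axes
  wdim <- c(1L, 1L, 1L)
  wdim[axis] <- length(pos)
  w <- array(f, dim = wdim)
  sweep_mult <- function(x, w, axis) {
    d <- dim(x)
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    xp <- xp * as.vector(w)  # recycles along the first axis
    aperm(xp, order(perm))
  }
  sweep_mult(a, 1 - f, axis) + sweep_mult(b, f, axis)
}

#' Resample a volume to a common grid
#'
#' Resamples onto the spacing in `spec`. Continuous images use separable
#' trilinear interpolation; label images use nearest-neighbour so binary masks
#' stay binary. The output grid has `round(n * s_old / s_new)` voxels per axis
#' (at least 1), sharing the same origin; a volume already at the target
#' spacing is returned unchanged.
#'
#' @param vol a [volume_grid].
#' @param spec a [preprocess_spec] (only `target_spacing_mm` is used).
#' @param mode `"continuous"` (trilinear) or `"label"` (nearest-neighbour).
#' @return A [volume_grid] at the target spacing.
#' @export
resample_to_common_grid <- function(vol, spec = preprocess_spec(),
                                    mode = c("continuous", "label")) {
  stopifnot(is_volume_grid(vol))
  mode <- match.arg(mode)
  s_old <- vol$spacing_mm
  s_new <- spec$target_spacing_mm
  d_old <- dim(vol$values)
  d_new <- pmax(1L, as.integer(round(d_old * s_old / s_new)))
  if (any(d_new < 1L)) stop("resampling produced a zero-sized grid")
  if (max(abs(s_old - s_new)) < 1e-9) return(vol)
  out <- vol$values
  nearest <- mode == "label"
  for (axis in 1:3) {
    if (d_new[axis] == d_old[axis] && abs(s_old[axis] - s_new[axis]) < 1e-9) next
    pos <- ((seq_len(d_new[axis]) - 1) * s_new[axis]) / s_old[axis] + 1
    out <- interp_axis(out, axis, pos, nearest = nearest)
  }
  volume_grid(out, spacing_mm = s_new, origin_mm = vol$origin_mm)
}

#' Clip and normalize intensities
#'
#' Clamps values to `[lo, hi]` and maps them affinely so that `lo -> 0` and
#' `hi -> 1`. This is a fixed global window (not per-volume min-max), so
#' normalized intensities are comparable across subjects. Applying the
#' function with window `(0, 1)` to an already-normalized volume is the
#' identity.
#'
#' @param vol a [volume_grid] (or plain array).
#' @param lo,hi window bounds, `lo < hi`.
#' @return Same type as `vol`, values in `[0, 1]`.
#' @export
clip_and_normalize <- function(vol, lo, hi) {
  if (lo >= hi) stop("'lo' must be strictly less than 'hi'")
  f <- function(v) (pmin(pmax(v, lo), hi) - lo) / (hi - lo)
  if (is_volume_grid(vol)) vg_like(vol, f(vol$values)) else f(vol)
}

#' Condition a raw CT/SUV pair for modelling
#'
#' Runs the standard order of operations: resample both volumes to the common
#' grid (CT and SUV with trilinear interpolation), then clip to the CT window
#' [-100, 250] HU and SUV window [0, 15], then normalize each window to
#' [0, 1]. Tissue classification must be run on the *raw* HU volume before
#' this step, because the tissue thresholds (-190, 200 HU) lie outside the CT
#' clip window.
#'
#' @param ct,suv [volume_grid]s on a common grid.
#' @param spec a [preprocess_spec].
#' @return list with elements `ct` and `suv`, both normalized to `[0, 1]`.
#' @export
preprocess_pair <- function(ct, suv, spec = preprocess_spec()) {
  stop_unless_same_grid(ct, suv, "ct and suv")
  ct_r <- resample_to_common_grid(ct, spec, "continuous")
  suv_r <- resample_to_common_grid(suv, spec, "continuous")
  list(ct = clip_and_normalize(ct_r, spec$ct_clip[1], spec$ct_clip[2]),
       suv = clip_and_normalize(suv_r, spec$suv_clip[1], spec$suv_clip[2]))
}
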