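#' Hounsfield-unit tissue classification rules
#'
#' The four HU windows used to decompose CT into tissue compartments:
#' bone `i >= 200`, lean tissue `-29 <= i <= 150`, adipose tissue
#' `-190 <= i <= -30`, air `i < -190`, where `i` is the raw voxel HU.
#' Boundary inclusivity follows the printed interval notation literally, so
#' -190 is adipose (not air) and the open gap (150, 200) HU belongs to no
#' tissue. The rules are pairwise disjoint by construction.
#'
#' @param bone_min inclusive lower HU bound for bone.
#' @param lean_range inclusive HU range for lean tissue.
#' @param adipose_range inclusive HU range for adipose tissue.
#' @param air_max exclusive upper HU bound for air.
#' @return A list of class `tissue_rules`.
#' @export
tissue_rules <- function(bone_min = 200,
                         lean_range = c(-29, 150),
                         adipose_range = c(-190, -30),
                         air_max = -190) {
  structure(list(bone_min = bone_min,
                 lean_range = as.numeric(lean_range),
                 adipose_range = as.numeric(adipose_range),
                 air_max = air_max),
            class = "tissue_rules")
}

#' Classify CT voxels into tissue compartments
#'
#' Applies the HU threshold rules to a raw (unclipped) CT volume and returns
#' four binary masks. At most one mask is 1 at any voxel; voxels in the HU
#' gap (150, 200) or the open interval (-30, -29) belong to no mask and stay
#' visible only in the original CT/SUV channels.
#'
#' @param ct [volume_grid] of raw HU values (before any clipping).
#' @param rules a [tissue_rules] object.
#' @return Named list of binary [volume_grid]s: `bone`, `lean`, `adipose`,
#'   `air`.
#' @export
classify_voxels <- function(ct, rules = tissue_rules()) {
  stopifnot(is_volume_grid(ct))
  i <- ct$values
  masks <- list(
    bone    = (i >= rules$bone_min),
    lean    = (i >= rules$lean_range[1] & i <= rules$lean_range[2]),
    adipose = (i >= rules$adipose_range[1] & i <= rules$adipose_range[2]),
    air     = (i < rules$air_max))
  lapply(masks, function(m) vg_like(ct, array(as.numeric(m), dim = dim(i))))
}

## normalize one masked CT channel over its occupied range; off-mask stays 0
normalize_ct_channel <- function(channel, mask) {
  v <- channel$values
  occ <- mask$values > 0
  if (!any(occ)) return(channel)
  lo <- min(v[occ]); hi <- max(v[occ])
  out <- array(0, dim = dim(v))
  out[occ] <- if (hi > lo) (v[occ] - lo) / (hi - lo) else 1
  vg_like(channel, out)
}

#' Build tissue-wise CT and SUV channels
#'
#' Multiplies each tissue mask voxel-wise with the raw CT and SUV volumes,
#' producing the per-tissue channels used as extra inputs alongside the
#' original images. With `normalize = TRUE` each masked channel is mapped to
#' [0, 1]: SUV channels through the fixed [0, 15] SUV window (so tissue
#' channels stay comparable across subjects) and CT channels through an
#' affine map over the channel's occupied HU range (off-mask voxels stay 0).
#' The original CT/SUV are deliberately left untouched here; they get the
#' global windows in [preprocess_pair()].
#'
#' @param ct [volume_grid] of raw HU.
#' @param suv [volume_grid] of SUV, same grid.
#' @param masks tissue masks from [classify_voxels()]; computed from `ct`
#'   when omitted.
#' @param normalize logical; normalize masked channels to [0, 1].
#' @param suv_window SUV window used to normalize masked SUV channels.
#' @return A list of class `tissue_channel_set` with elements `masks`,
#'   `ct_channels`, `suv_channels` (named lists over bone/lean/adipose/air),
#'   `normalized`.
#' @export
make_tissue_channels <- function(ct, suv, masks = NULL, normalize = FALSE,
                                 suv_window = c(0, 15)) {
  stopifnot(is_volume_grid(ct), is_volume_grid(suv))
  stop_unless_same_grid(ct, suv, "ct and suv")
  if (is.null(masks)) masks <- classify_voxels(ct)
  stopifnot(identical(sort(names(masks)), sort(c("bone", "lean", "adipose", "air"))))
  for (m in masks) stop_unless_same_grid(ct, m, "ct and masks")

  ct_channels <- lapply(masks, function(m) vg_like(ct, ct$values * m$values))
  suv_channels <- lapply(masks, function(m) vg_like(suv, suv$values * m$values))
  if (normalize) {
    ct_channels <- Map(normalize_ct_channel, ct_channels, masks)
    suv_channels <- lapply(suv_channels, clip_and_normalize,
                           lo = suv_window[1], hi = suv_window[2])
  }
  structure(list(masks = masks,
                 ct_channels = ct_channels,
                 suv_channels = suv_channels,
                 normalized = normalize),
            class = "tissue_channel_set")
}
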