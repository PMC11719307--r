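#' Enumerate projection angles
#'
#' Half-open arithmetic schedule `[start, stop)` in degrees. The default
#' whole-body schedule, -90 to +90 at 10 degree steps, yields the 18 viewing
#' angles -90, -80, ..., +80.
#'
#' @param start_deg inclusive start angle, degrees.
#' @param stop_deg exclusive stop angle, degrees.
#' @param step_deg positive step, degrees.
#' @return A list of class `angle_schedule` with element `angles`.
#' @export
enumerate_angles <- function(start_deg = -90, stop_deg = 90, step_deg = 10) {
  if (!is.numeric(step_deg) || step_deg <= 0) stop("'step_deg' must be positive")
  if (start_deg >= stop_deg) stop("'start_deg' must be less than 'stop_deg'")
  n <- ceiling((stop_deg - start_deg) / step_deg - 1e-9)
  angles <- start_deg + step_deg * (seq_len(n) - 1)
  structure(list(start_deg = start_deg, stop_deg = stop_deg,
                 step_deg = step_deg, angles = angles),
            class = "angle_schedule")
}

#' @export
length.angle_schedule <- function(x) length(x$angles)

#' @export
print.angle_schedule <- function(x, ...) {
  cat(sprintf("<angle_schedule> [%g, %g) deg, step %g: %d angles\n",
              x$start_deg, x$stop_deg, x$step_deg, length(x$angles)))
  invisible(x)
}

#' Manifest of projection records for a cohort
#'
#' One row per (scan, angle) pair; with the default 18-angle schedule a
#' 501-scan cohort yields 9018 projection records.
#'
#' @param n_scans number of scans.
#' @param schedule an [enumerate_angles()] schedule.
#' @return data.frame with columns `scan` and `angle_deg`.
#' @export
projection_manifest <- function(n_scans, schedule = enumerate_angles()) {
  stopifnot(n_scans >= 1)
  expand.grid(angle_deg = schedule$angles, scan = seq_len(n_scans))[, c("scan", "angle_deg")]
}

## round half away from zero-free: round-half-up. Used for all projection
## geometry so that adjacent voxels never collapse onto the same column the
## way IEEE round-half-even would.
rnd <- function(x) floor(x + 0.5)

## padded in-plane extent: covers any rotation of the (nx, ny) plane
pad_extent <- function(nx, ny) as.integer(ceiling(sqrt(nx^2 + ny^2)))

## rotation geometry shared by forward projection and backprojection:
## in-plane centers of the source and padded frames (1-based indices)
rot_geometry <- function(source_shape) {
  nx <- source_shape[1]; ny <- source_shape[2]
  P <- pad_extent(nx, ny)
  list(nx = nx, ny = ny, nz = source_shape[3], P = P,
       cx = (nx + 1) / 2, cy = (ny + 1) / 2, cp = (P + 1) / 2)
}

#' Maximum-intensity projection at a viewing angle
#'
#' Rotates the volume by `angle` about the craniocaudal (z) axis, with the
#' rotation centered at the in-plane grid center, and reduces by maximum
#' along the anterior-posterior (y) axis; angle 0 is therefore a coronal MIP.
#' The rotated frame is padded to the in-plane diagonal so no anatomy leaves
#' the field of view; rows of the output are z slices, columns the padded
#' in-plane coordinate.
#'
#' `mode = "max"` uses bilinear interpolation during rotation (exact
#' nearest-neighbour resampling at multiples of 90 degrees, where the
#' rotation is an axis permutation). `mode = "mask"` requires a binary input
#' and projects by rotating every foreground voxel forward and marking the
#' column it rounds to, so the output is binary and exactly consistent with
#' [backproject_mask()]: backprojecting a mask-mode projection is guaranteed
#' to contain every foreground voxel that produced it.
#'
#' @param vol a [volume_grid].
#' @param angle viewing angle, degrees.
#' @param mode `"max"` or `"mask"`.
#' @return A numeric matrix of dimension (nz, padded extent) with attribute
#'   `mip_geometry` recording `angle`, `source_shape` and `pad`.
#' @export
mip_at_angle <- function(vol, angle, mode = c("max", "mask")) {
  stopifnot(is_volume_grid(vol))
  mode <- match.arg(mode)
  g <- rot_geometry(dim(vol$values))
  th <- angle * pi / 180
  if (mode == "mask") {
    if (!is_binary(vol)) stop("mask-mode projection requires a binary volume")
    img <- project_mask_splat(vol$values, th, g)
  } else {
    img <- project_max_rotate(vol$values, th, g,
                              nearest = isTRUE(all.equal(angle %% 90, 0)) ||
                                isTRUE(all.equal(angle %% 90, 90)))
  }
  attr(img, "mip_geometry") <- list(angle = angle,
                                    source_shape = dim(vol$values),
                                    pad = g$P,
                                    spacing_mm = vol$spacing_mm)
  img
}

## forward splat projection of a binary volume: each foreground voxel is
## rotated by +theta and marks the padded column its x coordinate rounds to
project_mask_splat <- function(vals, th, g) {
  img <- matrix(0, nrow = g$nz, ncol = g$P)
  idx <- which(vals > 0)
  if (length(idx) == 0L) return(img)
  co <- arrayInd(idx, dim(vals))
  xr <- g$cp + (co[, 1] - g$cx) * cos(th) - (co[, 2] - g$cy) * sin(th)
  col <- rnd(xr)
  keep <- col >= 1 & col <= g$P
  img[cbind(co[keep, 3], col[keep])] <- 1
  img
}

## inverse-mapping rotation of the full volume followed by max along the
## rotated y axis; bilinear (or nearest) sampling, zero outside the source
project_max_rotate <- function(vals, th, g, nearest = FALSE) {
  P <- g$P; nx <- g$nx; ny <- g$ny; nz <- g$nz
  xp <- rep(seq_len(P), times = P) - g$cp   # x' (fast axis)
  yp <- rep(seq_len(P), each = P) - g$cp    # y'
  xs <- g$cx + xp * cos(th) + yp * sin(th)
  ys <- g$cy - xp * sin(th) + yp * cos(th)
  A2 <- matrix(vals, nx * ny, nz)
  gather <- function(ix, iy, w) {
    ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny & w > 0
    lin <- ifelse(ok, ix + (iy - 1L) * nx, 1L)
    (w * ok) * A2[lin, , drop = FALSE]
  }
  if (nearest) {
    rot <- gather(rnd(xs), rnd(ys), rep(1, length(xs)))
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    fx <- xs - x0; fy <- ys - y0
    rot <- gather(x0,      y0,      (1 - fx) * (1 - fy)) +
           gather(x0 + 1L, y0,      fx       * (1 - fy)) +
           gather(x0,      y0 + 1L, (1 - fx) * fy) +
           gather(x0 + 1L, y0 + 1L, fx       * fy)
  }
  dim(rot) <- c(P, P, nz)
  m <- rot[, 1, ]
  for (j in seq_len(P)[-1]) m <- pmax(m, rot[, j, ])
  t(m)  # (nz, P)
}

#' Build a multi-channel multi-angle projection stack
#'
#' For every angle of the schedule, projects the original SUV volume and
#' (when a [tissue_channel_set] is supplied) the four tissue-wise SUV
#' channels in max mode, and the ground-truth lesion mask in mask mode.
#' With tissue channels this gives the 5-channel projections (SUVorgMIP,
#' SUVboneMIP, SUVleanMIP, SUVadiposeMIP, SUVairMIP); without, a
#' single-channel (SUVorgMIP-only) stack. Under the default 18-angle
#' schedule a 5-channel stack holds 90 images plus 18 ground-truth masks.
#'
#' @param suv [volume_grid] of SUV values.
#' @param tissue optional [make_tissue_channels()] result; adds the four
#'   tissue SUV channels.
#' @param truth optional binary [volume_grid]; adds per-angle projected
#'   ground-truth masks.
#' @param schedule an [enumerate_angles()] schedule.
#' @return A list of class `projection_stack` with `angles`, `channels`,
#'   `images` (per angle, a named list of matrices), `gt_masks` (per angle
#'   or NULL), `source_shape`, `spacing_mm`, `pad`.
#' @export
build_projection_stack <- function(suv, tissue = NULL, truth = NULL,
                                   schedule = enumerate_angles()) {
  stopifnot(is_volume_grid(suv))
  vols <- list(SUVorgMIP = suv)
  if (!is.null(tissue)) {
    stopifnot(inherits(tissue, "tissue_channel_set"))
    for (m in tissue$suv_channels) stop_unless_same_grid(suv, m, "suv and tissue channels")
    vols <- c(vols, list(SUVboneMIP = tissue$suv_channels$bone,
                         SUVleanMIP = tissue$suv_channels$lean,
                         SUVadiposeMIP = tissue$suv_channels$adipose,
                         SUVairMIP = tissue$suv_channels$air))
  }
  if (!is.null(truth)) {
    stop_unless_same_grid(suv, truth, "suv and truth")
    if (!is_binary(truth)) stop("'truth' must be binary")
  }
  images <- lapply(schedule$angles, function(a)
    lapply(vols, function(v) mip_at_angle(v, a, "max")))
  gt <- if (!is.null(truth))
    lapply(schedule$angles, function(a) mip_at_angle(truth, a, "mask"))
  structure(list(angles = schedule,
                 channels = names(vols),
                 images = images,
                 gt_masks = gt,
                 source_shape = dim(suv$values),
                 spacing_mm = suv$spacing_mm,
                 pad = pad_extent(dim(suv$values)[1], dim(suv$values)[2])),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  cat(sprintf("<projection_stack> %d angles x %d channels (%s)%s\n",
              length(x$angles), length(x$channels),
              paste(x$channels, collapse = ", "),
              if (is.null(x$gt_masks)) "" else " + ground-truth masks"))
  invisible(x)
}
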