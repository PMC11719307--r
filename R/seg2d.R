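#' Construct a 2D segmenter
#'
#' A 2D segmenter maps one multi-channel projection (a named list of 2D
#' images) to one binary mask of the same shape. Deterministic reference
#' backends ([threshold_segmenter()], [oracle_segmenter()]) exercise the
#' geometric pipeline without any training; neural backends (e.g. a UNet++
#' over the 5-channel projections) can be plugged in behind the same
#' contract.
#'
#' @param name backend name.
#' @param accepts number of input channels the backend expects (1 for
#'   SUVorgMIP-only, 5 for the tissue-wise multi-channel input).
#' @param predict function `(channels, angle_index)` returning a binary
#'   matrix shaped like the input images.
#' @return An object of class `segmenter2d`.
#' @export
new_segmenter2d <- function(name, accepts, predict) {
  stopifnot(is.character(name), accepts >= 1, is.function(predict))
  structure(list(name = name, accepts = as.integer(accepts), predict = predict),
            class = "segmenter2d")
}

#' SUV-threshold 2D segmenter
#'
#' Thresholds the SUVorgMIP channel at a fixed SUV value. A deterministic
#' stand-in for a trained 2D network, sufficient to drive backprojection and
#' prior construction end to end.
#'
#' @param threshold positive SUV threshold; pixels strictly above it are
#'   foreground.
#' @return A `segmenter2d` accepting any stack (it reads only SUVorgMIP).
#' @export
threshold_segmenter <- function(threshold) {
  if (!is.numeric(threshold) || threshold < 0)
    stop("'threshold' must be non-negative")
  new_segmenter2d(
    name = sprintf("suv_threshold_%g", threshold),
    accepts = 1L,
    predict = function(channels, angle_index) {
      img <- channels$SUVorgMIP
      if (is.null(img)) stop("stack has no SUVorgMIP channel")
      out <- (img > threshold) * 1
      attr(out, "mip_geometry") <- attr(img, "mip_geometry")
      out
    })
}

#' Oracle 2D segmenter
#'
#' Returns the projected ground-truth mask at each angle — a perfect 2D
#' stage. Useful as an upper bound: downstream prior quality with any real
#' backend cannot exceed the oracle's on the same phantom.
#'
#' @param stack a [build_projection_stack()] result carrying `gt_masks`.
#' @return A `segmenter2d`.
#' @export
oracle_segmenter <- function(stack) {
  stopifnot(inherits(stack, "projection_stack"))
  if (is.null(stack$gt_masks))
    stop("oracle segmenter requires a stack built with ground truth")
  gt <- stack$gt_masks
  new_segmenter2d(
    name = "oracle",
    accepts = 1L,
    predict = function(channels, angle_index) gt[[angle_index]])
}

#' Ensemble of 2D segmenters by pixel-wise union
#'
#' Combines the masks of several backends with a pixel-wise OR, maximizing
#' the number of detected lesions; false-positive filtering is left to the
#' individual backends.
#'
#' @param ... two or more `segmenter2d` objects.
#' @return A `segmenter2d`.
#' @export
ensemble_segmenter <- function(...) {
  members <- list(...)
  stopifnot(length(members) >= 2, all(vapply(members, inherits, TRUE, "segmenter2d")))
  new_segmenter2d(
    name = paste0("ensemble(", paste(vapply(members, `[[`, "", "name"), collapse = "+"), ")"),
    accepts = max(vapply(members, `[[`, 1L, "accepts")),
    predict = function(channels, angle_index) {
      masks <- lapply(members, function(s) s$predict(channels, angle_index))
      out <- Reduce(pmax, masks)
      attr(out, "mip_geometry") <- attr(masks[[1]], "mip_geometry")
      out
    })
}

#' Run a 2D segmenter over a projection stack
#'
#' Applies the segmenter to every angle of the stack and validates the
#' contract: each output must be binary and shaped like the stack's images.
#' A 5-channel backend requires the stack to carry all five channels.
#'
#' @param segmenter a `segmenter2d`.
#' @param stack a `projection_stack`.
#' @return List of per-angle binary masks, each with the angle's
#'   `mip_geometry` attribute.
#' @export
predict_stack <- function(segmenter, stack) {
  stopifnot(inherits(segmenter, "segmenter2d"), inherits(stack, "projection_stack"))
  if (segmenter$accepts > length(stack$channels))
    stop(sprintf("segmenter '%s' expects %d channels but the stack has %d",
                 segmenter$name, segmenter$accepts, length(stack$channels)))
  lapply(seq_along(stack$angles$angles), function(i) {
    m <- segmenter$predict(stack$images[[i]], i)
    ref <- stack$images[[i]][[1]]
    if (!identical(dim(m), dim(ref)))
      stop(sprintf("backend '%s' returned a %s mask for a %s image",
                   segmenter$name, paste(dim(m), collapse = "x"),
                   paste(dim(ref), collapse = "x")))
    if (!is_binary(m))
      stop(sprintf("backend '%s' returned a non-binary mask", segmenter$name))
    if (is.null(attr(m, "mip_geometry")))
      attr(m, "mip_geometry") <- attr(ref, "mip_geometry")
    m
  })
}
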