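# Two-channel 3D confocal stack container with anisotropic voxel geometry.

#' Construct a confocal image stack
#'
#' A 3D voxel grid per channel with physical voxel sizes. The reference
#' acquisition geometry is a 460 um x 460 um field with 6.7 um optical
#' slices (slice thickness chosen to approximate a cell-nucleus diameter),
#' but any anisotropic geometry is accepted. Slice index 1 is the gel
#' surface plane; projections run along the slice axis.
#'
#' @param channels Named list of 3D numeric arrays (x, y, slice), identical
#'   dimensions; conventionally `nuclei` and `actin`.
#' @param pixel_size In-plane pixel size, um.
#' @param slice_thickness Axial slice thickness, um.
#' @return Object of class `image_stack`.
#' @export
image_stack <- function(channels, pixel_size, slice_thickness) {
  if (!is.list(channels) || is.null(names(channels)) || !length(channels)) {
    stop_invalid("channels", "must be a named list of 3D arrays")
  }
  dims <- dim(channels[[1]])
  if (length(dims) != 3L) stop_invalid("channels", "arrays must be 3D (x, y, slice)")
  for (nm in names(channels)) {
    if (!identical(dim(channels[[nm]]), dims)) {
      stop_invalid("channels", "all channels must share dimensions")
    }
  }
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(slice_thickness, "slice_thickness", positive = TRUE)
  structure(
    list(channels = channels, pixel_size = pixel_size,
         slice_thickness = slice_thickness,
         channel_names = names(channels), dim = dims),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- x$dim
  cat(sprintf("Confocal stack: %d x %d px x %d slices (%.1f x %.1f x %.1f um)\n",
              d[1], d[2], d[3], d[1] * x$pixel_size, d[2] * x$pixel_size,
              d[3] * x$slice_thickness))
  cat(sprintf("  voxel %.2f x %.2f x %.2f um; channels: %s\n",
              x$pixel_size, x$pixel_size, x$slice_thickness,
              paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

stack_channel <- function(stack, channel) {
  if (is.numeric(channel)) channel <- stack$channel_names[channel]
  if (!channel %in% stack$channel_names) {
    stop(sprintf("channel '%s' not present", channel), call. = FALSE)
  }
  stack$channels[[channel]]
}

# Voxel-centre physical coordinates along each axis.
stack_axes <- function(stack) {
  d <- stack$dim
  list(x = (seq_len(d[1]) - 0.5) * stack$pixel_size,
       y = (seq_len(d[2]) - 0.5) * stack$pixel_size,
       z = (seq_len(d[3]) - 0.5) * stack$slice_thickness)
}
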