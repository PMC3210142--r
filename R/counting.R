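# Integrated-fluorescence cell counting: calibrate the summed nuclear signal
# of an average single cell, then divide each cluster's background-corrected
# integrated signal by it.

# Default growth of segmented objects before summing: slightly over one
# nucleus diameter in-plane and two slices axially, enough to capture the
# sub-threshold tails of a nuclear blob at the reference geometry (the
# axial direction is the lossy one: a nucleus-sized object thresholds to
# only one or two 6.7 um slices).
default_dilate_um <- 8
default_dilate_slices <- 2L

dilation_px <- function(stack, dilate_um) {
  max(1L, as.integer(ceiling(dilate_um / stack$pixel_size)))
}

# Background-corrected integrated signal over a (dilated) voxel set.
integrated_signal <- function(v, idx, background_per_voxel) {
  sum(v[idx]) - background_per_voxel * length(idx)
}

#' Calibrate the fluorescent signal of a single cell nucleus
#'
#' Estimates the average summed nuclear fluorescence of one isolated
#' (non-clustered) cell: reference components are selected automatically as
#' those whose volume lies within a band around the median component volume
#' (or supplied explicitly), each is dilated so sub-threshold tails are
#' captured, and its summed intensity is background-corrected. The
#' per-voxel background is a trimmed mean over voxels outside all dilated
#' objects.
#'
#' @param stack An [image_stack()].
#' @param seg A [segment_objects()] result for the nuclei channel.
#' @param selection Integer object ids to use as reference singles, or
#'   `NULL` for automatic volume-band selection.
#' @param volume_band Relative band around the median component volume for
#'   automatic selection.
#' @param dilate_um In-plane dilation radius, um.
#' @param dilate_slices Axial dilation, slices.
#' @param trim Trim fraction for the background mean.
#' @return Object of class `nucleus_calibration`: `single_cell_signal`,
#'   `background_per_voxel`, `n_reference_cells`, `reference_ids`,
#'   `reference_signals`.
#' @export
calibrate_single_cell <- function(stack, seg, selection = NULL,
                                  volume_band = c(0.6, 1.7),
                                  dilate_um = default_dilate_um,
                                  dilate_slices = default_dilate_slices,
                                  trim = 0.2) {
  v <- stack_channel(stack, seg$channel)
  rpx <- dilation_px(stack, dilate_um)
  if (is.null(selection)) {
    med <- stats::median(seg$sizes)
    selection <- which(seg$sizes >= volume_band[1] * med &
                         seg$sizes <= volume_band[2] * med)
  }
  if (!length(selection)) {
    stop(paste("no isolated nuclei found for calibration;",
               "supply `selection` with reference object ids"), call. = FALSE)
  }
  dil <- lapply(selection, function(id)
    dilate_voxels(object_voxels(seg, id), seg$dims, rpx, dilate_slices))
  # background from voxels outside every dilated object
  obj_any <- dilate_voxels(which(seg$labels > 0L), seg$dims, rpx, dilate_slices)
  bg_vox <- as.numeric(v)[-obj_any]
  if (!length(bg_vox)) stop("no background voxels available", call. = FALSE)
  bg <- mean(bg_vox, trim = trim)
  sig <- vapply(dil, function(idx) integrated_signal(v, idx, bg), numeric(1))
  scs <- mean(sig)
  if (scs <= 0) stop("calibration signal <= 0", call. = FALSE)
  structure(
    list(single_cell_signal = scs, background_per_voxel = bg,
         n_reference_cells = length(selection), reference_ids = selection,
         reference_signals = sig,
         dilate_um = dilate_um, dilate_slices = dilate_slices),
    class = "nucleus_calibration")
}

#' @export
print.nucleus_calibration <- function(x, ...) {
  cat(sprintf("Single-cell nuclear calibration: %.4g units/cell (n = %d)\n",
              x$single_cell_signal, x$n_reference_cells))
  cat(sprintf("  background %.4g units/voxel\n", x$background_per_voxel))
  invisible(x)
}

#' Estimate the number of cells in a cluster from its integrated signal
#'
#' Sums the nuclear fluorescence over the cluster volume (the segmented
#' component grown by the same dilation used in calibration), subtracts the
#' per-voxel background, and divides by the average single-cell signal.
#' Negative corrected signals are clamped to zero with a warning.
#'
#' @param cluster Object id in `seg`, or a vector of linear voxel indices
#'   (taken as the already-outlined cluster volume and then dilated).
#' @param stack An [image_stack()].
#' @param cal A [calibrate_single_cell()] result.
#' @param seg The segmentation (required when `cluster` is an object id).
#' @param dilate Grow the voxel set before summing (default `TRUE`).
#' @return Estimated number of cells (non-negative real).
#' @export
count_cluster_cells <- function(cluster, stack, cal, seg = NULL, dilate = TRUE) {
  if (!inherits(cal, "nucleus_calibration") || cal$single_cell_signal <= 0) {
    stop("invalid calibration: single-cell signal must be positive", call. = FALSE)
  }
  if (!is.null(seg) && length(cluster) == 1L && cluster <= seg$n_objects) {
    idx <- object_voxels(seg, cluster)
    dims <- seg$dims
    channel <- seg$channel
  } else {
    idx <- as.integer(cluster)
    dims <- stack$dim
    channel <- "nuclei"
  }
  if (!length(idx)) return(0)
  v <- stack_channel(stack, channel)
  if (dilate) {
    idx <- dilate_voxels(idx, dims, dilation_px(stack, cal$dilate_um),
                         cal$dilate_slices)
  }
  est <- integrated_signal(v, idx, cal$background_per_voxel) / cal$single_cell_signal
  if (est < 0) {
    warning("negative background-corrected signal; clamping estimate to 0")
    est <- 0
  }
  est
}

#' Morphometrics of a segmented cluster
#'
#' Computes the three cluster dimensions: height perpendicular to the gel
#' surface (number of slices spanned times slice thickness), maximum area
#' projected onto the gel surface (projected pixel count times pixel area),
#' and maximum in-plane dimension (maximum Feret diameter of the projection,
#' measured between projected pixel centres; a single-pixel projection is
#' assigned its pixel diagonal).
#'
#' @param cluster Object id (with `seg`) or vector of linear voxel indices.
#' @param stack An [image_stack()] supplying the voxel geometry.
#' @param seg Optional segmentation for id lookup.
#' @return Named list: `height` (um), `projected_area` (um^2),
#'   `max_dimension` (um), `voxel_count`.
#' @export
measure_cluster <- function(cluster, stack, seg = NULL) {
  if (!is.null(seg) && length(cluster) == 1L && cluster <= seg$n_objects) {
    idx <- object_voxels(seg, cluster)
  } else {
    idx <- as.integer(cluster)
  }
  if (!length(idx)) stop("empty voxel set", call. = FALSE)
  dims <- stack$dim
  nx <- dims[1]; ny <- dims[2]
  px <- stack$pixel_size
  i0 <- idx - 1L
  xi <- i0 %% nx
  yi <- (i0 %/% nx) %% ny
  zi <- i0 %/% (nx * ny)
  height <- (max(zi) - min(zi) + 1L) * stack$slice_thickness
  proj <- unique(xi + yi * nx)
  area <- length(proj) * px^2
  if (length(proj) == 1L) {
    maxdim <- sqrt(2) * px
  } else {
    pxy <- cbind((proj %% nx) + 0.5, (proj %/% nx) + 0.5) * px
    hull <- grDevices::chull(pxy)
    pts <- pxy[hull, , drop = FALSE]
    maxdim <- sqrt(max(stats::dist(pts)^2))
  }
  list(height = height, projected_area = area, max_dimension = maxdim,
       voxel_count = length(idx))
}

#' Summarize cell clustering in a field
#'
#' Full field-level reduction: segment the nuclei channel, calibrate the
#' single-cell signal, estimate each component's cell content, classify
#' components as clusters when the estimate reaches `min_cluster_size`
#' (default 5, i.e. groups of more than 4 cells in mutual contact; a 0.5
#' rounding guard admits fractional estimates from 4.5 up), and report the
#' percentage of cells found in clusters together with per-cluster
#' morphometrics. Non-cluster components are counted directly as single
#' cells, so clustered + single cells equals the total by construction.
#'
#' @param stack An [image_stack()].
#' @param cal Optional [calibrate_single_cell()] result (computed if `NULL`).
#' @param min_cluster_size Minimum estimated cells for a cluster (cells).
#' @param rounding_guard Tolerance subtracted from `min_cluster_size` when
#'   comparing fractional estimates.
#' @param seg Optional precomputed segmentation.
#' @param ... Passed to [segment_objects()] / [calibrate_single_cell()].
#' @return Object of class `clustering_summary`: `n_total_cells`,
#'   `n_clustered_cells`, `percent_clustered`, `n_clusters`,
#'   `min_cluster_size`, and `clusters` (data frame of `ClusterRecord`s).
#' @export
summarize_clustering <- function(stack, cal = NULL, min_cluster_size = 5,
                                 rounding_guard = 0.5, seg = NULL, ...) {
  if (is.null(seg)) seg <- segment_objects(stack, ...)
  if (is.null(cal)) cal <- calibrate_single_cell(stack, seg)
  est <- vapply(seq_len(seg$n_objects), function(id)
    count_cluster_cells(id, stack, cal, seg = seg), numeric(1))
  is_cluster <- est >= (min_cluster_size - rounding_guard)
  n_clustered <- sum(est[is_cluster])
  n_singles <- sum(!is_cluster)
  n_total <- n_clustered + n_singles
  ids <- which(is_cluster)
  v <- stack_channel(stack, seg$channel)
  recs <- lapply(ids, function(id) {
    m <- measure_cluster(id, stack, seg = seg)
    idx <- dilate_voxels(object_voxels(seg, id), seg$dims,
                         dilation_px(stack, cal$dilate_um), cal$dilate_slices)
    data.frame(cluster_id = id, voxel_count = m$voxel_count,
               integrated_signal = integrated_signal(v, idx,
                                                     cal$background_per_voxel),
               estimated_cells = est[id], height = m$height,
               projected_area = m$projected_area,
               max_dimension = m$max_dimension)
  })
  clusters <- if (length(recs)) do.call(rbind, recs) else
    data.frame(cluster_id = integer(0), voxel_count = integer(0),
               integrated_signal = numeric(0), estimated_cells = numeric(0),
               height = numeric(0), projected_area = numeric(0),
               max_dimension = numeric(0))
  structure(
    list(n_total_cells = n_total, n_clustered_cells = n_clustered,
         percent_clustered = if (n_total > 0) 100 * n_clustered / n_total else 0,
         n_clusters = length(ids), n_single_cells = n_singles,
         min_cluster_size = min_cluster_size, clusters = clusters,
         estimates = est, calibration = cal),
    class = "clustering_summary")
}

#' @export
print.clustering_summary <- function(x, ...) {
  cat(sprintf("Cell clustering summary: %.1f%% of %.1f cells in %d clusters\n",
              x$percent_clustered, x$n_total_cells, x$n_clusters))
  cat(sprintf("  cluster definition: >= %g cells in contact; %d single cells\n",
              x$min_cluster_size, x$n_single_cells))
  if (nrow(x$clusters)) {
    cat(sprintf("  cluster sizes: %s cells\n",
                paste(sprintf("%.1f", x$clusters$estimated_cells), collapse = ", ")))
  }
  invisible(x)
}
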