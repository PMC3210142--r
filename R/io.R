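# File formats at the package boundary:
#   force curves     2-column TSV (z_piezo_um, deflection_nm) + JSON sidecar
#   image stacks     multi-page float TIFF (slice-major, channels
#                    interleaved within a slice) + JSON voxel metadata
#   assay plates     long-format CSV
# Internal units (um / nm / nN / Pa) are fixed; conversions live here only.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a force curve to TSV with a JSON metadata sidecar
#'
#' @param curve A [force_curve()].
#' @param path Output TSV path; metadata goes to the same stem `.json`.
#' @return Invisibly, the TSV path.
#' @export
write_force_curve <- function(curve, path) {
  df <- data.frame(z_piezo_um = curve$z_piezo,
                   deflection_nm = curve$deflection %||%
                     (curve_force(curve) / curve$cantilever_stiffness * 1000))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(cantilever_stiffness_pN_nm = curve$cantilever_stiffness,
               probe_radius_um = curve$probe_radius,
               label = curve$label)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a force curve from a delimited table
#'
#' Reads the package's TSV format (with its JSON sidecar) or any delimited
#' table with configurable column names. Either a deflection column (nm,
#' with cantilever stiffness from the sidecar or argument) or a force
#' column (nN) must be present.
#'
#' @param path Table path.
#' @param col_z,col_deflection,col_force Column names.
#' @param sep Field separator (default tab).
#' @param cantilever_stiffness,probe_radius Metadata overrides.
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path, col_z = "z_piezo_um",
                             col_deflection = "deflection_nm",
                             col_force = "force_nN", sep = "\t",
                             cantilever_stiffness = NULL, probe_radius = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  if (!col_z %in% names(df)) {
    stop(sprintf("column '%s' not found", col_z), call. = FALSE)
  }
  stiff <- cantilever_stiffness %||% meta$cantilever_stiffness_pN_nm %||% NA_real_
  radius <- probe_radius %||% meta$probe_radius_um %||% NA_real_
  if (col_deflection %in% names(df)) {
    force_curve(df[[col_z]], deflection = df[[col_deflection]],
                cantilever_stiffness = stiff, probe_radius = radius,
                label = meta$label %||% basename(path))
  } else if (col_force %in% names(df)) {
    force_curve(df[[col_z]], force = df[[col_force]],
                cantilever_stiffness = stiff %||% NA_real_,
                probe_radius = radius, label = meta$label %||% basename(path))
  } else {
    stop(sprintf("neither '%s' nor '%s' column found",
                 col_deflection, col_force), call. = FALSE)
  }
}

#' Write an image stack as multi-page TIFF plus JSON metadata
#'
#' Pages are slice-major with channels interleaved within each slice
#' (slice 1 channel 1, slice 1 channel 2, slice 2 channel 1, ...).
#' Intensities are stored as 32-bit float scaled to [0, 1]; the scale
#' factor and voxel geometry go to the JSON sidecar.
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path; metadata goes to the same stem `.json`.
#' @return Invisibly, the TIFF path.
#' @export
write_image_stack <- function(stack, path) {
  d <- stack$dim
  scale <- max(1e-12, max(vapply(stack$channels, max, numeric(1))))
  pages <- list()
  for (s in seq_len(d[3])) {
    for (ch in stack$channel_names) {
      # TIFF rows = y, columns = x
      pages[[length(pages) + 1L]] <- t(stack$channels[[ch]][, , s]) / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(pixel_size_um = stack$pixel_size,
               slice_thickness_um = stack$slice_thickness,
               n_slices = d[3], channels = stack$channel_names,
               intensity_scale = scale, page_order = "slice_major_channel_interleaved")
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path (JSON sidecar expected at the same stem unless
#'   `meta` is supplied).
#' @param meta Optional metadata list overriding the sidecar.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, meta = NULL) {
  meta <- meta %||% jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  chn <- meta$channels
  n_ch <- length(chn)
  n_sl <- length(pages) / n_ch
  if (n_sl != round(n_sl)) stop("page count not divisible by channels", call. = FALSE)
  dims <- c(ncol(pages[[1]]), nrow(pages[[1]]), n_sl)
  scale <- meta$intensity_scale %||% 1
  channels <- stats::setNames(
    lapply(seq_len(n_ch), function(ci) {
      arr <- array(0, dims)
      for (s in seq_len(n_sl)) {
        arr[, , s] <- t(pages[[(s - 1) * n_ch + ci]]) * scale
      }
      arr
    }), chn)
  image_stack(channels, pixel_size = meta$pixel_size_um,
              slice_thickness = meta$slice_thickness_um)
}

#' Write an assay plate table to CSV
#'
#' @param plate An `assay_plate` data frame.
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_plate_csv <- function(plate, path) {
  utils::write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' Read an assay plate table from CSV
#'
#' Expects at least `well`, `role`, `analyte`, `absorbance` columns.
#'
#' @param path CSV path.
#' @return An `assay_plate` data frame.
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "role", "analyte", "absorbance")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("plate CSV missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  class(df) <- c("assay_plate", "data.frame")
  df
}
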