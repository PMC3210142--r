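# Ground-truthed phantom generator for the cluster-counting analysis:
# fields of isolated nuclei plus densely packed 3D clusters, rendered as
# isotropic Gaussian blobs sampled onto the anisotropic voxel grid.

#' Specification for a simulated two-channel confocal stack
#'
#' Defaults follow the reference acquisition geometry: 460 um square field,
#' 6.7 um slices (one nucleus diameter), nuclei rendered as isotropic
#' Gaussian blobs with FWHM equal to the nucleus diameter. Noise defaults -
#' 10% per-nucleus intensity CV and a uniform background at 5% of the peak -
#' emulate staining variability and diffuse background; signal-dependent
#' (Poisson) noise can be enabled on top.
#'
#' @param field_size Field extent `c(x, y)`, um.
#' @param n_slices Number of confocal slices.
#' @param slice_thickness Slice thickness, um.
#' @param pixel_size In-plane pixel size, um.
#' @param nucleus_diameter Nucleus FWHM, um.
#' @param nucleus_peak_intensity Mean peak intensity, arbitrary units.
#' @param intensity_cv Coefficient of variation of per-nucleus peak intensity.
#' @param background_level Uniform background as a fraction of the mean peak.
#' @param shot_noise Add Poisson (signal-dependent) noise to each voxel.
#' @param cluster_specs List of cluster descriptions; each element is a list
#'   with `cell_count` and optionally `center` (`c(x, y, z)` um) and
#'   `packing_radius` (um). Missing centers/radii are chosen automatically.
#' @param n_single_cells Number of isolated (non-clustered) nuclei.
#' @param rng_seed Integer seed, or `NULL`.
#' @return Object of class `stack_sim_spec`.
#' @export
stack_sim_spec <- function(field_size = c(460, 460),
                           n_slices = 12,
                           slice_thickness = 6.7,
                           pixel_size = 1.8,
                           nucleus_diameter = 6.7,
                           nucleus_peak_intensity = 1000,
                           intensity_cv = 0.1,
                           background_level = 0.05,
                           shot_noise = FALSE,
                           cluster_specs = list(),
                           n_single_cells = 0,
                           rng_seed = NULL) {
  if (length(field_size) != 2L || any(field_size <= 0)) {
    stop_invalid("field_size", "must be two positive extents (um)")
  }
  check_scalar(n_slices, "n_slices", positive = TRUE)
  check_scalar(slice_thickness, "slice_thickness", positive = TRUE)
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  check_scalar(nucleus_diameter, "nucleus_diameter", positive = TRUE)
  check_scalar(nucleus_peak_intensity, "nucleus_peak_intensity", positive = TRUE)
  check_scalar(intensity_cv, "intensity_cv", nonnegative = TRUE)
  check_scalar(background_level, "background_level", nonnegative = TRUE)
  check_scalar(n_single_cells, "n_single_cells", nonnegative = TRUE)
  if (!is.list(cluster_specs)) stop_invalid("cluster_specs", "must be a list")
  for (cs in cluster_specs) {
    if (is.null(cs$cell_count) || cs$cell_count < 1) {
      stop_invalid("cluster_specs", "each cluster needs cell_count >= 1")
    }
  }
  structure(
    list(field_size = field_size, n_slices = as.integer(n_slices),
         slice_thickness = slice_thickness, pixel_size = pixel_size,
         nucleus_diameter = nucleus_diameter,
         nucleus_peak_intensity = nucleus_peak_intensity,
         intensity_cv = intensity_cv, background_level = background_level,
         shot_noise = isTRUE(shot_noise), cluster_specs = cluster_specs,
         n_single_cells = as.integer(n_single_cells), rng_seed = rng_seed),
    class = "stack_sim_spec")
}

# Default packing radius: random sequential addition of N centres with
# minimum spacing s succeeds comfortably below ~35% sphere packing; this
# keeps the occupied fraction near 20%.
auto_packing_radius <- function(n, spacing) {
  max(spacing, (spacing / 2) * (n / 0.2)^(1 / 3))
}

# Random sequential addition of `n` centres inside a sphere, restricted to
# the axial slab [z_lo, z_hi], with minimum pairwise spacing `s`.
pack_cluster <- function(n, center, radius, s, z_lo, z_hi, max_attempts = 50000L) {
  pts <- matrix(NA_real_, n, 3)
  got <- 0L
  attempts <- 0L
  while (got < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf("cluster of %d cells does not fit packing radius %.1f um",
                   n, radius), call. = FALSE)
    }
    u <- stats::runif(3, -1, 1)
    if (sum(u^2) > 1) next
    p <- center + radius * u
    if (p[3] < z_lo || p[3] > z_hi) next
    if (got > 0L) {
      dd <- sqrt(colSums((t(pts[seq_len(got), , drop = FALSE]) - p)^2))
      if (min(dd) < s) next
    }
    got <- got + 1L
    pts[got, ] <- p
  }
  pts
}

# Add one isotropic Gaussian blob (truncated at 4 sigma, where the density
# is ~3e-4 of peak) to `vol`. In-plane the Gaussian is point-sampled at
# pixel centres (pixels are fine relative to sigma); axially each slice
# integrates the Gaussian over its full thickness, as a thick confocal
# optical section does - this also makes the rendered integral independent
# of where the nucleus sits relative to the slice grid. Returns the updated
# volume and the rendered integral.
render_blob <- function(vol, axes, center, sigma, peak, slice_thickness) {
  r <- 4 * sigma
  ix <- which(abs(axes$x - center[1]) <= r)
  iy <- which(abs(axes$y - center[2]) <= r)
  iz <- which(abs(axes$z - center[3]) <= r)
  if (!length(ix) || !length(iy) || !length(iz)) {
    return(list(vol = vol, integral = 0))
  }
  gx <- exp(-(axes$x[ix] - center[1])^2 / (2 * sigma^2))
  gy <- exp(-(axes$y[iy] - center[2])^2 / (2 * sigma^2))
  # mean Gaussian density across the slice, normalized so a slice centred on
  # the nucleus reads close to the nominal peak
  h <- slice_thickness / 2
  gz <- (stats::pnorm((axes$z[iz] + h - center[3]) / sigma) -
           stats::pnorm((axes$z[iz] - h - center[3]) / sigma)) *
    sqrt(2 * pi) * sigma / slice_thickness
  blob <- peak * (gx %o% gy %o% gz)
  # zero out corners beyond the spherical support so truncation is
  # radially symmetric (keeps single/cluster tail losses identical)
  dx2 <- (axes$x[ix] - center[1])^2
  dy2 <- (axes$y[iy] - center[2])^2
  dz2 <- (axes$z[iz] - center[3])^2
  rr <- outer(outer(dx2, dy2, "+"), dz2, "+")
  blob[rr > r^2] <- 0
  vol[ix, iy, iz] <- vol[ix, iy, iz] + blob
  list(vol = vol, integral = sum(blob))
}

#' Simulate a two-channel confocal stack with known cell content
#'
#' Renders isolated nuclei and 3D multi-cell clusters as Gaussian blobs
#' (FWHM = nucleus diameter) on the anisotropic voxel grid, draws per-nucleus
#' peak intensities with the given CV, adds a constant background and
#' optional Poisson noise, and returns the stack together with a ground
#' truth table listing every nucleus (position, cluster membership, rendered
#' integral). Cluster nuclei are packed by rejection sampling inside a
#' sphere with minimum centre spacing 0.8 nucleus diameters, so neighbouring
#' nuclei touch and merge into one connected object after thresholding -
#' the regime the integrated-signal counting method is designed for. The
#' actin channel is a diffuse cell-body stand-in (wider Gaussian per cell)
#' and carries no ground-truth guarantees.
#'
#' @param spec A [stack_sim_spec()].
#' @return List with `stack` (an [image_stack()]) and `truth` (list:
#'   `nuclei` data frame, `clusters` data frame, `n_total`).
#' @export
simulate_stack <- function(spec) {
  if (!inherits(spec, "stack_sim_spec")) {
    spec <- do.call(stack_sim_spec, as.list(spec))
  }
  px <- spec$pixel_size
  dz <- spec$slice_thickness
  nx <- max(1L, round(spec$field_size[1] / px))
  ny <- max(1L, round(spec$field_size[2] / px))
  nz <- spec$n_slices
  sigma <- spec$nucleus_diameter / (2 * sqrt(2 * log(2)))  # FWHM -> sd
  r3 <- 4 * sigma  # rendered blob support radius; placement margin
  Lx <- nx * px; Ly <- ny * px; Lz <- nz * dz
  axes <- list(x = (seq_len(nx) - 0.5) * px,
               y = (seq_len(ny) - 0.5) * px,
               z = (seq_len(nz) - 0.5) * dz)

  with_seed(spec$rng_seed, {
    # ---- cluster geometry -------------------------------------------------
    spacing <- 0.8 * spec$nucleus_diameter
    clusters <- list()
    placed_centers <- matrix(numeric(0), 0, 3)
    placed_radius <- numeric(0)
    for (ci in seq_along(spec$cluster_specs)) {
      cs <- spec$cluster_specs[[ci]]
      n_cells <- as.integer(cs$cell_count)
      Rp <- cs$packing_radius %||% auto_packing_radius(n_cells, spacing)
      lo <- Rp + r3
      if (2 * lo > min(Lx, Ly)) {
        stop(sprintf("cluster of %d cells does not fit packing radius %.1f um",
                     n_cells, Rp), call. = FALSE)
      }
      z_lo <- r3; z_hi <- Lz - r3
      if (z_hi <= z_lo) {
        stop("stack too shallow for cluster rendering margin", call. = FALSE)
      }
      center <- cs$center %||% {
        ok <- FALSE; ctr <- NULL
        for (a in seq_len(2000L)) {
          ctr <- c(stats::runif(1, lo, Lx - lo), stats::runif(1, lo, Ly - lo),
                   min(max(Rp + r3, z_lo), (z_lo + z_hi) / 2))
          if (!nrow(placed_centers)) { ok <- TRUE; break }
          dd <- sqrt(rowSums((placed_centers[, 1:2, drop = FALSE] -
                                rep(ctr[1:2], each = nrow(placed_centers)))^2))
          if (all(dd > placed_radius + Rp + 3 * spec$nucleus_diameter)) {
            ok <- TRUE; break
          }
        }
        if (!ok) stop("could not place cluster centers apart", call. = FALSE)
        ctr
      }
      pts <- pack_cluster(n_cells, center, Rp, spacing, z_lo, z_hi)
      clusters[[ci]] <- list(id = ci, center = center, radius = Rp, points = pts)
      placed_centers <- rbind(placed_centers, center)
      placed_radius <- c(placed_radius, Rp)
    }

    # ---- isolated cells ---------------------------------------------------
    singles <- matrix(numeric(0), 0, 3)
    sep_single <- 3 * spec$nucleus_diameter
    if (spec$n_single_cells > 0L) {
      guard <- r3 + spec$nucleus_diameter
      for (k in seq_len(spec$n_single_cells)) {
        ok <- FALSE
        for (a in seq_len(20000L)) {
          p <- c(stats::runif(1, guard, Lx - guard),
                 stats::runif(1, guard, Ly - guard), r3)
          far_clusters <- !nrow(placed_centers) ||
            all(sqrt(rowSums((placed_centers[, 1:2, drop = FALSE] -
                                rep(p[1:2], each = nrow(placed_centers)))^2)) >
                  placed_radius + r3 + sep_single)
          far_singles <- !nrow(singles) ||
            all(sqrt(rowSums((singles[, 1:2, drop = FALSE] -
                                rep(p[1:2], each = nrow(singles)))^2)) > sep_single)
          if (far_clusters && far_singles) { ok <- TRUE; break }
        }
        if (!ok) stop("could not place isolated cells in field", call. = FALSE)
        singles <- rbind(singles, p)
      }
    }

    # ---- render -----------------------------------------------------------
    all_pts <- rbind(
      do.call(rbind, lapply(clusters, function(cl) cl$points)),
      singles)
    cluster_id <- c(unlist(lapply(clusters, function(cl)
      rep(cl$id, nrow(cl$points)))), rep(NA_integer_, nrow(singles)))
    n_nuc <- nrow(all_pts)
    peaks <- spec$nucleus_peak_intensity *
      pmax(0.2, 1 + spec$intensity_cv * stats::rnorm(n_nuc))
    nucl <- array(0, c(nx, ny, nz))
    actin <- array(0, c(nx, ny, nz))
    integrals <- numeric(n_nuc)
    sigma_a <- 1.6 * sigma
    for (i in seq_len(n_nuc)) {
      rb <- render_blob(nucl, axes, all_pts[i, ], sigma, peaks[i], dz)
      nucl <- rb$vol
      integrals[i] <- rb$integral
      actin <- render_blob(actin, axes, all_pts[i, ], sigma_a,
                           0.6 * spec$nucleus_peak_intensity, dz)$vol
    }
    bg <- spec$background_level * spec$nucleus_peak_intensity
    nucl <- nucl + bg
    actin <- actin + 0.5 * bg
    if (spec$shot_noise) {
      nucl[] <- stats::rpois(length(nucl), pmax(nucl, 0))
      actin[] <- stats::rpois(length(actin), pmax(actin, 0))
    }

    truth_nuclei <- data.frame(
      nucleus = seq_len(n_nuc),
      x = all_pts[, 1], y = all_pts[, 2], z = all_pts[, 3],
      cluster_id = cluster_id, peak = peaks, integral = integrals)
    truth_clusters <- if (length(clusters)) data.frame(
      cluster_id = vapply(clusters, `[[`, integer(1), "id"),
      n_cells = vapply(clusters, function(cl) nrow(cl$points), integer(1)),
      packing_radius = vapply(clusters, `[[`, numeric(1), "radius"),
      x = vapply(clusters, function(cl) cl$center[1], numeric(1)),
      y = vapply(clusters, function(cl) cl$center[2], numeric(1)),
      z = vapply(clusters, function(cl) cl$center[3], numeric(1)))
    else data.frame(cluster_id = integer(0), n_cells = integer(0),
                    packing_radius = numeric(0),
                    x = numeric(0), y = numeric(0), z = numeric(0))

    list(stack = image_stack(list(nuclei = nucl, actin = actin),
                             pixel_size = px, slice_thickness = dz),
         truth = list(nuclei = truth_nuclei, clusters = truth_clusters,
                      n_total = n_nuc, background = bg))
  })
}
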