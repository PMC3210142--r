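# Indentation-grid reduction and the cell height / modulus analyses.

#' Fit a set of indentation curves and summarize the moduli
#'
#' Applies [fit_hertz()] to each curve of an indentation map (e.g. a 5x5 grid
#' repeated at several locations, 75 tests per gel formulation) and reports
#' the mean and SD of the recovered moduli. Curves whose fit fails are
#' recorded with the failure reason and excluded from the summary.
#'
#' @param curves List of [force_curve()] objects.
#' @param nu Poisson's ratio passed to [fit_hertz()].
#' @param grid_shape Optional `c(rows, cols)` bookkeeping.
#' @param spacing_um Optional grid spacing bookkeeping, um.
#' @param ... Further arguments to [fit_hertz()].
#' @return Object of class `indentation_grid`: `fits` (list of `hertz_fit` or
#'   `NULL`), `failures` (character reasons), `table` (per-curve data frame),
#'   `summary_mean`, `summary_sd` (Pa; SD is `NA` for a single fit).
#' @export
process_grid <- function(curves, nu = 0.45, grid_shape = NULL,
                         spacing_um = NA_real_, ...) {
  if (!length(curves)) stop("at least one curve required", call. = FALSE)
  fits <- vector("list", length(curves))
  reasons <- rep(NA_character_, length(curves))
  for (i in seq_along(curves)) {
    fits[i] <- list(tryCatch(fit_hertz(curves[[i]], nu = nu, ...),
                             error = function(e) {
                               reasons[i] <<- conditionMessage(e)
                               NULL
                             }))
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all fits failed", call. = FALSE)
  E <- vapply(fits[ok], function(f) f$youngs_modulus, numeric(1))
  tab <- data.frame(
    curve = seq_along(curves),
    label = vapply(curves, function(cu) cu$label %||% "", character(1)),
    youngs_modulus = ifelse(ok,
                            vapply(fits, function(f)
                              if (is.null(f)) NA_real_ else f$youngs_modulus,
                              numeric(1)), NA_real_),
    r_squared = vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$r_squared, numeric(1)),
    contact_z = vapply(fits, function(f)
      if (is.null(f)) NA_real_ else f$contact_z, numeric(1)),
    failed = !ok,
    reason = reasons,
    stringsAsFactors = FALSE)
  structure(
    list(fits = fits, failures = reasons[!ok], table = tab,
         grid_shape = grid_shape, spacing_um = spacing_um,
         n_failed = sum(!ok),
         summary_mean = mean(E),
         summary_sd = if (length(E) > 1L) stats::sd(E) else NA_real_),
    class = "indentation_grid")
}

#' @export
print.indentation_grid <- function(x, ...) {
  n_ok <- sum(!x$table$failed)
  cat(sprintf("Indentation grid: %d curves (%d fitted, %d failed)\n",
              nrow(x$table), n_ok, x$n_failed))
  cat(sprintf("  E = %.4g +/- %s Pa\n", x$summary_mean,
              if (is.na(x$summary_sd)) "NA (single fit)"
              else sprintf("%.3g", x$summary_sd)))
  invisible(x)
}

#' Cell height from paired contact points
#'
#' The height of an attached cell is the difference between the indentation
#' contact point measured on top of the cell and that measured on the
#' adjacent substrate. The probe approaches with increasing piezo position,
#' so the cell-top contact occurs at a smaller tip-sample gap; the absolute
#' difference is returned so either argument order gives the height.
#'
#' @param cell_contact_z Contact point on the cell, um.
#' @param substrate_contact_z Contact point on the adjacent substrate, um.
#' @return Height, um.
#' @export
measure_cell_height <- function(cell_contact_z, substrate_contact_z) {
  abs(substrate_contact_z - cell_contact_z)
}

#' Linear regression of cell modulus on cell height
#'
#' Ordinary least-squares fit of per-cell Young's modulus against cell
#' height, with the two-sided t-test p-value for a nonzero slope. Accepts a
#' data frame with columns `cell_height` and `cell_modulus` (one row per
#' cell) or two numeric vectors.
#'
#' @param records Data frame of `CellHeightRecord`s, or heights vector.
#' @param moduli Moduli vector when `records` is numeric, Pa.
#' @return List: `slope` (Pa/um), `intercept` (Pa), `r_squared`, `p_value`,
#'   `n`, and the underlying `lm` fit.
#' @export
regress_height_modulus <- function(records, moduli = NULL) {
  if (is.data.frame(records)) {
    h <- records$cell_height
    E <- records$cell_modulus
  } else {
    h <- as.numeric(records)
    E <- as.numeric(moduli)
  }
  if (length(h) != length(E) || length(h) < 3L) {
    stop("need >= 3 paired records", call. = FALSE)
  }
  if (stats::var(h) == 0) stop("degenerate regressor: constant heights", call. = FALSE)
  fit <- stats::lm(E ~ h)
  # collinear inputs trigger a harmless precision note from summary.lm
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients[2, 4]),
       n = length(h),
       fit = fit)
}
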