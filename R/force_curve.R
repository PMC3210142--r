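# ForceCurve container and the Hertz forward model.
#
# Internal unit conventions (fixed throughout the package; conversions happen
# only at I/O boundaries):
#   piezo position / indentation  micrometres (um)
#   cantilever deflection         nanometres (nm)
#   force                         nanonewtons (nN)
#   cantilever stiffness          pN/nm (numerically equal to nN/um)
#   Young's modulus               pascals (Pa)

#' Hertz force for a rigid sphere indenting an elastic half-space
#'
#' Evaluates \eqn{F = (4/3) (E / (1 - \nu^2)) \sqrt{R} \, \delta^{3/2}}, the
#' Hertz contact solution for a rigid spherical probe on a flat elastic
#' surface. Negative indentations contribute zero force.
#'
#' @param E Young's modulus in Pa.
#' @param nu Poisson's ratio (0 <= nu < 0.5; 0.45 is conventional for
#'   polyacrylamide and basement-membrane gels, 0.49999 for cells).
#' @param radius_um Probe radius in micrometres.
#' @param delta_um Indentation depth(s) in micrometres.
#' @return Force in nN, same length as `delta_um`.
#' @examples
#' hertz_force(1000, 0.45, 2.5, 1)  # ~2.64 nN
#' @export
hertz_force <- function(E, nu, radius_um, delta_um) {
  check_scalar(E, "E", positive = TRUE)
  if (nu < 0 || nu >= 0.5) stop_invalid("nu", "must satisfy 0 <= nu < 0.5")
  check_scalar(radius_um, "radius_um", positive = TRUE)
  d <- pmax(delta_um, 0)
  # Pa * sqrt(um) * um^1.5 = Pa * um^2 * 1e-12 m^2 = 1e-12 N = 1e-3 nN
  (4 / 3) * (E / (1 - nu^2)) * sqrt(radius_um) * d^1.5 * 1e-3
}

#' Construct an AFM approach curve
#'
#' Bundles one AFM approach trace with its probe metadata. Either the raw
#' cantilever deflection (nm) or a pre-converted force channel (nN) may be
#' supplied; deflection-mode curves require the cantilever stiffness.
#'
#' @param z_piezo Strictly monotone piezo positions, um.
#' @param deflection Cantilever deflection, nm (or `NULL` when `force` given).
#' @param force Force channel, nN (or `NULL` when `deflection` given).
#' @param cantilever_stiffness Cantilever spring constant, pN/nm.
#' @param probe_radius Spherical probe radius, um.
#' @param label Optional identifier carried through fits.
#' @param truth Optional list of generator ground truth (kept for validation).
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(z_piezo, deflection = NULL, force = NULL,
                        cantilever_stiffness = NA_real_, probe_radius = NA_real_,
                        label = "", truth = NULL) {
  z_piezo <- as.numeric(z_piezo)
  n <- length(z_piezo)
  if (n < 20L) stop_invalid("z_piezo", "curve must have at least 20 samples")
  dz <- diff(z_piezo)
  if (!all(dz > 0) && !all(dz < 0)) {
    stop_invalid("z_piezo", "must be strictly monotone")
  }
  if (is.null(deflection) && is.null(force)) {
    stop_invalid("deflection", "one of deflection or force is required")
  }
  if (!is.null(deflection)) {
    deflection <- as.numeric(deflection)
    if (length(deflection) != n) {
      stop_invalid("deflection", "length must match z_piezo")
    }
    check_scalar(cantilever_stiffness, "cantilever_stiffness", positive = TRUE)
  }
  if (!is.null(force)) {
    force <- as.numeric(force)
    if (length(force) != n) stop_invalid("force", "length must match z_piezo")
  }
  structure(
    list(z_piezo = z_piezo, deflection = deflection, force = force,
         cantilever_stiffness = cantilever_stiffness,
         probe_radius = probe_radius, label = label, truth = truth),
    class = "force_curve")
}

# Force channel in nN regardless of acquisition mode.
curve_force <- function(curve) {
  if (!is.null(curve$force)) return(curve$force)
  # pN/nm * nm = pN; 1 nN = 1000 pN
  curve$cantilever_stiffness * curve$deflection / 1000
}

# Deflection expressed in um (zero for force-mode curves, where the piezo
# travel is taken as the tip-sample displacement).
curve_deflection_um <- function(curve) {
  if (is.null(curve$deflection)) return(numeric(length(curve$z_piezo)))
  curve$deflection / 1000
}

#' @export
print.force_curve <- function(x, ...) {
  mode <- if (is.null(x$deflection)) "force" else "deflection"
  cat(sprintf("AFM approach curve%s: %d samples, z %.3f to %.3f um (%s mode)\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$z_piezo), min(x$z_piezo), max(x$z_piezo), mode))
  if (!is.na(x$cantilever_stiffness)) {
    cat(sprintf("  cantilever stiffness %.1f pN/nm, probe radius %.2f um\n",
                x$cantilever_stiffness, x$probe_radius))
  }
  invisible(x)
}
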