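# Hertz spherical-contact analysis of AFM approach curves:
# contact-point extrapolation (CPE), F^(2/3)-vs-delta linearization, and the
# modulus estimate from the linearized slope.

# Robust baseline over the first `frac` of samples: a straight line (so slow
# drift is absorbed) plus the residual SD that sets the contact threshold.
baseline_fit <- function(z, f, frac = 0.25) {
  n <- max(8L, floor(frac * length(z)))
  idx <- seq_len(min(n, length(z)))
  fit <- stats::lm.fit(cbind(1, z[idx]), f[idx])
  list(coef = fit$coefficients, sd = stats::sd(fit$residuals), n = n)
}

baseline_eval <- function(bl, z) bl$coef[1] + bl$coef[2] * z

#' Locate the probe-surface contact point by extrapolation
#'
#' Contact-point extrapolation (CPE): the post-contact portion of a Hertzian
#' approach curve is linear in \eqn{F^{2/3}} versus tip-sample distance, so a
#' line fitted to the strongly indented region extrapolates back to the
#' baseline level exactly at the contact position. Concretely: (1) a robust
#' baseline (line over the first 25% of samples) defines the zero-force level
#' and its SD; (2) samples exceeding baseline + 5 SD are flagged as in
#' contact; (3) a straight line is fitted to \eqn{(F-\mathrm{baseline})^{2/3}}
#' against tip-sample distance over the top half of those samples; (4) the
#' line's zero crossing is the contact point.
#'
#' @param curve A [force_curve()].
#' @param nu Poisson's ratio (unused by the extrapolation itself; accepted so
#'   fitting code can pass one set of options through).
#' @param baseline_frac Fraction of leading samples treated as baseline.
#' @param threshold_sd Contact threshold in baseline SD units.
#' @param window_frac Fraction of in-contact samples (deepest first) used for
#'   the extrapolation line.
#' @param subtract_deflection Correct piezo travel by cantilever deflection
#'   (standard practice; disable for already-corrected distance axes).
#' @return Contact piezo position, um.
#' @export
estimate_contact_point <- function(curve, nu = 0.45,
                                   baseline_frac = 0.25,
                                   threshold_sd = 5,
                                   window_frac = 0.5,
                                   subtract_deflection = TRUE) {
  z <- curve$z_piezo
  f <- curve_force(curve)
  bl <- baseline_fit(z, f, baseline_frac)
  f0 <- f - baseline_eval(bl, z)
  thr <- threshold_sd * bl$sd
  in_contact <- which(f0 > thr)
  # guard: require contact beyond the baseline window itself
  in_contact <- in_contact[in_contact > bl$n]
  if (length(in_contact) < 3L) stop("no contact detected", call. = FALSE)
  # tip-sample distance: F^(2/3) is exactly linear in (z - deflection)
  s <- if (subtract_deflection) z - curve_deflection_um(curve) else z
  ord <- in_contact[order(f0[in_contact], decreasing = TRUE)]
  top <- ord[seq_len(max(3L, ceiling(window_frac * length(ord))))]
  y <- f0[top]^(2 / 3)
  fit <- stats::lm.fit(cbind(1, s[top]), y)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  if (!is.finite(b) || b <= 0) stop("no contact detected", call. = FALSE)
  zc <- -a / b
  rng <- range(z)
  if (zc < rng[1] || zc > rng[2]) {
    stop("no contact detected: extrapolated contact outside curve", call. = FALSE)
  }
  unname(zc)
}

#' Convert an approach curve to force-indentation form
#'
#' Given a contact point, returns post-contact samples as indentation depth
#' \eqn{\delta = (z - z_c) - d} (piezo travel past contact corrected by the
#' cantilever deflection \eqn{d}) and force \eqn{F = k d} (or the curve's
#' force channel unchanged).
#'
#' @param curve A [force_curve()].
#' @param contact_z Contact piezo position, um.
#' @param subtract_deflection Apply the deflection correction to delta.
#' @return List with `delta` (um) and `force` (nN), post-contact samples only.
#' @export
to_force_indentation <- function(curve, contact_z, subtract_deflection = TRUE) {
  z <- curve$z_piezo
  if (contact_z >= max(z)) stop("no post-contact data", call. = FALSE)
  if (contact_z < min(z)) stop("contact_z below curve range", call. = FALSE)
  f <- curve_force(curve)
  d_um <- if (subtract_deflection) curve_deflection_um(curve) else 0
  delta <- (z - contact_z) - d_um
  keep <- z > contact_z & delta >= 0
  list(delta = delta[keep], force = f[keep])
}

#' Fit the Hertz spherical-contact model to an approach curve
#'
#' Locates the contact point by [estimate_contact_point()], linearizes the
#' post-contact data as \eqn{F^{2/3}} versus indentation \eqn{\delta}, and
#' fits the slope \eqn{K} through the origin (the model forces \eqn{F = 0} at
#' \eqn{\delta = 0}). The modulus follows from
#' \eqn{E = K^{3/2} (3/4) (1 - \nu^2) / \sqrt{R}}. By default only
#' indentations up to 10% of the probe diameter enter the fit, respecting the
#' small-strain assumption of the Hertz solution.
#'
#' @param curve A [force_curve()]; `probe_radius` metadata must be set unless
#'   `radius_um` is supplied.
#' @param nu Poisson's ratio: 0.45 for gels, 0.49999 for cells.
#' @param radius_um Probe radius override, um.
#' @param contact_z Optional known contact point (skips CPE).
#' @param max_delta_frac Indentation cap as a fraction of probe diameter
#'   (`Inf` to disable).
#' @param free_intercept Fit the linearized slope with a free intercept
#'   instead of through the origin (sensitivity checks only).
#' @param subtract_deflection Deflection correction flag, passed through.
#' @param ... Further arguments to [estimate_contact_point()].
#' @return Object of class `hertz_fit` with elements `youngs_modulus` (Pa),
#'   `poisson_ratio`, `contact_z` (um), `slope_K` ((nN)^(2/3)/um),
#'   `r_squared`, `n_points_used`, `residual_sd`, and the linearized data.
#' @export
fit_hertz <- function(curve, nu = 0.45, radius_um = NULL, contact_z = NULL,
                      max_delta_frac = 0.1, free_intercept = FALSE,
                      subtract_deflection = TRUE, ...) {
  if (nu < 0 || nu >= 0.5) stop_invalid("nu", "must satisfy 0 <= nu < 0.5")
  R <- radius_um %||% curve$probe_radius
  if (is.null(R) || is.na(R) || R <= 0) {
    stop_invalid("radius_um", "probe radius required (curve metadata or argument)")
  }
  z <- curve$z_piezo
  f <- curve_force(curve)
  bl <- baseline_fit(z, f)
  if (is.null(contact_z)) {
    contact_z <- estimate_contact_point(curve, nu,
                                        subtract_deflection = subtract_deflection,
                                        ...)
  }
  fi <- to_force_indentation(curve, contact_z,
                             subtract_deflection = subtract_deflection)
  fcorr <- fi$force - baseline_eval(bl, contact_z + fi$delta)
  keep <- fi$delta > 0
  if (is.finite(max_delta_frac)) {
    keep <- keep & fi$delta <= max_delta_frac * 2 * R
  }
  delta <- fi$delta[keep]
  y <- pmax(fcorr[keep], 0)^(2 / 3)
  if (length(delta) < 10L) {
    stop("fewer than 10 post-contact samples", call. = FALSE)
  }
  if (free_intercept) {
    ls <- stats::lm.fit(cbind(1, delta), y)
    K <- ls$coefficients[2]
    fitted <- ls$fitted.values
  } else {
    K <- sum(y * delta) / sum(delta^2)
    fitted <- K * delta
  }
  if (!is.finite(K) || K <= 0) stop("non-physical fit: negative slope", call. = FALSE)
  res <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - sum(res^2) / ss_tot)) else NA_real_
  E <- unname(K)^1.5 * (3 / 4) * (1 - nu^2) / (sqrt(R) * 1e-3)
  structure(
    list(youngs_modulus = E, poisson_ratio = nu, contact_z = contact_z,
         r_squared = r2, slope_K = unname(K), n_points_used = length(delta),
         residual_sd = stats::sd(res), probe_radius = R,
         free_intercept = free_intercept, label = curve$label,
         data = list(delta = delta, f23 = y)),
    class = "hertz_fit")
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf("Hertz spherical-contact fit%s\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  cat(sprintf("  E = %.4g Pa  (nu = %g, R = %g um)\n",
              x$youngs_modulus, x$poisson_ratio, x$probe_radius))
  cat(sprintf("  contact at z = %.4f um; %d points; R^2 = %.4f\n",
              x$contact_z, x$n_points_used, x$r_squared))
  invisible(x)
}

#' @export
coef.hertz_fit <- function(object, ...) {
  c(youngs_modulus = object$youngs_modulus,
    contact_z = object$contact_z,
    slope_K = object$slope_K)
}

#' @export
summary.hertz_fit <- function(object, ...) {
  out <- unclass(object)
  out$data <- NULL
  structure(out, class = "summary.hertz_fit")
}

#' @export
print.summary.hertz_fit <- function(x, ...) {
  print(structure(c(x, list(data = NULL)), class = "hertz_fit"))
  cat(sprintf("  linearized slope K = %.4g (nN)^(2/3)/um, residual SD %.3g\n",
              x$slope_K, x$residual_sd))
  invisible(x)
}

#' Predicted Hertz force at given indentations
#'
#' @param object A `hertz_fit`.
#' @param delta_um Indentation depths, um (default: the fitted depths).
#' @param ... Ignored.
#' @return Predicted force, nN.
#' @export
predict.hertz_fit <- function(object, delta_um = NULL, ...) {
  d <- delta_um %||% object$data$delta
  hertz_force(object$youngs_modulus, object$poisson_ratio,
              object$probe_radius, d)
}

#' @export
residuals.hertz_fit <- function(object, ...) {
  object$data$f23 - object$slope_K * object$data$delta
}

#' Diagnostic plot of a Hertz fit
#'
#' Plots the linearized data \eqn{F^{2/3}} versus indentation with the fitted
#' through-origin line.
#'
#' @param x A `hertz_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hertz_fit <- function(x, ...) {
  graphics::plot(x$data$delta, x$data$f23,
                 xlab = expression(delta ~ "(um)"),
                 ylab = expression(F^{2/3} ~ "(nN)"^{2/3}),
                 main = sprintf("Hertz linearization: E = %.3g Pa", x$youngs_modulus),
                 ...)
  graphics::abline(0, x$slope_K, col = "red")
  invisible(x)
}
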