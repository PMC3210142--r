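# Seeded forward simulation of AFM approach curves.

#' Specification for a simulated force curve
#'
#' Parameters of the Hertzian forward model used by [simulate_force_curve()].
#' Defaults mirror the experimental setup the analysis assumes: a 5 um
#' diameter spherical probe on a nominally 60 pN/nm cantilever, gel
#' Poisson's ratio 0.45, and additive force noise of 1% of the maximum force.
#' The default maximum indentation (0.5 um, 10% of the probe diameter)
#' matches the small-strain regime the Hertz fit itself uses, so simulated
#' curves are informative over their whole sampled depth.
#'
#' @param true_modulus Ground-truth Young's modulus, Pa.
#' @param poisson_ratio Poisson's ratio, in [0, 0.5).
#' @param probe_radius Probe radius, um.
#' @param contact_position Piezo coordinate of probe-surface contact, um.
#' @param cantilever_stiffness Spring constant, pN/nm.
#' @param max_indentation Maximum simulated indentation depth, um.
#' @param sample_spacing Piezo sampling interval, um.
#' @param noise_sd_fraction Gaussian force-noise SD as a fraction of the
#'   maximum (noiseless) force.
#' @param baseline_slope Linear baseline drift, nN per um of piezo travel.
#' @param rng_seed Integer seed, or `NULL` to draw from the current stream.
#' @return An object of class `curve_sim_spec`.
#' @export
curve_sim_spec <- function(true_modulus,
                           poisson_ratio = 0.45,
                           probe_radius = 2.5,
                           contact_position = 1.0,
                           cantilever_stiffness = 60,
                           max_indentation = 0.5,
                           sample_spacing = 0.01,
                           noise_sd_fraction = 0.01,
                           baseline_slope = 0,
                           rng_seed = NULL) {
  check_scalar(true_modulus, "true_modulus", positive = TRUE)
  check_scalar(poisson_ratio, "poisson_ratio")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5) {
    stop_invalid("poisson_ratio", "must satisfy 0 <= nu < 0.5")
  }
  check_scalar(probe_radius, "probe_radius", positive = TRUE)
  check_scalar(contact_position, "contact_position", positive = TRUE)
  check_scalar(cantilever_stiffness, "cantilever_stiffness", positive = TRUE)
  check_scalar(max_indentation, "max_indentation", positive = TRUE)
  check_scalar(sample_spacing, "sample_spacing", positive = TRUE)
  check_scalar(noise_sd_fraction, "noise_sd_fraction", nonnegative = TRUE)
  check_scalar(baseline_slope, "baseline_slope")
  structure(
    list(true_modulus = true_modulus, poisson_ratio = poisson_ratio,
         probe_radius = probe_radius, contact_position = contact_position,
         cantilever_stiffness = cantilever_stiffness,
         max_indentation = max_indentation, sample_spacing = sample_spacing,
         noise_sd_fraction = noise_sd_fraction,
         baseline_slope = baseline_slope, rng_seed = rng_seed),
    class = "curve_sim_spec")
}

# Solve k*d = A*((z - zc) - d)^{3/2} for the deflection d at each piezo
# position past contact. Vectorized damped Newton; the residual is monotone
# in d on [0, z - zc], so convergence is unconditional.
solve_deflection_um <- function(u, k_nN_um, A) {
  d <- numeric(length(u))
  if (!length(u)) return(d)
  for (i in seq_len(60L)) {
    delta <- pmax(u - d, 0)
    f <- k_nN_um * d - A * delta^1.5
    fp <- k_nN_um + 1.5 * A * sqrt(delta)
    step <- f / fp
    d <- pmin(pmax(d - step, 0), u)
    if (max(abs(step)) < 1e-12) break
  }
  d
}

#' Simulate one AFM approach curve
#'
#' Generates a deflection-mode approach trace: zero force (plus optional
#' linear drift) before the contact position, and a Hertzian response after
#' contact in which the cantilever deflection is solved self-consistently
#' (the indentation is the piezo travel past contact minus the deflection).
#' Gaussian noise with SD `noise_sd_fraction` times the maximum noiseless
#' force is added to the force signal. The generating spec is retained in
#' `$truth` so round-trip accuracy can be scored.
#'
#' @param spec A [curve_sim_spec()].
#' @return A [force_curve()] with ground truth attached.
#' @export
simulate_force_curve <- function(spec) {
  if (!inherits(spec, "curve_sim_spec")) {
    spec <- do.call(curve_sim_spec, as.list(spec))
  }
  k <- spec$cantilever_stiffness  # pN/nm == nN/um
  A <- (4 / 3) * (spec$true_modulus / (1 - spec$poisson_ratio^2)) *
    sqrt(spec$probe_radius) * 1e-3  # nN per um^1.5
  f_max <- A * spec$max_indentation^1.5
  z_end <- spec$contact_position + spec$max_indentation + f_max / k
  z <- seq(0, z_end, by = spec$sample_spacing)
  post <- z > spec$contact_position
  d_um <- numeric(length(z))
  d_um[post] <- solve_deflection_um(z[post] - spec$contact_position, k, A)
  force <- k * d_um
  with_seed(spec$rng_seed, {
    if (spec$noise_sd_fraction > 0) {
      force <- force + stats::rnorm(length(z), 0, spec$noise_sd_fraction * f_max)
    }
    if (spec$baseline_slope != 0) {
      force <- force + spec$baseline_slope * (z - z[1])
    }
    force_curve(
      z_piezo = z,
      deflection = force / k * 1000,  # um -> nm equivalent deflection
      cantilever_stiffness = k,
      probe_radius = spec$probe_radius,
      label = sprintf("sim_E%.0fPa", spec$true_modulus),
      truth = spec)
  })
}
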