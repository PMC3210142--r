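# Self-validation harnesses: ground-truthed simulations scored end-to-end
# through the package's own pipeline. These back the method-performance
# figures the analyses rely on (cluster-count accuracy, Hertz fit quality
# and repeatability).

#' Score integrated-signal cluster counting against ground truth
#'
#' Simulates `n_phantoms` seeded confocal fields, each containing one
#' cluster (size drawn uniformly from `size_range`) plus isolated reference
#' nuclei, runs the full segmentation / calibration / counting pipeline, and
#' reports the relative error of every cluster-count estimate. The phantom
#' noise model follows the generator defaults (per-nucleus intensity CV,
#' uniform background as a fraction of peak).
#'
#' @param n_phantoms Number of independent fields.
#' @param size_range Inclusive range of true cluster sizes, cells.
#' @param n_singles Isolated reference nuclei per field.
#' @param intensity_cv Per-nucleus peak-intensity CV.
#' @param background_level Background as a fraction of mean peak intensity.
#' @param shot_noise Add Poisson noise.
#' @param seed Integer seed for the whole benchmark.
#' @return List: `results` (data frame with `true_cells`,
#'   `estimated_cells`, `rel_error_pct` per phantom) and
#'   `max_rel_error_pct`.
#' @export
benchmark_cluster_counting <- function(n_phantoms = 20, size_range = c(5, 150),
                                       n_singles = 10, intensity_cv = 0.1,
                                       background_level = 0.05,
                                       shot_noise = FALSE, seed = 1) {
  res <- with_seed(seed, {
    sizes <- sample(seq(size_range[1], size_range[2]), n_phantoms,
                    replace = TRUE)
    out <- vector("list", n_phantoms)
    for (i in seq_len(n_phantoms)) {
      sim <- simulate_stack(stack_sim_spec(
        cluster_specs = list(list(cell_count = sizes[i])),
        n_single_cells = n_singles,
        intensity_cv = intensity_cv,
        background_level = background_level,
        shot_noise = shot_noise,
        rng_seed = NULL))
      seg <- segment_objects(sim$stack)
      cal <- calibrate_single_cell(sim$stack, seg)
      est <- count_cluster_cells(which.max(seg$sizes), sim$stack, cal, seg = seg)
      out[[i]] <- data.frame(phantom = i, true_cells = sizes[i],
                             estimated_cells = est,
                             rel_error_pct = 100 * abs(est - sizes[i]) / sizes[i])
    }
    do.call(rbind, out)
  })
  list(results = res, max_rel_error_pct = max(res$rel_error_pct))
}

#' Score Hertz modulus recovery over simulated indentation grids
#'
#' Simulates `n_per` noisy approach curves for each true modulus (defaults:
#' the gel formulations spanning 100 Pa to 15.2 kPa, 75 tests per
#' formulation, 1% force noise), fits every curve, and summarizes recovery:
#' per-modulus mean, SD, relative SD, and the minimum linearized-fit R^2.
#'
#' @param moduli True Young's moduli, Pa.
#' @param n_per Curves per modulus.
#' @param nu Poisson's ratio for simulation and fitting.
#' @param noise_sd_fraction Force-noise SD as a fraction of maximum force.
#' @param seed Integer seed.
#' @param ... Further arguments to [curve_sim_spec()].
#' @return List: `fits` (per-curve data frame), `summary` (per-modulus data
#'   frame with `mean_E`, `sd_E`, `rsd_pct`, `min_r_squared`),
#'   `min_r_squared`, `max_rsd_pct`.
#' @export
benchmark_hertz_recovery <- function(moduli = c(100, 235, 720, 2100, 15200),
                                     n_per = 75, nu = 0.45,
                                     noise_sd_fraction = 0.01, seed = 1, ...) {
  fits <- with_seed(seed, {
    out <- vector("list", length(moduli) * n_per)
    k <- 0L
    for (E in moduli) {
      spec <- curve_sim_spec(E, poisson_ratio = nu,
                             noise_sd_fraction = noise_sd_fraction,
                             rng_seed = NULL, ...)
      for (i in seq_len(n_per)) {
        cv <- simulate_force_curve(spec)
        ft <- fit_hertz(cv, nu = nu)
        k <- k + 1L
        out[[k]] <- data.frame(true_modulus = E, replicate = i,
                               youngs_modulus = ft$youngs_modulus,
                               r_squared = ft$r_squared,
                               contact_z = ft$contact_z)
      }
    }
    do.call(rbind, out)
  })
  sm <- do.call(rbind, lapply(split(fits, fits$true_modulus), function(d) {
    data.frame(true_modulus = d$true_modulus[1],
               mean_E = mean(d$youngs_modulus),
               sd_E = stats::sd(d$youngs_modulus),
               rsd_pct = 100 * stats::sd(d$youngs_modulus) / mean(d$youngs_modulus),
               min_r_squared = min(d$r_squared))
  }))
  rownames(sm) <- NULL
  list(fits = fits, summary = sm,
       min_r_squared = min(fits$r_squared),
       max_rsd_pct = max(sm$rsd_pct))
}
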