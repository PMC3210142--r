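# Seeded simulation of plate-reader absorbance data for the DMMB (sGAG)
# and DNA assays: a linear standard curve plus Gaussian absorbance noise.

#' Specification for a simulated assay plate
#'
#' Emulates a DMMB plate read at 535 nm: standards spanning the linear range
#' of a chondroitin-4-sulfate calibration, plus samples and no-analyte
#' blanks. Absorbance is `intercept + slope * concentration + noise`.
#'
#' @param standard_concentrations Standard concentrations, ug/mL (>= 2
#'   distinct values).
#' @param curve_slope Absorbance per (ug/mL).
#' @param curve_intercept Blank absorbance.
#' @param sample_true_concentrations True sample concentrations, ug/mL.
#' @param sample_volumes Sample volumes, mL (scalar or per sample).
#' @param dna_per_sample DNA content per sample, ng (scalar or per sample).
#' @param absorbance_noise_sd Gaussian noise SD, absorbance units.
#' @param rng_seed Integer seed, or `NULL`.
#' @return Object of class `plate_sim_spec`.
#' @export
plate_sim_spec <- function(standard_concentrations = c(0, 5, 10, 20, 30, 40),
                           curve_slope = 0.02,
                           curve_intercept = 0.05,
                           sample_true_concentrations = numeric(0),
                           sample_volumes = 1,
                           dna_per_sample = 100,
                           absorbance_noise_sd = 0.005,
                           rng_seed = NULL) {
  sc <- as.numeric(standard_concentrations)
  if (length(unique(sc)) < 2L) {
    stop_invalid("standard_concentrations", "need >= 2 distinct concentrations")
  }
  if (any(sc < 0)) stop_invalid("standard_concentrations", "must be >= 0")
  check_scalar(curve_slope, "curve_slope")
  if (curve_slope == 0) stop_invalid("curve_slope", "must be nonzero")
  check_scalar(curve_intercept, "curve_intercept")
  if (any(sample_true_concentrations < 0)) {
    stop_invalid("sample_true_concentrations", "must be >= 0")
  }
  if (any(sample_volumes <= 0)) stop_invalid("sample_volumes", "must be > 0")
  check_scalar(absorbance_noise_sd, "absorbance_noise_sd", nonnegative = TRUE)
  structure(
    list(standard_concentrations = sc, curve_slope = curve_slope,
         curve_intercept = curve_intercept,
         sample_true_concentrations = as.numeric(sample_true_concentrations),
         sample_volumes = sample_volumes, dna_per_sample = dna_per_sample,
         absorbance_noise_sd = absorbance_noise_sd, rng_seed = rng_seed),
    class = "plate_sim_spec")
}

#' Simulate an assay plate read
#'
#' Produces a long-format plate table (`well`, `role`, `analyte`,
#' `concentration_true`, `absorbance`, `volume_ml`, `dna_ng`) with standard,
#' sample, and blank wells. Blank wells read the curve intercept (plus
#' noise) and double as the no-cell control readings for sample correction.
#'
#' @param spec A [plate_sim_spec()].
#' @param analyte Analyte label for the plate (default `"sGAG"`).
#' @return Data frame of class `assay_plate`.
#' @export
simulate_plate <- function(spec, analyte = "sGAG") {
  if (!inherits(spec, "plate_sim_spec")) {
    spec <- do.call(plate_sim_spec, as.list(spec))
  }
  n_std <- length(spec$standard_concentrations)
  n_smp <- length(spec$sample_true_concentrations)
  n_blk <- 3L
  conc <- c(spec$standard_concentrations, spec$sample_true_concentrations,
            rep(0, n_blk))
  role <- c(rep("standard", n_std), rep("sample", n_smp), rep("blank", n_blk))
  vol <- c(rep(NA_real_, n_std),
           rep(spec$sample_volumes, length.out = max(n_smp, 1L))[seq_len(n_smp)],
           rep(NA_real_, n_blk))
  dna <- c(rep(NA_real_, n_std),
           rep(spec$dna_per_sample, length.out = max(n_smp, 1L))[seq_len(n_smp)],
           rep(NA_real_, n_blk))
  with_seed(spec$rng_seed, {
    absorb <- spec$curve_intercept + spec$curve_slope * conc
    if (spec$absorbance_noise_sd > 0) {
      absorb <- absorb + stats::rnorm(length(absorb), 0, spec$absorbance_noise_sd)
    }
    out <- data.frame(
      well = sprintf("W%02d", seq_along(conc)),
      role = role, analyte = analyte,
      concentration_true = conc, absorbance = absorb,
      volume_ml = vol, dna_ng = dna,
      stringsAsFactors = FALSE)
    class(out) <- c("assay_plate", "data.frame")
    out
  })
}
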