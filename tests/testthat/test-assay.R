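# DMMB / DNA assay reduction: calibration, control-corrected quantification,
# and cumulative accumulation.

test_that("standard-curve fit reproduces an exact line and is order-invariant", {
  conc <- c(0, 20, 40)
  ab <- c(0.05, 0.45, 0.85)
  cv <- fit_standard_curve(conc, ab)
  expect_equal(cv$slope, 0.02, tolerance = 1e-12)
  expect_equal(cv$intercept, 0.05, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  shuf <- c(3, 1, 2)
  cv2 <- fit_standard_curve(conc[shuf], ab[shuf])
  expect_equal(cv2$slope, cv$slope)
  expect_equal(cv2$intercept, cv$intercept)
  expect_error(fit_standard_curve(rep(10, 4), rnorm(4)), "degenerate")
  expect_error(fit_standard_curve(c(0, 10), c(0.1, 0.3)), ">= 3 standards")
  expect_warning(fit_standard_curve(c(0, 10, 20, 30), c(0.1, 0.5, 0.3, 0.9)),
                 "R\\^2")
})

test_that("curve inversion recovers concentrations", {
  cv <- fit_standard_curve(c(0, 20, 40), c(0.05, 0.45, 0.85))
  expect_equal(predict(cv, 0.45), 20)
})

test_that("sample quantification satisfies blank identity and proportionality", {
  cv <- fit_standard_curve(c(0, 20, 40), c(0.05, 0.45, 0.85))
  # sample reading equal to its control: zero sGAG
  s0 <- assay_sample("BME", "0-3", media_absorbance = c(0.2, 0.2),
                     control_absorbance = 0.2, sample_volume = 1, dna_ng = 50)
  expect_equal(quantify_sample(s0, cv)$total_sgag_ug, 0)
  # doubling the volume doubles the total
  s1 <- assay_sample("BME", "0-3", media_absorbance = 0.45,
                     control_absorbance = 0.05, sample_volume = 1, dna_ng = 100)
  s2 <- assay_sample("BME", "0-3", media_absorbance = 0.45,
                     control_absorbance = 0.05, sample_volume = 2, dna_ng = 100)
  q1 <- quantify_sample(s1, cv); q2 <- quantify_sample(s2, cv)
  expect_equal(q2$total_sgag_ug, 2 * q1$total_sgag_ug)
  # and the DNA normalization divides through
  expect_equal(q1$sgag_per_dna, q1$total_sgag_ug / 100)
  # negative net concentrations clamp at zero with a warning
  sneg <- assay_sample("BME", "0-3", media_absorbance = 0.02,
                       control_absorbance = 0.10, sample_volume = 1, dna_ng = 10)
  expect_warning(qn <- quantify_sample(sneg, cv), "clamped")
  expect_equal(qn$total_sgag_ug, 0)
  expect_error(quantify_sample(
    assay_sample("BME", "0-3", 0.4, control_absorbance = 0.05,
                 sample_volume = 1, dna_ng = 0), cv), "dna_ng")
})

test_that("simulated plates round-trip through the full assay reduction", {
  spec <- plate_sim_spec(sample_true_concentrations = 30,
                         absorbance_noise_sd = 0, rng_seed = 7)
  plate <- simulate_plate(spec)
  std <- plate[plate$role == "standard", ]
  cv <- fit_standard_curve(std$concentration_true, std$absorbance)
  smp <- plate[plate$role == "sample", ]
  blank <- plate[plate$role == "blank", ]
  q <- quantify_sample(
    assay_sample("BME", "0-3", media_absorbance = smp$absorbance,
                 control_absorbance = blank$absorbance,
                 sample_volume = 1, dna_ng = 100), cv)
  expect_equal(q$total_sgag_ug, 30, tolerance = 1e-9)
  expect_equal(q$sgag_per_dna, 0.3, tolerance = 1e-9)
})

test_that("noisy plate reduction recovers truth within propagated error", {
  spec <- plate_sim_spec(sample_true_concentrations = rep(25, 6),
                         absorbance_noise_sd = 0.005, rng_seed = 8)
  plate <- simulate_plate(spec)
  std <- plate[plate$role == "standard", ]
  cv <- fit_standard_curve(std$concentration_true, std$absorbance)
  smp <- plate[plate$role == "sample", ]
  blank <- plate[plate$role == "blank", ]
  q <- quantify_sample(
    assay_sample("BME", "0-3", media_absorbance = smp$absorbance,
                 control_absorbance = blank$absorbance,
                 sample_volume = 1, dna_ng = 100), cv)
  # SE of the mean net absorbance difference, propagated through the slope
  se_conc <- spec$absorbance_noise_sd * sqrt(1 / 6 + 1 / 3) / spec$curve_slope
  expect_lt(abs(q$total_sgag_ug - 25), 3 * se_conc)
})

test_that("cumulative production is a running sum preserving fold ratios", {
  recs <- data.frame(
    condition = rep(c("gel", "rigid"), each = 4),
    interval = rep(c("0-3", "3-6", "6-9", "9-12"), 2),
    sgag_per_dna = c(1.7, 1.7, 1.7, 1.7, 1, 1, 1, 1))
  acc <- accumulate_production(recs)
  gel <- acc[acc$condition == "gel", ]
  expect_equal(gel$cumulative_sgag_per_dna, cumsum(gel$sgag_per_dna))
  # last cumulative value equals the sum of intervals exactly
  expect_equal(gel$cumulative_sgag_per_dna[4], sum(gel$sgag_per_dna))
  # a constant per-interval ratio is preserved at day 12
  rigid <- acc[acc$condition == "rigid", ]
  expect_equal(gel$cumulative_sgag_per_dna[4] / rigid$cumulative_sgag_per_dna[4],
               1.7, tolerance = 1e-12)
  # a single interval is its own cumulative series
  one <- accumulate_production(recs[recs$interval == "0-3" &
                                      recs$condition == "gel", ])
  expect_equal(one$cumulative_sgag_per_dna, one$sgag_per_dna)
  # duplicate intervals and gap sequences are rejected
  dup <- recs[c(1, 1), ]
  expect_error(accumulate_production(dup), "duplicate interval")
  gap <- recs[c(1, 3), ]
  expect_error(accumulate_production(gap), "prefix")
})
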