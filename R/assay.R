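# Reduction of DMMB (sGAG) and DNA plate data: standard-curve calibration,
# control-corrected quantification, volume scaling, DNA normalization, and
# cumulative production over 3-day culture intervals.

assay_intervals <- c("0-3", "3-6", "6-9", "9-12")

#' Fit a linear assay standard curve
#'
#' Ordinary least-squares line through standard absorbances (e.g. a DMMB
#' calibration against chondroitin-4-sulfate). Warns when the calibration
#' R^2 falls below `warn_r2`.
#'
#' @param concentrations Standard concentrations, ug/mL.
#' @param absorbances Measured absorbances.
#' @param analyte `"sGAG"` or `"DNA"` (label only).
#' @param warn_r2 R^2 below which a warning is issued.
#' @return Object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `analyte`, `concentration_range`, `n`.
#' @export
fit_standard_curve <- function(concentrations, absorbances, analyte = "sGAG",
                               warn_r2 = 0.98) {
  conc <- as.numeric(concentrations)
  ab <- as.numeric(absorbances)
  if (length(conc) != length(ab)) stop("lengths differ", call. = FALSE)
  if (length(conc) < 3L) stop("need >= 3 standards", call. = FALSE)
  if (length(unique(conc)) < 2L) {
    stop("degenerate standards: need >= 2 distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(ab ~ conc)
  r2 <- suppressWarnings(summary(fit))$r.squared
  if (is.finite(r2) && r2 < warn_r2) {
    warning(sprintf("standard curve R^2 = %.3f below %.2f", r2, warn_r2))
  }
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = r2, analyte = analyte,
         concentration_range = range(conc), n = length(conc), fit = fit),
    class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("%s standard curve: A = %.4g + %.4g x conc (R^2 = %.4f, n = %d)\n",
              x$analyte, x$intercept, x$slope, x$r_squared, x$n))
  cat(sprintf("  calibrated over %.3g-%.3g ug/mL\n",
              x$concentration_range[1], x$concentration_range[2]))
  invisible(x)
}

#' Invert a standard curve
#'
#' @param object A `standard_curve`.
#' @param absorbance Absorbance value(s).
#' @param ... Ignored.
#' @return Concentration(s), ug/mL.
#' @export
predict.standard_curve <- function(object, absorbance, ...) {
  (absorbance - object$intercept) / object$slope
}

#' Construct one assay sample
#'
#' One culture sample over one 3-day interval: replicate absorbances for the
#' media fraction, the substrate digest fraction, and the matched no-cell
#' control wells (same substrate, no cells), plus the sample volume and DNA
#' content for normalization. `control_absorbance` may be a single vector
#' applied to both fractions or a list with elements `media` and `digest`.
#'
#' @param condition Substrate condition label.
#' @param interval One of `"0-3"`, `"3-6"`, `"6-9"`, `"9-12"` (days).
#' @param media_absorbance Media-fraction absorbances.
#' @param digest_absorbance Digest-fraction absorbances.
#' @param control_absorbance Control absorbances (vector or list).
#' @param sample_volume Volume per fraction, mL.
#' @param dna_ng DNA content, ng.
#' @return Object of class `assay_sample`.
#' @export
assay_sample <- function(condition, interval, media_absorbance,
                         digest_absorbance = numeric(0),
                         control_absorbance = 0,
                         sample_volume = 1, dna_ng = NA_real_) {
  interval <- as.character(interval)
  if (!interval %in% assay_intervals) {
    stop_invalid("interval", sprintf("must be one of %s",
                                     paste(assay_intervals, collapse = ", ")))
  }
  check_scalar(sample_volume, "sample_volume", positive = TRUE)
  structure(
    list(condition = condition, interval = interval,
         media_absorbance = as.numeric(media_absorbance),
         digest_absorbance = as.numeric(digest_absorbance),
         control_absorbance = control_absorbance,
         sample_volume = sample_volume, dna_ng = dna_ng),
    class = "assay_sample")
}

control_mean <- function(ctrl, fraction) {
  if (is.list(ctrl) && !is.null(ctrl[[fraction]])) {
    return(mean(as.numeric(ctrl[[fraction]])))
  }
  mean(as.numeric(unlist(ctrl)))
}

#' Quantify total analyte in one sample
#'
#' For each fraction (media, digest) the mean absorbance is corrected by the
#' mean of the matched control wells and converted to a net concentration by
#' dividing the corrected absorbance by the standard-curve slope (control
#' wells share the curve's blank response, so the intercept cancels in the
#' subtraction). Net concentrations are multiplied by the sample volume,
#' summed across fractions to give total sGAG, and normalized to DNA.
#' Negative net concentrations are clamped to zero with a warning.
#'
#' @param sample An [assay_sample()].
#' @param curve A [fit_standard_curve()] result.
#' @param clamp_negative Clamp negative net concentrations at 0.
#' @return One-row data frame (a `ProductionRecord` without the cumulative
#'   column): `condition`, `interval`, `total_sgag_ug`, `sgag_per_dna`.
#' @export
quantify_sample <- function(sample, curve, clamp_negative = TRUE) {
  if (!inherits(curve, "standard_curve") || curve$slope == 0) {
    stop("invalid standard curve", call. = FALSE)
  }
  if (is.na(sample$dna_ng) || sample$dna_ng <= 0) {
    stop("dna_ng must be > 0 for normalization", call. = FALSE)
  }
  fracs <- list(media = sample$media_absorbance, digest = sample$digest_absorbance)
  total <- 0
  for (nm in names(fracs)) {
    ab <- fracs[[nm]]
    if (!length(ab)) next
    conc <- (mean(ab) - control_mean(sample$control_absorbance, nm)) / curve$slope
    if (conc < 0) {
      if (clamp_negative) {
        warning(sprintf("negative net concentration in %s fraction; clamped to 0", nm))
        conc <- 0
      }
    }
    total <- total + conc * sample$sample_volume
  }
  data.frame(condition = sample$condition, interval = sample$interval,
             total_sgag_ug = total, sgag_per_dna = total / sample$dna_ng,
             stringsAsFactors = FALSE)
}

#' Accumulate per-interval production into cumulative series
#'
#' Orders each condition's interval records along the culture timeline
#' (days 0-3, 3-6, 6-9, 9-12; the recorded intervals must form a prefix of
#' that sequence) and appends the running cumulative sGAG/DNA. The final
#' cumulative value equals the sum of the interval values exactly, and
#' day-12 fold differences between conditions can be read off the last row.
#'
#' @param records Data frame with columns `condition`, `interval`,
#'   `sgag_per_dna` (and optionally `total_sgag_ug`).
#' @return Data frame with an added `cumulative_sgag_per_dna` column,
#'   ordered by condition and interval.
#' @export
accumulate_production <- function(records) {
  if (!all(c("condition", "interval", "sgag_per_dna") %in% names(records))) {
    stop("records need condition, interval, sgag_per_dna", call. = FALSE)
  }
  out <- lapply(split(records, records$condition), function(d) {
    pos <- match(d$interval, assay_intervals)
    if (anyNA(pos)) stop("unknown interval label", call. = FALSE)
    if (anyDuplicated(pos)) {
      stop(sprintf("duplicate interval for condition '%s'", d$condition[1]),
           call. = FALSE)
    }
    d <- d[order(pos), , drop = FALSE]
    if (!identical(match(d$interval, assay_intervals), seq_len(nrow(d)))) {
      stop(sprintf("intervals for condition '%s' must form a prefix of %s",
                   d$condition[1], paste(assay_intervals, collapse = ", ")),
           call. = FALSE)
    }
    d$cumulative_sgag_per_dna <- cumsum(d$sgag_per_dna)
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
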