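# Conversion of raw 24-hour urine collections and energy-expenditure records
# into biomarker intake estimates, plus the agreement summaries used in the
# validation tables.

#' Protein intake from 24-hour urinary nitrogen
#'
#' Assumes a fixed fraction of ingested nitrogen (81% by default) is
#' excreted in a complete 24-hour collection, and converts nitrogen to
#' protein with the standard Kjeldahl factor 6.25 g protein / g nitrogen.
#'
#' @param nitrogen Urinary nitrogen, g/24 h (vectorized, `NA` passed
#'   through).
#' @param excreted_fraction Fraction of intake excreted within 24 h.
#' @param nitrogen_to_protein Protein mass per unit nitrogen.
#' @return Estimated protein intake, g/day.
#' @export
#' @examples
#' protein_from_nitrogen(11.34)  # 87.5 g/day
protein_from_nitrogen <- function(nitrogen, excreted_fraction = 0.81,
                                  nitrogen_to_protein = 6.25) {
  if (any(nitrogen < 0, na.rm = TRUE))
    stop("nitrogen must be >= 0", call. = FALSE)
  nitrogen / excreted_fraction * nitrogen_to_protein
}

#' Potassium intake from 24-hour urinary excretion
#'
#' @param potassium Urinary potassium, g/24 h (vectorized).
#' @param excreted_fraction Fraction of intake excreted in urine (80%).
#' @return Estimated potassium intake, g/day.
#' @export
#' @examples
#' potassium_from_excretion(1.68)  # 2.1 g/day
potassium_from_excretion <- function(potassium, excreted_fraction = 0.80) {
  if (any(potassium < 0, na.rm = TRUE))
    stop("potassium must be >= 0", call. = FALSE)
  potassium / excreted_fraction
}

#' Calibration coefficients for the sucrose + fructose sugar biomarker
#'
#' Urinary sucrose plus fructose is a *predictive* biomarker of total sugar
#' intake: it correlates with intake but needs a feeding-study calibration.
#' The published equation, applied on the natural-log excretion scale, is
#' `M* = M - 1.67 - 0.02 * S + 0.71 * A` with `S` an indicator for women
#' and `A` log-transformed age.
#'
#' @param intercept,sex,log_age Coefficients; defaults are the published
#'   values.
#' @return An object of class `calibration_coefficients`.
#' @export
calibration_coefficients <- function(intercept = -1.67, sex = -0.02,
                                     log_age = 0.71) {
  stopifnot(is.finite(intercept), is.finite(sex), is.finite(log_age))
  structure(list(intercept = intercept, sex = sex, log_age = log_age),
            class = "calibration_coefficients")
}

#' Calibrate the urinary sugars biomarker for age and sex
#'
#' @param log_excretion Log of 24-hour urinary sucrose + fructose excretion
#'   (log mg/24 h; vectorized).
#' @param sex 0 for men, 1 for women.
#' @param log_age Natural log of age in years.
#' @param coeffs A [calibration_coefficients()] object.
#' @return Calibrated log biomarker `M*`, used in place of the raw
#'   biomarker in the measurement model.
#' @export
#' @examples
#' calibrate_sugar_biomarker(5, sex = 1, log_age = log(50))  # 6.088
calibrate_sugar_biomarker <- function(log_excretion, sex, log_age,
                                      coeffs = calibration_coefficients()) {
  stopifnot(inherits(coeffs, "calibration_coefficients"))
  if (!all(sex %in% c(0, 1, NA)))
    stop("sex must be coded 0 (man) / 1 (woman)", call. = FALSE)
  log_excretion + coeffs$intercept + coeffs$sex * sex +
    coeffs$log_age * log_age
}

#' Classify a 24-hour urine collection by PABA recovery and missed voids
#'
#' Para-aminobenzoic acid (PABA) tablets taken with meals act as a
#' completeness check: recovery near 93% of the 240 mg dose indicates a
#' complete collection.  In the `main` analysis every collection is
#' retained unless 2 or more voids were missed.  In the `sensitivity`
#' analysis, recovery in \[85, 110\]% counts as `complete`, recovery in
#' \[50, 85)% is `rescalable` (analytes can be rescaled to the expected 93%
#' recovery), and anything below 50% or above 110% is `excluded`.
#' Boundaries are closed at 50, 85 and 110, with 85 belonging to
#' `complete`.
#'
#' @param recovery PABA recovery, percent of dose (vectorized).
#' @param missed_voids Number of voids missed during the collection.
#' @param mode `"main"` or `"sensitivity"`.
#' @return Character vector: `"complete"`, `"rescalable"` or `"excluded"`.
#' @export
classify_paba <- function(recovery, missed_voids,
                          mode = c("main", "sensitivity")) {
  mode <- match.arg(mode)
  if (any(recovery < 0, na.rm = TRUE))
    stop("recovery must be >= 0", call. = FALSE)
  if (any(missed_voids < 0 | missed_voids != round(missed_voids),
          na.rm = TRUE))
    stop("missed_voids must be a nonnegative integer count", call. = FALSE)
  n <- max(length(recovery), length(missed_voids))
  recovery <- rep_len(recovery, n)
  missed_voids <- rep_len(missed_voids, n)
  out <- rep("complete", n)
  if (mode == "sensitivity") {
    out[recovery < 85 & recovery >= 50] <- "rescalable"
    out[recovery < 50 | recovery > 110] <- "excluded"
  }
  out[missed_voids >= 2] <- "excluded"
  out
}

#' Rescale an analyte to the expected 93% PABA recovery
#'
#' For collections classified `rescalable`, analyte amounts are scaled
#' proportionally up to the recovery expected of a complete collection:
#' `rescaled = analyte * target / recovery`.
#'
#' @param analyte Analyte amount (vectorized).
#' @param recovery Observed PABA recovery, percent; must be `> 0`.
#' @param target Recovery expected for a complete collection (93%).
#' @return Rescaled analyte amount.
#' @export
#' @examples
#' rescale_for_recovery(10, 62)  # 15 g
rescale_for_recovery <- function(analyte, recovery, target = 93) {
  if (any(recovery <= 0, na.rm = TRUE))
    stop("recovery must be > 0 to rescale", call. = FALSE)
  analyte * target / recovery
}

#' Total energy expenditure from its measured components
#'
#' TEE is the sum of resting energy expenditure (REE, indirect
#' calorimetry), activity energy expenditure (AEE, accelerometry) and the
#' thermic effect of food, the last assumed to be 10% *of TEE*.  That
#' definition forces `TEE = (REE + AEE) / (1 - tef_fraction)`, so the
#' identity `TEE = REE + AEE + tef_fraction * TEE` holds exactly.
#' Participants whose weight changed by more than 5% over the study are not
#' in energy balance and their TEE is excluded (returned as `NA` with the
#' `excluded` flag set).
#'
#' @param ree Resting energy expenditure, MJ/day (vectorized).
#' @param aee Activity energy expenditure, MJ/day.
#' @param weight_change Percent weight change since the first clinic visit.
#' @param tef_fraction Thermic effect of food as a fraction of TEE.
#' @param max_weight_change Exclusion threshold on `|weight_change|`.
#' @return A data frame with columns `tee` (MJ/day, `NA` when excluded) and
#'   `excluded` (logical).
#' @export
#' @examples
#' total_energy_expenditure(6.3, 3.6, 0)  # 11 MJ/day
total_energy_expenditure <- function(ree, aee, weight_change = 0,
                                     tef_fraction = 0.1,
                                     max_weight_change = 5) {
  if (any(ree < 0, na.rm = TRUE) || any(aee < 0, na.rm = TRUE))
    stop("ree and aee must be >= 0", call. = FALSE)
  n <- max(length(ree), length(aee), length(weight_change))
  tee <- rep_len(ree + aee, n) / (1 - tef_fraction)
  excluded <- rep_len(abs(weight_change) > max_weight_change, n)
  excluded[is.na(excluded)] <- FALSE
  tee[excluded] <- NA_real_
  data.frame(tee = tee, excluded = excluded)
}

#' Nutrient density (energy-adjusted intake)
#'
#' @param nutrient Nutrient intake, g/day.
#' @param energy Energy intake or expenditure, MJ/day; must be `> 0`.
#' @return Density in g/MJ.
#' @export
nutrient_density <- function(nutrient, energy) {
  if (any(energy <= 0, na.rm = TRUE))
    stop("energy must be > 0", call. = FALSE)
  nutrient / energy
}

#' Geometric mean with t-based 95% confidence interval
#'
#' Exponentiated mean of logs, with the interval computed on the log scale
#' (one-sample t) and back-transformed.
#'
#' @param values Positive values; `NA` removed.
#' @param level Confidence level.
#' @return A list with `geometric_mean`, `ci` (length 2) and `n`.
#' @export
geometric_mean_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values", call. = FALSE)
  if (any(values <= 0))
    stop("geometric mean requires strictly positive values", call. = FALSE)
  lx <- log(values)
  m <- mean(lx)
  n <- length(lx)
  if (n == 1L || stats::sd(lx) == 0)
    return(list(geometric_mean = exp(m), ci = exp(c(m, m)), n = n))
  hw <- stats::qt(1 - (1 - level) / 2, n - 1L) * stats::sd(lx) / sqrt(n)
  list(geometric_mean = exp(m), ci = exp(c(m - hw, m + hw)), n = n)
}

#' Bland-Altman mean percentage difference between a tool and a reference
#'
#' For each participant the mean over occasions of log tool values minus
#' the mean over occasions of log reference values is formed; the average
#' of those paired differences is back-transformed and expressed as a
#' percentage: `100 * (exp(mean(tool - ref)) - 1)`.  Pairs where either
#' side is entirely missing are dropped.
#'
#' @param tool_log_values Per-participant mean of log tool measurements.
#' @param ref_log_values Per-participant mean of log reference
#'   measurements, paired by position.
#' @param level Confidence level for the t-based interval.
#' @return A list with `percent` (mean % difference), `ci`, and `n` pairs
#'   used.
#' @export
mean_percent_difference <- function(tool_log_values, ref_log_values,
                                    level = 0.95) {
  if (length(tool_log_values) != length(ref_log_values))
    stop("inputs must be paired by participant", call. = FALSE)
  d <- tool_log_values - ref_log_values
  d <- d[!is.na(d)]
  if (!length(d)) stop("no complete pairs", call. = FALSE)
  m <- mean(d)
  if (length(d) == 1L || stats::sd(d) == 0) {
    ci <- 100 * (exp(c(m, m)) - 1)
  } else {
    hw <- stats::qt(1 - (1 - level) / 2, length(d) - 1L) *
      stats::sd(d) / sqrt(length(d))
    ci <- 100 * (exp(c(m - hw, m + hw)) - 1)
  }
  list(percent = 100 * (exp(m) - 1), ci = ci, n = length(d))
}

#' Convert raw urine collections into biomarker intake estimates
#'
#' Applies the completeness rules and conversions to a table of 24-hour
#' urine collections: PABA/missed-void classification, optional rescaling
#' of nitrogen and potassium to the expected 93% recovery (sensitivity
#' mode), nitrogen-to-protein and potassium conversions, and the age/sex
#' calibration of the sucrose + fructose sugar biomarker.
#'
#' @param urine Data frame with columns `participant_id`, `occasion`,
#'   `urine_volume` (L/24 h), `nitrogen` (g/24 h), `potassium` (g/24 h),
#'   `sucrose` (mg/24 h), `fructose` (mg/24 h), `paba_recovery` (% of
#'   dose), `missed_voids` (count).
#' @param covariates Data frame with `participant_id`, `sex`, `age`
#'   (years), needed for the sugar calibration.
#' @param mode `"main"` or `"sensitivity"` (see [classify_paba()]).
#' @param coeffs Sugar [calibration_coefficients()].
#' @param excreted_n,excreted_k Excreted fractions for nitrogen and
#'   potassium.
#' @return The input table with appended columns `paba_status`, `rescaled`,
#'   `protein_biomarker` (g/day), `potassium_biomarker` (g/day) and
#'   `sugar_biomarker_calibrated` (log scale); biomarkers are `NA` for
#'   excluded collections.  Re-running on an already-rescaled table is an
#'   error (rescaling is not idempotent).
#' @export
prepare_urine_records <- function(urine, covariates,
                                  mode = c("main", "sensitivity"),
                                  coeffs = calibration_coefficients(),
                                  excreted_n = 0.81, excreted_k = 0.80) {
  mode <- match.arg(mode)
  req <- c("participant_id", "occasion", "nitrogen", "potassium",
           "sucrose", "fructose", "paba_recovery", "missed_voids")
  miss <- setdiff(req, names(urine))
  if (length(miss))
    stop("urine table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if ("rescaled" %in% names(urine) && any(urine$rescaled, na.rm = TRUE))
    stop("table already contains rescaled records; refusing to rescale ",
         "again", call. = FALSE)
  out <- urine
  out$paba_status <- classify_paba(out$paba_recovery, out$missed_voids, mode)
  out$rescaled <- out$paba_status == "rescalable"
  keep <- out$paba_status != "excluded"

  nitrogen <- out$nitrogen
  potassium <- out$potassium
  resc <- out$rescaled
  nitrogen[resc] <- rescale_for_recovery(nitrogen[resc],
                                         out$paba_recovery[resc])
  potassium[resc] <- rescale_for_recovery(potassium[resc],
                                          out$paba_recovery[resc])

  cv <- covariates[match(out$participant_id, covariates$participant_id), ]
  sugars <- out$sucrose + out$fructose
  if (any(sugars <= 0 & keep, na.rm = TRUE))
    stop("nonpositive sucrose + fructose excretion cannot be ",
         "log-transformed", call. = FALSE)

  out$protein_biomarker <- ifelse(keep,
    protein_from_nitrogen(nitrogen, excreted_n), NA_real_)
  out$potassium_biomarker <- ifelse(keep,
    potassium_from_excretion(potassium, excreted_k), NA_real_)
  out$sugar_biomarker_calibrated <- ifelse(keep,
    calibrate_sugar_biomarker(log(sugars), cv$sex, log(cv$age), coeffs),
    NA_real_)
  out
}

#' Convert energy-expenditure records into reference energy values
#'
#' @param energy Data frame with columns `participant_id`, `occasion`,
#'   `ree`, `aee` (MJ/day) and `weight_change` (% since first visit).
#' @inheritParams total_energy_expenditure
#' @return The input table with appended columns `tee` (MJ/day, `NA` when
#'   excluded) and `tee_excluded`.
#' @export
prepare_energy_records <- function(energy, tef_fraction = 0.1,
                                   max_weight_change = 5) {
  req <- c("participant_id", "occasion", "ree", "aee", "weight_change")
  miss <- setdiff(req, names(energy))
  if (length(miss))
    stop("energy table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  res <- total_energy_expenditure(energy$ree, energy$aee,
                                  energy$weight_change,
                                  tef_fraction, max_weight_change)
  energy$tee <- res$tee
  energy$tee_excluded <- res$excluded
  energy
}
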