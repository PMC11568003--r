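# Clinical risk factor (CRF) layer: multiplicative hazard-ratio adjustment of
# the baseline fracture hazard, plus a BMD term raising the gradient of risk
# to the power of the T-score deficit. Death hazards are never CRF-adjusted.

RISK_FACTOR_NAMES <- c("prior_fracture", "parent_hip_fracture", "current_smoking",
                       "glucocorticoids", "rheumatoid_arthritis", "alcohol_high")

#' A subject's clinical risk profile
#'
#' Six dichotomous clinical risk factors, femoral-neck BMD T-score (optional),
#' BMI, age and sex. BMI is recorded but does not modify hazards by default;
#' comparison grids fix it at a single value for all profiles.
#'
#' @param age age in years (>= 50; the model is undefined below 50).
#' @param sex "male" or "female".
#' @param prior_fracture,parent_hip_fracture,current_smoking,glucocorticoids,rheumatoid_arthritis,alcohol_high
#'   logical indicators (default FALSE).
#' @param t_score femoral-neck BMD T-score in SD units, or \code{NA} if BMD is
#'   unknown (then the BMD term is 1).
#' @param bmi body-mass index in kg/m^2 (default 26).
#' @return A \code{risk_profile}.
#' @export
risk_profile <- function(age, sex, prior_fracture = FALSE,
                         parent_hip_fracture = FALSE, current_smoking = FALSE,
                         glucocorticoids = FALSE, rheumatoid_arthritis = FALSE,
                         alcohol_high = FALSE, t_score = NA_real_, bmi = 26) {
  if (!sex %in% c("male", "female")) value_error("sex must be 'male' or 'female'")
  if (!is.na(t_score) && (t_score < -6 || t_score > 3)) {
    value_error(sprintf("t_score %g outside the plausible range [-6, 3]", t_score))
  }
  if (bmi < 10 || bmi > 60) value_error(sprintf("bmi %g outside [10, 60]", bmi))
  factors <- c(prior_fracture = isTRUE(prior_fracture),
               parent_hip_fracture = isTRUE(parent_hip_fracture),
               current_smoking = isTRUE(current_smoking),
               glucocorticoids = isTRUE(glucocorticoids),
               rheumatoid_arthritis = isTRUE(rheumatoid_arthritis),
               alcohol_high = isTRUE(alcohol_high))
  structure(list(age = age, sex = sex, factors = factors,
                 t_score = t_score, bmi = bmi),
            class = "risk_profile")
}

#' Hazard-ratio parameterisation of the risk-factor layer
#'
#' Per-outcome (hip, MOF) hazard ratios for the six dichotomous factors, plus
#' a per-outcome gradient of risk: the multiplicative hazard increase per 1 SD
#' decrease in T-score below \code{reference_t_score}. All coefficients are
#' configurable; the packaged defaults are documentation placeholders in the
#' range typical of the published CRF meta-analyses, not calibrated values.
#'
#' @param hip,mof named numeric vectors of hazard ratios (> 0), names from
#'   \code{prior_fracture, parent_hip_fracture, current_smoking,
#'   glucocorticoids, rheumatoid_arthritis, alcohol_high}.
#' @param gradient_of_risk named numeric: HR per 1 SD T-score decrease, one
#'   entry per outcome, each >= 1.
#' @param reference_t_score T-score at which the BMD term is 1 (default 0).
#' @param label free-text label.
#' @return A \code{risk_factor_model}.
#' @export
risk_factor_model <- function(hip = default_hazard_ratios("hip"),
                              mof = default_hazard_ratios("mof"),
                              gradient_of_risk = c(hip = 1.8, mof = 1.6),
                              reference_t_score = 0,
                              label = "default placeholder coefficients") {
  check_hr <- function(x, nm) {
    bad <- setdiff(names(x), RISK_FACTOR_NAMES)
    if (length(bad)) config_error(sprintf("unknown risk factor(s) in %s: %s",
                                          nm, paste(bad, collapse = ", ")))
    if (any(x <= 0)) value_error(sprintf("%s hazard ratios must be positive", nm))
    x
  }
  hip <- check_hr(hip, "hip")
  mof <- check_hr(mof, "mof")
  if (any(gradient_of_risk < 1)) value_error("gradient_of_risk must be >= 1")
  if (!all(c("hip", "mof") %in% names(gradient_of_risk))) {
    config_error("gradient_of_risk needs entries named 'hip' and 'mof'")
  }
  structure(list(hip = hip, mof = mof, gradient_of_risk = gradient_of_risk,
                 reference_t_score = reference_t_score, label = label),
            class = "risk_factor_model")
}

#' @rdname risk_factor_model
#' @param outcome "hip" or "mof" (the default set is shared by both).
#' @export
default_hazard_ratios <- function(outcome = c("hip", "mof")) {
  outcome <- match.arg(outcome)
  # One common CRF set for both outcomes; only the BMD gradient differs
  # (steeper for hip). Keeping the hip/MOF multiplier skew below the smallest
  # MOF:hip incidence ratio (~2 in extreme old age) guarantees the adjusted
  # MOF hazard dominates the adjusted hip hazard for every profile, so the
  # hip probability can never exceed the MOF probability.
  c(prior_fracture = 1.9, parent_hip_fracture = 1.8,
    current_smoking = 1.5, glucocorticoids = 1.9,
    rheumatoid_arthritis = 1.6, alcohol_high = 1.6)
}

#' Multiplicative hazard adjustment for a risk profile
#'
#' Returns the product of the hazard ratios of the profile's active indicators
#' times \code{gradient_of_risk ^ (reference_t_score - t_score)}. An unknown
#' (NA) T-score contributes a BMD term of 1. The product commutes, so the
#' result is independent of indicator order.
#'
#' @param profile a \code{risk_profile}.
#' @param model a \code{risk_factor_model}.
#' @param outcome "hip" or "mof".
#' @return A positive multiplier applied to the baseline fracture hazard.
#' @export
hazard_multiplier <- function(profile, model, outcome = c("hip", "mof")) {
  outcome <- match.arg(outcome)
  hrs <- model[[outcome]]
  active <- names(profile$factors)[profile$factors]
  crf <- prod(hrs[intersect(active, names(hrs))], 1)
  bmd <- if (is.na(profile$t_score)) 1 else {
    model$gradient_of_risk[[outcome]] ^ (model$reference_t_score - profile$t_score)
  }
  crf * bmd
}

#' Enumerate the comparison grid of risk profiles
#'
#' Builds the full factorial array of risk-factor combinations crossed with
#' T-score levels at each requested age: \code{2^k * length(t_scores)}
#' profiles per age (512 for six factors and eight T-scores). The ordering is
#' deterministic: ages outermost, then T-scores, then binary combinations in
#' binary-counter order (first factor toggling fastest). This is an array of
#' combinations, not a population simulation.
#'
#' @param ages integer vector of ages (years).
#' @param t_scores numeric vector of T-score levels (default 0 to -3.5 by 0.5).
#' @param factor_names subset of the six risk-factor names (default all six).
#' @param sex "male" or "female".
#' @param bmi BMI fixed across the grid (default 26).
#' @return A \code{profile_grid}: list with \code{ages}, \code{t_scores},
#'   \code{factor_names}, \code{sex} and \code{profiles} (list of
#'   \code{risk_profile}).
#' @export
enumerate_grid <- function(ages, t_scores = seq(0, -3.5, by = -0.5),
                           factor_names = RISK_FACTOR_NAMES,
                           sex = "female", bmi = 26) {
  if (length(t_scores) == 0) config_error("t_scores must be non-empty")
  bad <- setdiff(factor_names, RISK_FACTOR_NAMES)
  if (length(bad)) {
    config_error(sprintf("unknown risk factor name(s): %s", paste(bad, collapse = ", ")))
  }
  k <- length(factor_names)
  profiles <- list()
  for (age in ages) {
    for (t in t_scores) {
      for (code in seq_len(2^k) - 1L) {
        on <- as.logical(bitwAnd(code, bitwShiftL(1L, seq_len(k) - 1L)) > 0)
        args <- stats::setNames(as.list(on), factor_names)
        profiles[[length(profiles) + 1L]] <- do.call(risk_profile, c(
          list(age = age, sex = sex, t_score = t, bmi = bmi), args))
      }
    }
  }
  structure(list(ages = ages, t_scores = t_scores, factor_names = factor_names,
                 sex = sex, profiles = profiles),
            class = "profile_grid")
}

#' Apply a risk profile's multiplier to a hazard path
#'
#' Scales the fracture hazards by [hazard_multiplier()]; death hazards are
#' left untouched (no CRF acts on mortality).
#'
#' @inheritParams hazard_multiplier
#' @param base a \code{hazard_path} for the unadjusted (reference) subject.
#' @return A new \code{hazard_path}.
#' @export
adjusted_hazard_path <- function(base, profile, model, outcome = c("hip", "mof")) {
  outcome <- match.arg(outcome)
  m <- hazard_multiplier(profile, model, outcome)
  hazard_path(base$fracture * m, base$death)
}

# Stable identity key for a profile (used to assert grid uniqueness).
profile_key <- function(p) {
  paste(p$age, p$sex, paste(as.integer(p$factors), collapse = ""),
        format(p$t_score), sep = "|")
}

#' @export
print.risk_profile <- function(x, ...) {
  on <- names(x$factors)[x$factors]
  cat(sprintf("risk_profile: %s, age %g, T-score %s, BMI %g, factors: %s\n",
              x$sex, x$age,
              if (is.na(x$t_score)) "unknown" else format(x$t_score),
              x$bmi, if (length(on)) paste(on, collapse = ", ") else "none"))
  invisible(x)
}

#' @export
print.risk_factor_model <- function(x, ...) {
  cat(sprintf("risk_factor_model: %s\n", x$label))
  tab <- rbind(hip = x$hip[RISK_FACTOR_NAMES], mof = x$mof[RISK_FACTOR_NAMES])
  colnames(tab) <- RISK_FACTOR_NAMES
  print(tab)
  cat(sprintf("gradient of risk (per SD): hip %g, mof %g; reference T-score %g\n",
              x$gradient_of_risk[["hip"]], x$gradient_of_risk[["mof"]],
              x$reference_t_score))
  invisible(x)
}

#' @export
print.profile_grid <- function(x, ...) {
  cat(sprintf("profile_grid: %d profile(s) = %d age(s) x %d T-score(s) x 2^%d combinations (%s)\n",
              length(x$profiles), length(x$ages), length(x$t_scores),
              length(x$factor_names), x$sex))
  invisible(x)
}
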