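#' Coefficients of the parametric 5-year Framingham cardiovascular risk model
#'
#' Published coefficient set of the accelerated-failure-time (Weibull) equation
#' for incident cardiovascular disease of any type, from Anderson KM, Odell PM,
#' Wilson PWF, Kannel WB. Cardiovascular disease risk profiles.
#' *Am Heart J* 1991;121:293-298.
#'
#' The model computes a location parameter
#' \deqn{\mu = \beta_0 + \beta_f F - 1.4792\,\log a - 14.4588\,F\log a +
#'       1.8515\,F(\log a)^2 - 0.9119\,\log SBP - 0.2767\,S -
#'       0.7181\,\log(TC/HDL) - 0.1759\,D - 0.1999\,FD - 0.5865\,L}
#' with \eqn{F} female, \eqn{a} age (years), \eqn{S} smoking, \eqn{D} diabetes
#' and \eqn{L} ECG left-ventricular hypertrophy indicators, a scale parameter
#' \eqn{\sigma = \exp(\theta_0 + \theta_1 \mu)}, and the probability of a first
#' cardiovascular event within \eqn{t} years
#' \deqn{p(t) = 1 - \exp\{-\exp[(\log t - \mu)/\sigma]\}.}
#'
#' @return Named list of coefficients (location terms `intercept`, `female`,
#'   `log_age`, `female_log_age`, `female_log_age_sq`, `log_sbp`, `smoker`,
#'   `log_tc_hdl`, `diabetes`, `female_diabetes`, `lvh`; scale terms `theta0`,
#'   `theta1`).
#' @export
fre_coefficients <- function() {
  list(
    intercept         = 15.5305,
    female            = 28.4441,
    log_age           = -1.4792,
    female_log_age    = -14.4588,
    female_log_age_sq = 1.8515,
    log_sbp           = -0.9119,
    smoker            = -0.2767,
    log_tc_hdl        = -0.7181,
    diabetes          = -0.1759,
    female_diabetes   = -0.1999,
    lvh               = -0.5865,
    theta0            = 0.9145,
    theta1            = -0.2784
  )
}

#' Construct cardiovascular risk profiles
#'
#' Builds a tibble of individual risk profiles, one row per person, with the
#' arguments recycled to a common length. Inputs are validated against the
#' admissible physiological domain.
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age in years (45-49 for the modelled cohort).
#' @param sbp Systolic blood pressure, mmHg (70-260).
#' @param tc Total cholesterol, mmol/L (1-15).
#' @param hdl HDL cholesterol, mmol/L (0.3-4).
#' @param smoker Logical, current smoker.
#' @param diabetic Logical, diabetes (absent in the modelled healthy cohort).
#' @param lvh Logical, ECG left-ventricular hypertrophy (absent by default).
#' @return A tibble with columns `sex`, `age`, `sbp`, `tc`, `hdl`, `smoker`,
#'   `diabetic`, `lvh`.
#' @export
risk_profile <- function(sex, age = 47, sbp, tc, hdl, smoker,
                         diabetic = FALSE, lvh = FALSE) {
  p <- tibble::tibble(
    sex = as.character(sex), age = as.numeric(age), sbp = as.numeric(sbp),
    tc = as.numeric(tc), hdl = as.numeric(hdl), smoker = as.logical(smoker),
    diabetic = as.logical(diabetic), lvh = as.logical(lvh)
  )
  validate_profiles(p, age_range = c(45, 49))
  p
}

validate_profiles <- function(p, age_range = c(30, 74)) {
  stopifnot(is.data.frame(p), nrow(p) >= 1)
  need <- c("sex", "age", "sbp", "tc", "hdl", "smoker", "diabetic", "lvh")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("profile is missing columns: ", paste(miss, collapse = ", "))
  if (!all(p$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  chk <- function(x, lo, hi, what) {
    bad <- !is.finite(x) | x < lo | x > hi
    if (any(bad)) stop(sprintf("%s outside admissible domain [%g, %g]", what, lo, hi))
  }
  chk(p$age, age_range[1], age_range[2], "age")
  chk(p$sbp, 70, 260, "SBP")
  chk(p$tc, 1, 15, "total cholesterol")
  chk(p$hdl, 0.3, 4, "HDL")
  invisible(p)
}

#' Five-year cardiovascular disease risk
#'
#' Evaluates the parametric Framingham risk equation (see
#' [fre_coefficients()]) for each profile, returning the probability of a
#' first cardiovascular event of any modelled subtype within `years` years.
#' The function is strictly increasing in SBP and total cholesterol,
#' decreasing in HDL, and higher for smokers, holding everything else fixed.
#'
#' @param profiles Data frame of risk profiles, as from [risk_profile()] or
#'   [sample_cohort()].
#' @param coef Coefficient list, by default [fre_coefficients()].
#' @param years Risk horizon in years (default 5, the horizon used throughout
#'   the pipeline).
#' @return Numeric vector of event probabilities in (0, 1).
#' @export
five_year_cvd_risk <- function(profiles, coef = fre_coefficients(), years = 5) {
  validate_profiles(profiles)
  f <- as.numeric(profiles$sex == "female")
  la <- log(profiles$age)
  mu <- coef$intercept +
    coef$female * f +
    coef$log_age * la +
    coef$female_log_age * f * la +
    coef$female_log_age_sq * f * la^2 +
    coef$log_sbp * log(profiles$sbp) +
    coef$smoker * as.numeric(profiles$smoker) +
    coef$log_tc_hdl * log(profiles$tc / profiles$hdl) +
    coef$diabetes * as.numeric(profiles$diabetic) +
    coef$female_diabetes * f * as.numeric(profiles$diabetic) +
    coef$lvh * as.numeric(profiles$lvh)
  sigma <- exp(coef$theta0 + coef$theta1 * mu)
  u <- (log(years) - mu) / sigma
  1 - exp(-exp(u))
}

#' Mean cohort incidence
#'
#' Arithmetic mean of individual 5-year risks over a simulated cohort: the
#' cohort-level incidence used as the arm-specific event probability.
#'
#' @param profiles Data frame of risk profiles (non-empty).
#' @param coef Coefficient list passed to [five_year_cvd_risk()].
#' @return Mean 5-year risk (scalar fraction).
#' @export
cohort_incidence <- function(profiles, coef = fre_coefficients()) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0)
    stop("cohort must contain at least one profile")
  mean(five_year_cvd_risk(profiles, coef))
}
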