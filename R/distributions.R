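RISK_FACTORS <- c("SBP", "TC", "HDL", "smoking")

#' Load a model configuration
#'
#' Reads the YAML configuration carrying every model input: per-sex categorical
#' risk-factor distributions, intervention relative risks, event-subtype
#' allocation, age-band incidence/mortality/SMRs, utilities, costs, the
#' health-check service-bundle cost model, PSA priors and run settings.
#' The shipped default (`system.file("extdata", "default_config.yaml",
#' package = "checkup45")`) emulates the risk-factor distributions of 45-49
#' year old Australians in the 2011 National Health Survey; its bins are
#' synthetic, calibrated so that the usual-care arm reproduces the published
#' 5-year incidences (see the package vignette).
#'
#' @param path Path to a YAML configuration file. Default: the shipped config.
#' @return A validated configuration object (class `hc_config`).
#' @export
load_config <- function(path = default_config_path()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
  cfg$distributions <- lapply_names(cfg$distributions, function(d, sex) {
    as_risk_dist(d, sex, age = cfg$settings$fre_age %||% 47)
  })
  structure(cfg, class = "hc_config")
}

#' @rdname load_config
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "checkup45", mustWork = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lapply_names <- function(x, f) {
  out <- lapply(names(x), function(nm) f(x[[nm]], nm))
  names(out) <- names(x)
  out
}

#' Load per-sex risk-factor distributions
#'
#' Extracts the categorical risk-factor distributions (SBP, total cholesterol,
#' HDL, smoking) from a configuration, one `risk_dist` object per sex.
#'
#' @param config A configuration object or a path to one.
#' @return Named list with elements `male` and `female`.
#' @export
load_distributions <- function(config = load_config()) {
  if (is.character(config)) config <- load_config(config)
  config$distributions
}

as_risk_dist <- function(d, sex, age = 47) {
  factors <- list()
  for (fac in c("SBP", "TC", "HDL")) {
    if (is.null(d[[fac]]))
      stop("distribution schema error (", sex, "): missing factor ", fac)
    b <- do.call(rbind, lapply(d[[fac]], function(x)
      data.frame(label = x$label %||% NA_character_,
                 lower = x$lower, upper = x$upper,
                 value = x$value %||% ((x$lower + x$upper) / 2),
                 mass = x$mass)))
    b <- tibble::as_tibble(b)
    factors[[fac]] <- b
  }
  if (is.null(d$smoking))
    stop("distribution schema error (", sex, "): missing factor smoking")
  sm <- d$smoking
  if (is.list(sm)) sm <- unlist(sm)
  if (length(sm) == 1) sm <- c(smoker = unname(sm), `non-smoker` = 1 - unname(sm))
  factors$smoking <- tibble::tibble(
    label = c("smoker", "non-smoker"),
    lower = NA_real_, upper = NA_real_,
    value = c(TRUE, FALSE),
    mass = c(sm[["smoker"]], sm[["non-smoker"]])
  )
  dist <- structure(list(sex = sex, age = age, factors = factors),
                    class = "risk_dist")
  validate_risk_dist(dist)
  dist
}

validate_risk_dist <- function(dist, tol = 1e-6) {
  for (fac in RISK_FACTORS) {
    b <- dist$factors[[fac]]
    if (is.null(b))
      stop("distribution schema error (", dist$sex, "): missing factor ", fac)
    if (any(b$mass < 0 | b$mass > 1))
      stop("distribution schema error (", dist$sex, ", ", fac,
           "): bin mass outside [0, 1]")
    s <- sum(b$mass)
    if (abs(s - 1) > tol)
      stop(sprintf("distribution schema error (%s, %s): bin masses sum to %.6f, not 1",
                   dist$sex, fac, s))
    # normalize residual rounding so downstream sums are exact
    dist$factors[[fac]]$mass <- b$mass / s
    if (fac != "smoking") {
      if (any(b$value < b$lower - 1e-9 | b$value > b$upper + 1e-9))
        stop("distribution schema error (", dist$sex, ", ", fac,
             "): representative value outside its bin")
      o <- order(b$lower)
      if (any(abs(b$upper[o][-nrow(b)] - b$lower[o][-1]) > 1e-9))
        stop("distribution schema error (", dist$sex, ", ", fac,
             "): bins do not partition the support")
    }
  }
  invisible(dist)
}

#' Sample a cohort of risk profiles
#'
#' Draws `n` individual profiles from a per-sex categorical risk-factor
#' distribution. Factors are sampled independently (the survey source reports
#' marginal distributions only); each sampled bin contributes its
#' representative value as the continuous input to the risk equation.
#' Reproducible: a fixed `seed` yields a bitwise-identical cohort.
#'
#' @param dist A `risk_dist` object.
#' @param n Number of profiles (>= 1).
#' @param seed Integer seed.
#' @return Tibble of `n` risk profiles (columns as in [risk_profile()]).
#' @export
sample_cohort <- function(dist, n, seed = 1L) {
  stopifnot(inherits(dist, "risk_dist"))
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop("n must be a positive integer")
  n <- as.integer(n)
  set.seed(as.integer(seed))
  draw <- function(b) b$value[sample.int(nrow(b), n, replace = TRUE, prob = b$mass)]
  tibble::tibble(
    sex = dist$sex,
    age = dist$age,
    sbp = draw(dist$factors$SBP),
    tc = draw(dist$factors$TC),
    hdl = draw(dist$factors$HDL),
    smoker = as.logical(draw(dist$factors$smoking)),
    diabetic = FALSE,
    lvh = FALSE
  )
}

#' Apply health-check intervention effects to a distribution
#'
#' Implements the reallocation model for the treatment effect: for each
#' treated factor, the total probability mass above the high-risk threshold is
#' multiplied by the relative risk of remaining at high risk, and the removed
#' mass is redistributed over the below-threshold bins proportionally to their
#' existing masses (smoking: the smoker mass is multiplied by its RR and moved
#' to the non-smoker bin). Factors without an effect (HDL) are unchanged and
#' total mass is conserved exactly.
#'
#' @param dist A `risk_dist` object (usual-care distribution).
#' @param effects Named list of intervention effects; each element has a `rr`
#'   and, for continuous factors, a `threshold` aligned with a bin boundary.
#'   Names must be factors present in `dist`.
#' @return The modified `risk_dist` for the health-check arm.
#' @export
apply_intervention <- function(dist, effects) {
  stopifnot(inherits(dist, "risk_dist"))
  for (fac in names(effects)) {
    eff <- effects[[fac]]
    if (is.null(dist$factors[[fac]]))
      stop("intervention effect refers to unknown factor ", fac)
    rr <- eff$rr
    if (!is.numeric(rr) || rr <= 0 || rr > 1)
      stop("relative risk for ", fac, " must be in (0, 1]")
    b <- dist$factors[[fac]]
    if (fac == "smoking") {
      i <- which(b$value == TRUE)
      moved <- b$mass[i] * (1 - rr)
      b$mass[i] <- b$mass[i] - moved
      b$mass[-i] <- b$mass[-i] + moved
    } else {
      thr <- eff$threshold
      if (is.null(thr)) stop("effect on ", fac, " lacks a threshold")
      straddle <- b$lower < thr & b$upper > thr
      if (any(straddle))
        stop("threshold ", thr, " for ", fac,
             " does not align with a bin boundary; redistribution is ill-defined")
      hi <- b$lower >= thr
      if (!any(hi) || all(hi))
        stop("threshold ", thr, " for ", fac, " leaves no bins on one side")
      moved <- sum(b$mass[hi]) * (1 - rr)
      b$mass[hi] <- b$mass[hi] * rr
      lo_tot <- sum(b$mass[!hi])
      b$mass[!hi] <- b$mass[!hi] * (1 + moved / lo_tot)
    }
    dist$factors[[fac]]$mass <- b$mass
  }
  dist
}

#' Exact expected cohort risk under a categorical distribution
#'
#' Computes the population-mean 5-year risk analytically by enumerating every
#' joint risk-factor bin combination (factors independent) and weighting the
#' risk-equation output by the product of bin masses. This is the
#' infinite-cohort limit of [sample_cohort()] + [cohort_incidence()] and is
#' used for the deterministic base case.
#'
#' @param dist A `risk_dist` object.
#' @param coef Risk-equation coefficients.
#' @return Expected 5-year risk (scalar).
#' @export
expected_risk <- function(dist, coef = fre_coefficients()) {
  stopifnot(inherits(dist, "risk_dist"))
  g <- expand.grid(
    sbp = seq_len(nrow(dist$factors$SBP)),
    tc = seq_len(nrow(dist$factors$TC)),
    hdl = seq_len(nrow(dist$factors$HDL)),
    sm = 1:2
  )
  profiles <- tibble::tibble(
    sex = dist$sex, age = dist$age,
    sbp = dist$factors$SBP$value[g$sbp],
    tc = dist$factors$TC$value[g$tc],
    hdl = dist$factors$HDL$value[g$hdl],
    smoker = as.logical(dist$factors$smoking$value[g$sm]),
    diabetic = FALSE, lvh = FALSE
  )
  w <- dist$factors$SBP$mass[g$sbp] * dist$factors$TC$mass[g$tc] *
    dist$factors$HDL$mass[g$hdl] * dist$factors$smoking$mass[g$sm]
  sum(w * five_year_cvd_risk(profiles, coef))
}

#' Above-threshold probability mass of one factor
#'
#' @param dist A `risk_dist` object.
#' @param factor Factor name (`"SBP"`, `"TC"` or `"smoking"`).
#' @param threshold Threshold for continuous factors (ignored for smoking).
#' @return Total mass above the threshold (smoking: smoker prevalence).
#' @export
above_threshold_mass <- function(dist, factor, threshold = NULL) {
  b <- dist$factors[[factor]]
  if (is.null(b)) stop("unknown factor ", factor)
  if (factor == "smoking") return(sum(b$mass[b$value == TRUE]))
  if (is.null(threshold)) stop("threshold required for ", factor)
  sum(b$mass[b$lower >= threshold])
}

#' Export a cohort to CSV
#'
#' Writes one row per profile with the documented column order
#' `sex, age, sbp, tc, hdl, smoker, diabetic, lvh`.
#'
#' @param profiles Tibble from [sample_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(profiles, path) {
  validate_profiles(profiles)
  utils::write.csv(profiles[, c("sex", "age", "sbp", "tc", "hdl",
                                "smoker", "diabetic", "lvh")],
                   path, row.names = FALSE)
  invisible(path)
}
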