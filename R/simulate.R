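#' Exact arm-level 5-year risks from a configuration
#'
#' Computes the usual-care and health-check 5-year CVD incidences per sex as
#' exact expectations of the risk equation over the categorical risk-factor
#' distributions ([expected_risk()]), with the health-check distribution
#' derived by [apply_intervention()]. If the configuration carries an
#' explicit `incidence_5yr` block it overrides the computed values.
#'
#' @param config An `hc_config` object.
#' @return Named list (`male`, `female`) of vectors
#'   `c(usual_care = , health_check = )`.
#' @export
arm_risks <- function(config) {
  stopifnot(inherits(config, "hc_config"))
  out <- lapply(c("male", "female"), function(sex) {
    ov <- config$incidence_5yr[[sex]]
    if (!is.null(ov))
      return(c(usual_care = ov$usual_care, health_check = ov$health_check))
    uc <- config$distributions[[sex]]
    hc <- apply_intervention(uc, config$effects)
    c(usual_care = expected_risk(uc), health_check = expected_risk(hc))
  })
  names(out) <- c("male", "female")
  out
}

#' Monte Carlo simulation of both arms
#'
#' Repeats the cohort microsimulation: in each repetition a fresh usual-care
#' cohort and a fresh health-check cohort of `n` individuals are sampled from
#' their respective distributions (independent arms by default; `paired =
#' TRUE` reuses the usual-care uniform draws in the health-check arm as a
#' common-random-numbers device), mean 5-year risks are computed with the
#' risk equation, and the between-arm relative risk is recorded. Seeds for
#' every repetition derive from the master seed via [split_seed()].
#'
#' @param config An `hc_config` object (supplies distributions and effects).
#' @param sex `"male"` or `"female"`.
#' @param n Cohort size per arm per repetition (the study design uses 5,000).
#' @param reps Number of repetitions (>= 2; the study design uses 1,000).
#' @param seed Master integer seed.
#' @param paired Use common random numbers across arms (default `FALSE`).
#' @return List with `estimates` (tibble: one row per arm with mean risk and
#'   2.5/97.5 percentiles over repetitions), `rr` (tibble: mean and
#'   percentiles of the per-repetition relative risk), and `draws` (tibble of
#'   per-repetition arm means).
#' @export
simulate_arms <- function(config, sex, n = 5000, reps = 1000, seed = 1L,
                          paired = FALSE) {
  stopifnot(inherits(config, "hc_config"))
  if (reps < 2) stop("reps must be at least 2")
  dist_uc <- config$distributions[[sex]]
  dist_hc <- apply_intervention(dist_uc, config$effects)
  uc <- hc <- numeric(reps)
  for (r in seq_len(reps)) {
    s_uc <- split_seed(seed, 2L * r)
    s_hc <- if (paired) s_uc else split_seed(seed, 2L * r + 1L)
    uc[r] <- cohort_incidence(sample_cohort(dist_uc, n, s_uc))
    hc[r] <- cohort_incidence(sample_cohort(dist_hc, n, s_hc))
  }
  rr <- hc / uc
  pct <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  summarize <- function(arm, x) {
    q <- pct(x)
    tibble::tibble(arm = arm, sex = sex, mean = mean(x),
                   p2.5 = q[1], p97.5 = q[2], reps = reps, n = n)
  }
  list(
    estimates = rbind(summarize("usual_care", uc), summarize("health_check", hc)),
    rr = tibble::tibble(sex = sex, mean = mean(rr),
                        p2.5 = pct(rr)[1], p97.5 = pct(rr)[2], reps = reps),
    draws = tibble::tibble(rep = seq_len(reps), usual_care = uc,
                           health_check = hc, rr = rr)
  )
}
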