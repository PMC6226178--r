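# Shared fixtures: the default configuration is loaded once per test run,
# and small synthetic distributions are built in code.

.fixture_env <- new.env()

test_config <- function() {
  if (is.null(.fixture_env$cfg)) .fixture_env$cfg <- load_config()
  .fixture_env$cfg
}

test_params <- function() build_parameters(test_config())

# A params object with selected components replaced (list-style overrides).
params_with <- function(params, ...) {
  mods <- list(...)
  for (nm in names(mods)) params[[nm]] <- mods[[nm]]
  params
}

zero_epi_params <- function() {
  p <- test_params()
  for (sex in c("male", "female")) {
    p$mortality[[sex]][] <- 0
    p$incidence[[sex]][] <- 0
  }
  p
}

# Two-bin toy distribution with configurable masses, for distribution-level
# unit tests (independent of the shipped calibrated defaults).
toy_dist <- function(sex = "male", smoker = 0.2,
                     sbp_hi = 0.10, tc_hi = 0.25) {
  mk_bins <- function(lower, upper, value, mass) {
    tibble::tibble(label = paste0("b", seq_along(lower)),
                   lower = lower, upper = upper, value = value, mass = mass)
  }
  structure(list(
    sex = sex, age = 47,
    factors = list(
      SBP = mk_bins(c(90, 120, 140), c(120, 140, 200), c(110, 128, 155),
                    c(0.5 - sbp_hi / 2, 0.5 - sbp_hi / 2, sbp_hi)),
      TC = mk_bins(c(2.5, 5, 6), c(5, 6, 10), c(4.5, 5.5, 7.0),
                   c(0.5 - tc_hi / 2, 0.5 - tc_hi / 2, tc_hi)),
      HDL = mk_bins(c(0.5, 1.3), c(1.3, 3), c(1.1, 1.6), c(0.6, 0.4)),
      smoking = tibble::tibble(label = c("smoker", "non-smoker"),
                               lower = NA_real_, upper = NA_real_,
                               value = c(TRUE, FALSE),
                               mass = c(smoker, 1 - smoker))
    )), class = "risk_dist")
}

point_mass_dist <- function(sex = "male") {
  d <- toy_dist(sex)
  for (fac in c("SBP", "TC", "HDL"))
    d$factors[[fac]]$mass <- c(1, rep(0, nrow(d$factors[[fac]]) - 1))
  d$factors$smoking$mass <- c(0, 1)
  d
}

default_effects <- function() test_config()$effects
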