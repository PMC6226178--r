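test_that("the shipped configuration loads with complete, normalized distributions", {
  cfg <- test_config()
  for (sex in c("male", "female")) {
    d <- cfg$distributions[[sex]]
    expect_s3_class(d, "risk_dist")
    expect_setequal(names(d$factors), c("SBP", "TC", "HDL", "smoking"))
    for (fac in names(d$factors))
      expect_equal(sum(d$factors[[fac]]$mass), 1, tolerance = 1e-12)
  }
})

test_that("schema violations are rejected with the offending factor named", {
  d <- toy_dist()
  d$factors$smoking$mass <- c(0.6, 0.5)
  expect_error(checkup45:::validate_risk_dist(d), "smoking")
  d <- toy_dist()
  d$factors$TC <- NULL
  expect_error(checkup45:::validate_risk_dist(d), "TC")
  d <- toy_dist()
  d$factors$SBP$value[1] <- 300
  expect_error(checkup45:::validate_risk_dist(d), "SBP")
  d <- toy_dist()
  d$factors$SBP$lower[2] <- 125 # gap between bins
  expect_error(checkup45:::validate_risk_dist(d), "partition")
})

test_that("point-mass distributions produce identical profiles", {
  d <- point_mass_dist()
  cohort <- sample_cohort(d, 10, seed = 3)
  expect_equal(nrow(cohort), 10)
  expect_equal(nrow(unique(cohort)), 1)
})

test_that("sampling is bitwise reproducible under a fixed seed", {
  d <- test_config()$distributions$male
  a <- sample_cohort(d, 500, seed = 99)
  b <- sample_cohort(d, 500, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, sample_cohort(d, 500, seed = 100)))
  expect_error(sample_cohort(d, 0, seed = 1), "positive")
})

test_that("empirical bin frequencies converge to configured masses", {
  d <- toy_dist(smoker = 0.2)
  n <- 1e5
  cohort <- sample_cohort(d, n, seed = 7)
  # 4-sigma binomial bands
  band <- function(p) 4 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(cohort$smoker) - 0.2), band(0.2))
  sbp <- d$factors$SBP
  for (i in seq_len(nrow(sbp)))
    expect_lt(abs(mean(cohort$sbp == sbp$value[i]) - sbp$mass[i]),
              band(sbp$mass[i]))
})

test_that("intervention reallocation does the published arithmetic", {
  d <- toy_dist(smoker = 0.2, sbp_hi = 0.10)
  out <- apply_intervention(d, list(smoking = list(rr = 0.9)))
  expect_equal(above_threshold_mass(out, "smoking"), 0.18)
  # SBP: above-140 mass 0.10 with RR 0.71 -> 0.071; below bins scaled by
  # conservation, (1 - 0.071) / 0.90
  out <- apply_intervention(d, list(SBP = list(threshold = 140, rr = 0.71)))
  expect_equal(above_threshold_mass(out, "SBP", 140), 0.071)
  lo_scale <- (1 - 0.071) / 0.90
  expect_equal(out$factors$SBP$mass[1:2], d$factors$SBP$mass[1:2] * lo_scale)
})

test_that("intervention conserves mass, only helps, and RR=1 is the identity", {
  effects <- default_effects()
  for (sex in c("male", "female")) {
    uc <- test_config()$distributions[[sex]]
    hc <- apply_intervention(uc, effects)
    for (fac in names(hc$factors))
      expect_equal(sum(hc$factors[[fac]]$mass), 1, tolerance = 1e-9)
    expect_lte(above_threshold_mass(hc, "SBP", 140),
               above_threshold_mass(uc, "SBP", 140))
    expect_lte(above_threshold_mass(hc, "TC", 6),
               above_threshold_mass(uc, "TC", 6))
    expect_lte(above_threshold_mass(hc, "smoking"),
               above_threshold_mass(uc, "smoking"))
    # HDL is untreated and must be untouched
    expect_identical(hc$factors$HDL, uc$factors$HDL)
    identity_effects <- lapply(effects, function(e) { e$rr <- 1; e })
    same <- apply_intervention(uc, identity_effects)
    for (fac in names(uc$factors))
      expect_equal(same$factors[[fac]]$mass, uc$factors[[fac]]$mass)
  }
})

test_that("a threshold off a bin boundary is rejected", {
  d <- toy_dist()
  expect_error(apply_intervention(d, list(SBP = list(threshold = 145, rr = 0.7))),
               "bin boundary")
  expect_error(apply_intervention(d, list(glucose = list(rr = 0.9))), "unknown factor")
  expect_error(apply_intervention(d, list(SBP = list(threshold = 140, rr = 1.2))),
               "relative risk")
})

test_that("exact expected risk matches large-sample Monte Carlo", {
  d <- test_config()$distributions$male
  exact <- expected_risk(d)
  n <- 1e5
  mc <- cohort_incidence(sample_cohort(d, n, seed = 21))
  # individual risks have sd ~0.03; 4-sigma Monte Carlo band
  expect_lt(abs(mc - exact), 4 * 0.035 / sqrt(n))
})

test_that("usual-care expected risks sit at the calibrated cohort incidences", {
  cfg <- test_config()
  expect_equal(expected_risk(cfg$distributions$male), 0.037, tolerance = 2e-3)
  expect_equal(expected_risk(cfg$distributions$female), 0.015, tolerance = 2e-3)
})

test_that("cohorts round-trip through CSV export", {
  d <- point_mass_dist()
  cohort <- sample_cohort(d, 5, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(cohort, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), 5)
  expect_equal(back$sbp, cohort$sbp)
  expect_equal(back$smoker, cohort$smoker)
})
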