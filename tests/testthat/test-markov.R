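test_that("annualization is the exact constant-hazard conversion", {
  expect_equal(annualize(0), 0)
  # frozen from independent arithmetic: 1 - 0.963^(1/5)
  expect_equal(annualize(0.037), 0.007512016141, tolerance = 1e-10)
  # round trip: applying the annual probability five times recovers p5
  p5 <- seq(0.01, 0.5, by = 0.01)
  expect_equal(1 - (1 - annualize(p5))^5, p5, tolerance = 1e-12)
  expect_error(annualize(1), "\\[0, 1\\)")
})

test_that("subtype split applies the allocation shares", {
  alloc <- c(SA = 0.2, UA = 0.2, MI = 0.2, stroke = 0.2, TIA = 0.2)
  expect_equal(unname(split_by_subtype(0.05, alloc)), rep(0.01, 5))
  expect_equal(unname(split_by_subtype(0, alloc)), rep(0, 5))
  # published male share: MI gets 42.87% of the annual CVD probability
  params <- test_params()
  p <- split_by_subtype(0.0075, params$alloc$male)
  expect_equal(unname(p["MI"]), 0.0075 * 0.4287)
  # shares summing to 1 conserve the total
  expect_equal(sum(split_by_subtype(0.03, alloc)), 0.03)
})

test_that("transition matrices are row-stochastic with an absorbing dead state", {
  params <- test_params()
  for (sex in c("male", "female")) {
    for (cycle in c(1, 3, 5, 6, 20, 50)) {
      P <- build_transition_matrix(params, sex, cycle, p5 = 0.037)
      expect_equal(rowSums(P), setNames(rep(1, 12), health_states()),
                   tolerance = 1e-12)
      expect_true(all(P >= 0))
      expect_equal(P["Dead", ], setNames(c(rep(0, 11), 1), health_states()))
      # tunnel property: event states cannot remain in themselves
      for (st in paste0("Event_", c("SA", "UA", "MI", "stroke", "TIA")))
        expect_equal(P[st, st], 0)
    }
  }
})

test_that("arms share transition probabilities from cycle 6 onwards", {
  params <- test_params()
  P_uc <- build_transition_matrix(params, "male", 6, p5 = 0.037)
  P_hc <- build_transition_matrix(params, "male", 6, p5 = 0.032)
  expect_identical(P_uc, P_hc)
  # ...but not in the first five cycles
  expect_false(identical(build_transition_matrix(params, "male", 3, 0.037),
                         build_transition_matrix(params, "male", 3, 0.032)))
})

test_that("post-event mortality is the SMR-multiplied background rate", {
  params <- test_params()
  # male aged 67 (cycle 23 from entry at 45): post-MI death 0.01628 x 2.28
  P <- build_transition_matrix(params, "male", 23, p5 = 0.037)
  expect_equal(P["Post_MI", "Dead"], 0.01628 * 2.28, tolerance = 1e-12)
  expect_equal(P["Event_MI", "Dead"], 0.01628 * 2.28, tolerance = 1e-12)
  # SMR-multiplied mortality is capped at 1
  capped <- params_with(params, smr = lapply(params$smr, function(x) x * 50))
  P <- build_transition_matrix(capped, "male", 50, p5 = 0.037)
  expect_equal(P["Post_stroke", "Dead"], 1)
})

test_that("cohort propagation conserves occupancy and dead is monotone", {
  params <- test_params()
  for (sex in c("male", "female")) {
    trace <- run_cohort(params, sex, p5 = 0.037)
    expect_equal(nrow(trace), 50)
    expect_equal(rowSums(trace), rep(1, 50), tolerance = 1e-9)
    expect_true(all(diff(trace[, "Dead"]) >= 0))
  }
})

test_that("degenerate cohorts behave as closed-form limits", {
  params <- test_params()
  all_dead <- c(rep(0, 11), 1)
  trace <- run_cohort(params, "male", p5 = 0.037, init = all_dead)
  expect_equal(unname(trace[, "Dead"]), rep(1, 50))
  # no incidence, no mortality: everyone stays CVD-free for 50 cycles
  p0 <- zero_epi_params()
  trace <- run_cohort(p0, "male", p5 = 0)
  expect_equal(unname(trace[, "NoCVD"]), rep(1, 50))
  expect_equal(life_years(trace, discount = 0), 50)
})

test_that("no repeat events: post-event occupancy flows only to itself or death", {
  params <- test_params()
  init <- rep(0, 12); init[9] <- 1 # all in Post_MI
  trace <- run_cohort(params, "male", p5 = 0.037, init = init)
  other <- setdiff(health_states(), c("Post_MI", "Dead"))
  expect_equal(max(abs(trace[, other])), 0)
})

test_that("propagation equals an independent matrix-power computation", {
  params <- test_params()
  mats <- lapply(1:50, function(t) build_transition_matrix(params, "male", t, 0.037))
  x0 <- c(1, rep(0, 11))
  trace <- run_cohort(params, "male", p5 = 0.037)
  # independent: accumulate the matrix product first, then apply to x0
  acc <- diag(12)
  for (t in 1:50) {
    acc <- acc %*% mats[[t]]
    expect_equal(unname(trace[t, ]), as.vector(x0 %*% acc), tolerance = 1e-12)
  }
  # random row-stochastic 12-state chains through the same propagation kernel
  set.seed(5)
  for (rep in 1:5) {
    M <- matrix(rexp(144), 12, 12)
    M <- M / rowSums(M)
    rand_mats <- replicate(10, M, simplify = FALSE)
    got <- checkup45:::propagate(x0, rand_mats)
    want <- t(vapply(1:10, function(t) {
      as.vector(x0 %*% Reduce(`%*%`, rand_mats[1:t]))
    }, numeric(12)))
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("life-years and QALYs respond to discounting monotonically", {
  params <- test_params()
  trace <- run_cohort(params, "male", p5 = 0.037)
  expect_lte(life_years(trace, 0.05), life_years(trace, 0.035))
  expect_lte(life_years(trace, 0.035), life_years(trace, 0))
  expect_lte(qalys(trace, params, 0.05), qalys(trace, params, 0.035))
  expect_lte(qalys(trace, params, 0.035), qalys(trace, params, 0))
})

test_that("single-cycle QALY is utility over one discount factor", {
  params <- params_with(zero_epi_params(), cycles = 1L)
  for (sex in c("male", "female"))
    params$pop_utility[[sex]][] <- 0.8
  trace <- run_cohort(params, "male", p5 = 0)
  expect_equal(qalys(trace, params, discount = 0.05), 0.8 / 1.05, tolerance = 1e-12)
})

test_that("a lower intervention incidence yields at least as many LYs and QALYs", {
  params <- test_params()
  uc <- run_cohort(params, "male", p5 = 0.037)
  hc <- run_cohort(params, "male", p5 = 0.032)
  expect_gte(life_years(hc, 0), life_years(uc, 0))
  expect_gte(qalys(hc, params), qalys(uc, params))
})

test_that("TIA carries no utility decrement in event or post-event states", {
  params <- test_params()
  u <- checkup45:::state_utilities(params, "male", 47)
  expect_equal(unname(u["Event_TIA"]), 1)
  expect_equal(unname(u["Post_TIA"]), unname(u["NoCVD"]))
  expect_lt(u["Post_stroke"], u["NoCVD"])
})
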