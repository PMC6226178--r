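#' Accumulate discounted lifetime costs over a trace
#'
#' Per cycle, each event-state occupancy incurs its acute hospitalization
#' cost and each post-event occupancy incurs the annual post-event cost
#' (fraction `f` of the acute cost), discounted by `(1 + rate)^-cycle`. The
#' health-check arm additionally carries the direct health-check cost once,
#' at entry (time zero, undiscounted); usual care carries no primary-care
#' cost.
#'
#' @param trace A `state_trace` from [run_cohort()].
#' @param params A `cea_params` object.
#' @param arm `"usual_care"` or `"health_check"`.
#' @param f Post-event annual cost fraction; defaults to
#'   `params$post_cost_fraction`.
#' @param discount Annual discount rate; defaults to `params$discount`.
#' @param check_cost Direct health-check cost for the health-check arm;
#'   defaults to the sex-specific mean in `params`.
#' @return Total discounted cost (AUD) per cohort member.
#' @export
accumulate_costs <- function(trace, params, arm = c("usual_care", "health_check"),
                             f = params$post_cost_fraction,
                             discount = params$discount,
                             check_cost = NULL) {
  check_trace(trace)
  arm <- match.arg(arm)
  sex <- attr(trace, "sex")
  ac <- params$acute_cost
  ev <- trace[, paste0("Event_", CVD_SUBTYPES), drop = FALSE]
  po <- trace[, paste0("Post_", CVD_SUBTYPES), drop = FALSE]
  df <- (1 + discount)^(-seq_len(nrow(trace)))
  total <- sum(df * (ev %*% ac + po %*% (f * ac)))
  if (arm == "health_check") {
    if (is.null(check_cost)) check_cost <- params$check_cost[[sex]][["mean"]]
    total <- total + check_cost
  }
  total
}

#' Lifetime outcome of one arm
#'
#' Runs the Markov cohort for one sex and arm and returns its discounted
#' outcome triplet (life-years, QALYs, cost).
#'
#' @param params A `cea_params` object.
#' @param sex `"male"` or `"female"`.
#' @param arm `"usual_care"` or `"health_check"`.
#' @param p5 Arm-specific 5-year CVD risk.
#' @param f,discount,check_cost Optional overrides, as in
#'   [accumulate_costs()].
#' @return One-row tibble: `arm`, `sex`, `ly`, `qaly`, `cost`.
#' @export
arm_outcome <- function(params, sex, arm, p5,
                        f = params$post_cost_fraction,
                        discount = params$discount,
                        check_cost = NULL) {
  trace <- run_cohort(params, sex, p5)
  tibble::tibble(
    arm = arm, sex = sex,
    ly = life_years(trace, params$ly_discount),
    qaly = qalys(trace, params, discount),
    cost = accumulate_costs(trace, params, arm, f, discount, check_cost)
  )
}

#' Incremental cost-effectiveness ratios
#'
#' Computes unrounded incremental cost, life-years and QALYs between arms,
#' the ICER per life-year and per QALY, and a dominance classification
#' following standard cost-effectiveness conventions: `"trade-off"` when the
#' ratio is informative, `"dominant"` when the intervention is cheaper and at
#' least as effective, `"dominated"` when costlier and no more effective, and
#' `"undefined"` (with `NA` ratio, no error) when the effect difference is
#' zero but costs differ.
#'
#' @param control Outcome row for usual care (from [arm_outcome()]).
#' @param intervention Outcome row for the health check.
#' @return One-row tibble: `sex`, `d_ly`, `d_qaly`, `d_cost`, `icer_ly`,
#'   `icer_qaly`, `classification`.
#' @export
compute_icer <- function(control, intervention) {
  if (!identical(control$sex, intervention$sex))
    stop("arms being compared must share the same sex")
  d_cost <- intervention$cost - control$cost
  d_ly <- intervention$ly - control$ly
  d_qaly <- intervention$qaly - control$qaly
  classify <- function(de, dc) {
    if (de == 0 && dc == 0) "equivalent"
    else if (de == 0) "undefined"
    else if (dc <= 0 && de > 0) "dominant"
    else if (dc >= 0 && de < 0) "dominated"
    else "trade-off"
  }
  ratio <- function(de, dc) if (de == 0) NA_real_ else dc / de
  tibble::tibble(
    sex = control$sex,
    d_ly = d_ly, d_qaly = d_qaly, d_cost = d_cost,
    icer_ly = ratio(d_ly, d_cost),
    icer_qaly = ratio(d_qaly, d_cost),
    classification = classify(d_qaly, d_cost)
  )
}

#' Expected direct cost of the health check
#'
#' Service-bundle costing of the health check: the base check cost (practice
#' visits and pathology of the check itself) plus, for each detected risk
#' condition, its annual management bundle weighted by condition prevalence
#' and by the treatment uptake and compliance rates. The minimum assumes no
#' follow-up intervention at all; the maximum assumes full uptake and
#' compliance.
#'
#' @param model The `health_check_model` block of a configuration: list with
#'   `base_cost` and per-sex `uptake`, `compliance` and `conditions` (each a
#'   list with `name`, `prevalence`, `annual_cost`).
#' @param sex `"male"` or `"female"`.
#' @return Named numeric vector `mean`, `min`, `max` (AUD).
#' @export
expected_direct_cost <- function(model, sex) {
  m <- model[[sex]]
  if (is.null(m)) stop("health-check cost model incomplete for ", sex)
  base <- model$base_cost
  prev <- vapply(m$conditions, function(x) x$prevalence, numeric(1))
  cost <- vapply(m$conditions, function(x) x$annual_cost, numeric(1))
  if (any(prev < 0 | prev > 1) || any(c(m$uptake, m$compliance) < 0) ||
      any(c(m$uptake, m$compliance) > 1))
    stop("rates in the health-check cost model must lie in [0, 1]")
  follow <- sum(prev * cost)
  c(mean = base + m$uptake * m$compliance * follow,
    min = base,
    max = base + follow)
}

#' Run the deterministic scenario grid
#'
#' One deterministic model evaluation per scenario per sex, varying the
#' post-event disutility reduction `rho` (0, 0.25, 0.5, 0.75, 1), the
#' post-event cost fraction `f` (0.10, 0.15, 0.20) and the annual discount
#' rate (0.05, 0.035) one at a time around the base case.
#'
#' @param config An `hc_config` object.
#' @param scenarios Optional data frame with columns `scenario`, `rho`, `f`,
#'   `discount`; defaults to the standard grid.
#' @return Tibble with one row per scenario per sex: incremental life-years,
#'   QALYs, cost, and ICERs per life-year and per QALY.
#' @export
run_scenarios <- function(config, scenarios = NULL) {
  if (is.null(scenarios)) {
    scenarios <- tibble::tibble(
      scenario = c("base", "rho_0", "rho_0.25", "rho_0.75", "rho_1",
                   "f_0.10", "f_0.20", "discount_3.5"),
      rho = c(0.5, 0, 0.25, 0.75, 1, 0.5, 0.5, 0.5),
      f = c(0.15, 0.15, 0.15, 0.15, 0.15, 0.10, 0.20, 0.15),
      discount = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.035)
    )
  }
  if (!"base" %in% scenarios$scenario)
    stop("the scenario grid must include the base case")
  p5 <- arm_risks(config)
  base_params <- build_parameters(config)
  out <- list()
  for (i in seq_len(nrow(scenarios))) {
    params <- base_params
    params$rho <- scenarios$rho[i]
    params$post_cost_fraction <- scenarios$f[i]
    params$discount <- scenarios$discount[i]
    for (sex in c("male", "female")) {
      uc <- arm_outcome(params, sex, "usual_care", p5[[sex]]["usual_care"])
      hc <- arm_outcome(params, sex, "health_check", p5[[sex]]["health_check"])
      ic <- compute_icer(uc, hc)
      out[[length(out) + 1]] <- tibble::tibble(
        scenario = scenarios$scenario[i],
        rho = scenarios$rho[i], f = scenarios$f[i],
        discount = scenarios$discount[i], ic)
    }
  }
  do.call(rbind, out)
}
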