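#' Health states of the Markov model
#'
#' Twelve states: alive without CVD; five single-cycle tunnel states marking
#' the first event of stable angina (SA), unstable angina (UA), myocardial
#' infarction (MI), stroke and TIA; five corresponding post-event states; and
#' dead. Repeat events are not modelled: post-event occupancy can flow only to
#' itself or to death.
#'
#' @return Character vector of the 12 state identifiers, in matrix order.
#' @export
health_states <- function() {
  c("NoCVD",
    paste0("Event_", CVD_SUBTYPES),
    paste0("Post_", CVD_SUBTYPES),
    "Dead")
}

#' Convert a 5-year probability to an annual probability
#'
#' Constant-hazard actuarial conversion `1 - (1 - p5)^(1/5)`: five repeated
#' applications of the annual probability reproduce the 5-year probability.
#'
#' @param p5 Five-year event probability in \[0, 1).
#' @return Annual probability.
#' @export
annualize <- function(p5) {
  if (any(p5 < 0 | p5 >= 1)) stop("p5 must lie in [0, 1)")
  1 - (1 - p5)^(1 / 5)
}

#' Split an annual CVD probability across event subtypes
#'
#' Allocates the annual first-event probability to the five modelled
#' subtypes using the allocation shares as given. When the shares sum to 1
#' the subtype probabilities sum to `p`; the published shares sum to
#' slightly less than 1, leaving the residual share of events (subtypes
#' outside the modelled five) without a modelled transition.
#'
#' @param p Annual probability of a first CVD event of any type.
#' @param alloc Named allocation vector over `SA, UA, MI, stroke, TIA`.
#' @return Named vector of subtype probabilities.
#' @export
split_by_subtype <- function(p, alloc) {
  p * alloc[CVD_SUBTYPES]
}

subtype_probs <- function(params, sex, cycle, p5) {
  age <- params$start_age + cycle - 1
  if (cycle <= 5) {
    if (is.null(p5)) stop("cycles 1-5 need the arm-specific 5-year risk p5")
    split_by_subtype(annualize(p5), params$alloc[[sex]])
  } else {
    params$incidence[[sex]][inc_band(age), ]
  }
}

#' Build the one-cycle transition matrix
#'
#' Row-stochastic 12x12 matrix for one model cycle. The `NoCVD` row carries
#' the five subtype event probabilities (derived from the arm-specific 5-year
#' risk in cycles 1-5, and from the age-band incidence table, identical in
#' both arms, from cycle 6 onwards), the CVD-free background mortality, and
#' the staying probability as remainder. Event and post-event rows die with
#' probability `min(1, SMR x background mortality)` and otherwise move to (or
#' remain in) the post-event state. `Dead` is absorbing.
#'
#' @param params A `cea_params` object.
#' @param sex `"male"` or `"female"`.
#' @param cycle Cycle index in 1..cycles.
#' @param p5 Arm-specific 5-year CVD risk (used in cycles 1-5 only).
#' @return 12x12 matrix with dimnames [health_states()].
#' @export
build_transition_matrix <- function(params, sex, cycle, p5 = NULL) {
  stopifnot(inherits(params, "cea_params"))
  if (cycle < 1 || cycle > params$cycles) stop("cycle out of range")
  age <- params$start_age + cycle - 1
  m <- params$mortality[[sex]][mort_band(age)]
  pX <- subtype_probs(params, sex, cycle, p5)
  s <- pmin(1, m * params$smr[[sex]])
  P <- matrix(0, 12, 12, dimnames = list(health_states(), health_states()))
  P[1, 2:6] <- pX
  P[1, 12] <- m
  P[1, 1] <- 1 - m - sum(pX)
  if (P[1, 1] < 0) stop("internal consistency error: event + death probability exceeds 1")
  for (k in 1:5) {
    P[1 + k, 6 + k] <- 1 - s[k]
    P[1 + k, 12] <- s[k]
    P[6 + k, 6 + k] <- 1 - s[k]
    P[6 + k, 12] <- s[k]
  }
  P[12, 12] <- 1
  bad <- abs(rowSums(P) - 1) > 1e-12
  if (any(bad)) stop("internal consistency error: row sums differ from 1")
  P
}

propagate <- function(x0, matrices) {
  trace <- matrix(0, length(matrices), length(x0))
  x <- x0
  for (t in seq_along(matrices)) {
    x <- as.vector(x %*% matrices[[t]])
    trace[t, ] <- x
  }
  trace
}

#' Run the Markov cohort model
#'
#' Propagates the cohort occupancy vector through the per-cycle transition
#' matrices, starting from everyone alive without CVD (or a supplied initial
#' vector). Occupancy is recorded at the end of each cycle; the cohort ages
#' one year per cycle from `params$start_age`.
#'
#' @param params A `cea_params` object.
#' @param sex `"male"` or `"female"`.
#' @param p5 Arm-specific 5-year CVD risk applied in cycles 1-5.
#' @param init Initial occupancy probability vector (length 12, sums to 1).
#' @return A `state_trace`: cycles x 12 occupancy matrix with attributes
#'   `ages` (cohort age in each cycle) and `sex`.
#' @export
run_cohort <- function(params, sex, p5, init = NULL) {
  stopifnot(inherits(params, "cea_params"))
  if (is.null(init)) init <- c(1, rep(0, 11))
  if (length(init) != 12 || any(init < 0) || abs(sum(init) - 1) > 1e-9)
    stop("init must be a probability vector over the 12 states")
  mats <- lapply(seq_len(params$cycles), function(t)
    build_transition_matrix(params, sex, t, p5))
  trace <- propagate(init, mats)
  colnames(trace) <- health_states()
  structure(trace,
            ages = params$start_age + seq_len(params$cycles) - 1,
            sex = sex, class = c("state_trace", "matrix"))
}

check_trace <- function(trace) {
  if (!inherits(trace, "state_trace")) stop("expected a state_trace")
  if (any(abs(rowSums(trace) - 1) > 1e-9))
    stop("trace occupancy is not conserved")
  invisible(trace)
}

#' Discounted life-years of a trace
#'
#' Sums the alive occupancy per cycle, discounted by `(1 + rate)^-cycle`.
#' The package reports life-years undiscounted by default (`rate = 0`), with
#' QALYs and costs discounted; see the vignette for the reporting convention.
#'
#' @param trace A `state_trace` from [run_cohort()].
#' @param discount Annual discount rate (default 0).
#' @return Total (discounted) life-years per cohort member.
#' @export
life_years <- function(trace, discount = 0) {
  check_trace(trace)
  alive <- 1 - trace[, "Dead"]
  sum(alive * (1 + discount)^(-seq_len(nrow(trace))))
}

state_utilities <- function(params, sex, age) {
  pu <- params$pop_utility[[sex]][util_band(age)]
  acute <- params$acute_utility
  dec <- 1 - acute # decrement of the acute event year, measured from full health
  post <- pu * (1 - (1 - params$rho) * dec)
  c(NoCVD = unname(pu), stats::setNames(acute, paste0("Event_", CVD_SUBTYPES)),
    stats::setNames(post, paste0("Post_", CVD_SUBTYPES)), Dead = 0)
}

#' Discounted quality-adjusted life-years of a trace
#'
#' Per cycle, occupancy is weighted by state utility and discounted by
#' `(1 + rate)^-cycle`. `NoCVD` carries the age-band population utility; the
#' single-cycle event states carry the absolute acute-event utility weights;
#' post-event states carry the population utility reduced by the retained
#' share `1 - rho` of the acute disutility `1 - u_acute`, applied
#' multiplicatively. TIA has acute utility 1 and therefore contributes no
#' decrement in either its event or post-event state.
#'
#' @param trace A `state_trace`.
#' @param params A `cea_params` object (supplies utilities and `rho`).
#' @param discount Annual discount rate; defaults to `params$discount`.
#' @return Total discounted QALYs per cohort member.
#' @export
qalys <- function(trace, params, discount = params$discount) {
  check_trace(trace)
  sex <- attr(trace, "sex")
  ages <- attr(trace, "ages")
  total <- 0
  for (t in seq_len(nrow(trace))) {
    u <- state_utilities(params, sex, ages[t])
    total <- total + sum(trace[t, ] * u) * (1 + discount)^(-t)
  }
  total
}
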