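CVD_SUBTYPES <- c("SA", "UA", "MI", "stroke", "TIA")
MORT_BANDS <- c("45-54", "55-64", "65-74", "75-84", "85-94")
INC_BANDS <- c("50-54", "55-64", "65-74", "75-84", "85-94")
UTIL_BANDS <- c("40-49", "50-59", "60-69", "70-79", "80+")

validate_config <- function(cfg) {
  need <- c("settings", "effects", "distributions", "allocation", "incidence",
            "mortality", "smr", "utilities", "costs", "health_check_model", "psa")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config schema error: missing top-level block(s): ",
         paste(miss, collapse = ", "))
  for (sex in c("male", "female")) {
    if (is.null(cfg$distributions[[sex]]))
      stop("config schema error at distributions$", sex, ": missing sex")
    if (is.null(cfg$allocation[[sex]]))
      stop("config schema error at allocation$", sex, ": missing sex")
    a <- unlist(cfg$allocation[[sex]])
    if (length(setdiff(CVD_SUBTYPES, names(a))) > 0)
      stop("config schema error at allocation$", sex, ": need all five subtypes")
    if (abs(sum(a) - 1) > 0.1)
      stop("config schema error at allocation$", sex,
           ": subtype proportions sum to ", sum(a))
    for (band in INC_BANDS)
      if (is.null(cfg$incidence[[sex]][[band]]))
        stop("config schema error at incidence$", sex, "$`", band, "`")
    for (band in MORT_BANDS)
      if (is.null(cfg$mortality[[sex]][[band]]))
        stop("config schema error at mortality$", sex, "$`", band, "`")
  }
  for (st in CVD_SUBTYPES)
    if (is.null(cfg$smr[[st]]))
      stop("config schema error at smr$", st)
  invisible(cfg)
}

#' Assemble Markov model parameters from a configuration
#'
#' Collects every transition, mortality, utility and cost input into a flat
#' parameter object consumed by the Markov engine and the costing functions.
#' Event allocations are normalized to sum to one on load; SMR-multiplied
#' mortality is capped at 1 at evaluation time.
#'
#' @param config An `hc_config` object from [load_config()].
#' @return A `cea_params` object: list with elements `alloc`, `incidence`,
#'   `mortality`, `smr`, `pop_utility`, `acute_utility`, `rho`,
#'   `acute_cost`, `post_cost_fraction`, `check_cost`, `discount`,
#'   `ly_discount`, `cycles`, `start_age`.
#' @export
build_parameters <- function(config) {
  stopifnot(inherits(config, "hc_config"))
  s <- config$settings
  mat_bands <- function(block, bands) {
    m <- do.call(rbind, lapply(bands, function(b) unlist(block[[b]])[CVD_SUBTYPES]))
    rownames(m) <- bands
    colnames(m) <- CVD_SUBTYPES
    m
  }
  per_sex <- function(f) {
    out <- lapply(c("male", "female"), f)
    names(out) <- c("male", "female")
    out
  }
  # Subtype shares are applied as given: the published shares sum to slightly
  # less than 1 (events outside the five modelled subtypes produce no modelled
  # event). Set settings$normalize_allocation: true to rescale them to 1.
  alloc <- per_sex(function(sex) {
    a <- unlist(config$allocation[[sex]])[CVD_SUBTYPES]
    if (isTRUE(s$normalize_allocation)) a <- a / sum(a)
    a
  })
  incidence <- per_sex(function(sex) mat_bands(config$incidence[[sex]], INC_BANDS))
  mortality <- per_sex(function(sex) {
    m <- unlist(config$mortality[[sex]])[MORT_BANDS]
    names(m) <- MORT_BANDS
    m
  })
  smr <- per_sex(function(sex) {
    v <- vapply(CVD_SUBTYPES, function(st) {
      x <- config$smr[[st]]
      if (!is.null(x$mean)) x$mean else x[[sex]]$mean
    }, numeric(1))
    names(v) <- CVD_SUBTYPES
    v
  })
  pop_utility <- per_sex(function(sex) {
    u <- vapply(UTIL_BANDS, function(b) config$utilities$population[[sex]][[b]]$mean,
                numeric(1))
    names(u) <- UTIL_BANDS
    u
  })
  acute_utility <- vapply(CVD_SUBTYPES,
                          function(st) config$utilities$acute[[st]]$mean, numeric(1))
  check_cost <- per_sex(function(sex) unlist(config$costs$health_check[[sex]]))
  structure(list(
    alloc = alloc,
    incidence = incidence,
    mortality = mortality,
    smr = smr,
    pop_utility = pop_utility,
    acute_utility = acute_utility,
    rho = config$utilities$post_event_disutility_reduction %||% 0.5,
    acute_cost = vapply(CVD_SUBTYPES, function(st) config$costs$acute[[st]],
                        numeric(1)),
    post_cost_fraction = config$costs$post_event_cost_fraction %||% 0.15,
    check_cost = check_cost,
    discount = s$discount_rate %||% 0.05,
    ly_discount = s$ly_discount_rate %||% 0,
    cycles = as.integer(s$cycles %||% 50L),
    start_age = s$start_age %||% 45
  ), class = "cea_params")
}

# age-band lookups; ages past the last band reuse it
mort_band <- function(age) {
  MORT_BANDS[pmin(findInterval(age, c(0, 55, 65, 75, 85)), 5)]
}
inc_band <- function(age) {
  INC_BANDS[pmin(findInterval(age, c(0, 55, 65, 75, 85)), 5)]
}
util_band <- function(age) {
  UTIL_BANDS[pmin(findInterval(age, c(0, 50, 60, 70, 80)), 5)]
}

#' Derive a child seed from a master seed
#'
#' Deterministic seed splitting so that each module (cohort sampling,
#' repetition streams, PSA draws) consumes an independent stream while the
#' whole pipeline is reproducible from one master seed. Uses a Lehmer-style
#' step modulo the Mersenne prime 2^31 - 1, so child seeds stay valid R
#' integer seeds.
#'
#' @param master Master integer seed.
#' @param stream Stream index (>= 0).
#' @return A positive integer seed.
#' @export
split_seed <- function(master, stream) {
  m <- 2147483647
  x <- (as.numeric(master) %% m) * 48271 + as.numeric(stream) * 69621 + 1
  as.integer(x %% m)
}
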