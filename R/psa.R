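#' Build a sampler for one parameter prior
#'
#' Supported families, parameterized as the input tables print them:
#' * `lognormal` — mean and 95% CI; the log-scale SD is the CI half-width on
#'   the log scale divided by 1.96, and the location is set so the sampler
#'   mean equals the printed mean.
#' * `beta` — mean and SE, shape parameters by moment matching; an SE of zero
#'   gives a degenerate sampler at the mean.
#' * `uniform` — explicit `min`/`max` bounds, or `mean` with a `fraction`
#'   giving symmetric +/- bounds.
#'
#' @param prior List with `family` and family-appropriate fields (`mean`,
#'   `ci`, `se`, `min`, `max`, `fraction`).
#' @return List with `q` (quantile function) and `r` (random generator).
#' @export
fit_prior <- function(prior) {
  fam <- prior$family
  if (fam == "lognormal") {
    if (is.null(prior$ci)) stop("lognormal prior needs a 95% CI")
    sdlog <- (log(prior$ci[[2]]) - log(prior$ci[[1]])) / (2 * 1.96)
    meanlog <- log(prior$mean) - sdlog^2 / 2
    q <- function(p) stats::qlnorm(p, meanlog, sdlog)
  } else if (fam == "beta") {
    m <- prior$mean
    se <- prior$se %||% 0
    if (se == 0) {
      q <- function(p) rep(m, length(p))
    } else {
      if (se^2 >= m * (1 - m))
        stop("beta prior fit error: SE implies variance >= mean(1-mean)")
      nu <- m * (1 - m) / se^2 - 1
      q <- function(p) stats::qbeta(p, m * nu, (1 - m) * nu)
    }
  } else if (fam == "uniform") {
    if (!is.null(prior$min)) {
      lo <- prior$min; hi <- prior$max
    } else {
      fr <- prior$fraction %||% 0.25
      lo <- prior$mean * (1 - fr); hi <- prior$mean * (1 + fr)
    }
    q <- function(p) stats::qunif(p, lo, hi)
  } else {
    stop("unknown prior family: ", fam)
  }
  list(q = q, r = function(n) q(stats::runif(n)))
}

smr_prior <- function(config, st, sex) {
  x <- config$smr[[st]]
  if (is.null(x$mean)) x <- x[[sex]]
  fit_prior(list(family = "lognormal", mean = x$mean, ci = x$ci))
}

# One joint parameter draw: returns modified params and per-arm p5, given a
# named vector of uniform quantiles (shared across sexes for sex-common
# parameters; arm incidences share a quantile when psa$arm_correlation is
# "shared").
psa_draw <- function(config, base_params, u) {
  params <- base_params
  fr <- config$psa$default_uniform_fraction %||% 0.25
  unif <- function(mean, p) {
    y <- stats::qunif(p, mean * (1 - fr), mean * (1 + fr))
    names(y) <- names(mean)
    y
  }
  for (sex in c("male", "female")) {
    for (st in CVD_SUBTYPES)
      params$smr[[sex]][st] <- smr_prior(config, st, sex)$q(u[[paste0("smr_", st, "_", sex)]])
    a <- params$alloc[[sex]]
    a2 <- unif(a, u[paste0("alloc_", CVD_SUBTYPES, "_", sex)])
    params$alloc[[sex]] <- a2 / sum(a2) * sum(a) # perturb shares, keep total
    inc <- params$incidence[[sex]]
    for (b in rownames(inc))
      inc[b, ] <- unif(inc[b, ], u[[paste0("inc_", b, "_", sex)]])
    params$incidence[[sex]] <- inc
    mrt <- params$mortality[[sex]]
    params$mortality[[sex]] <- unif(mrt, u[[paste0("mort_", sex)]])
    pu <- config$utilities$population[[sex]]
    params$pop_utility[[sex]] <- vapply(UTIL_BANDS, function(b)
      fit_prior(list(family = "beta", mean = pu[[b]]$mean, se = pu[[b]]$se))$q(
        u[[paste0("popu_", b, "_", sex)]]), numeric(1))
    ck <- config$costs$health_check[[sex]]
    params$check_cost[[sex]]["mean"] <-
      stats::qunif(u[[paste0("check_", sex)]], ck$min, ck$max)
  }
  for (st in CVD_SUBTYPES) {
    au <- config$utilities$acute[[st]]
    params$acute_utility[st] <- fit_prior(list(family = "beta", mean = au$mean,
                                               se = au$se %||% 0))$q(u[[paste0("au_", st)]])
    params$acute_cost[st] <- unif(config$costs$acute[[st]], u[[paste0("cost_", st)]])
  }
  shared <- identical(config$psa$arm_correlation %||% "shared", "shared")
  p5 <- lapply(c("male", "female"), function(sex) {
    iv <- config$psa$incidence_intervals[[sex]]
    qa <- u[[paste0("p5_uc_", sex)]]
    qb <- if (shared) qa else u[[paste0("p5_hc_", sex)]]
    c(usual_care = stats::qunif(qa, iv$usual_care[[1]], iv$usual_care[[2]]),
      health_check = stats::qunif(qb, iv$health_check[[1]], iv$health_check[[2]]))
  })
  names(p5) <- c("male", "female")
  list(params = params, p5 = p5)
}

psa_quantile_names <- function() {
  sexes <- c("male", "female")
  c(outer_names("smr_", CVD_SUBTYPES, sexes),
    outer_names("alloc_", CVD_SUBTYPES, sexes),
    outer_names("inc_", INC_BANDS, sexes),
    paste0("mort_", sexes),
    outer_names("popu_", UTIL_BANDS, sexes),
    paste0("check_", sexes),
    paste0("au_", CVD_SUBTYPES),
    paste0("cost_", CVD_SUBTYPES),
    paste0("p5_uc_", sexes),
    paste0("p5_hc_", sexes))
}

outer_names <- function(prefix, a, b) {
  as.vector(t(outer(a, b, function(x, y) paste0(prefix, x, "_", y))))
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_draws` joint parameter samples from the configured priors
#' (lognormal SMRs, beta utilities, uniform costs, allocations, incidences
#' and mortalities, and arm-level 5-year risks sampled uniformly within
#' their credibility intervals, with a shared quantile across arms by
#' default), runs the full Markov and costing model per draw for both sexes
#' and arms, and records the incremental cost and effect of each draw.
#' Reproducible: the draw matrix is generated in one block from the master
#' seed.
#'
#' @param config An `hc_config` object.
#' @param n_draws Number of joint draws (>= 1; the study design uses 1,000).
#' @param seed Master integer seed.
#' @return Tibble with one row per draw per sex: `draw`, `sex`, `d_ly`,
#'   `d_qaly`, `d_cost`, `icer_qaly`.
#' @export
run_psa <- function(config, n_draws = 1000, seed = 1L) {
  stopifnot(inherits(config, "hc_config"))
  if (n_draws < 1) stop("n_draws must be at least 1")
  base_params <- build_parameters(config)
  nms <- psa_quantile_names()
  set.seed(as.integer(seed))
  U <- matrix(stats::runif(n_draws * length(nms)), n_draws, length(nms),
              dimnames = list(NULL, nms))
  out <- vector("list", 2L * n_draws)
  k <- 0L
  for (i in seq_len(n_draws)) {
    dr <- psa_draw(config, base_params, U[i, ])
    for (sex in c("male", "female")) {
      uc <- arm_outcome(dr$params, sex, "usual_care", dr$p5[[sex]][["usual_care"]])
      hc <- arm_outcome(dr$params, sex, "health_check", dr$p5[[sex]][["health_check"]])
      ic <- compute_icer(uc, hc)
      k <- k + 1L
      out[[k]] <- tibble::tibble(draw = i, sex = sex, d_ly = ic$d_ly,
                                 d_qaly = ic$d_qaly, d_cost = ic$d_cost,
                                 icer_qaly = ic$icer_qaly)
    }
  }
  do.call(rbind, out)
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the probability of
#' cost-effectiveness is the fraction of PSA draws with non-negative net
#' monetary benefit (threshold x incremental QALYs - incremental cost).
#'
#' @param draws PSA draws from [run_psa()] (optionally pre-filtered by sex).
#' @param thresholds Willingness-to-pay grid (AUD/QALY); the default spans
#'   $0-$150,000 in $1,000 steps and always includes $28,000 and $50,000.
#' @return Tibble: `sex`, `threshold`, `probability`.
#' @export
ceac <- function(draws, thresholds = ceac_thresholds()) {
  if (nrow(draws) == 0) stop("no PSA draws supplied")
  out <- list()
  for (sex in unique(draws$sex)) {
    d <- draws[draws$sex == sex, ]
    prob <- vapply(thresholds, function(l) mean(l * d$d_qaly - d$d_cost >= 0),
                   numeric(1))
    out[[sex]] <- tibble::tibble(sex = sex, threshold = thresholds,
                                 probability = prob)
  }
  do.call(rbind, out)
}

#' @rdname ceac
#' @export
ceac_thresholds <- function() {
  sort(unique(c(seq(0, 150000, by = 1000), 28000, 50000)))
}

#' Plot the cost-effectiveness plane or acceptability curve
#'
#' Convenience ggplot2 wrappers over the machine-readable PSA outputs.
#'
#' @param draws PSA draws from [run_psa()].
#' @param curve CEAC tibble from [ceac()].
#' @return A ggplot object.
#' @export
plot_cep <- function(draws) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(draws, ggplot2::aes(x = .data$d_qaly, y = .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (AUD)")
}

#' @rdname plot_cep
#' @export
plot_ceac <- function(curve) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$threshold, y = .data$probability,
                                      colour = .data$sex)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (AUD/QALY)",
                  y = "Probability cost-effective")
}
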