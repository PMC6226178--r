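#' Run the deterministic base case
#'
#' The full deterministic pipeline for both sexes: arm-level 5-year CVD
#' incidences ([arm_risks()], computed from the risk-factor distributions
#' unless overridden in the configuration), 50-cycle Markov cohort runs per
#' arm, discounted costs and QALYs, undiscounted life-years, and ICERs per
#' life-year and per QALY. Deterministic given the configuration.
#'
#' @param config An `hc_config` object (or a path to a YAML configuration).
#' @return List with `outcomes` (one row per sex per arm), `icers` (one row
#'   per sex, unrounded), `incidence` (the arm-level 5-year risks used), and
#'   `table` (display rounding: life-years and QALYs to 3 decimals, currency
#'   to whole dollars).
#' @export
run_base_case <- function(config = load_config()) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "hc_config"))
  params <- build_parameters(config)
  p5 <- arm_risks(config)
  outcomes <- list()
  icers <- list()
  for (sex in c("male", "female")) {
    uc <- arm_outcome(params, sex, "usual_care", p5[[sex]][["usual_care"]])
    hc <- arm_outcome(params, sex, "health_check", p5[[sex]][["health_check"]])
    outcomes[[length(outcomes) + 1]] <- rbind(uc, hc)
    icers[[sex]] <- compute_icer(uc, hc)
  }
  outcomes <- do.call(rbind, outcomes)
  icers <- do.call(rbind, icers)
  table <- icers
  table$d_ly <- round(table$d_ly, 3)
  table$d_qaly <- round(table$d_qaly, 3)
  table$d_cost <- round(table$d_cost)
  table$icer_ly <- round(table$icer_ly)
  table$icer_qaly <- round(table$icer_qaly)
  list(outcomes = outcomes, icers = icers, incidence = p5, table = table)
}

#' Validate modelled incidence against a reference table
#'
#' Side-by-side informational comparison of modelled annual subtype
#' incidences with a user-supplied national reference table (sex x subtype
#' with 95% CIs). Rows are flagged `"within"` or `"outside"` the reference
#' interval; no pass/fail exit status is implied.
#'
#' @param model Data frame with columns `sex`, `subtype`, `incidence`.
#' @param reference Data frame with columns `sex`, `subtype`, `incidence`,
#'   `ci_lower`, `ci_upper`.
#' @return Tibble joining both with a `flag` column.
#' @export
validate_incidence <- function(model, reference) {
  need_m <- c("sex", "subtype", "incidence")
  need_r <- c(need_m, "ci_lower", "ci_upper")
  if (!is.data.frame(reference) || nrow(reference) == 0 ||
      length(setdiff(need_r, names(reference))) > 0)
    stop("reference schema error: need non-empty columns ",
         paste(need_r, collapse = ", "))
  if (!is.data.frame(model) || length(setdiff(need_m, names(model))) > 0)
    stop("model table schema error: need columns ", paste(need_m, collapse = ", "))
  merged <- merge(model, reference, by = c("sex", "subtype"),
                  suffixes = c("_model", "_reference"))
  merged$flag <- ifelse(merged$incidence_model >= merged$ci_lower &
                          merged$incidence_model <= merged$ci_upper,
                        "within", "outside")
  tibble::as_tibble(merged)
}

#' Modelled first-cycle annual incidence by subtype
#'
#' Annual subtype incidences implied by the usual-care arm in the first model
#' cycle, in the shape consumed by [validate_incidence()].
#'
#' @param config An `hc_config` object.
#' @return Tibble with columns `sex`, `subtype`, `incidence`.
#' @export
model_incidence_table <- function(config) {
  params <- build_parameters(config)
  p5 <- arm_risks(config)
  out <- list()
  for (sex in c("male", "female")) {
    p <- split_by_subtype(annualize(p5[[sex]][["usual_care"]]),
                          params$alloc[[sex]])
    out[[sex]] <- tibble::tibble(sex = sex, subtype = CVD_SUBTYPES,
                                 incidence = unname(p))
  }
  do.call(rbind, out)
}

config_digest <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(strip_dists(config)), auto_unbox = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

strip_dists <- function(config) {
  config$distributions <- lapply(config$distributions, function(d)
    lapply(d$factors, function(b) as.data.frame(b)))
  config
}

#' Run the whole pipeline and write its outputs
#'
#' End-to-end orchestration: base case, scenario grid, incidence simulation
#' summary, PSA draws and CEAC, written as CSV files plus a JSON run manifest
#' recording the configuration digest, master seed, package version and
#' output inventory. Identical configuration and seed produce byte-identical
#' CSVs.
#'
#' @param config An `hc_config` object or path.
#' @param outdir Output directory (created if missing).
#' @param seed Master integer seed fanned out to the simulation and PSA
#'   streams via [split_seed()].
#' @param n,reps Cohort size and repetitions for the incidence simulation.
#' @param n_draws PSA draws.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = load_config(), outdir, seed = 1L,
                         n = 5000, reps = 200, n_draws = 1000) {
  if (is.character(config)) config <- load_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  base <- run_base_case(config)
  scen <- run_scenarios(config)
  sims <- do.call(rbind, lapply(c("male", "female"), function(sex) {
    s <- simulate_arms(config, sex, n = n, reps = reps,
                       seed = split_seed(seed, 1L))
    cbind(s$estimates, rr_mean = s$rr$mean)
  }))
  draws <- run_psa(config, n_draws = n_draws, seed = split_seed(seed, 2L))
  curve <- ceac(draws)
  files <- c(base_case = "base_case.csv", scenarios = "scenarios.csv",
             incidence = "incidence_simulation.csv", cep = "psa_cep.csv",
             ceac = "ceac.csv")
  utils::write.csv(base$icers, file.path(outdir, files["base_case"]), row.names = FALSE)
  utils::write.csv(scen, file.path(outdir, files["scenarios"]), row.names = FALSE)
  utils::write.csv(sims, file.path(outdir, files["incidence"]), row.names = FALSE)
  utils::write.csv(draws, file.path(outdir, files["cep"]), row.names = FALSE)
  utils::write.csv(curve, file.path(outdir, files["ceac"]), row.names = FALSE)
  manifest <- list(
    config_digest = config_digest(config),
    master_seed = as.integer(seed),
    package_version = as.character(utils::packageVersion("checkup45")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    outputs = as.list(unname(files))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
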