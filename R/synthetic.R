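DISEASES <- c("knee_oa", "hip_oa", "low_back_pain", "shoulder_pain",
              "fibromyalgia", "all_mskd")

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Reference parameter table for chronic musculoskeletal pain in Chile
#'
#' The package's bundled parameter set: per-disease, per-severity prevalence
#' of chronic pain in the adult population, monthly severity transition
#' probabilities and death probability, monthly treatment costs of the
#' severity health baskets and of depression/anxiety, pain-attributable
#' fractions, disutilities, and per-leave work-loss summaries, each with its
#' published mean, standard error and distribution family.
#'
#' Transcription choices (see the methods vignette for rationale): the
#' lower-back-pain "very severe" prevalence stratum is merged into severe
#' (means summed, SEs combined root-sum-of-squares) because the model has
#' three alive severity states; shoulder pain's combined moderate/severe
#' prevalence is carried under moderate (severe starts at 0 and is populated
#' by transitions) and its combined disutility applies to both states;
#' fibromyalgia has no mild prevalence (fixed 0) but keeps its mild cost and
#' a zero mild disutility, the mild state being reachable via transitions.
#' Transition probabilities are fixed point estimates (the elicitation data
#' behind them are not published). `adult_population` is an assumption
#' (15,000,000 adults, approximately Chile) — the published table does not
#' state it — and per-disease annual sick-leave counts are back-calculated
#' from reported subsidy totals and per-leave costs.
#'
#' @return A validated [parameter_table()] covering `knee_oa`, `hip_oa`,
#'   `low_back_pain`, `shoulder_pain`, `fibromyalgia` and the catch-all
#'   `all_mskd`.
#' @examples
#' pars <- fixture_parameter_table()
#' pars$transition[["moderate_mild"]]  # 0.5555
#' @export
fixture_parameter_table <- function() {
  beta <- function(m, s) dist_spec("beta", m, s)
  gam <- function(m, s) dist_spec("gamma", m, s)
  lnorm <- function(m, s) dist_spec("lognormal", m, s)
  fixed <- function(m) dist_spec("fixed", m)

  prevalence <- list(
    knee_oa = list(mild = beta(0.0301, 0.0045),
                   moderate = beta(0.0032, 0.0011),
                   severe = beta(0.0022, 0.0009)),
    hip_oa = list(mild = beta(0.0180, 0.0025),
                  moderate = beta(0.0010, 0.0005),
                  severe = beta(0.0017, 0.0008)),
    low_back_pain = list(
      mild = beta(0.0061, 0.0031),
      moderate = beta(0.0342, 0.0064),
      # severe + very-severe strata merged: 1.79% + 1.00%, SEs in quadrature
      severe = beta(0.0179 + 0.0100, sqrt(0.0039^2 + 0.0025^2))),
    shoulder_pain = list(mild = beta(0.0008, 0.0003),
                         moderate = beta(0.0289, 0.0043),  # moderate/severe
                         severe = fixed(0)),
    fibromyalgia = list(mild = fixed(0),
                        moderate = beta(0.0137, 0.0036),
                        severe = beta(0.0341, 0.0041)),
    all_mskd = list(mild = beta(0.0098, 0.0050),
                    moderate = beta(0.0990, 0.0819),
                    severe = beta(0.1155, 0.0998)))

  state_cost <- list(
    knee_oa = list(mild = gam(8.50, 8.33), moderate = gam(15.07, 14.77),
                   severe = gam(61.29, 60.07)),
    hip_oa = list(mild = gam(8.60, 8.43), moderate = gam(15.07, 14.77),
                  severe = gam(61.29, 60.07)),
    low_back_pain = list(mild = gam(6.97, 6.83), moderate = gam(13.75, 13.48),
                         severe = gam(54.22, 53.13)),
    shoulder_pain = list(mild = gam(8.65, 8.48), moderate = gam(15.56, 15.25),
                         severe = gam(51.76, 50.72)),
    fibromyalgia = list(mild = gam(6.97, 6.83), moderate = gam(9.70, 9.51),
                        severe = gam(83.26, 81.60)),
    all_mskd = list(mild = gam(7.94, 7.78), moderate = gam(13.83, 13.56),
                    severe = gam(62.37, 61.12)))

  disutility <- list(
    knee_oa = list(mild = beta(0.023, 0.0122), moderate = beta(0.079, 0.0286),
                   severe = beta(0.165, 0.0612)),
    hip_oa = list(mild = beta(0.023, 0.0122), moderate = beta(0.079, 0.0286),
                  severe = beta(0.165, 0.0612)),
    low_back_pain = list(mild = beta(0.020, 0.0122),
                         moderate = beta(0.054, 0.0224),
                         severe = beta(0.322, 0.1140)),
    shoulder_pain = list(mild = beta(0.028, 0.0143),
                         moderate = beta(0.117, 0.0423),  # combined estimate
                         severe = beta(0.117, 0.0423)),
    fibromyalgia = list(mild = fixed(0), moderate = beta(0.317, 0.1143),
                        severe = beta(0.518, 0.1714)),
    all_mskd = list(mild = beta(0.020, 0.0122), moderate = beta(0.054, 0.0224),
                    severe = beta(0.272, 0.0974)))

  workloss <- list(
    knee_oa = list(productivity_cost_per_leave = lnorm(617.17, 3.42),
                   subsidy_cost_per_leave = lnorm(518.66, 3.33),
                   days_per_leave = lnorm(19.41, 0.09)),
    hip_oa = list(productivity_cost_per_leave = lnorm(793.94, 5.43),
                  subsidy_cost_per_leave = lnorm(725.79, 5.62),
                  days_per_leave = lnorm(27.12, 0.15)),
    low_back_pain = list(productivity_cost_per_leave = lnorm(265.69, 0.42),
                         subsidy_cost_per_leave = lnorm(183.03, 0.40),
                         days_per_leave = lnorm(8.51, 0.01)),
    shoulder_pain = list(productivity_cost_per_leave = lnorm(527.89, 3.97),
                         subsidy_cost_per_leave = lnorm(403.75, 3.66),
                         days_per_leave = lnorm(15.31, 0.10)),
    fibromyalgia = list(productivity_cost_per_leave = lnorm(468.02, 3.49),
                        subsidy_cost_per_leave = lnorm(371.61, 3.27),
                        days_per_leave = lnorm(10.40, 0.11)),
    all_mskd = list(productivity_cost_per_leave = lnorm(312.42, 0.50),
                    subsidy_cost_per_leave = lnorm(225.84, 0.48),
                    days_per_leave = lnorm(9.94, 0.01)))

  parameter_table(
    diseases = DISEASES,
    prevalence = prevalence,
    transition = c(mild_moderate = 0.1841, mild_severe = 0.1070,
                   moderate_mild = 0.5555, moderate_severe = 0.2738,
                   severe_mild = 0.3315, severe_moderate = 0.5914),
    death_prob = beta(0.0004, 0.0001),
    state_cost = state_cost,
    depression_cost = gam(26.20, 25.68),
    anxiety_cost = gam(14.55, 14.26),
    depression_paf = list(knee_oa = beta(0.0054, 0.0035),
                          hip_oa = beta(0.0048, 0.0026),
                          low_back_pain = beta(0.0064, 0.0035),
                          shoulder_pain = beta(0.0129, 0.0090),
                          fibromyalgia = beta(0.1315, 0.0366),
                          all_mskd = beta(0.1692, 0.0330)),
    anxiety_paf = beta(0.0530, 0.0135),
    disutility = disutility,
    workloss = workloss,
    initial_split = c(0.075, 0.325, 0.60),
    adult_population = 15e6,
    cycles = 12,
    # annual leave counts: low_back_pain as reported; others back-calculated
    # from reported annual subsidy totals / per-leave subsidy cost
    n_leaves = c(knee_oa = 16883, hip_oa = 7165, low_back_pain = 273297,
                 shoulder_pain = 10923, fibromyalgia = 8396))
}

#' Generate a synthetic record-level sick-leave dataset
#'
#' Emulates insurer sick-leave databases (which are not publicly
#' deposited): per disease, leave durations are drawn from a lognormal
#' fitted by moments to the configured expected days (with a -0.5
#' continuity correction so that the ceiling to whole days recovers the
#' target mean) and record-level standard deviation; daily wages are drawn
#' from an independent lognormal. Insurer membership is sampled
#' public/private (public share 0.78, roughly the public insurer's
#' population coverage); public records carry a FONASA income category A-D,
#' private records the category `"private"`. Drawn wages are stored on every
#' record, i.e. the dataset arrives with wages already resolved.
#'
#' @param config Data frame with one row per disease: columns `disease`,
#'   `expected_days` (> 0.5), `expected_daily_wage`, `n_records` (>= 1) and
#'   optionally `days_sd`, `wage_sd` (record-level standard deviations;
#'   defaults: coefficient of variation 1.0 for durations, 0.8 for wages).
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param public_share Probability that a record belongs to the public
#'   insurer.
#' @return A [sick_leave_records()] data frame with
#'   `sum(config$n_records)` rows.
#' @export
generate_sick_leave_dataset <- function(config, seed, public_share = 0.78) {
  stopifnot(is.data.frame(config),
            all(c("disease", "expected_days", "expected_daily_wage",
                  "n_records") %in% names(config)))
  if (any(config$n_records < 1))
    stop("generate_sick_leave_dataset: n_records must be >= 1 per disease")
  if (any(config$expected_days <= 0.5))
    stop("generate_sick_leave_dataset: expected_days must exceed 0.5 ",
         "(continuity correction)")
  if (any(config$expected_daily_wage <= 0))
    stop("generate_sick_leave_dataset: expected_daily_wage must be positive")
  if (is.null(config$days_sd)) config$days_sd <- NA_real_
  if (is.null(config$wage_sd)) config$wage_sd <- NA_real_
  config$days_sd[is.na(config$days_sd)] <-
    1.0 * config$expected_days[is.na(config$days_sd)]
  config$wage_sd[is.na(config$wage_sd)] <-
    0.8 * config$expected_daily_wage[is.na(config$wage_sd)]

  with_seed(seed, {
    parts <- lapply(seq_len(nrow(config)), function(i) {
      n <- as.integer(config$n_records[i])
      dp <- fit_lognormal_moments(config$expected_days[i] - 0.5,
                                  config$days_sd[i])
      wp <- fit_lognormal_moments(config$expected_daily_wage[i],
                                  config$wage_sd[i])
      duration <- pmax(1L, as.integer(ceiling(
        stats::rlnorm(n, dp[["mu"]], dp[["sigma"]]))))
      wage <- stats::rlnorm(n, wp[["mu"]], wp[["sigma"]])
      insurer <- ifelse(stats::runif(n) < public_share, "public", "private")
      category <- ifelse(insurer == "private", "private",
                         sample(c("A", "B", "C", "D"), n, replace = TRUE,
                                prob = c(0.30, 0.30, 0.25, 0.15)))
      sick_leave_records(config$disease[i], insurer, category, duration, wage)
    })
    out <- do.call(rbind, parts)
    class(out) <- c("sick_leave_records", "data.frame")
    out
  })
}

# synthetic FONASA category daily wages, USD/day (A poorest); the real
# category averages are estimated from household-survey microdata that is
# out of scope here
DEFAULT_WAGE_TABLE <- c(A = 10, B = 15, C = 22, D = 32)

#' Generate a self-contained test scenario
#'
#' Bundles a parameter table, a synthetic sick-leave dataset and a wage
#' table so every pipeline stage can run without external data.
#' `"tiny"` covers two diseases with 100 records and a small population, for
#' fast end-to-end smoke runs; `"national"` carries the full
#' [fixture_parameter_table()] with 10,000 records allocated to diseases
#' proportionally to their annual leave counts, duration/wage targets taken
#' from the per-leave work-loss summaries.
#'
#' @param name `"tiny"` or `"national"`.
#' @param seed Integer seed for the record generator.
#' @return List of class `"pain_scenario"` with elements `name`, `seed`,
#'   `parameters` (a [parameter_table()]), `records`
#'   (a [sick_leave_records()] data frame) and `wage_table`.
#' @export
generate_scenario <- function(name = c("tiny", "national"), seed = 1L) {
  name <- match.arg(name)
  full <- fixture_parameter_table()
  if (name == "tiny") {
    keep <- c("low_back_pain", "knee_oa")
    pars <- parameter_table(
      diseases = keep,
      prevalence = full$prevalence[keep],
      transition = full$transition,
      death_prob = full$death_prob,
      state_cost = full$state_cost[keep],
      depression_cost = full$depression_cost,
      anxiety_cost = full$anxiety_cost,
      depression_paf = full$depression_paf[keep],
      anxiety_paf = full$anxiety_paf,
      disutility = full$disutility[keep],
      workloss = full$workloss[keep],
      initial_split = full$initial_split,
      adult_population = 1e5,
      cycles = 12,
      n_leaves = full$n_leaves[keep])
    n_rec <- c(low_back_pain = 50L, knee_oa = 50L)
  } else {
    pars <- full
    share <- full$n_leaves / sum(full$n_leaves)
    n_rec <- round(1e4 * share)
    n_rec[n_rec < 1] <- 1
  }
  config <- do.call(rbind, lapply(names(n_rec), function(d) {
    wl <- pars$workloss[[d]]
    days <- wl$days_per_leave$mean
    data.frame(disease = d, expected_days = days,
               expected_daily_wage = wl$productivity_cost_per_leave$mean /
                 days,
               n_records = n_rec[[d]])
  }))
  records <- generate_sick_leave_dataset(config, seed)
  structure(list(name = name, seed = as.integer(seed), parameters = pars,
                 records = records, wage_table = DEFAULT_WAGE_TABLE),
            class = "pain_scenario")
}

#' @export
print.pain_scenario <- function(x, ...) {
  cat(sprintf("<pain_scenario> '%s' (seed %d): %d disease(s), %d record(s)\n",
              x$name, x$seed, length(x$parameters$diseases),
              nrow(x$records)))
  invisible(x)
}

#' Write a scenario bundle to a directory
#'
#' Writes `parameters.json` ([write_parameters()]), `records.csv`
#' ([write_sick_leave_csv()]) and `wage_table.csv`.
#'
#' @param scenario A [generate_scenario()] bundle.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "pain_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_parameters(scenario$parameters, file.path(dir, "parameters.json"))
  write_sick_leave_csv(scenario$records, file.path(dir, "records.csv"))
  utils::write.csv(
    data.frame(income_category = names(scenario$wage_table),
               daily_wage = as.numeric(scenario$wage_table)),
    file.path(dir, "wage_table.csv"), row.names = FALSE)
  invisible(dir)
}
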