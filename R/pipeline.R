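#' Evaluate the deterministic cost-of-illness model once
#'
#' The deterministic core that the PSA re-runs per draw: for every disease
#' in the table it builds the monthly transition matrix, seeds a closed
#' cohort of prevalent cases, runs it for the configured cycles, accrues
#' therapeutic-management costs, attributes depression/anxiety costs to
#' prevalent cases, and computes QALY losses and attributable episodes.
#'
#' Severity seeding (`init_mode`): `"consultation"` (default) splits
#' prevalent cases 7.5% / 32.5% / 60% across mild/moderate/severe, the
#' distribution observed at first consultation; `"prevalence"` seeds each
#' severity state directly from its own prevalence estimate.
#'
#' @param pars A [parameter_table()].
#' @param init_mode `"consultation"` or `"prevalence"`.
#' @param validate Re-validate the table before evaluating (skipped inside
#'   the PSA loop for speed).
#' @return List with `outcomes` (long data frame: `outcome`, `disease`,
#'   `value`, including a `five_mskd` sum over the named, non-catch-all
#'   diseases), `traces` (per-disease `cohort_trace`), `prevalent_cases`
#'   (named vector) and `matrix` (the transition matrix).
#' @export
evaluate_model <- function(pars,
                           init_mode = c("consultation", "prevalence"),
                           validate = TRUE) {
  stopifnot(inherits(pars, "parameter_table"))
  init_mode <- match.arg(init_mode)
  if (validate) {
    report <- validate_parameters(pars)
    if (nrow(report) > 0L)
      stop("evaluate_model: invalid parameter table (",
           nrow(report), " violation(s)); see validate_parameters()")
  }
  m <- build_transition_matrix(pars$transition, pars$death_prob$mean)
  named <- setdiff(pars$diseases, "all_mskd")

  traces <- list()
  prevalent <- stats::setNames(numeric(length(pars$diseases)),
                               pars$diseases)
  rows <- list()
  add <- function(outcome, disease, value)
    rows[[length(rows) + 1L]] <<- data.frame(outcome = outcome,
                                             disease = disease,
                                             value = value)
  for (d in pars$diseases) {
    prev <- vapply(pars$prevalence[[d]], function(s) s$mean, numeric(1))
    cases <- pars$adult_population * sum(prev)
    prevalent[[d]] <- cases
    initial <- if (init_mode == "consultation") cases * pars$initial_split
               else pars$adult_population * prev[ALIVE_STATES]
    trace <- run_cohort(initial, m, pars$cycles)
    traces[[d]] <- trace

    costs <- vapply(pars$state_cost[[d]], function(s) s$mean, numeric(1))
    add("cost_pain_management", d, accrue_state_costs(trace, costs)$total)
    dpaf <- pars$depression_paf[[d]]$mean
    apaf <- pars$anxiety_paf$mean
    add("cost_depression", d,
        attributable_mental_health_cost(cases, dpaf,
                                        pars$depression_cost$mean,
                                        months = pars$cycles))
    add("cost_anxiety", d,
        attributable_mental_health_cost(cases, apaf, pars$anxiety_cost$mean,
                                        months = pars$cycles))
    disut <- vapply(pars$disutility[[d]], function(s) s$mean, numeric(1))
    add("qalys_lost", d, lhsu(trace, disut, paf = 1))
    add("depression_episodes", d, attributable_episodes(cases, dpaf))
    add("anxiety_episodes", d, attributable_episodes(cases, apaf))
  }
  outcomes <- do.call(rbind, rows)
  sums <- stats::aggregate(value ~ outcome,
                           data = outcomes[outcomes$disease %in% named, ],
                           FUN = sum)
  sums$disease <- "five_mskd"
  outcomes <- rbind(outcomes, sums[c("outcome", "disease", "value")])

  list(outcomes = outcomes, traces = traces, prevalent_cases = prevalent,
       matrix = m)
}

# expected work-loss totals when no record-level data are supplied:
# per-leave published summaries scaled by annual leave counts
expected_workloss <- function(pars) {
  ds <- intersect(pars$diseases, names(pars$n_leaves))
  if (length(ds) == 0L) return(NULL)
  do.call(rbind, lapply(ds, function(d) {
    wl <- pars$workloss[[d]]
    n <- pars$n_leaves[[d]]
    data.frame(disease = d, n_leaves = n,
               subsidy_total = wl$subsidy_cost_per_leave$mean * n,
               productivity_total = wl$productivity_cost_per_leave$mean * n,
               days_total = wl$days_per_leave$mean * n)
  }))
}

resolve_input <- function(x, loader, stage, what) {
  if (is.character(x)) {
    if (!file.exists(x))
      stop(stage, " stage: ", what, " file not found: ", x)
    loader(x)
  } else x
}

#' Run the full cost-of-illness pipeline
#'
#' Orchestrates every stage — parameter loading/validation, the Markov
#' cohort model, cost accrual, consequences, work-loss estimation and
#' (optionally) the probabilistic sensitivity analysis — and assembles the
#' results-table-style reports plus a run manifest. Each stage logs to the
#' console via [message()].
#'
#' @param parameters A [parameter_table()] or path to a JSON file for
#'   [load_parameters()].
#' @param records Optional [sick_leave_records()] data frame or CSV path;
#'   when supplied, sick-leave subsidy and productivity losses are estimated
#'   from the records (95% confidence intervals), otherwise from the
#'   table's expected per-leave summaries times annual leave counts.
#' @param wage_table Optional named mapping FONASA category -> USD/day; when
#'   supplied, public records' wages are re-imputed from it.
#' @param mode `"deterministic"` (point-estimate pipeline) or `"psa"`
#'   (additionally wraps the pipeline in [run_psa()]).
#' @param n_sims,seed PSA settings (see [run_psa()]).
#' @param init_mode Severity seeding mode (see [evaluate_model()]).
#' @param out_dir Optional directory; when given, reports are written as
#'   CSV/JSON (`cost_report.csv/.json`, `consequences.csv`,
#'   `workloss_subsidy.csv`, `workloss_productivity.csv`,
#'   `psa_summary.csv`, `manifest.json`).
#' @return List of class `"pain_report"`: `cost_report`
#'   ([aggregate_cost_report()]), `consequences` (data frame disease x
#'   `qalys_lost`, `depression_episodes`, `anxiety_episodes`,
#'   `sick_leave_days`), `workloss` (list `subsidy`, `productivity`, and
#'   `source`), `psa` (a [run_psa()] summary or `NULL`), `ratios`
#'   ([render_results_ratios()]) and `manifest`.
#' @export
run_pipeline <- function(parameters, records = NULL, wage_table = NULL,
                         mode = c("deterministic", "psa"), n_sims = 10000L,
                         seed = 1L,
                         init_mode = c("consultation", "prevalence"),
                         out_dir = NULL) {
  mode <- match.arg(mode)
  init_mode <- match.arg(init_mode)

  message("[params] loading and validating parameters")
  pars <- resolve_input(parameters, load_parameters, "params", "parameters")
  stopifnot(inherits(pars, "parameter_table"))

  message("[model] running cohort model, costs and consequences")
  det <- evaluate_model(pars, init_mode = init_mode)
  out <- det$outcomes

  message("[workloss] estimating sick-leave subsidy and productivity losses")
  records <- resolve_input(records, read_sick_leave_csv, "workloss",
                           "records")
  if (!is.null(records)) {
    if (!is.null(wage_table)) records <- resolve_wages(records, wage_table)
    subsidy <- subsidy_cost(records)
    productivity <- productivity_loss(records)
    wl_source <- "records"
    per_dis <- function(summ)
      stats::setNames(summ$total[summ$disease != "overall"],
                      summ$disease[summ$disease != "overall"])
    abs_tot <- per_dis(subsidy)
    prod_tot <- per_dis(productivity)
    days_tot <- vapply(split(records$duration_days, records$disease), sum,
                       numeric(1))
  } else {
    wl <- expected_workloss(pars)
    if (is.null(wl))
      stop("workloss stage: no records supplied and the parameter table ",
           "has no annual leave counts (n_leaves)")
    subsidy <- productivity <- NULL
    wl_source <- "expected"
    abs_tot <- stats::setNames(wl$subsidy_total, wl$disease)
    prod_tot <- stats::setNames(wl$productivity_total, wl$disease)
    days_tot <- stats::setNames(wl$days_total, wl$disease)
  }

  message("[report] aggregating cost report")
  comp <- rbind(
    data.frame(disease = out$disease[out$outcome == "cost_pain_management"],
               domain = "pain_management",
               total = out$value[out$outcome == "cost_pain_management"]),
    data.frame(disease = out$disease[out$outcome == "cost_depression"],
               domain = "depression",
               total = out$value[out$outcome == "cost_depression"]),
    data.frame(disease = out$disease[out$outcome == "cost_anxiety"],
               domain = "anxiety",
               total = out$value[out$outcome == "cost_anxiety"]))
  comp <- comp[comp$disease != "five_mskd", ]
  comp <- rbind(comp,
                data.frame(disease = names(abs_tot), domain = "absenteeism",
                           total = as.numeric(abs_tot)),
                data.frame(disease = names(prod_tot),
                           domain = "productivity_losses",
                           total = as.numeric(prod_tot)))
  cost_report <- aggregate_cost_report(comp)

  cons_dis <- setdiff(unique(out$disease), "five_mskd")
  pick <- function(oc, d) {
    v <- out$value[out$outcome == oc & out$disease == d]
    if (length(v)) v else NA_real_
  }
  consequences <- data.frame(
    disease = cons_dis,
    qalys_lost = vapply(cons_dis, pick, numeric(1), oc = "qalys_lost"),
    depression_episodes = vapply(cons_dis, pick, numeric(1),
                                 oc = "depression_episodes"),
    anxiety_episodes = vapply(cons_dis, pick, numeric(1),
                              oc = "anxiety_episodes"),
    sick_leave_days = vapply(cons_dis, function(d)
      if (d %in% names(days_tot)) days_tot[[d]] else NA_real_, numeric(1)),
    row.names = NULL)

  psa <- NULL
  if (mode == "psa") {
    message("[psa] running ", n_sims, " Monte-Carlo simulations (seed ",
            seed, ")")
    psa <- run_psa(pars, n_sims = n_sims, seed = seed, init_mode = init_mode)
  }

  ratios <- render_results_ratios(cost_report)

  tmp <- tempfile(fileext = ".json")
  write_parameters(pars, tmp)
  manifest <- list(parameters_md5 = unname(tools::md5sum(tmp)),
                   mode = mode, init_mode = init_mode,
                   workloss_source = wl_source,
                   n_records = if (is.null(records)) 0L else nrow(records),
                   n_sims = if (mode == "psa") as.integer(n_sims) else 0L,
                   seed = as.integer(seed),
                   package_version =
                     as.character(utils::packageVersion("paincost")))
  unlink(tmp)

  result <- structure(list(parameters = pars, cost_report = cost_report,
                           consequences = consequences,
                           workloss = list(subsidy = subsidy,
                                           productivity = productivity,
                                           source = wl_source),
                           psa = psa, ratios = ratios, manifest = manifest),
                      class = "pain_report")

  if (!is.null(out_dir)) {
    message("[write] writing reports to ", out_dir)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cost_report(cost_report, file.path(out_dir, "cost_report.csv"),
                      file.path(out_dir, "cost_report.json"))
    utils::write.csv(consequences, file.path(out_dir, "consequences.csv"),
                     row.names = FALSE, na = "")
    if (!is.null(subsidy)) {
      write_workloss_summary(subsidy,
                             file.path(out_dir, "workloss_subsidy.csv"))
      write_workloss_summary(productivity,
                             file.path(out_dir, "workloss_productivity.csv"))
    }
    if (!is.null(psa))
      utils::write.csv(as.data.frame(psa),
                       file.path(out_dir, "psa_summary.csv"),
                       row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.pain_report <- function(x, ...) {
  cat("<pain_report>", x$manifest$mode, "run,",
      length(setdiff(x$cost_report$by_disease$disease,
                     c("five_mskd", "rest_of_mskd", "total_mskd"))),
      "disease(s)\n")
  print(x$cost_report)
  invisible(x)
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Headline ratio table from a cost report
#'
#' Computes the results-section ratios: the named-disease share of the
#' grand total, each cost domain's share of the grand total, each disease's
#' share within its domain, and the ratio of the costliest to the
#' second-costliest disease per domain. Percentages and ratios are rendered
#' half-up to one decimal; undefined ratios (zero denominators) render as
#' `NA`, never 0.
#'
#' @param report A [aggregate_cost_report()] result.
#' @return List of class `"results_ratios"` with elements `named_of_total`
#'   (scalar %), `domain_of_total` (named %), `disease_within_domain` (data
#'   frame with `share_pct` and `rendered`), `top_ratio` (data frame per
#'   domain: costliest vs runner-up and their ratio).
#' @export
render_results_ratios <- function(report) {
  if (!inherits(report, "cost_report"))
    stop("render_results_ratios: missing component: need a cost_report")
  sh <- report$shares
  dwd <- sh$disease_within_domain
  dwd$rendered <- round_half_up(dwd$share_pct, 1)

  named <- setdiff(report$by_disease$disease,
                   c("five_mskd", "rest_of_mskd", "total_mskd"))
  top_ratio <- do.call(rbind, lapply(report$domains, function(dom) {
    v <- dwd[dwd$domain == dom & dwd$disease %in% named, ]
    v <- v[order(-v$share_pct), ]
    if (nrow(v) < 2L || is.na(v$share_pct[2]) || v$share_pct[2] == 0)
      data.frame(domain = dom, top = v$disease[1], second = NA_character_,
                 ratio = NA_real_)
    else
      data.frame(domain = dom, top = v$disease[1], second = v$disease[2],
                 ratio = round_half_up(v$share_pct[1] / v$share_pct[2], 1))
  }))

  structure(list(
    named_of_total = round_half_up(sh$named_of_total, 1),
    domain_of_total = round_half_up(sh$domain_of_total, 1),
    disease_within_domain = dwd,
    top_ratio = top_ratio), class = "results_ratios")
}

#' @export
print.results_ratios <- function(x, ...) {
  cat("<results_ratios>\n")
  cat(sprintf("  named diseases / grand total: %.1f%%\n", x$named_of_total))
  cat("  domain shares of grand total:\n")
  for (d in names(x$domain_of_total))
    cat(sprintf("    %-20s %5.1f%%\n", d, x$domain_of_total[[d]]))
  cat("  costliest vs runner-up per domain:\n")
  for (i in seq_len(nrow(x$top_ratio)))
    with(x$top_ratio[i, ], cat(sprintf("    %-20s %s / %s = %.1f\n",
                                       domain, top, second, ratio)))
  invisible(x)
}

#' Reported national cost-and-consequence estimates (transcription)
#'
#' The published Chilean annual estimates that the aggregation layer is
#' checked against: per-disease and total costs by domain (USD) and
#' consequence counts (QALYs lost, attributable depression/anxiety episodes,
#' sick-leave days). Values printed in the source's running text are
#' transcribed exactly; values printed only in its summary table (in
#' millions with a comma decimal separator) are transcribed at that
#' precision. Aggregate rows (`five_mskd`, `rest_of_mskd`, `total_mskd`)
#' carry the *printed* aggregates, so internal inconsistencies of the source
#' (notably the sick-leave-days total) are preserved, not resolved.
#'
#' @return Data frame with columns `outcome`, `disease`, `value`.
#' @export
reported_results <- function() {
  path <- system.file("extdata", "reported_results.csv",
                      package = "paincost")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
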