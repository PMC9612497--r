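ALIVE_STATES <- c("mild", "moderate", "severe")
ALL_STATES <- c(ALIVE_STATES, "dead")
TRANSITION_KEYS <- c("mild_moderate", "mild_severe",
                     "moderate_mild", "moderate_severe",
                     "severe_mild", "severe_moderate")

REQUIRED_KEYS <- c("diseases", "prevalence", "transition", "death_prob",
                   "state_cost", "depression_cost", "anxiety_cost",
                   "depression_paf", "anxiety_paf", "disutility", "workloss",
                   "initial_split", "adult_population", "cycles", "n_leaves")
OPTIONAL_KEYS <- c("transition_ess")

# lenient builder: no invariant checks, so invalid values can be loaded and
# then reported by validate_parameters() rather than erroring half-parsed
new_dist_spec <- function(family, mean, se = 0) {
  structure(list(family = family, mean = as.numeric(mean),
                 se = as.numeric(se)),
            class = "dist_spec")
}

#' Assemble a model parameter table
#'
#' Bundles every input of the cost-of-illness model — prevalence, monthly
#' severity transition probabilities, monthly state costs, mental-health
#' costs and attributable fractions, disutilities, per-leave work-loss
#' summaries, the initial severity split, population size and cycle count —
#' into a single validated object consumed by the downstream pipeline.
#'
#' @param diseases Character vector of disease identifiers.
#' @param prevalence Named list: `prevalence[[disease]][[severity]]` is a
#'   [dist_spec()] for the adult-population prevalence proportion.
#' @param transition Named numeric vector of monthly probabilities for the
#'   six ordered alive-state pairs `mild_moderate`, `mild_severe`,
#'   `moderate_mild`, `moderate_severe`, `severe_mild`, `severe_moderate`.
#' @param death_prob [dist_spec()] for the monthly all-cause death
#'   probability (applied uniformly to all alive states).
#' @param state_cost Named list: `state_cost[[disease]][[severity]]` is a
#'   [dist_spec()] in USD per month.
#' @param depression_cost,anxiety_cost [dist_spec()] monthly treatment cost,
#'   USD.
#' @param depression_paf Named list of [dist_spec()] per disease: fraction of
#'   depression attributable to the disease's chronic pain.
#' @param anxiety_paf [dist_spec()]: the single all-MSKD anxiety fraction,
#'   applied uniformly across diseases.
#' @param disutility Named list: `disutility[[disease]][[severity]]` is a
#'   [dist_spec()] utility decrement in `[0, 1]`.
#' @param workloss Named list per disease with [dist_spec()] elements
#'   `productivity_cost_per_leave`, `subsidy_cost_per_leave`,
#'   `days_per_leave`.
#' @param initial_split Length-3 proportions (mild, moderate, severe) used to
#'   seed the state vector; must sum to 1.
#' @param adult_population Positive count of adults at risk.
#' @param cycles Number of monthly cycles (12 for the one-year horizon).
#' @param n_leaves Named numeric vector: annual sick-leave count per disease
#'   (diseases with unknown counts may be omitted).
#' @param transition_ess Optional effective sample size enabling joint
#'   Dirichlet uncertainty on transition rows in the PSA; `NULL` (default)
#'   keeps transitions fixed.
#' @return An object of class `"parameter_table"`. Invariants are checked;
#'   see [validate_parameters()].
#' @seealso [fixture_parameter_table()] for the bundled reference table,
#'   [load_parameters()] / [write_parameters()] for file I/O.
#' @export
parameter_table <- function(diseases, prevalence, transition, death_prob,
                            state_cost, depression_cost, anxiety_cost,
                            depression_paf, anxiety_paf, disutility, workloss,
                            initial_split, adult_population, cycles, n_leaves,
                            transition_ess = NULL) {
  tab <- structure(
    list(diseases = as.character(diseases),
         prevalence = prevalence,
         transition = transition[TRANSITION_KEYS],
         death_prob = death_prob,
         state_cost = state_cost,
         depression_cost = depression_cost,
         anxiety_cost = anxiety_cost,
         depression_paf = depression_paf,
         anxiety_paf = anxiety_paf,
         disutility = disutility,
         workloss = workloss,
         initial_split = stats::setNames(as.numeric(initial_split),
                                         ALIVE_STATES),
         adult_population = as.numeric(adult_population),
         cycles = as.numeric(cycles),
         n_leaves = n_leaves,
         transition_ess = transition_ess),
    class = "parameter_table")
  report <- validate_parameters(tab)
  if (nrow(report) > 0L)
    stop("parameter_table: invalid parameters:\n",
         paste(sprintf("  - %s: %s", report$parameter, report$rule),
               collapse = "\n"))
  tab
}

#' @export
print.parameter_table <- function(x, ...) {
  cat("<parameter_table>\n")
  cat("  diseases:        ", paste(x$diseases, collapse = ", "), "\n")
  cat("  cycles:          ", x$cycles, "month(s)\n")
  cat("  adult population:", format(x$adult_population, big.mark = ","), "\n")
  cat("  initial split:   ",
      paste(sprintf("%s %.1f%%", names(x$initial_split),
                    100 * x$initial_split), collapse = ", "), "\n")
  cat("  transition mode: ",
      if (is.null(x$transition_ess)) "fixed point estimates"
      else sprintf("dirichlet_row (ess = %g)", x$transition_ess), "\n")
  invisible(x)
}

#' Validate a parameter table
#'
#' Checks every invariant of the parameter set and returns a report listing
#' each violation: probability and fraction ranges, nonnegative costs, beta
#' moment-fit feasibility, the initial-split sum, referenced-disease
#' consistency, and Markov feasibility (exit probabilities plus death must
#' not exceed 1 from any alive state). An empty report means the table is
#' valid.
#'
#' @param table A [parameter_table()] (or a structurally similar list, e.g.
#'   one freshly parsed from file).
#' @return A data frame of class `"validation_report"` with columns
#'   `parameter` and `rule`; zero rows iff valid.
#' @export
validate_parameters <- function(table) {
  bad <- list()
  flag <- function(parameter, rule)
    bad[[length(bad) + 1L]] <<- data.frame(parameter = parameter, rule = rule)

  diseases <- table$diseases
  if (length(diseases) == 0L) flag("diseases", "must be nonempty")

  check_spec <- function(name, spec, proportion = FALSE) {
    if (!is_dist_spec(spec)) { flag(name, "not a dist_spec"); return() }
    if (!spec$family %in% c("beta", "gamma", "lognormal", "dirichlet_row",
                            "fixed"))
      flag(name, paste("unknown family", spec$family))
    if (!is.finite(spec$mean) || spec$mean < 0)
      flag(name, "mean must be nonnegative")
    if (!is.finite(spec$se) || spec$se < 0)
      flag(name, "se must be nonnegative")
    if (proportion && (spec$mean < 0 || spec$mean > 1))
      flag(name, "proportion outside [0,1]")
    if (spec$family == "beta") {
      if (spec$mean < 0 || spec$mean > 1)
        flag(name, "beta mean outside [0,1]")
      else if (spec$se > 0 && spec$se^2 >= spec$mean * (1 - spec$mean))
        flag(name, "beta moment infeasibility (se^2 >= mean*(1-mean))")
    }
    if (spec$family %in% c("gamma", "lognormal") && spec$mean <= 0)
      flag(name, paste(spec$family, "requires mean > 0"))
  }
  check_nested <- function(field, proportion) {
    block <- table[[field]]
    extra <- setdiff(names(block), diseases)
    if (length(extra))
      flag(field, paste("references unknown disease(s):",
                        paste(extra, collapse = ", ")))
    for (d in names(block))
      for (s in names(block[[d]]))
        check_spec(paste(field, d, s, sep = "."), block[[d]][[s]], proportion)
  }

  check_nested("prevalence", proportion = TRUE)
  check_nested("state_cost", proportion = FALSE)
  check_nested("disutility", proportion = TRUE)
  check_nested("workloss", proportion = FALSE)

  extra <- setdiff(names(table$depression_paf), diseases)
  if (length(extra))
    flag("depression_paf", paste("references unknown disease(s):",
                                 paste(extra, collapse = ", ")))
  for (d in names(table$depression_paf))
    check_spec(paste0("depression_paf.", d), table$depression_paf[[d]],
               proportion = TRUE)
  check_spec("anxiety_paf", table$anxiety_paf, proportion = TRUE)
  check_spec("death_prob", table$death_prob, proportion = TRUE)
  check_spec("depression_cost", table$depression_cost)
  check_spec("anxiety_cost", table$anxiety_cost)

  tr <- table$transition
  missing_tr <- setdiff(TRANSITION_KEYS, names(tr))
  if (length(missing_tr))
    flag("transition", paste("missing pair(s):",
                             paste(missing_tr, collapse = ", ")))
  for (k in intersect(TRANSITION_KEYS, names(tr)))
    if (!is.finite(tr[[k]]) || tr[[k]] < 0 || tr[[k]] > 1)
      flag(paste0("transition.", k), "probability outside [0,1]")

  # Markov feasibility: exits + death must leave a nonnegative stay prob
  if (length(missing_tr) == 0L && is_dist_spec(table$death_prob)) {
    death <- table$death_prob$mean
    for (s in ALIVE_STATES) {
      exits <- sum(unlist(tr[grep(paste0("^", s, "_"), names(tr))]))
      if (is.finite(exits) && exits + death > 1)
        flag(paste0("transition.", s),
             "state exit probabilities exceed 1 (exits + death > 1)")
    }
  }

  split <- table$initial_split
  if (length(split) != 3L)
    flag("initial_split", "must have exactly 3 components")
  else {
    if (abs(sum(split) - 1) > 1e-9)
      flag("initial_split", sprintf("must sum to 1 (sums to %g)", sum(split)))
    if (any(split < 0 | split > 1))
      flag("initial_split", "components outside [0,1]")
  }

  if (!is.numeric(table$adult_population) || length(table$adult_population)
      != 1L || !is.finite(table$adult_population) ||
      table$adult_population < 1)
    flag("adult_population", "must be a positive count")
  if (!is.numeric(table$cycles) || length(table$cycles) != 1L ||
      !is.finite(table$cycles) || table$cycles < 1)
    flag("cycles", "must be >= 1")

  nl <- table$n_leaves
  extra <- setdiff(names(nl), diseases)
  if (length(extra))
    flag("n_leaves", paste("references unknown disease(s):",
                           paste(extra, collapse = ", ")))
  if (length(nl) && any(!is.finite(unlist(nl)) | unlist(nl) < 0))
    flag("n_leaves", "counts must be nonnegative")

  if (!is.null(table$transition_ess) &&
      (!is.numeric(table$transition_ess) || table$transition_ess <= 0))
    flag("transition_ess", "must be a positive effective sample size")

  report <- if (length(bad)) do.call(rbind, bad)
            else data.frame(parameter = character(), rule = character())
  class(report) <- c("validation_report", "data.frame")
  report
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) cat("<validation_report> no violations\n")
  else {
    cat(sprintf("<validation_report> %d violation(s):\n", nrow(x)))
    for (i in seq_len(nrow(x)))
      cat(sprintf("  - %s: %s\n", x$parameter[i], x$rule[i]))
  }
  invisible(x)
}

spec_to_list <- function(spec) spec[c("family", "mean", "se")]
list_to_spec <- function(x, where) {
  if (!is.list(x) || !all(c("family", "mean", "se") %in% names(x)))
    stop("load_parameters: malformed distribution at ", where,
         " (need family, mean, se)")
  new_dist_spec(x$family, x$mean, x$se)
}
nested_to_list <- function(block) lapply(block, function(d)
  lapply(d, spec_to_list))
nested_to_spec <- function(block, field) {
  out <- lapply(names(block), function(d) {
    dd <- block[[d]]
    stats::setNames(lapply(names(dd), function(s)
      list_to_spec(dd[[s]], paste(field, d, s, sep = "."))), names(dd))
  })
  stats::setNames(out, names(block))
}

#' Write a parameter table to a JSON configuration file
#'
#' The file is the package's single configuration format: one file holds one
#' complete parameter set and round-trips through [load_parameters()]
#' field-for-field.
#'
#' @param table A [parameter_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(table, path) {
  stopifnot(inherits(table, "parameter_table"))
  out <- list(
    diseases = table$diseases,
    prevalence = nested_to_list(table$prevalence),
    transition = as.list(table$transition),
    death_prob = spec_to_list(table$death_prob),
    state_cost = nested_to_list(table$state_cost),
    depression_cost = spec_to_list(table$depression_cost),
    anxiety_cost = spec_to_list(table$anxiety_cost),
    depression_paf = lapply(table$depression_paf, spec_to_list),
    anxiety_paf = spec_to_list(table$anxiety_paf),
    disutility = nested_to_list(table$disutility),
    workloss = nested_to_list(table$workloss),
    initial_split = as.list(table$initial_split),
    adult_population = table$adult_population,
    cycles = table$cycles,
    n_leaves = as.list(table$n_leaves))
  if (!is.null(table$transition_ess))
    out$transition_ess <- table$transition_ess
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load and validate a parameter table from a JSON configuration file
#'
#' Parses the documented configuration schema, rejects unknown keys, and
#' runs [validate_parameters()]; any missing required key or violated
#' invariant raises an error naming the offending parameter.
#'
#' @param path Path to a JSON file written by [write_parameters()] (or by
#'   hand, following the same schema).
#' @return A validated [parameter_table()].
#' @examples
#' path <- system.file("extdata", "mskd_parameters.json", package = "paincost")
#' pars <- load_parameters(path)
#' pars$transition[["mild_moderate"]]
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("load_parameters: file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  missing <- setdiff(REQUIRED_KEYS, names(raw))
  if (length(missing))
    stop("load_parameters: schema error, missing required key(s): ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(names(raw), c(REQUIRED_KEYS, OPTIONAL_KEYS))
  if (length(unknown))
    stop("load_parameters: schema error, unknown key(s): ",
         paste(unknown, collapse = ", "))

  tab <- structure(list(
    diseases = as.character(unlist(raw$diseases)),
    prevalence = nested_to_spec(raw$prevalence, "prevalence"),
    transition = vapply(raw$transition, as.numeric,
                        numeric(1))[TRANSITION_KEYS],
    death_prob = list_to_spec(raw$death_prob, "death_prob"),
    state_cost = nested_to_spec(raw$state_cost, "state_cost"),
    depression_cost = list_to_spec(raw$depression_cost, "depression_cost"),
    anxiety_cost = list_to_spec(raw$anxiety_cost, "anxiety_cost"),
    depression_paf = stats::setNames(
      lapply(names(raw$depression_paf), function(d)
        list_to_spec(raw$depression_paf[[d]], paste0("depression_paf.", d))),
      names(raw$depression_paf)),
    anxiety_paf = list_to_spec(raw$anxiety_paf, "anxiety_paf"),
    disutility = nested_to_spec(raw$disutility, "disutility"),
    workloss = nested_to_spec(raw$workloss, "workloss"),
    initial_split = stats::setNames(
      vapply(raw$initial_split, as.numeric, numeric(1))[ALIVE_STATES],
      ALIVE_STATES),
    adult_population = as.numeric(raw$adult_population),
    cycles = as.numeric(raw$cycles),
    n_leaves = vapply(raw$n_leaves, as.numeric, numeric(1)),
    transition_ess = if (is.null(raw$transition_ess)) NULL
                     else as.numeric(raw$transition_ess)),
    class = "parameter_table")

  report <- validate_parameters(tab)
  if (nrow(report) > 0L)
    stop("load_parameters: validation error:\n",
         paste(sprintf("  - %s: %s", report$parameter, report$rule),
               collapse = "\n"))
  tab
}

#' Flatten a parameter table to a data frame
#'
#' One row per scalar parameter with columns `name`, `disease`, `severity`,
#' `mean`, `se`, `family` — the layout used for the CSV export of the full
#' parameter list.
#'
#' @param table A [parameter_table()].
#' @return A data frame.
#' @export
flatten_parameters <- function(table) {
  rows <- list()
  add <- function(name, disease, severity, spec)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, disease = disease, severity = severity,
      mean = spec$mean, se = spec$se, family = spec$family)
  for (d in names(table$prevalence))
    for (s in names(table$prevalence[[d]]))
      add("prevalence", d, s, table$prevalence[[d]][[s]])
  for (k in names(table$transition))
    add(paste0("transition_", k), NA, NA,
        new_dist_spec("fixed", table$transition[[k]]))
  add("death_prob", NA, NA, table$death_prob)
  for (d in names(table$state_cost))
    for (s in names(table$state_cost[[d]]))
      add("state_cost", d, s, table$state_cost[[d]][[s]])
  add("depression_cost", NA, NA, table$depression_cost)
  add("anxiety_cost", NA, NA, table$anxiety_cost)
  for (d in names(table$depression_paf))
    add("depression_paf", d, NA, table$depression_paf[[d]])
  add("anxiety_paf", NA, NA, table$anxiety_paf)
  for (d in names(table$disutility))
    for (s in names(table$disutility[[d]]))
      add("disutility", d, s, table$disutility[[d]][[s]])
  for (d in names(table$workloss))
    for (s in names(table$workloss[[d]]))
      add(s, d, NA, table$workloss[[d]][[s]])
  do.call(rbind, rows)
}

#' Export the flattened parameter list as CSV
#'
#' @param table A [parameter_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_parameters_csv <- function(table, path) {
  utils::write.csv(flatten_parameters(table), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
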