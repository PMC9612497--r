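#' Build a table of sick-leave records
#'
#' One row per sick-leave event. Public-insurer (FONASA) records usually
#' carry an income category (A-D) instead of an observed wage, which is
#' imputed via [impute_daily_wage()]; private-insurer records carry the wage
#' observed in the database.
#'
#' @param disease Character vector of disease identifiers.
#' @param insurer `"public"` or `"private"`.
#' @param income_category `"A"`, `"B"`, `"C"`, `"D"` (FONASA income bands,
#'   A poorest) or `"private"`.
#' @param duration_days Positive integer leave duration.
#' @param daily_wage Nonnegative USD per day.
#' @return A data frame of class `"sick_leave_records"`.
#' @export
sick_leave_records <- function(disease, insurer, income_category,
                               duration_days, daily_wage) {
  insurer <- match.arg(insurer, c("public", "private"), several.ok = TRUE)
  bad <- setdiff(income_category, c("A", "B", "C", "D", "private"))
  if (length(bad))
    stop("sick_leave_records: unknown income_category: ",
         paste(unique(bad), collapse = ", "))
  if (any(duration_days < 1) || any(duration_days != floor(duration_days)))
    stop("sick_leave_records: duration_days must be integers >= 1")
  if (any(daily_wage < 0))
    stop("sick_leave_records: daily_wage must be nonnegative")
  structure(data.frame(disease = as.character(disease),
                       insurer = insurer,
                       income_category = as.character(income_category),
                       duration_days = as.integer(duration_days),
                       daily_wage = as.numeric(daily_wage)),
            class = c("sick_leave_records", "data.frame"))
}

#' Read / write sick-leave records as CSV
#'
#' CSV columns: `disease`, `insurer`, `income_category`, `duration_days`,
#' `daily_wage`.
#'
#' @param path CSV path.
#' @return [read_sick_leave_csv()]: a `sick_leave_records` data frame.
#' @export
read_sick_leave_csv <- function(path) {
  if (!file.exists(path)) stop("read_sick_leave_csv: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("disease", "insurer", "income_category", "duration_days",
            "daily_wage")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("read_sick_leave_csv: missing column(s): ",
         paste(missing, collapse = ", "))
  sick_leave_records(df$disease, df$insurer, df$income_category,
                     df$duration_days, df$daily_wage)
}

#' @rdname read_sick_leave_csv
#' @param records A `sick_leave_records` data frame.
#' @export
write_sick_leave_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Days of a sick leave paid by the insurer
#'
#' Chilean insurers (public or private) pay from the 4th day of leave
#' onwards, i.e. days 4-10 for leaves of up to 10 days — the first three
#' days are discounted (borne by the employer). For leaves of 11 days or
#' more the insurer pays the entire period from day 1.
#'
#' @param duration_days Integer vector of leave durations, each >= 1.
#' @return Integer vector of insurer-paid days: 0 for durations <= 3,
#'   `duration - 3` for 4-10, `duration` for >= 11.
#' @examples
#' paid_subsidy_days(c(3, 10, 11))  # 0 7 11
#' @export
paid_subsidy_days <- function(duration_days) {
  if (any(duration_days < 1) || any(duration_days != floor(duration_days)))
    stop("paid_subsidy_days: duration_days must be integers >= 1")
  d <- as.integer(duration_days)
  ifelse(d <= 3L, 0L, ifelse(d <= 10L, d - 3L, d))
}

# shared summary machinery: per-record costs -> per-disease mean, SE,
# normal-approximation 95% CI, and totals
summarize_workloss <- function(records, per_record_cost) {
  split_cost <- split(per_record_cost, records$disease)
  rows <- lapply(names(split_cost), function(d) {
    x <- split_cost[[d]]
    n <- length(x)
    m <- mean(x)
    se <- if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_
    data.frame(disease = d, n_leaves = n, mean_per_leave = m, se = se,
               lower_95 = m - 1.96 * se, upper_95 = m + 1.96 * se,
               total = sum(x))
  })
  overall <- {
    x <- per_record_cost
    n <- length(x)
    m <- mean(x)
    se <- if (n > 1L) stats::sd(x) / sqrt(n) else NA_real_
    data.frame(disease = "overall", n_leaves = n, mean_per_leave = m,
               se = se, lower_95 = m - 1.96 * se, upper_95 = m + 1.96 * se,
               total = sum(x))
  }
  out <- rbind(do.call(rbind, rows), overall)
  out$interval_kind <- "confidence"
  rownames(out) <- NULL
  out
}

#' Sick-leave subsidy cost (insurer-paid wage replacement)
#'
#' Per-record cost is `paid_subsidy_days(duration) * daily_wage`. Reports,
#' per disease and overall: the mean cost per leave, its standard error, a
#' 95% confidence interval (`mean +/- 1.96 * SE`, normal approximation), the
#' number of leaves, and the total. Diseases with no records are simply
#' absent from the output.
#'
#' @param records A [sick_leave_records()] data frame. Wages must already be
#'   resolved (see [impute_daily_wage()]).
#' @return Data frame with one row per disease plus an `overall` row;
#'   columns `disease`, `n_leaves`, `mean_per_leave`, `se`, `lower_95`,
#'   `upper_95`, `total`, `interval_kind`.
#' @examples
#' r <- sick_leave_records("lbp", "public", "B", c(8, 20), c(30, 30))
#' subsidy_cost(r)$total  # per-record costs 150 and 600
#' @export
subsidy_cost <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  cost <- paid_subsidy_days(records$duration_days) * records$daily_wage
  summarize_workloss(records, cost)
}

#' Productivity losses under the human capital approach
#'
#' Values the full absence at the individual's daily income: per-record cost
#' is `duration_days * daily_wage`, with no discount of the first three days
#' (the employer-paid days are still lost production to society). Summaries
#' are as in [subsidy_cost()]; for every record the productivity loss is at
#' least the subsidy cost.
#'
#' @inheritParams subsidy_cost
#' @return As [subsidy_cost()].
#' @export
productivity_loss <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  cost <- records$duration_days * records$daily_wage
  summarize_workloss(records, cost)
}

#' Impute a daily wage from a FONASA income category
#'
#' Public-insurer sick-leave records report the beneficiary's income
#' category (A-D) rather than a wage; the average daily wage of each
#' category is looked up in a wage table. Private records carry their
#' observed wage and bypass imputation (see `resolve_wages()` behaviour in
#' [generate_scenario()] bundles).
#'
#' @param income_category Character vector of categories.
#' @param wage_table Named numeric vector/list mapping category to USD/day.
#' @return Numeric vector of daily wages.
#' @export
impute_daily_wage <- function(income_category, wage_table) {
  wage_table <- unlist(wage_table)
  unknown <- setdiff(unique(income_category), names(wage_table))
  if (length(unknown))
    stop("impute_daily_wage: category not in wage table: ",
         paste(unknown, collapse = ", "))
  unname(wage_table[income_category])
}

#' Resolve wages on a mixed public/private record set
#'
#' Applies [impute_daily_wage()] to public records (overwriting
#' `daily_wage` from the wage table) and keeps private records' observed
#' wages as-is.
#'
#' @param records A [sick_leave_records()] data frame.
#' @param wage_table Named mapping of FONASA category to USD/day.
#' @return The records with `daily_wage` resolved.
#' @export
resolve_wages <- function(records, wage_table) {
  pub <- records$insurer == "public"
  if (any(pub))
    records$daily_wage[pub] <- impute_daily_wage(records$income_category[pub],
                                                 wage_table)
  records
}

#' Export a work-loss summary as CSV and JSON
#'
#' @param summary A [subsidy_cost()] / [productivity_loss()] result.
#' @param csv_path,json_path Output paths; `NULL` skips that format.
#' @return Invisibly, the paths written.
#' @export
write_workloss_summary <- function(summary, csv_path = NULL,
                                   json_path = NULL) {
  written <- character()
  if (!is.null(csv_path)) {
    utils::write.csv(summary, csv_path, row.names = FALSE, na = "")
    written <- c(written, csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    written <- c(written, json_path)
  }
  invisible(written)
}
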