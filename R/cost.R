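COST_DOMAINS <- c("pain_management", "depression", "anxiety",
                  "absenteeism", "productivity_losses")

#' Monthly cost basket for one disease
#'
#' Health baskets aggregate physician visits, physiotherapy, pharmacological
#' treatment and hospitalizations into one expected monthly cost per pain
#' severity; item-level composition enters the model only through these
#' aggregates. Depression and anxiety treatment costs are carried alongside
#' because they are attributed to pain via attributable fractions.
#'
#' @param disease Disease identifier.
#' @param monthly_cost Named numeric vector, USD per person-month in each
#'   severity state (`mild`, `moderate`, `severe`).
#' @param depression_monthly,anxiety_monthly USD per person-month of treating
#'   an attributable mental-health case.
#' @return An object of class `"cost_basket"`.
#' @export
cost_basket <- function(disease, monthly_cost, depression_monthly = 0,
                        anxiety_monthly = 0) {
  stopifnot(is.numeric(monthly_cost),
            all(ALIVE_STATES %in% names(monthly_cost)))
  if (any(monthly_cost < 0) || depression_monthly < 0 || anxiety_monthly < 0)
    stop("cost_basket: costs must be nonnegative")
  structure(list(disease = disease,
                 monthly_cost = monthly_cost[ALIVE_STATES],
                 depression_monthly = depression_monthly,
                 anxiety_monthly = anxiety_monthly),
            class = "cost_basket")
}

#' Accrue therapeutic-management costs over a cohort trace
#'
#' Costs accrue at the end of each monthly cycle: the per-cycle cost is the
#' occupancy of each alive severity state times that state's monthly cost,
#' summed over states; the total sums cycles `1..T`. No discounting is
#' applied (one-year horizon).
#'
#' @param trace A [run_cohort()] trace.
#' @param basket A [cost_basket()] (or a named numeric vector of monthly
#'   costs per severity).
#' @return List with `total` (USD) and `per_cycle` (numeric vector, one
#'   entry per cycle `1..T`).
#' @examples
#' m <- build_transition_matrix(numeric(0), 0)
#' tr <- run_cohort(c(0, 0, 100), m, 12)
#' accrue_state_costs(tr, cost_basket("lbp",
#'   c(mild = 6.97, moderate = 13.75, severe = 54.22)))$total  # 65064
#' @export
accrue_state_costs <- function(trace, basket) {
  stopifnot(inherits(trace, "cohort_trace"))
  costs <- if (inherits(basket, "cost_basket")) basket$monthly_cost
           else basket
  if (!all(ALIVE_STATES %in% names(costs)))
    stop("accrue_state_costs: basket severities must cover ",
         paste(ALIVE_STATES, collapse = ", "))
  costs <- costs[ALIVE_STATES]
  occ <- unclass(trace)[-1L, ALIVE_STATES, drop = FALSE]
  per_cycle <- as.numeric(occ %*% costs)
  list(total = sum(per_cycle), per_cycle = per_cycle)
}

#' Mental-health treatment cost attributable to chronic pain
#'
#' Depression and anxiety attach to prevalent cases (not to the severity
#' trace): the attributable cost is
#' `prevalent_cases * paf * monthly_cost * months`, where `paf` is the
#' pain-attributable fraction of the mental-health condition.
#'
#' @param prevalent_cases Number of prevalent chronic-pain cases.
#' @param paf Pain-attributable fraction, in `[0, 1]`.
#' @param monthly_cost USD per case-month of treatment.
#' @param months Months of treatment per attributable case (default 12, the
#'   model horizon).
#' @return USD.
#' @examples
#' attributable_mental_health_cost(1000, 0.1315, 26.20, 12)  # 41343.6
#' @export
attributable_mental_health_cost <- function(prevalent_cases, paf,
                                            monthly_cost, months = 12) {
  if (!is.numeric(paf) || paf < 0 || paf > 1)
    stop("attributable_mental_health_cost: paf must lie in [0,1], got ", paf)
  stopifnot(prevalent_cases >= 0, monthly_cost >= 0, months >= 0)
  prevalent_cases * paf * monthly_cost * months
}

#' Aggregate per-disease, per-domain cost components into a report
#'
#' Builds the cost side of the results table: per-disease totals across
#' domains, the sum over the named diseases, a rest-of-MSKD residual
#' (all-MSKD minus the named-disease sum, for domains where an all-MSKD
#' figure exists), the grand total, and unrounded percentage shares
#' (domain within grand total; disease within domain; named-disease share of
#' the grand total). Shares are computed before any rounding; zero
#' denominators yield `NA` ("undefined"), never 0.
#'
#' @param components Data frame with columns `disease`, `domain`, `total`
#'   (USD). `domain` must be one of `pain_management`, `depression`,
#'   `anxiety`, `absenteeism`, `productivity_losses`. Rows for the catch-all
#'   disease (`all_mskd_id`) provide domain-wide totals from which the
#'   rest-of-MSKD residual is derived.
#' @param all_mskd_id Identifier of the all-cause catch-all disease
#'   (default `"all_mskd"`).
#' @return An object of class `"cost_report"`: list with `by_disease` (wide
#'   data frame, one row per disease plus `five_mskd`, `rest_of_mskd`,
#'   `total_mskd`), `grand_total` (USD), and `shares` (list with
#'   `domain_of_total`, `disease_within_domain`, `named_of_total`).
#' @export
aggregate_cost_report <- function(components, all_mskd_id = "all_mskd") {
  stopifnot(is.data.frame(components),
            all(c("disease", "domain", "total") %in% names(components)))
  bad <- setdiff(unique(components$domain), COST_DOMAINS)
  if (length(bad))
    stop("aggregate_cost_report: unknown domain(s): ",
         paste(bad, collapse = ", "))
  if (any(components$total < 0))
    stop("aggregate_cost_report: negative cost component")

  domains <- intersect(COST_DOMAINS, unique(components$domain))
  named <- setdiff(unique(components$disease), all_mskd_id)
  has_all <- all_mskd_id %in% components$disease

  cell <- function(d, dom) {
    v <- components$total[components$disease == d & components$domain == dom]
    if (length(v) == 0L) NA_real_ else sum(v)
  }
  wide <- sapply(domains, function(dom) vapply(named, cell, numeric(1),
                                               dom = dom))
  wide <- matrix(wide, nrow = length(named),
                 dimnames = list(named, domains))
  named_sum <- colSums(wide, na.rm = TRUE)
  all_row <- if (has_all) vapply(domains, cell, numeric(1), d = all_mskd_id)
             else rep(NA_real_, length(domains))
  # domain-wide total: the all-MSKD figure where supplied, else the
  # named-disease sum (domains measured only for the named diseases)
  domain_total <- stats::setNames(ifelse(is.na(all_row), named_sum, all_row),
                                  domains)
  rest <- all_row - named_sum

  by_disease <- data.frame(disease = c(named, "five_mskd", "rest_of_mskd",
                                       "total_mskd"),
                           rbind(wide, five_mskd = named_sum,
                                 rest_of_mskd = rest,
                                 total_mskd = domain_total),
                           row.names = NULL, check.names = FALSE)
  by_disease$total <- rowSums(by_disease[, domains, drop = FALSE],
                              na.rm = TRUE)
  by_disease$total[rowSums(!is.na(by_disease[, domains, drop = FALSE])) ==
                     0L] <- NA_real_

  grand_total <- sum(domain_total)
  pct <- function(num, den) {
    den <- rep(den, length.out = length(num))
    ifelse(is.na(den) | den == 0, NA_real_, 100 * num / den)
  }
  disease_within_domain <- do.call(rbind, lapply(domains, function(dom)
    data.frame(disease = named, domain = dom,
               share_pct = pct(wide[, dom], domain_total[[dom]]))))
  named_total <- sum(named_sum)
  shares <- list(
    domain_of_total = stats::setNames(pct(domain_total, grand_total),
                                      domains),
    disease_within_domain = disease_within_domain,
    named_of_total = pct(named_total, grand_total))

  structure(list(by_disease = by_disease, grand_total = grand_total,
                 domains = domains, shares = shares,
                 all_mskd_id = all_mskd_id),
            class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat("<cost_report> grand total USD",
      format(round(x$grand_total), big.mark = ","), "\n")
  df <- x$by_disease
  df[-1] <- lapply(df[-1], function(v) round(v))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Export a cost report as CSV and JSON
#'
#' @param report A [aggregate_cost_report()] result.
#' @param csv_path,json_path Output paths; `NULL` skips that format.
#' @return Invisibly, a character vector of the paths written.
#' @export
write_cost_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "cost_report"))
  written <- character()
  if (!is.null(csv_path)) {
    utils::write.csv(report$by_disease, csv_path, row.names = FALSE, na = "")
    written <- c(written, csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(by_disease = report$by_disease, grand_total = report$grand_total,
           shares = list(
             domain_of_total = as.list(report$shares$domain_of_total),
             disease_within_domain = report$shares$disease_within_domain,
             named_of_total = report$shares$named_of_total)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    written <- c(written, json_path)
  }
  invisible(written)
}
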