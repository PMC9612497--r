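lbp_basket <- cost_basket("low_back_pain",
                          c(mild = 6.97, moderate = 13.75, severe = 54.22),
                          depression_monthly = 26.20,
                          anxiety_monthly = 14.55)

test_that("state-cost accrual sums occupancy times monthly cost", {
  tr <- constant_trace(c(0, 0, 100), 12)
  acc <- accrue_state_costs(tr, lbp_basket)
  expect_equal(acc$total, 100 * 54.22 * 12)  # 65,064
  expect_length(acc$per_cycle, 12)
  expect_equal(acc$per_cycle, rep(5422, 12))

  # empty cohort accrues nothing
  expect_equal(accrue_state_costs(constant_trace(c(0, 0, 0)), lbp_basket)$total,
               0)
  # one cycle, one person per state: a + b + c
  tr1 <- constant_trace(c(1, 1, 1), 1)
  expect_equal(accrue_state_costs(tr1, c(mild = 2, moderate = 3,
                                         severe = 5))$total, 10)
  expect_error(accrue_state_costs(tr1, c(mild = 1, moderate = 2)),
               "severities")
})

test_that("accrual is additive over cycles and monotone in costs", {
  set.seed(31)
  m <- build_transition_matrix(random_exits(), 0.001)
  tr <- run_cohort(c(500, 300, 200), m, 12)
  costs <- c(mild = 5, moderate = 10, severe = 50)
  acc <- accrue_state_costs(tr, costs)
  expect_equal(acc$total, sum(acc$per_cycle))
  # raising any one state cost weakly increases the total
  for (s in names(costs)) {
    up <- costs; up[s] <- up[s] + 1
    expect_gte(accrue_state_costs(tr, up)$total, acc$total)
  }
})

test_that("attributable mental-health cost is the fraction product", {
  expect_equal(attributable_mental_health_cost(1000, 0.1315, 26.20, 12),
               41343.6)
  expect_equal(attributable_mental_health_cost(500, 0, 26.20, 12), 0)
  expect_equal(attributable_mental_health_cost(1, 1, 14.55, 1), 14.55)
  expect_error(attributable_mental_health_cost(10, 1.2, 5, 12), "paf")
})

test_that("cost report aggregates diseases, domains and residuals", {
  comp <- reported_cost_components()
  rep <- aggregate_cost_report(comp)

  five <- rep$by_disease[rep$by_disease$disease == "five_mskd", ]
  expect_equal(five$pain_management, 566183770)
  # residual = all-MSKD total minus the five-disease sum
  rest <- rep$by_disease[rep$by_disease$disease == "rest_of_mskd", ]
  expect_equal(rest$pain_management, 685598439 - 566183770)
  # domains without an all-MSKD figure fall back to the named sum
  tot <- rep$by_disease[rep$by_disease$disease == "total_mskd", ]
  expect_equal(tot$absenteeism, five$absenteeism)

  # single disease, single domain: total is that component
  one <- aggregate_cost_report(data.frame(disease = "knee_oa",
                                          domain = "depression",
                                          total = 123))
  expect_equal(one$grand_total, 123)
  expect_equal(one$shares$disease_within_domain$share_pct, 100)

  # all-zero components: shares are undefined, not zero
  z <- aggregate_cost_report(data.frame(disease = c("a", "b"),
                                        domain = "anxiety",
                                        total = c(0, 0)))
  expect_true(all(is.na(z$shares$disease_within_domain$share_pct)))
  expect_true(is.na(z$shares$named_of_total))

  expect_error(aggregate_cost_report(data.frame(disease = "a",
                                                domain = "anxiety",
                                                total = -1)), "negative")
  expect_error(aggregate_cost_report(data.frame(disease = "a",
                                                domain = "parking",
                                                total = 1)), "unknown domain")
})

test_that("within-domain shares sum to 100 when every disease is included", {
  set.seed(5)
  comp <- expand.grid(disease = letters[1:6],
                      domain = c("absenteeism", "productivity_losses"),
                      stringsAsFactors = FALSE)
  comp$total <- runif(nrow(comp), 10, 1000)
  rep <- aggregate_cost_report(comp)
  for (dom in rep$domains) {
    s <- rep$shares$disease_within_domain
    expect_equal(sum(s$share_pct[s$domain == dom]), 100, tolerance = 0.2)
  }
})

test_that("cost report exports to CSV and JSON", {
  rep <- aggregate_cost_report(reported_cost_components())
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_cost_report(rep, csv, js)
  back <- read.csv(csv)
  expect_equal(back$pain_management[back$disease == "low_back_pain"],
               187908323)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$grand_total, rep$grand_total)
})
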