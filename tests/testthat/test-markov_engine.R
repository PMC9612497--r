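test_that("transition matrix rows are the published exits plus residual stay", {
  m <- build_transition_matrix(fixture_transition, 0.0004)
  expect_equal(unname(m["mild", ]), c(0.7085, 0.1841, 0.1070, 0.0004))
  expect_equal(m["moderate", "moderate"], 0.1703)
  expect_equal(m["severe", "severe"], 0.0767)
  expect_equal(unname(m["dead", ]), c(0, 0, 0, 1))
  expect_equal(unname(rowSums(m)), rep(1, 4))

  # no exits, no death: identity
  expect_equal(unclass(build_transition_matrix(numeric(0), 0)),
               diag(4), ignore_attr = TRUE)

  expect_error(build_transition_matrix(c(moderate_mild = 0.9,
                                         moderate_severe = 0.2738), 0.0004),
               "infeasible row for state 'moderate'")
  expect_error(build_transition_matrix(c(bogus_pair = 0.1), 0), "unknown")
})

test_that("cohort trace conserves mass and factorizes survival", {
  m <- build_transition_matrix(fixture_transition, 0.0004)
  tr <- run_cohort(c(750, 3250, 6000), m, 12)
  expect_equal(dim(tr), c(13L, 4L))
  expect_equal(unname(unclass(tr)[1, ]), c(750, 3250, 6000, 0))
  # mass conservation at every cycle
  expect_equal(unname(rowSums(tr)), rep(10000, 13), tolerance = 1e-12)
  # dead column nondecreasing
  expect_true(all(diff(tr[, "dead"]) >= 0))
  # uniform death hazard: total alive = N * (1 - death)^t exactly
  alive <- rowSums(tr[, c("mild", "moderate", "severe")])
  expect_equal(unname(alive), 10000 * (1 - 0.0004)^(0:12), tolerance = 1e-12)

  # empty cohort stays empty
  expect_equal(sum(run_cohort(c(0, 0, 0), m, 5)), 0)
  # identity matrix: occupancy is a fixed point
  id <- build_transition_matrix(numeric(0), 0)
  tr2 <- run_cohort(c(1, 2, 3), id, 7)
  expect_true(all(apply(unclass(tr2), 2, function(col)
    all(col == col[1]))))
  expect_error(run_cohort(c(-1, 0, 0), m, 2), "nonnegative")
})

test_that("survival factorization holds for random transition sets", {
  set.seed(42)
  for (i in 1:1000) {
    death <- runif(1, 0, 0.05)
    m <- build_transition_matrix(random_exits(), death)
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-12)
    init <- runif(3, 0, 1000)
    tr <- run_cohort(init, m, 5)
    expect_equal(unname(rowSums(tr)), rep(sum(init), 6), tolerance = 1e-9)
    alive <- sum(tr[6, 1:3])
    expect_equal(alive, sum(init) * (1 - death)^5, tolerance = 1e-9)
  }
})

test_that("cohort with zero death keeps total alive constant", {
  set.seed(7)
  m <- build_transition_matrix(random_exits(), 0)
  tr <- run_cohort(c(100, 200, 300), m, 24)
  expect_equal(unname(rowSums(tr[, 1:3])), rep(600, 25), tolerance = 1e-9)
  expect_equal(unname(tr[, "dead"]), rep(0, 25))
})

test_that("stationary alive distribution matches power iteration", {
  m <- build_transition_matrix(fixture_transition, 0.0004)
  pi_pkg <- stationary_alive_distribution(m)
  expect_equal(sum(pi_pkg), 1, tolerance = 1e-10)

  alive <- unclass(m)[1:3, 1:3]
  p <- alive / rowSums(alive)
  pi_oracle <- power_iteration_stationary(p)
  expect_equal(unname(pi_pkg), pi_oracle, tolerance = 1e-8)

  # uniform chain: exits 1/3 to each other state leaves rows (1/3,1/3,1/3)
  uni <- build_transition_matrix(
    c(mild_moderate = 1 / 3, mild_severe = 1 / 3,
      moderate_mild = 1 / 3, moderate_severe = 1 / 3,
      severe_mild = 1 / 3, severe_moderate = 1 / 3), 0)
  expect_equal(unname(stationary_alive_distribution(uni)), rep(1 / 3, 3),
               tolerance = 1e-12)

  # everything funnels into mild: stationary mass concentrates there
  funnel <- build_transition_matrix(
    c(moderate_mild = 1, severe_mild = 1), 0)
  expect_equal(unname(stationary_alive_distribution(funnel)), c(1, 0, 0),
               tolerance = 1e-10)
})

test_that("long-run cohort severity mix converges to the stationary vector", {
  m <- build_transition_matrix(fixture_transition, 0.0004)
  tr <- run_cohort(c(1000, 0, 0), m, 1e4)
  emp <- tr[nrow(tr), 1:3] / sum(tr[nrow(tr), 1:3])
  expect_equal(unname(emp), unname(stationary_alive_distribution(m)),
               tolerance = 1e-6)
})

test_that("trace exports round-trip through CSV", {
  m <- build_transition_matrix(fixture_transition, 0.0004)
  tr <- run_cohort(c(10, 20, 30), m, 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(tr, tmp)
  back <- read.csv(tmp)
  expect_equal(names(back), c("cycle", "mild", "moderate", "severe", "dead"))
  expect_equal(back$mild, unname(tr[, "mild"]))
})
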