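test_that("credibility interval matches the sorted-interpolation oracle", {
  ci <- credibility_interval(1:10000, 0.95)
  expect_equal(unname(ci), c(250.975, 9750.025))

  # brute-force oracle: sort + linear interpolation between order statistics
  oracle <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  set.seed(44)
  for (n in 2:50) {
    x <- rlnorm(n, 1, 0.7)
    ci <- credibility_interval(x, 0.95)
    expect_equal(ci[["lower"]], oracle(x, 0.025))
    expect_equal(ci[["upper"]], oracle(x, 0.975))
  }

  expect_equal(unname(credibility_interval(rep(3.3, 5))), c(3.3, 3.3))
  # symmetric sample: interval symmetric about the median
  x <- c(-(50:1), 50:1)
  ci <- credibility_interval(x)
  expect_equal(ci[["lower"]], -ci[["upper"]])
  expect_error(credibility_interval(1), "at least 2")
  expect_error(credibility_interval(1:10, 1.5), "level")
})

test_that("parameter draws pass through fixed values and stay in support", {
  pars <- fixture_parameter_table()
  drawn <- draw_parameters(pars, seed = 5)
  # fixed entries are untouched
  expect_equal(drawn$prevalence$fibromyalgia$mild$mean, 0)
  expect_equal(drawn$transition, pars$transition)  # fixed by default
  # uncertain entries become fixed sampled values
  expect_equal(drawn$death_prob$family, "fixed")
  expect_true(drawn$death_prob$mean != pars$death_prob$mean)

  # beta draws stay in [0,1]
  x <- draw_dist(dist_spec("beta", 0.099, 0.0819), 1e5)
  expect_true(all(x >= 0 & x <= 1))
  # anxiety-cost draws recover the published mean
  set.seed(10)
  y <- draw_dist(dist_spec("gamma", 14.55, 14.26), 1e5)
  expect_lt(abs(mean(y) - 14.55), 4 * sd(y) / sqrt(1e5))
})

test_that("per-parameter streams are stable under schema growth", {
  pars <- fixture_parameter_table()
  d1 <- draw_parameters(pars, seed = 9)
  grown <- pars
  grown$diseases <- c(pars$diseases, "neck_pain")
  grown$prevalence$neck_pain <- list(
    mild = dist_spec("beta", 0.01, 0.002),
    moderate = dist_spec("beta", 0.01, 0.002),
    severe = dist_spec("beta", 0.01, 0.002))
  grown$depression_paf$neck_pain <- dist_spec("beta", 0.01, 0.002)
  class(grown) <- "parameter_table"
  d2 <- draw_parameters(grown, seed = 9)
  # pre-existing parameters get identical draws despite the added disease
  expect_equal(d2$death_prob$mean, d1$death_prob$mean)
  expect_equal(d2$prevalence$knee_oa$mild$mean, d1$prevalence$knee_oa$mild$mean)
})

test_that("dirichlet_row mode perturbs transitions but keeps feasibility", {
  pars <- fixture_parameter_table()
  pars$transition_ess <- 200
  class(pars) <- "parameter_table"
  drawn <- draw_parameters(pars, seed = 2)
  expect_false(isTRUE(all.equal(drawn$transition,
                                fixture_parameter_table()$transition)))
  for (s in c("mild", "moderate", "severe")) {
    exits <- sum(unlist(drawn$transition[grep(paste0("^", s, "_"),
                                              names(drawn$transition))]))
    expect_lte(exits, 1)
    expect_gte(exits, 0)
  }
})

test_that("the PSA is a pure function of table, n_sims and seed", {
  sc <- generate_scenario("tiny", seed = 1)
  a <- run_psa(sc$parameters, n_sims = 60, seed = 123)
  b <- run_psa(sc$parameters, n_sims = 60, seed = 123)
  expect_identical(a, b)
  c2 <- run_psa(sc$parameters, n_sims = 60, seed = 124)
  expect_false(identical(a$mean, c2$mean))
  expect_error(run_psa(sc$parameters, n_sims = 1, seed = 1), "n_sims")
})

test_that("an all-fixed table gives zero-width intervals at the point result", {
  sc <- generate_scenario("tiny", seed = 1)
  pars <- sc$parameters
  fix_block <- function(block) lapply(block, function(d)
    lapply(d, function(s) paincost:::new_dist_spec("fixed", s$mean)))
  for (f in c("prevalence", "state_cost", "disutility", "workloss"))
    pars[[f]] <- fix_block(pars[[f]])
  pars$depression_paf <- lapply(pars$depression_paf, function(s)
    paincost:::new_dist_spec("fixed", s$mean))
  for (f in c("anxiety_paf", "death_prob", "depression_cost", "anxiety_cost"))
    pars[[f]] <- paincost:::new_dist_spec("fixed", pars[[f]]$mean)
  class(pars) <- "parameter_table"

  psa <- run_psa(pars, n_sims = 10, seed = 77)
  det <- evaluate_model(pars)$outcomes
  key <- paste(psa$outcome, psa$disease)
  det_val <- det$value[match(key, paste(det$outcome, det$disease))]
  expect_equal(psa$mean, det_val)
  expect_equal(psa$lower_95, det_val)
  expect_equal(psa$upper_95, det_val)
})

test_that("PSA mean of a linear outcome obeys the law of large numbers", {
  # fix everything except the gamma monthly depression cost; the depression
  # cost outcome is then linear in that single parameter, so the PSA mean
  # approaches the deterministic value with relative error < 3/sqrt(n)
  sc <- generate_scenario("tiny", seed = 1)
  pars <- sc$parameters
  fix_block <- function(block) lapply(block, function(d)
    lapply(d, function(s) paincost:::new_dist_spec("fixed", s$mean)))
  for (f in c("prevalence", "state_cost", "disutility", "workloss"))
    pars[[f]] <- fix_block(pars[[f]])
  pars$depression_paf <- lapply(pars$depression_paf, function(s)
    paincost:::new_dist_spec("fixed", s$mean))
  for (f in c("anxiety_paf", "death_prob", "anxiety_cost"))
    pars[[f]] <- paincost:::new_dist_spec("fixed", pars[[f]]$mean)
  class(pars) <- "parameter_table"

  n <- 1000
  psa <- run_psa(pars, n_sims = n, seed = 31)
  det <- evaluate_model(pars)$outcomes
  m_psa <- psa$mean[psa$outcome == "cost_depression" &
                      psa$disease == "five_mskd"]
  m_det <- det$value[det$outcome == "cost_depression" &
                       det$disease == "five_mskd"]
  expect_lt(abs(m_psa - m_det) / m_det, 3 / sqrt(n))
  # and the gamma draws induce a nondegenerate credibility interval
  expect_lt(psa$lower_95[psa$outcome == "cost_depression" &
                           psa$disease == "five_mskd"], m_psa)
})
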