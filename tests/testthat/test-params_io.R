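test_that("beta moment fit reproduces mean and se exactly", {
  p <- fit_beta_moments(0.5, 0.05)
  expect_equal(unname(p), c(49.5, 49.5))

  # symmetry: mean 1/2 always gives alpha = beta
  for (se in c(0.01, 0.1, 0.3)) {
    p <- fit_beta_moments(0.5, se)
    expect_equal(p[["alpha"]], p[["beta"]])
  }

  # analytic round trip over a parameter grid
  grid <- expand.grid(mean = c(0.0008, 0.053, 0.099, 0.322, 0.9),
                      cv = c(0.05, 0.3, 0.8))
  for (i in seq_len(nrow(grid))) {
    m <- grid$mean[i]; se <- grid$cv[i] * m
    if (se^2 >= m * (1 - m)) next
    mom <- paincost:::dist_moments(dist_spec("beta", m, se))
    expect_equal(mom[["mean"]], m, tolerance = 1e-10)
    expect_equal(mom[["sd"]], se, tolerance = 1e-10)
  }

  expect_error(fit_beta_moments(0.2, 0.5), "infeasible")
  expect_error(fit_beta_moments(1.2, 0.1), "strictly in")
})

test_that("gamma moment fit matches closed form and limits", {
  p <- fit_gamma_moments(14.55, 14.26)
  expect_equal(p[["shape"]], 1.04108679, tolerance = 1e-8)
  expect_equal(p[["rate"]], 0.0715523567, tolerance = 1e-8)

  expect_equal(fit_gamma_moments(7.3, 7.3)[["shape"]], 1)  # exponential

  mom <- paincost:::dist_moments(dist_spec("gamma", 61.29, 60.07))
  expect_equal(mom[["mean"]], 61.29, tolerance = 1e-10)
  expect_equal(mom[["sd"]], 60.07, tolerance = 1e-10)

  expect_error(fit_gamma_moments(-1, 2), "positive")
  expect_error(fit_gamma_moments(1, 0), "positive")
})

test_that("lognormal moment fit matches closed form and degenerates", {
  p <- fit_lognormal_moments(265.69, 0.42)
  sigma2 <- log(1 + (0.42 / 265.69)^2)
  expect_equal(p[["sigma"]], sqrt(sigma2), tolerance = 1e-12)
  expect_equal(p[["mu"]], log(265.69) - sigma2 / 2, tolerance = 1e-12)
  expect_equal(p[["sigma"]], 0.0015807887, tolerance = 1e-6)

  mom <- paincost:::dist_moments(dist_spec("lognormal", 27.12, 0.15))
  expect_equal(mom[["mean"]], 27.12, tolerance = 1e-10)
  expect_equal(mom[["sd"]], 0.15, tolerance = 1e-10)

  # se -> 0 collapses to a point mass at the mean
  p0 <- fit_lognormal_moments(8.51, 0)
  expect_equal(p0[["sigma"]], 0)
  expect_equal(exp(p0[["mu"]]), 8.51)
  expect_equal(draw_dist(dist_spec("lognormal", 8.51, 0), 5), rep(8.51, 5))

  expect_error(fit_lognormal_moments(0, 1), "positive")
})

test_that("sampling fitted distributions recovers the published moments", {
  n <- 1e5
  cases <- list(list(spec = dist_spec("beta", 0.099, 0.0819), seed = 11),
                list(spec = dist_spec("gamma", 83.26, 81.60), seed = 12),
                list(spec = dist_spec("lognormal", 8.51, 0.01), seed = 13))
  for (cs in cases) {
    set.seed(cs$seed)
    x <- draw_dist(cs$spec, n)
    mc_se <- sd(x) / sqrt(n)
    expect_lt(abs(mean(x) - cs$spec$mean), 4 * mc_se)
    expect_equal(sd(x), cs$spec$se, tolerance = 0.05)
  }
})

test_that("bundled parameter file loads, validates and round-trips", {
  path <- system.file("extdata", "mskd_parameters.json",
                      package = "paincost")
  pars <- load_parameters(path)
  expect_s3_class(pars, "parameter_table")
  expect_equal(pars$transition[["mild_moderate"]], 0.1841)
  expect_equal(pars, fixture_parameter_table())

  tmp <- withr::local_tempfile(fileext = ".json")
  write_parameters(pars, tmp)
  expect_equal(load_parameters(tmp), pars)

  # CSV export flattens every distribution-valued parameter
  csv <- withr::local_tempfile(fileext = ".csv")
  export_parameters_csv(pars, csv)
  flat <- read.csv(csv)
  expect_true(all(c("name", "disease", "severity", "mean", "se", "family")
                  %in% names(flat)))
  expect_true(any(flat$name == "prevalence" & flat$disease == "fibromyalgia"))
})

test_that("schema and invariant violations are reported by name", {
  pars <- fixture_parameter_table()
  tmp <- withr::local_tempfile(fileext = ".json")

  bad <- pars; bad$initial_split <- c(mild = 0.5, moderate = 0.5,
                                      severe = 0.5)
  class(bad) <- "parameter_table"
  rep <- validate_parameters(bad)
  expect_true(any(grepl("initial_split", rep$parameter)))
  write_parameters(bad, tmp)
  expect_error(load_parameters(tmp), "initial_split")

  # missing required key named in the error
  raw <- jsonlite::read_json(system.file("extdata", "mskd_parameters.json",
                                         package = "paincost"))
  raw$death_prob <- NULL
  jsonlite::write_json(raw, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(load_parameters(tmp), "death_prob")

  # unknown keys are rejected, not silently ignored
  raw <- jsonlite::read_json(system.file("extdata", "mskd_parameters.json",
                                         package = "paincost"))
  raw$discount_rate <- 0.03
  jsonlite::write_json(raw, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(load_parameters(tmp), "unknown key.*discount_rate")
})

test_that("validation flags Markov infeasibility and beta infeasibility", {
  pars <- fixture_parameter_table()
  expect_equal(nrow(validate_parameters(pars)), 0L)

  bad <- pars
  bad$transition[["moderate_mild"]] <- 0.9  # 0.9 + 0.2738 + death > 1
  class(bad) <- "parameter_table"
  rep <- validate_parameters(bad)
  expect_true(any(grepl("exit probabilities exceed 1", rep$rule)))

  bad2 <- pars
  bad2$prevalence$knee_oa$mild <- paincost:::new_dist_spec("beta", 0.2, 0.5)
  class(bad2) <- "parameter_table"
  rep2 <- validate_parameters(bad2)
  expect_true(any(grepl("beta moment infeasibility", rep2$rule)))
})
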