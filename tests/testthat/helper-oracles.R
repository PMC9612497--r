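# independent oracles used across tests

# left fixed vector of a row-stochastic matrix by brute-force power iteration
power_iteration_stationary <- function(p, iters = 10000L, tol = 1e-14) {
  v <- rep(1 / nrow(p), nrow(p))
  for (i in seq_len(iters)) {
    v2 <- as.numeric(v %*% p)
    v2 <- v2 / sum(v2)
    if (max(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  v
}

# day-by-day payment oracle for the Chilean subsidy rule: insurers pay each
# day from the 4th onward, and the whole period when the leave reaches 11 days
brute_subsidy_days <- function(duration) {
  vapply(duration, function(d) {
    if (d >= 11) return(d)
    sum(seq_len(d) >= 4)
  }, numeric(1))
}

# random feasible transition-exit sets (exits + death <= 1 per state)
random_exits <- function() {
  draw_row <- function() {
    x <- stats::runif(2)
    x / sum(x) * stats::runif(1, 0, 0.89)  # leaves room for death <= 0.1
  }
  m1 <- draw_row(); m2 <- draw_row(); m3 <- draw_row()
  c(mild_moderate = m1[1], mild_severe = m1[2],
    moderate_mild = m2[1], moderate_severe = m2[2],
    severe_mild = m3[1], severe_moderate = m3[2])
}

fixture_transition <- c(mild_moderate = 0.1841, mild_severe = 0.1070,
                        moderate_mild = 0.5555, moderate_severe = 0.2738,
                        severe_mild = 0.3315, severe_moderate = 0.5914)

# a constant-occupancy trace (identity transitions, no death)
constant_trace <- function(initial, cycles = 12) {
  run_cohort(initial, build_transition_matrix(numeric(0), 0), cycles)
}

# reported national estimates, reshaped for aggregation tests
reported_cost_components <- function() {
  rep_df <- reported_results()
  cost <- rep_df[rep_df$outcome %in% c("pain_management", "depression",
                                       "anxiety", "absenteeism",
                                       "productivity_losses"), ]
  five <- c("knee_oa", "hip_oa", "fibromyalgia", "shoulder_pain",
            "low_back_pain")
  comp <- cost[cost$disease %in% five, ]
  # the source's all-MSKD totals feed the catch-all disease rows
  tot <- cost[cost$disease == "total_mskd", ]
  tot$disease <- "all_mskd"
  out <- rbind(comp, tot)
  data.frame(disease = out$disease, domain = out$outcome, total = out$value)
}
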