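# stable 32-bit FNV-1a-style hash of a parameter name; combined with the
# master seed it gives each parameter its own reproducible RNG stream, so
# adding or removing one parameter never shuffles another's draws
stable_hash <- function(x) {
  h <- 216613626
  for (b in utf8ToInt(x)) {
    h <- bitwXor(as.integer(h %% 2147483647), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

param_stream_seed <- function(name, seed)
  as.integer((stable_hash(name) + as.numeric(seed) * 1000003) %% 2147483647)

# every uncertain (non-fixed, se > 0) scalar parameter of a table, as
# name -> dist_spec
uncertain_params <- function(table) {
  out <- list()
  put <- function(name, spec) {
    if (is_dist_spec(spec) && spec$family != "fixed" && spec$se > 0)
      out[[name]] <<- spec
  }
  for (field in c("prevalence", "state_cost", "disutility", "workloss"))
    for (d in names(table[[field]]))
      for (s in names(table[[field]][[d]]))
        put(paste(field, d, s, sep = "."), table[[field]][[d]][[s]])
  for (d in names(table$depression_paf))
    put(paste0("depression_paf.", d), table$depression_paf[[d]])
  put("anxiety_paf", table$anxiety_paf)
  put("death_prob", table$death_prob)
  put("depression_cost", table$depression_cost)
  put("anxiety_cost", table$anxiety_cost)
  out
}

# n draws per uncertain parameter, each from its own seeded stream;
# optionally joint Dirichlet draws per transition row when transition_ess set
draw_parameter_matrix <- function(table, n, seed) {
  specs <- uncertain_params(table)
  draws <- lapply(names(specs), function(nm)
    with_seed(param_stream_seed(nm, seed), draw_dist(specs[[nm]], n)))
  names(draws) <- names(specs)

  if (!is.null(table$transition_ess)) {
    ess <- table$transition_ess
    tr <- table$transition
    for (s in ALIVE_STATES) {
      keys <- TRANSITION_KEYS[startsWith(TRANSITION_KEYS, paste0(s, "_"))]
      exits <- unlist(tr[keys])
      stay <- 1 - sum(exits)  # alive-conditional stay probability
      alpha <- ess * c(exits, stay)
      if (any(alpha <= 0)) next
      mat <- with_seed(param_stream_seed(paste0("transition.", s), seed), {
        g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha,
                                                                 each = n)),
                    nrow = n)
        g / rowSums(g)
      })
      for (j in seq_along(keys))
        draws[[paste0("transition.", keys[j])]] <- mat[, j]
    }
  }
  draws
}

# replace each uncertain parameter of `table` by draw i, as fixed values
table_for_draw <- function(table, draws, i) {
  out <- table
  for (nm in names(draws)) {
    v <- draws[[nm]][i]
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (parts[1] == "transition") {
      out$transition[[parts[2]]] <- v
    } else if (length(parts) == 3L) {
      out[[parts[1]]][[parts[2]]][[parts[3]]] <- new_dist_spec("fixed", v)
    } else if (length(parts) == 2L) {
      out[[parts[1]]][[parts[2]]] <- new_dist_spec("fixed", v)
    } else {
      out[[nm]] <- new_dist_spec("fixed", v)
    }
  }
  out
}

#' Draw one sampled parameter table
#'
#' Replaces every uncertain parameter by an independent draw from its
#' method-of-moments fitted distribution; fixed parameters pass through
#' unchanged. Each parameter has its own RNG stream derived from a stable
#' hash of its name combined with `seed`, so draws are independent across
#' parameters and stable under schema growth.
#'
#' @param table A valid [parameter_table()].
#' @param seed Integer seed.
#' @return A parameter table whose uncertain entries are replaced by fixed
#'   sampled values.
#' @export
draw_parameters <- function(table, seed = 1L) {
  stopifnot(inherits(table, "parameter_table"))
  table_for_draw(table, draw_parameter_matrix(table, 1L, seed), 1L)
}

#' Empirical credibility interval
#'
#' The central `level` interval of a sample: the `(1 - level)/2` and
#' `1 - (1 - level)/2` empirical percentiles, computed with linear
#' interpolation between order statistics ([stats::quantile()] type 7, the
#' common default).
#'
#' @param samples Numeric vector, at least 2 values.
#' @param level Coverage level in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' credibility_interval(1:10000)  # c(250.975, 9750.025)
#' @export
credibility_interval <- function(samples, level = 0.95) {
  if (length(samples) < 2L)
    stop("credibility_interval: need at least 2 samples")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("credibility_interval: level must lie in (0, 1)")
  a <- (1 - level) / 2
  q <- stats::quantile(samples, probs = c(a, 1 - a), names = FALSE,
                       type = 7)
  c(lower = q[1], upper = q[2])
}

#' Probabilistic sensitivity analysis of the full pipeline
#'
#' Runs the deterministic pipeline (Markov cohort, cost accrual,
#' consequences) once per Monte-Carlo draw of the parameter table and
#' summarizes every outcome by its mean and 95% credibility interval
#' (2.5th/97.5th percentiles across draws). Work-loss outcomes are excluded:
#' they are estimated directly from record-level data with confidence
#' intervals (see [subsidy_cost()]). Identical `(table, n_sims, seed)` give
#' identical summaries. Draws whose pipeline evaluation fails are discarded
#' and counted; more than 1% discards aborts the run.
#'
#' @param table A valid [parameter_table()].
#' @param n_sims Number of Monte-Carlo draws (>= 2); 10,000 by default.
#' @param seed Integer master seed.
#' @param init_mode Severity seeding mode passed to the pipeline (see
#'   [evaluate_model()]).
#' @return An object of class `"psa_summary"`: data frame with columns
#'   `outcome`, `disease`, `mean`, `lower_95`, `upper_95`, `interval_kind`
#'   (`"credibility"`), `n_sims`, `seed`, plus attribute `n_discarded`.
#' @export
run_psa <- function(table, n_sims = 10000L, seed = 1L,
                    init_mode = c("consultation", "prevalence")) {
  stopifnot(inherits(table, "parameter_table"))
  if (n_sims < 2L) stop("run_psa: n_sims must be >= 2")
  init_mode <- match.arg(init_mode)
  n_sims <- as.integer(n_sims)

  draws <- draw_parameter_matrix(table, n_sims, seed)
  results <- vector("list", n_sims)
  failures <- character()
  for (i in seq_len(n_sims)) {
    res <- tryCatch(
      evaluate_model(table_for_draw(table, draws, i), init_mode = init_mode,
                     validate = FALSE),
      error = function(e) e)
    if (inherits(res, "error")) failures <- c(failures, conditionMessage(res))
    else results[[i]] <- res$outcomes
  }
  n_bad <- length(failures)
  if (n_bad > 0.01 * n_sims)
    stop("run_psa: ", n_bad, " of ", n_sims, " draws failed (> 1%); first: ",
         failures[1])
  results <- results[!vapply(results, is.null, logical(1))]

  key <- paste(results[[1]]$outcome, results[[1]]$disease, sep = "|")
  mat <- vapply(results, function(df) df$value, numeric(nrow(results[[1]])))
  mat <- matrix(mat, nrow = length(key))
  summ <- do.call(rbind, lapply(seq_along(key), function(j) {
    ci <- credibility_interval(mat[j, ], 0.95)
    data.frame(outcome = results[[1]]$outcome[j],
               disease = results[[1]]$disease[j],
               mean = mean(mat[j, ]), lower_95 = ci[["lower"]],
               upper_95 = ci[["upper"]], interval_kind = "credibility",
               n_sims = n_sims, seed = as.integer(seed))
  }))
  attr(summ, "n_discarded") <- n_bad
  class(summ) <- c("psa_summary", "data.frame")
  summ
}

#' @export
print.psa_summary <- function(x, ...) {
  cat(sprintf("<psa_summary> %d outcome(s), %d simulation(s), seed %d\n",
              nrow(x), x$n_sims[1], x$seed[1]))
  df <- as.data.frame(x)
  df$mean <- signif(df$mean, 6)
  df$lower_95 <- signif(df$lower_95, 6)
  df$upper_95 <- signif(df$upper_95, 6)
  print(df[c("outcome", "disease", "mean", "lower_95", "upper_95")],
        row.names = FALSE)
  invisible(x)
}
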