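#' Build the monthly transition matrix over pain-severity states
#'
#' Constructs the 4x4 row-stochastic matrix over (mild, moderate, severe,
#' dead). Death acts as an independent uniform monthly hazard competing with
#' the severity transitions; the probability of staying in a state is the
#' residual `1 - sum(exits) - death`. The dead row is absorbing.
#'
#' @param exits Named numeric vector of monthly probabilities for the six
#'   ordered alive-state pairs (`mild_moderate`, `mild_severe`,
#'   `moderate_mild`, `moderate_severe`, `severe_mild`, `severe_moderate`).
#'   Missing pairs default to 0.
#' @param death Monthly probability of death from other causes, applied
#'   identically to every alive state.
#' @return A `transition_matrix`: a 4x4 numeric matrix with dimnames
#'   `mild, moderate, severe, dead`, rows summing to 1.
#' @examples
#' m <- build_transition_matrix(
#'   c(mild_moderate = 0.1841, mild_severe = 0.1070,
#'     moderate_mild = 0.5555, moderate_severe = 0.2738,
#'     severe_mild = 0.3315, severe_moderate = 0.5914),
#'   death = 0.0004)
#' m["mild", ]  # stay probability 0.7085
#' @export
build_transition_matrix <- function(exits, death) {
  stopifnot(is.numeric(death), length(death) == 1L, death >= 0, death <= 1)
  full <- stats::setNames(numeric(length(TRANSITION_KEYS)), TRANSITION_KEYS)
  unknown <- setdiff(names(exits), TRANSITION_KEYS)
  if (length(unknown))
    stop("build_transition_matrix: unknown transition(s): ",
         paste(unknown, collapse = ", "))
  full[names(exits)] <- exits
  if (any(full < 0 | full > 1))
    stop("build_transition_matrix: probabilities must lie in [0,1]")

  m <- matrix(0, 4, 4, dimnames = list(ALL_STATES, ALL_STATES))
  for (s in ALIVE_STATES) {
    out <- full[grep(paste0("^", s, "_"), names(full))]
    if (sum(out) + death > 1 + 1e-12)
      stop("build_transition_matrix: infeasible row for state '", s,
           "': exits (", sum(out), ") + death (", death, ") exceed 1")
    for (k in names(out)) {
      to <- sub(paste0("^", s, "_"), "", k)
      m[s, to] <- out[[k]]
    }
    m[s, "dead"] <- death
    m[s, s] <- 1 - sum(out) - death
  }
  m["dead", "dead"] <- 1
  structure(m, class = c("transition_matrix", "matrix", "array"))
}

assert_transition_matrix <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4L, 4L)))
  if (any(m < -1e-12 | m > 1 + 1e-12))
    stop("transition matrix entries outside [0,1]")
  if (any(abs(rowSums(m) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1")
  if (!isTRUE(all.equal(unname(m[4L, ]), c(0, 0, 0, 1), tolerance = 1e-12)))
    stop("dead state must be absorbing")
  invisible(m)
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("<transition_matrix> monthly, states", paste(ALL_STATES,
                                                   collapse = " / "), "\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Simulate a closed cohort through the Markov model
#'
#' Propagates a closed cohort (no incident cases) through `cycles` monthly
#' steps: occupancy at cycle `t + 1` is occupancy at `t` times the transition
#' matrix. Total mass (alive + dead) is conserved and, because death is a
#' uniform hazard, the total alive after `t` cycles equals
#' `N * (1 - death)^t` for any severity transitions.
#'
#' @param initial Length-3 nonnegative counts in (mild, moderate, severe) at
#'   cycle 0.
#' @param matrix A [build_transition_matrix()] result.
#' @param cycles Number of monthly cycles (>= 1).
#' @return A `cohort_trace`: a `(cycles + 1) x 4` matrix of occupancy counts,
#'   rows named by cycle `0..cycles`, columns `mild, moderate, severe, dead`.
#' @examples
#' m <- build_transition_matrix(
#'   c(mild_moderate = 0.1841, mild_severe = 0.1070,
#'     moderate_mild = 0.5555, moderate_severe = 0.2738,
#'     severe_mild = 0.3315, severe_moderate = 0.5914), 0.0004)
#' tr <- run_cohort(c(750, 3250, 6000), m, 12)
#' sum(tr[13, c("mild", "moderate", "severe")])  # 10000 * 0.9996^12
#' @export
run_cohort <- function(initial, matrix, cycles) {
  if (length(initial) != 3L || any(!is.finite(initial)))
    stop("run_cohort: initial must be 3 finite alive-state counts")
  if (any(initial < 0))
    stop("run_cohort: initial counts must be nonnegative")
  stopifnot(length(cycles) == 1L, cycles >= 1)
  assert_transition_matrix(matrix)
  cycles <- as.integer(cycles)

  occ <- base::matrix(0, cycles + 1L, 4L,
                      dimnames = list(0:cycles, ALL_STATES))
  occ[1L, ] <- c(initial, 0)
  for (t in seq_len(cycles))
    occ[t + 1L, ] <- occ[t, ] %*% matrix
  structure(occ, class = c("cohort_trace", "matrix", "array"))
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace> %d cycle(s) of 1 month, cohort size %s\n",
              nrow(x) - 1L, format(sum(x[1L, ]), big.mark = ",")))
  print(utils::head(unclass(x), 13L), ...)
  if (nrow(x) > 13L) cat("  ...", nrow(x) - 13L, "more cycle(s)\n")
  invisible(x)
}

#' Convert a cohort trace to a data frame
#'
#' @param x A `cohort_trace`.
#' @param ... Unused.
#' @return A data frame with columns `cycle`, `mild`, `moderate`, `severe`,
#'   `dead`.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = as.integer(rownames(x)), unclass(x)[, , drop = FALSE],
             row.names = NULL)
}

#' Export a cohort trace as CSV
#'
#' @param trace A `cohort_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Stationary severity distribution of the alive chain
#'
#' Diagnostic for the severity process conditional on being alive: the 3x3
#' alive submatrix is renormalized by row (removing the uniform death
#' hazard) and its left fixed vector is returned. Computed from the left
#' eigendecomposition; an eigenvalue-1 eigenvector must exist for the
#' irreducible renormalized chain.
#'
#' @param matrix A [build_transition_matrix()] result.
#' @return Named length-3 vector of proportions over (mild, moderate,
#'   severe), summing to 1.
#' @export
stationary_alive_distribution <- function(matrix) {
  assert_transition_matrix(matrix)
  alive <- unclass(matrix)[ALIVE_STATES, ALIVE_STATES]
  rs <- rowSums(alive)
  if (any(rs <= 0))
    stop("stationary_alive_distribution: an alive state has no alive exit")
  p <- alive / rs
  e <- eigen(t(p))
  i <- which.min(abs(e$values - 1))
  if (abs(e$values[i] - 1) > 1e-8)
    stop("stationary_alive_distribution: no unit eigenvalue; ",
         "is the alive chain irreducible?")
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  if (any(v < -1e-10))
    stop("stationary_alive_distribution: negative stationary mass; ",
         "is the alive chain irreducible?")
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), ALIVE_STATES)
}
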