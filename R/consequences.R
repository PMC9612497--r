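#' Loss in health-state utilities (QALYs) attributable to chronic pain
#'
#' For each monthly cycle the alive occupancy of each severity state is
#' multiplied by that state's disutility and by the chronic-pain
#' attributable fraction, summed over states and cycles `1..T`, and scaled
#' by the cycle length in years (1/12). With that scaling a cohort that
#' spends the full year in a state loses exactly `disutility * paf` QALYs
#' per person, so utilities lost over the one-year horizon are QALYs.
#'
#' @param trace A [run_cohort()] trace (12 cycles for the one-year horizon).
#' @param disutility Named numeric vector: utility decrement per severity
#'   state (`mild`, `moderate`, `severe`), each in `[0, 1]`.
#' @param paf Chronic-pain attributable fraction of the disability, in
#'   `[0, 1]` (scalar per disease; defaults to 1).
#' @param cycle_years Length of one cycle in years (default 1/12).
#' @return QALYs lost (nonnegative real).
#' @examples
#' m <- build_transition_matrix(numeric(0), 0)
#' tr <- run_cohort(c(0, 0, 1000), m, 12)
#' lhsu(tr, c(mild = 0.02, moderate = 0.054, severe = 0.322))  # 322
#' @export
lhsu <- function(trace, disutility, paf = 1, cycle_years = 1 / 12) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (!is.numeric(paf) || paf < 0 || paf > 1)
    stop("lhsu: paf must lie in [0,1], got ", paf)
  if (!all(ALIVE_STATES %in% names(disutility)))
    stop("lhsu: disutility must name severities ",
         paste(ALIVE_STATES, collapse = ", "))
  if (any(disutility < 0 | disutility > 1))
    stop("lhsu: disutilities must lie in [0,1]")
  occ <- unclass(trace)[-1L, ALIVE_STATES, drop = FALSE]
  sum(occ %*% disutility[ALIVE_STATES]) * paf * cycle_years
}

#' Mental-health episodes attributable to chronic pain
#'
#' The number of depression (or anxiety) episodes attributed to a disease's
#' chronic pain is the attributable fraction applied to the prevalent
#' cases: `prevalent_cases * fraction`. The count is returned unrounded;
#' rendering rounds to whole episodes.
#'
#' @param prevalent_cases Number of prevalent chronic-pain cases.
#' @param fraction Attributable fraction (dPAF for depression, the all-MSKD
#'   fraction for anxiety), in `[0, 1]`.
#' @return Real-valued episode count, never exceeding `prevalent_cases`.
#' @examples
#' attributable_episodes(10000, 0.1315)  # 1315
#' @export
attributable_episodes <- function(prevalent_cases, fraction) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("attributable_episodes: fraction must lie in [0,1], got ", fraction)
  stopifnot(prevalent_cases >= 0)
  prevalent_cases * fraction
}
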