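# Discrete-hazard survival simulator.

#' Discrete daily hazard profile targeting a median survival day
#'
#' Builds a geometric-after-onset daily hazard: zero before `onset`, then a
#' constant per-day death probability chosen so cumulative survival crosses
#' 0.5 at the target median day.
#'
#' @param median_day Target median survival (postnatal day).
#' @param onset First day with nonzero hazard (default `median_day - 2`,
#'   giving the steep post-onset decline characteristic of early-lethality
#'   epilepsy cohorts).
#' @param max_day Length of the profile (days).
#' @return Numeric vector of daily death probabilities, length `max_day`.
#' @export
hazard_profile <- function(median_day, onset = median_day - 2, max_day = 90) {
  if (onset < 1 || median_day <= onset)
    stop("hazard_profile: need 1 <= onset < median_day")
  p <- 1 - 0.5^(1 / (median_day - onset + 0.5))
  h <- numeric(max_day)
  h[onset:max_day] <- p
  h
}

#' Simulate survival records from discrete hazard profiles
#'
#' Each subject's death day is the first day on which a Bernoulli draw at
#' that day's hazard succeeds; subjects surviving the whole profile are
#' censored at `censor_day`.
#'
#' @param groups Named list; each element a list with `hazard` (daily death
#'   probabilities, all in \[0,1\]) and `n` (subjects, >= 1).
#' @param seed RNG seed (required).
#' @param censor_day Administrative censoring day (default: hazard length).
#' @return Data frame of survival records: `subject`, `group`, `day`,
#'   `event` (1 = death, 0 = censored).
#' @export
simulate_survival <- function(groups, seed, censor_day = NULL) {
  if (length(groups) == 0 || is.null(names(groups)))
    stop("simulate_survival: groups must be a named list")
  for (g in groups) {
    if (any(g$hazard < 0 | g$hazard > 1))
      stop("simulate_survival: hazards must be probabilities in [0,1]")
    if (g$n < 1) stop("simulate_survival: n must be >= 1 per group")
  }
  with_seed(seed, {
    recs <- lapply(names(groups), function(label) {
      g <- groups[[label]]
      cd <- censor_day %||% length(g$hazard)
      day <- integer(g$n); event <- integer(g$n)
      for (i in seq_len(g$n)) {
        d_death <- NA_integer_
        for (d in seq_along(g$hazard)) {
          if (g$hazard[d] > 0 && runif(1) < g$hazard[d]) { d_death <- d; break }
        }
        if (!is.na(d_death) && d_death <= cd) {
          day[i] <- d_death; event[i] <- 1L
        } else {
          day[i] <- cd; event[i] <- 0L
        }
      }
      data.frame(subject = paste0(label, "_", seq_len(g$n)),
                 group = label, day = day, event = event)
    })
    do.call(rbind, recs)
  })
}
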