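# Kaplan-Meier estimation and the Mantel-Cox (log-rank) test, on the
# survival-record layout produced by simulate_survival().

#' Kaplan-Meier survival curve and median
#'
#' Product-limit estimator for one group of survival records, with
#' censoring. The median is the first day at which estimated survival
#' drops to 0.5 or below; it is NA (undefined) when survival never
#' reaches 0.5.
#'
#' @param records Survival data frame (`day`, `event`, optional `group`).
#' @param group If given, restrict to this group label.
#' @return Object of class `km_curve`: `curve` (data frame `day`,
#'   `survival`, `n_risk`, `n_event`), `median` (day or NA), `n`.
#' @export
km_estimate <- function(records, group = NULL) {
  if (!is.null(group)) records <- records[records$group == group, ]
  if (nrow(records) == 0) stop("km_estimate: no records")
  fit <- survival::survfit(survival::Surv(day, event) ~ 1, data = records)
  med <- unname(summary(fit)$table["median"])
  structure(list(curve = data.frame(day = fit$time, survival = fit$surv,
                                    n_risk = fit$n.risk,
                                    n_event = fit$n.event),
                 median = if (is.na(med)) NA_real_ else med,
                 n = nrow(records)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n = %d, median = %s\n", x$n,
              if (is.na(x$median)) "undefined" else format(x$median)))
  invisible(x)
}

#' Mantel-Cox (log-rank) test between survival groups
#'
#' Unweighted log-rank test with the standard hypergeometric variance at
#' tied death times.
#'
#' @param records Survival data frame with `group`, `day`, `event`;
#'   exactly 2 groups and at least one death required.
#' @return List: `chisq` (1 df), `p`.
#' @export
logrank_test <- function(records) {
  groups <- unique(records$group)
  if (length(groups) < 2)
    stop("logrank_test: need two groups")
  if (sum(records$event) == 0)
    stop("logrank_test: no deaths in either group")
  sd_ <- survival::survdiff(survival::Surv(day, event) ~ group,
                            data = records)
  df <- length(sd_$n) - 1
  list(chisq = unname(sd_$chisq),
       p = pchisq(sd_$chisq, df = df, lower.tail = FALSE))
}
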