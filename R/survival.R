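#' Kaplan-Meier product-limit estimate
#'
#' @param time Follow-up times (months, > 0).
#' @param event 1 = event, 0 = censored.
#' @return Data frame of class `nm_km`: `time` (distinct event/censor
#'   times in order), `n_risk`, `n_event`, `n_censor`, `surv` (product-
#'   limit estimate after `time`). Censored times do not drop the curve.
#' @export
km_estimate <- function(time, event) {
  stopif(length(time) == 0, "need at least one record")
  stopif(any(time <= 0), "times must be > 0")
  stopif(!all(event %in% c(0, 1)), "event must be 0/1")
  ut <- sort(unique(time))
  n <- length(time)
  s <- 1
  out <- data.frame(time = ut, n_risk = NA_real_, n_event = NA_real_,
                    n_censor = NA_real_, surv = NA_real_)
  for (i in seq_along(ut)) {
    at_risk <- sum(time >= ut[i])
    d <- sum(time == ut[i] & event == 1)
    c0 <- sum(time == ut[i] & event == 0)
    if (d > 0) s <- s * (1 - d / at_risk)
    out$n_risk[i] <- at_risk
    out$n_event[i] <- d
    out$n_censor[i] <- c0
    out$surv[i] <- s
  }
  class(out) <- c("nm_km", "data.frame")
  out
}

#' @export
plot.nm_km <- function(x, add = FALSE, ...) {
  t0 <- c(0, x$time)
  s0 <- c(1, x$surv)
  if (add) lines(t0, s0, type = "s", ...)
  else plot(t0, s0, type = "s", ylim = c(0, 1), xlab = "Time (months)",
            ylab = "Survival probability", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard 1-df chi-squared log-rank comparing event distributions of two
#' groups. With no events in either group the statistic is 0 and p = 1
#' (flagged).
#'
#' @param time,event Survival records.
#' @param group Two-level factor per record.
#' @return List: `statistic`, `df = 1`, `p`, `flag`.
#' @export
logrank_test <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  stopif(nlevels(group) != 2, "exactly two groups required")
  g1 <- group == levels(group)[1]
  if (sum(event) == 0)
    return(list(statistic = 0, df = 1, p = 1, flag = "no events"))
  ut <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (V < 1e-12) 0 else (O1 - E1)^2 / V
  list(statistic = stat, df = 1,
       p = pchisq(stat, 1, lower.tail = FALSE), flag = "ok")
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose risk ordering matches
#' observed survival ordering: a pair is comparable when the earlier time
#' is an event (at tied times, an event precedes a censoring); concordant
#' when the earlier-failing patient has the higher risk; tied risks count
#' one half. Tied event times are not comparable.
#'
#' @param risk Risk scores (higher = worse expected survival).
#' @param time,event Survival records.
#' @return c-index in [0, 1].
#' @export
concordance_index <- function(risk, time, event) {
  n <- length(risk)
  conc <- 0; comp <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) {
        if (event[i] == event[j]) next       # both events or both censored
        a <- if (event[i] == 1) i else j     # the event precedes
        b <- if (event[i] == 1) j else i
      } else {
        a <- if (time[i] < time[j]) i else j # earlier
        b <- if (time[i] < time[j]) j else i
        if (event[a] != 1) next
      }
      comp <- comp + 1
      if (risk[a] > risk[b]) conc <- conc + 1
      else if (risk[a] == risk[b]) conc <- conc + 0.5
    }
  }
  stopif(comp == 0, "no comparable pairs")
  conc / comp
}

#' Cox proportional-hazards wrapper
#'
#' Thin adapter over [survival::coxph()]: fits the model, returns the
#' hazard ratio with its 95% CI per covariate and the model concordance.
#' Non-convergence warnings are surfaced, not swallowed.
#'
#' @param time,event Survival records.
#' @param covariates Data frame (or vector) of covariates.
#' @return List: `hr`, `ci_lower`, `ci_upper`, `p`, `concordance`, `fit`.
#' @export
cox_wrapper <- function(time, event, covariates) {
  if (is.null(dim(covariates)))
    covariates <- data.frame(x = covariates)
  df <- cbind(data.frame(.time = time, .event = event), covariates)
  fit <- survival::coxph(
    survival::Surv(.time, .event) ~ ., data = df)
  s <- summary(fit)
  list(hr = s$conf.int[, "exp(coef)"],
       ci_lower = s$conf.int[, "lower .95"],
       ci_upper = s$conf.int[, "upper .95"],
       p = s$coefficients[, "Pr(>|z|)"],
       concordance = unname(s$concordance["C"]),
       fit = fit)
}
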