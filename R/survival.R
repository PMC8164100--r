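# Product-limit estimation and restricted mean survival time.  Fitting is
# delegated to survival::survfit; the RMST area/variance computation and the
# ratio test are implemented here.

#' Fit a Kaplan-Meier curve
#'
#' Product-limit estimate for one sample of right-censored times, with
#' Greenwood variance.  At tied times events are processed before censorings.
#'
#' @param times observed times (months), `>= 0`.
#' @param events event indicators (1 = event, 0 = censored).
#' @return An `rmdor_km` object: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` at each distinct observed time, `greenwood` (the cumulative
#'   Greenwood sum `sum d/(n(n-d))`, non-decreasing), `var` (the Greenwood
#'   variance `S(t)^2 * greenwood`), `max_followup` (largest observed time)
#'   and `n`.
#' @examples
#' km_fit(c(1, 2, 3), c(1, 0, 1))
#' @export
km_fit <- function(times, events) {
  if (length(times) == 0L) stop("empty input")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  d <- fit$n.event
  n <- fit$n.risk
  # Greenwood increment; where the curve hits zero (n == d) the increment is
  # undefined and capped at zero — the variance of an estimate fixed at 0.
  inc <- ifelse(n > d, d / (n * (n - d)), 0)
  gw <- cumsum(inc)
  structure(list(time = fit$time, n_risk = n, n_event = d,
                 n_censor = fit$n.censor, surv = fit$surv,
                 greenwood = gw, var = fit$surv^2 * gw,
                 max_followup = max(times), n = length(times)),
            class = "rmdor_km")
}

#' @export
print.rmdor_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n=%d, %d events, max follow-up %.3g months\n",
              x$n, sum(x$n_event), x$max_followup))
  invisible(x)
}

# Evaluate a right-continuous KM step function at arbitrary times,
# carrying the last value forward beyond the largest observed time.
km_surv_at <- function(curve, t) {
  ev <- curve$n_event > 0
  steps <- curve$time[ev]
  s <- curve$surv[ev]
  if (length(steps) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, steps)
  c(1, s)[idx + 1L]
}

#' Restricted mean survival time from a fitted KM curve
#'
#' The area under the Kaplan-Meier step function on `[0, tau]`, truncated at
#' the largest observed time when `tau` exceeds it, with the standard
#' large-sample variance (sum over event times of the squared remaining area
#' times the Greenwood increment).
#'
#' @param curve an `rmdor_km` from [km_fit()].
#' @param tau restriction horizon in months, `> 0`.
#' @return An `rmdor_rmst` object with `tau`, `tau_effective`
#'   (`min(tau, max_followup)`), `estimate` (months) and `variance`.
#' @examples
#' rmst(km_fit(c(1, 2, 3), c(1, 1, 1)), tau = 3)  # estimate 2.0
#' @export
rmst <- function(curve, tau) {
  stopifnot(inherits(curve, "rmdor_km"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a single positive number")
  tau_eff <- min(tau, curve$max_followup)
  ev <- curve$n_event > 0
  tt <- curve$time[ev]
  ss <- curve$surv[ev]
  keep <- tt < tau_eff
  tt <- tt[keep]
  ss <- ss[keep]
  # step-function area: S is 1 on [0, t_1), ss[i] on [t_i, t_{i+1})
  widths <- diff(c(0, tt, tau_eff))
  heights <- c(1, ss)
  est <- sum(widths * heights)
  # variance: sum over event times t_i < tau_eff of A_i^2 * d/(n(n-d)),
  # A_i = area under S from t_i to tau_eff
  if (length(tt) > 0L) {
    tail_areas <- rev(cumsum(rev(ss * diff(c(tt, tau_eff)))))
    inc <- ifelse(curve$n_risk[ev] > curve$n_event[ev],
                  curve$n_event[ev] /
                    (curve$n_risk[ev] * (curve$n_risk[ev] - curve$n_event[ev])),
                  0)[keep]
    variance <- sum(tail_areas^2 * inc)
  } else {
    variance <- 0
  }
  structure(list(tau = tau, tau_effective = tau_eff, estimate = est,
                 variance = variance), class = "rmdor_rmst")
}

#' @export
print.rmdor_rmst <- function(x, ...) {
  cat(sprintf("RMST up to tau=%.3g (effective %.3g): %.4f months (SE %.4f)\n",
              x$tau, x$tau_effective, x$estimate, sqrt(x$variance)))
  invisible(x)
}

new_test_result <- function(test, estimate = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p_value, tau = NA_real_,
                            method, statistic = NA_real_, degenerate = FALSE) {
  structure(list(test = test, tau = tau, estimate = estimate,
                 ci_low = ci_low, ci_high = ci_high, p_value = p_value,
                 statistic = statistic, method = method,
                 degenerate = degenerate),
            class = "rmdor_test")
}

#' @export
print.rmdor_test <- function(x, ...) {
  cat(sprintf("%s (%s)%s\n", x$test, x$method,
              if (x$degenerate) " [degenerate]" else ""))
  if (!is.na(x$tau)) cat(sprintf("  tau: %.3g months\n", x$tau))
  if (!is.na(x$estimate))
    cat(sprintf("  estimate: %.4f (95%% CI %.4f to %.4f)\n",
                x$estimate, x$ci_low, x$ci_high))
  cat(sprintf("  p-value: %.4g\n", x$p_value))
  invisible(x)
}

#' @export
as.data.frame.rmdor_test <- function(x, ...) {
  data.frame(test = x$test, tau = x$tau, estimate = x$estimate,
             ci_low = x$ci_low, ci_high = x$ci_high, p_value = x$p_value,
             method = x$method, degenerate = x$degenerate,
             stringsAsFactors = FALSE)
}

#' Two-sided unweighted log-rank test
#'
#' @param times_a,events_a times and event indicators for the first arm.
#' @param times_b,events_b times and event indicators for the second arm.
#' @return An `rmdor_test` with the chi-squared statistic and its p-value
#'   from the 1-df reference distribution.  If neither arm has any event the
#'   result is flagged degenerate with `p = 1`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  stopifnot(length(times_a) > 0L, length(times_b) > 0L)
  if (sum(events_a) + sum(events_b) == 0)
    return(new_test_result("LOGRANK_PFS", p_value = 1, method = "asymptotic",
                           degenerate = TRUE))
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp <- rep(c(0L, 1L), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  p <- pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  new_test_result("LOGRANK_PFS", p_value = p, method = "asymptotic",
                  statistic = sd$chisq)
}

#' RMST ratio test of progression-free survival
#'
#' Compares two arms by the ratio of restricted mean survival times at a
#' shared horizon `tau_eff = min(tau, max follow-up of either arm)`, with
#' normal-approximation inference on the log ratio (delta-method variance).
#'
#' @inheritParams logrank_test
#' @param tau restriction horizon in months.
#' @return An `rmdor_test` with `estimate` = RMST ratio (first over second
#'   arm) and a 95% confidence interval.  A warning is emitted when `tau` is
#'   truncated.
#' @export
rmst_ratio_test <- function(times_a, events_a, times_b, events_b, tau) {
  stopifnot(length(times_a) > 0L, length(times_b) > 0L, tau > 0)
  tau_eff <- min(tau, max(times_a), max(times_b))
  if (tau_eff < tau)
    warning(sprintf("tau=%.3g exceeds follow-up; truncated to %.3g",
                    tau, tau_eff))
  ra <- rmst(km_fit(times_a, events_a), tau_eff)
  rb <- rmst(km_fit(times_b, events_b), tau_eff)
  if (ra$estimate <= 0 || rb$estimate <= 0)
    stop("RMST of zero; ratio test undefined")
  log_ratio <- log(ra$estimate) - log(rb$estimate)
  se <- sqrt(ra$variance / ra$estimate^2 + rb$variance / rb$estimate^2)
  if (se == 0) {
    p <- if (abs(log_ratio) < 1e-12) 1 else 0
    ci <- exp(c(log_ratio, log_ratio))
  } else {
    z <- log_ratio / se
    p <- 2 * pnorm(-abs(z))
    ci <- exp(log_ratio + c(-1, 1) * qnorm(0.975) * se)
  }
  new_test_result("RMST_PFS", estimate = ra$estimate / rb$estimate,
                  ci_low = ci[1], ci_high = ci[2], p_value = p,
                  tau = tau_eff, method = "asymptotic",
                  statistic = if (se > 0) log_ratio / se else 0)
}
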