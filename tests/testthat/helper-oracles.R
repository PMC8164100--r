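# Shared fixtures and independent oracles for the test suite.

# The four-patient worked cohort: two responders (one converting to CR),
# two never-responders, all progressions observed.
worked_cohort <- function() {
  cohort(patient_id = c("A", "B", "C", "D"), arm = "arm1",
         t_response = c(2, 2, NA, NA),
         first_response_type = c("PR", "PR", NA, NA),
         t_cr = c(NA, 4, NA, NA),
         t_event = c(10, 12, 3, 6), pfs_event = 1)
}

# Random valid single-arm cohort, optionally censored, for property tests.
random_arm <- function(n, arm = "A", censor = TRUE, p_resp = 0.4,
                       p_cr = 0.3) {
  onset <- round(runif(n, 0.2, 6), 3)
  dur <- round(rexp(n, 0.15), 3)
  resp <- runif(n) < p_resp
  t_prog <- ifelse(resp, onset + dur, round(rexp(n, 0.25), 3) + 0.01)
  cens_t <- if (censor) round(runif(n, 0.5, 18), 3) else rep(Inf, n)
  t_event <- pmin(t_prog, cens_t)
  pfs_event <- as.integer(t_prog <= cens_t)
  seen_resp <- resp & onset <= t_event
  cr_dest <- runif(n) < p_cr
  conv <- ifelse(runif(n) < 0.5, 0, round(rexp(n, 0.3), 3))
  t_cr_lat <- onset + conv
  seen_cr <- seen_resp & cr_dest & t_cr_lat <= t_event
  cohort(
    patient_id = sprintf("%s%04d", arm, seq_len(n)), arm = arm,
    t_response = ifelse(seen_resp, onset, NA_real_),
    first_response_type = ifelse(!seen_resp, NA_character_,
                                 ifelse(seen_cr & conv == 0, "CR", "PR")),
    t_cr = ifelse(seen_cr, t_cr_lat, NA_real_),
    t_event = t_event, pfs_event = pfs_event
  )
}

# Brute-force per-patient time-in-state means for UNCENSORED data, truncated
# at tau.  Independent of the KM-difference construction: clips each
# patient's state interval to [0, tau] and averages.
oracle_state_means <- function(arm, tau) {
  clip <- function(t) pmin(t, tau)
  t_ev <- arm$t_event
  t_re <- ifelse(is.na(arm$t_response), Inf, arm$t_response)
  t_cr <- ifelse(is.na(arm$t_cr), Inf, arm$t_cr)
  list(
    rmst_pfs = mean(clip(t_ev)),
    dor = mean(pmax(0, clip(t_ev) - clip(pmin(t_re, t_ev)))),
    docr = mean(pmax(0, clip(t_ev) - clip(pmin(t_cr, t_ev)))),
    dopr = mean(pmax(0, clip(pmin(t_cr, t_ev)) - clip(pmin(t_re, t_ev)))),
    dosd = mean(clip(pmin(t_re, t_ev)))
  )
}

# Pearson chi-squared on a 2x2 responder table by the closed formula.
oracle_chisq_p <- function(a, b, c, d) {
  n <- a + b + c + d
  stat <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# Restricted mean DOR implied by an arm_config with no censoring, by 1-D
# numerical integration of the probability of being in response:
# p_resp * int_0^tau P(onset <= t < onset + duration) dt.
oracle_analytic_dor <- function(cfg, tau) {
  dens <- function(u, spec) {
    switch(spec$family,
           exponential = dexp(u, spec$rate),
           weibull = dweibull(u, spec$shape, spec$scale))
  }
  surv <- function(u, spec) {
    switch(spec$family,
           exponential = pexp(u, spec$rate, lower.tail = FALSE),
           weibull = pweibull(u, spec$shape, spec$scale, lower.tail = FALSE))
  }
  p_in_resp <- function(t) {
    vapply(t, function(ti) {
      stats::integrate(function(u)
        dens(u, cfg$dist_t_resp) * surv(ti - u, cfg$dist_resp_to_prog),
        lower = 0, upper = ti, rel.tol = 1e-9)$value
    }, numeric(1))
  }
  cfg$p_resp * stats::integrate(p_in_resp, 0, tau, rel.tol = 1e-8)$value
}
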