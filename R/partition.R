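# Restricted mean duration of response and the Q-TWiST partition of
# restricted mean PFS into durations of CR, PR and stable disease.
#
# The construction: for a horizon tau, the restricted mean time spent in
# response equals the area between the KM curve of PFS and the KM curve of
# the composite "response or progression/death, whichever first" time.
# Replacing first response by first CR gives the restricted mean duration of
# CR, and differences of these areas partition restricted mean PFS.

# Area under a fitted KM curve on [0, upto], carrying the last value forward
# past the largest observation (needed when one curve's follow-up ends before
# the shared horizon).  Mirrors the compiled routine exactly.
km_area_r <- function(curve, upto) {
  ev <- curve$n_event > 0
  tt <- curve$time[ev]
  ss <- curve$surv[ev]
  keep <- tt < upto
  tt <- tt[keep]
  ss <- ss[keep]
  sum(diff(c(0, tt, upto)) * c(1, ss))
}

#' Composite response/progression times for the KM-difference construction
#'
#' For each patient, the observed time to the earlier of response initiation
#' and the PFS event (`t0_resp`, event indicator `e0_resp`), the analogue for
#' first complete response (`t0_cr`, `e0_cr`), and the observed PFS time
#' itself (`t1`, `e1`).  A patient censored for PFS before responding is
#' censored for the composite at the same time.
#'
#' @param arm a single-arm `rmdor_cohort` (or any cohort; arms are ignored).
#' @return A data frame with columns `t0_resp`, `e0_resp`, `t0_cr`, `e0_cr`,
#'   `t1`, `e1`, one row per patient.
#' @export
composite_times <- function(arm) {
  validate_cohort(arm)
  has_resp <- !is.na(arm$t_response)
  has_cr <- !is.na(arm$t_cr)
  data.frame(
    t0_resp = ifelse(has_resp, arm$t_response, arm$t_event),
    e0_resp = as.integer(has_resp | arm$pfs_event == 1L),
    t0_cr = ifelse(has_cr, arm$t_cr, arm$t_event),
    e0_cr = as.integer(has_cr | arm$pfs_event == 1L),
    t1 = arm$t_event,
    e1 = arm$pfs_event
  )
}

#' Probability-of-being-in-response curve
#'
#' Estimates, at each grid time `t`, the probability that a randomized
#' patient is in objective response (CR or PR) and progression free:
#' the difference between the KM curve of PFS and the KM curve of the
#' composite response-or-progression time.  Small negative values from
#' estimation noise are clipped to zero (the clip count is recorded in the
#' `"n_clipped"` attribute).
#'
#' @param arm a single-arm `rmdor_cohort`.
#' @param tau_grid sorted positive evaluation times (months).
#' @return A data frame with columns `time` and `pbir`.
#' @export
pbir_curve <- function(arm, tau_grid) {
  if (nrow(arm) == 0L) stop("empty arm")
  stopifnot(all(tau_grid > 0), !is.unsorted(tau_grid))
  ct <- composite_times(arm)
  s_pfs <- km_surv_at(km_fit(ct$t1, ct$e1), tau_grid)
  s_comp <- km_surv_at(km_fit(ct$t0_resp, ct$e0_resp), tau_grid)
  pbir <- s_pfs - s_comp
  n_clip <- sum(pbir < 0)
  if (n_clip > 0) {
    message(n_clip, " negative PBIR value(s) clipped to 0")
    pbir <- pmax(pbir, 0)
  }
  structure(data.frame(time = tau_grid, pbir = pbir), n_clipped = n_clip)
}

#' Partition restricted mean PFS into response-state durations
#'
#' Computes restricted mean PFS up to `tau` and partitions it, in the
#' Q-TWiST fashion, into the restricted mean durations of complete response
#' (DOCR), partial response (DOPR) and stable disease (DOSD); the restricted
#' mean duration of response is `DOR = DOCR + DOPR`, and
#' `RMST_PFS = DOR + DOSD`.  All quantities are means over every randomized
#' patient, responders and non-responders alike, in months.
#'
#' When `tau` exceeds the arm's largest observed time it is truncated with a
#' warning; `tau_effective` records the horizon actually used.
#'
#' @param arm a single-arm `rmdor_cohort`.
#' @param tau restriction horizon in months, `> 0`.
#' @param n_boot number of stratified bootstrap resamples for per-component
#'   standard errors; `0` (default) skips them.
#' @param seed optional integer seed for the bootstrap.
#' @return An `rmdor_partition` object with fields `tau`, `tau_effective`,
#'   `rmst_pfs`, `dor`, `docr`, `dopr`, `dosd` and, when `n_boot > 0`, a
#'   named vector `boot_se`.
#' @examples
#' x <- cohort(patient_id = letters[1:4], arm = "A",
#'             t_response = c(2, 2, NA, NA),
#'             first_response_type = c("PR", "PR", NA, NA),
#'             t_cr = c(NA, 4, NA, NA),
#'             t_event = c(10, 12, 3, 6), pfs_event = 1)
#' rm_partition(x, tau = 12)
#' @export
rm_partition <- function(arm, tau, n_boot = 0, seed = NULL) {
  if (nrow(arm) == 0L) stop("empty arm")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("tau must be a single positive number")
  ct <- composite_times(arm)
  tau_eff <- min(tau, max(ct$t1))
  if (tau_eff < tau)
    warning(sprintf("tau=%.3g exceeds follow-up; truncated to %.3g",
                    tau, tau_eff))
  comp <- partition_components(ct, tau_eff)
  out <- c(list(tau = tau, tau_effective = tau_eff), comp)
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- nrow(ct)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      unlist(partition_components(ct[idx, , drop = FALSE], tau_eff))
    }, numeric(5))
    out$boot_se <- apply(boots, 1, stats::sd)
  }
  structure(out, class = "rmdor_partition")
}

partition_components <- function(ct, tau_eff) {
  a_pfs <- km_area_r(km_fit(ct$t1, ct$e1), tau_eff)
  a_resp <- km_area_r(km_fit(ct$t0_resp, ct$e0_resp), tau_eff)
  a_cr <- km_area_r(km_fit(ct$t0_cr, ct$e0_cr), tau_eff)
  dor <- a_pfs - a_resp
  docr <- a_pfs - a_cr
  list(rmst_pfs = a_pfs, dor = dor, docr = docr, dopr = dor - docr,
       dosd = a_pfs - dor)
}

#' @export
print.rmdor_partition <- function(x, ...) {
  cat(sprintf("Restricted mean PFS partition up to tau=%.3g months (effective %.3g)\n",
              x$tau, x$tau_effective))
  comp <- c(RMST_PFS = x$rmst_pfs, DOR = x$dor, DOCR = x$docr,
            DOPR = x$dopr, DOSD = x$dosd)
  for (nm in names(comp)) {
    se_txt <- if (!is.null(x$boot_se)) {
      key <- c(RMST_PFS = "rmst_pfs", DOR = "dor", DOCR = "docr",
               DOPR = "dopr", DOSD = "dosd")[[nm]]
      sprintf(" (boot SE %.3f)", x$boot_se[[key]])
    } else ""
    cat(sprintf("  %-8s %7.4f months%s\n", nm, comp[[nm]], se_txt))
  }
  invisible(x)
}

#' @export
as.data.frame.rmdor_partition <- function(x, ...) {
  data.frame(tau = x$tau, tau_effective = x$tau_effective,
             rmst_pfs = x$rmst_pfs, dor = x$dor, docr = x$docr,
             dopr = x$dopr, dosd = x$dosd)
}

state_pair <- function(ct, state) {
  switch(state,
         DOR = list(t1 = ct$t1, e1 = ct$e1, t0 = ct$t0_resp, e0 = ct$e0_resp),
         DOCR = list(t1 = ct$t1, e1 = ct$e1, t0 = ct$t0_cr, e0 = ct$e0_cr),
         DOPR = list(t1 = ct$t0_cr, e1 = ct$e0_cr,
                     t0 = ct$t0_resp, e0 = ct$e0_resp),
         stop("unknown state: ", state))
}

#' Treatment effect on a restricted mean response duration
#'
#' Compares two arms on the restricted mean duration of response (DOR),
#' complete response (DOCR) or partial response (DOPR) at a shared horizon
#' `tau_eff = min(tau, both arms' maximum follow-up)`.  The point estimate is
#' the ratio (first over second arm) of the restricted mean durations; the
#' 95% CI is a stratified percentile bootstrap over patients within arm; the
#' two-sided p-value is a permutation test of the *difference* in restricted
#' means under arm-label exchange, with add-one correction
#' `p = (1 + #(|diff*| >= |diff|)) / (n_perm + 1)`.  Testing the difference
#' keeps the test well defined when a resample has no responders; by the
#' asymptotic equivalence of difference- and ratio-based tests the two carry
#' the same information.
#'
#' @param arm_a,arm_b single-arm `rmdor_cohort`s.
#' @param tau restriction horizon in months.
#' @param state one of `"DOR"`, `"DOCR"`, `"DOPR"`.
#' @param n_boot bootstrap resamples for the CI (`0` skips the CI).
#' @param n_perm permutation resamples for the p-value.
#' @param seed integer seed for the resampling.
#' @return An `rmdor_test` with `method = "permutation"`.  When both arms
#'   have zero patients ever in the state the result is flagged degenerate
#'   with `p = 1` and an absent estimate.
#' @export
duration_effect <- function(arm_a, arm_b, tau, state = c("DOR", "DOCR", "DOPR"),
                            n_boot = 1000, n_perm = 1000, seed = NULL) {
  state <- match.arg(state)
  if (nrow(arm_a) == 0L || nrow(arm_b) == 0L) stop("empty arm")
  stopifnot(tau > 0, n_perm >= 1)
  ct_a <- composite_times(arm_a)
  ct_b <- composite_times(arm_b)
  tau_eff <- min(tau, max(ct_a$t1), max(ct_b$t1))
  pa <- state_pair(ct_a, state)
  pb <- state_pair(ct_b, state)
  mean_a <- km_area_r(km_fit(pa$t1, pa$e1), tau_eff) -
    km_area_r(km_fit(pa$t0, pa$e0), tau_eff)
  mean_b <- km_area_r(km_fit(pb$t1, pb$e1), tau_eff) -
    km_area_r(km_fit(pb$t0, pb$e0), tau_eff)
  if (mean_a == 0 && mean_b == 0)
    return(new_test_result(state, p_value = 1, tau = tau_eff,
                           method = "permutation", degenerate = TRUE))
  t1 <- c(pa$t1, pb$t1); e1 <- c(pa$e1, pb$e1)
  t0 <- c(pa$t0, pb$t0); e0 <- c(pa$e0, pb$e0)
  arm <- rep(c(0L, 1L), c(nrow(ct_a), nrow(ct_b)))
  obs_diff <- mean_a - mean_b
  if (!is.null(seed)) set.seed(seed)
  count <- .perm_count_cpp(t1, as.integer(e1), t0, as.integer(e0), arm,
                           tau_eff, obs_diff, as.integer(n_perm))
  p <- (1 + count) / (n_perm + 1)
  est <- if (mean_b > 0) mean_a / mean_b else Inf
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    ratios <- .boot_ratio_cpp(t1, as.integer(e1), t0, as.integer(e0), arm,
                              tau_eff, as.integer(n_boot))
    ok <- ratios[is.finite(ratios)]
    if (length(ok) >= 2) ci <- unname(stats::quantile(ok, c(0.025, 0.975)))
    if (length(ok) < n_boot)
      message(n_boot - length(ok),
              " bootstrap resample(s) with zero denominator dropped")
  }
  new_test_result(state, estimate = est, ci_low = ci[1], ci_high = ci[2],
                  p_value = p, tau = tau_eff, method = "permutation",
                  statistic = obs_diff)
}
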