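# Objective response rate and its chi-squared comparison.

#' Objective response rate of one arm
#'
#' A responder is any patient whose first CR or PR was observed during
#' follow-up (`t_response` present); confirmation scans and minimum-duration
#' rules are outside the data model.
#'
#' @param arm a single-arm `rmdor_cohort`.
#' @return A list with `n`, `n_resp` and `rate`.
#' @export
orr <- function(arm) {
  if (nrow(arm) == 0L) stop("empty arm")
  n_resp <- sum(!is.na(arm$t_response))
  list(n = nrow(arm), n_resp = n_resp, rate = n_resp / nrow(arm))
}

#' Chi-squared test of objective response rates
#'
#' Pearson chi-squared on the 2x2 responder table, by default without
#' continuity correction.  The estimate is the rate difference (first minus
#' second arm) with a normal-approximation 95% CI.
#'
#' @param arm_a,arm_b single-arm `rmdor_cohort`s.
#' @param correct apply the Yates continuity correction (default `FALSE`).
#' @return An `rmdor_test`.  A pooled table with zero responders or zero
#'   non-responders is degenerate: `p = 1`, flagged.
#' @export
orr_chisq_test <- function(arm_a, arm_b, correct = FALSE) {
  oa <- orr(arm_a)
  ob <- orr(arm_b)
  diff <- oa$rate - ob$rate
  se <- sqrt(oa$rate * (1 - oa$rate) / oa$n + ob$rate * (1 - ob$rate) / ob$n)
  ci <- diff + c(-1, 1) * qnorm(0.975) * se
  pooled_resp <- oa$n_resp + ob$n_resp
  if (pooled_resp == 0 || pooled_resp == oa$n + ob$n)
    return(new_test_result("CHISQ_ORR", estimate = diff, ci_low = ci[1],
                           ci_high = ci[2], p_value = 1,
                           method = "asymptotic", degenerate = TRUE))
  tab <- rbind(c(oa$n_resp, oa$n - oa$n_resp),
               c(ob$n_resp, ob$n - ob$n_resp))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  new_test_result("CHISQ_ORR", estimate = diff, ci_low = ci[1],
                  ci_high = ci[2], p_value = unname(ct$p.value),
                  method = "asymptotic", statistic = unname(ct$statistic))
}
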