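# Multi-state synthetic trial generator.  Patients follow a monotone
# deepening trajectory: a responder fraction with an onset time, optional
# PR-to-CR conversion, durable post-response progression; non-responders
# progress on their own (shorter) clock; independent exponential dropout and
# optional snapping of onset times to an assessment grid.

#' Specify a parametric distribution for the generator
#'
#' @param family `"exponential"` (parameter `rate`, per month),
#'   `"weibull"` (`shape`, `scale` in months) or `"fixed"` (degenerate at
#'   `value` months).
#' @param ... the family's parameters, all positive (`value >= 0`).
#' @return A `dist_spec` list.
#' @examples
#' dist_spec("exponential", rate = 0.1)
#' dist_spec("weibull", shape = 1.6, scale = 4)
#' @export
dist_spec <- function(family = c("exponential", "weibull", "fixed"), ...) {
  family <- match.arg(family)
  pars <- list(...)
  needed <- switch(family, exponential = "rate",
                   weibull = c("shape", "scale"), fixed = "value")
  if (!setequal(names(pars), needed))
    stop(family, " requires parameter(s): ", paste(needed, collapse = ", "))
  vals <- unlist(pars[needed])
  if (any(!is.finite(vals)) || any(vals < 0) ||
      (family != "fixed" && any(vals <= 0)))
    stop("distribution parameters must be positive")
  structure(c(list(family = family), pars[needed]), class = "dist_spec")
}

r_dist <- function(n, spec) {
  switch(spec$family,
         exponential = rexp(n, rate = spec$rate),
         weibull = rweibull(n, shape = spec$shape, scale = spec$scale),
         fixed = rep(spec$value, n))
}

# survival function P(X > t); used by calibration and test oracles
s_dist <- function(t, spec) {
  switch(spec$family,
         exponential = exp(-spec$rate * t),
         weibull = exp(-(t / spec$scale)^spec$shape),
         fixed = as.numeric(t < spec$value))
}

#' Configure one synthetic trial arm
#'
#' @param p_resp probability a patient ever responds (CR or PR).
#' @param p_cr_given_resp probability a responder eventually converts to (or
#'   starts in) CR.
#' @param dist_t_resp [dist_spec()] for the response onset time (months from
#'   randomization).
#' @param dist_pr_to_cr [dist_spec()] for the PR-to-CR conversion time after
#'   onset, or the string `"immediate"` (CR is the first response).
#' @param dist_resp_to_prog [dist_spec()] for progression/death after
#'   response onset.
#' @param dist_nonresp_prog [dist_spec()] for progression/death of
#'   never-responders, from randomization.
#' @param dropout_rate exponential censoring hazard per month (`>= 0`);
#'   pre-administrative dropout.
#' @param assessment_interval months between response assessments; onset and
#'   CR times are snapped up to the next multiple (never past the PFS time),
#'   or `NULL` (default) for continuous times.
#' @return An `arm_config` list.
#' @export
arm_config <- function(p_resp, p_cr_given_resp, dist_t_resp,
                       dist_pr_to_cr = "immediate", dist_resp_to_prog,
                       dist_nonresp_prog, dropout_rate = 0,
                       assessment_interval = NULL) {
  stopifnot(p_resp >= 0, p_resp <= 1, p_cr_given_resp >= 0,
            p_cr_given_resp <= 1, dropout_rate >= 0,
            inherits(dist_t_resp, "dist_spec"),
            inherits(dist_resp_to_prog, "dist_spec"),
            inherits(dist_nonresp_prog, "dist_spec"))
  if (!identical(dist_pr_to_cr, "immediate") &&
      !inherits(dist_pr_to_cr, "dist_spec"))
    stop("dist_pr_to_cr must be a dist_spec or \"immediate\"")
  if (!is.null(assessment_interval)) stopifnot(assessment_interval > 0)
  structure(list(p_resp = p_resp, p_cr_given_resp = p_cr_given_resp,
                 dist_t_resp = dist_t_resp, dist_pr_to_cr = dist_pr_to_cr,
                 dist_resp_to_prog = dist_resp_to_prog,
                 dist_nonresp_prog = dist_nonresp_prog,
                 dropout_rate = dropout_rate,
                 assessment_interval = assessment_interval),
            class = "arm_config")
}

#' Configure a two-arm scenario
#'
#' @param name scenario label.
#' @param arm_configs named list of exactly two [arm_config()]s; the names
#'   become the cohort's arm labels.
#' @param truth_label `"alternative"` if the arms differ, `"null"` if not;
#'   `"null"` requires identical configurations.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(name, arm_configs,
                            truth_label = c("alternative", "null")) {
  truth_label <- match.arg(truth_label)
  stopifnot(is.list(arm_configs), length(arm_configs) == 2L,
            !is.null(names(arm_configs)), all(nzchar(names(arm_configs))),
            all(vapply(arm_configs, inherits, logical(1), "arm_config")))
  if (truth_label == "null" &&
      !isTRUE(all.equal(unclass(arm_configs[[1]]), unclass(arm_configs[[2]]))))
    stop("truth_label \"null\" requires identical arm configurations")
  structure(list(name = name, arm_configs = arm_configs,
                 truth_label = truth_label), class = "scenario_config")
}

# bounded integer substream seed derived from a root seed; exact in double
# arithmetic for root < 2^31
derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483647) * 69069 + 12345 + k) %%
               2147483647)
}

simulate_arm_records <- function(cfg, n) {
  resp <- runif(n) < cfg$p_resp
  t_resp <- r_dist(n, cfg$dist_t_resp)
  cr_dest <- runif(n) < cfg$p_cr_given_resp
  conv <- if (identical(cfg$dist_pr_to_cr, "immediate")) rep(0, n)
          else r_dist(n, cfg$dist_pr_to_cr)
  dur <- r_dist(n, cfg$dist_resp_to_prog)
  prog_nr <- r_dist(n, cfg$dist_nonresp_prog)
  dropout <- if (cfg$dropout_rate > 0) rexp(n, cfg$dropout_rate) else rep(Inf, n)

  t_prog <- ifelse(resp, t_resp + dur, prog_nr)
  t_event <- pmin(t_prog, dropout)
  pfs_event <- as.integer(t_prog <= dropout)
  t_cr_lat <- ifelse(resp & cr_dest, t_resp + conv, NA_real_)

  if (!is.null(cfg$assessment_interval)) {
    step <- cfg$assessment_interval
    snap <- function(t) step * ceiling(t / step)
    t_resp_s <- pmin(snap(t_resp), t_event)
    t_cr_lat <- ifelse(is.na(t_cr_lat), NA_real_,
                       pmax(pmin(snap(t_cr_lat), t_event), t_resp_s))
  } else {
    t_resp_s <- t_resp
  }
  seen_resp <- resp & t_resp <= t_event
  seen_cr <- !is.na(t_cr_lat) & seen_resp & t_cr_lat <= t_event
  data.frame(
    t_response = ifelse(seen_resp, t_resp_s, NA_real_),
    first_response_type = ifelse(!seen_resp, NA_character_,
                                 ifelse(seen_cr & t_cr_lat == t_resp_s,
                                        "CR", "PR")),
    t_cr = ifelse(seen_cr, t_cr_lat, NA_real_),
    t_event = t_event,
    pfs_event = pfs_event,
    stringsAsFactors = FALSE
  )
}

#' Simulate patients from one arm configuration
#'
#' Draws independent multi-state trajectories: responder status, response
#' onset, optional CR conversion, progression after onset (responders) or
#' from randomization (never-responders), and exponential dropout.  Because
#' a responder's progression clock starts at onset, `t_response <= t_event`
#' always holds; a dropout before onset leaves the response unobserved.
#'
#' @param cfg an [arm_config()].
#' @param n number of patients.
#' @param arm arm label for the records.
#' @param id_prefix prefix for generated patient ids.
#' @return An `rmdor_cohort` of `n` records.  Uses the current RNG state;
#'   see [simulate_cohort()] for seeded generation.
#' @export
simulate_arm <- function(cfg, n, arm = "A", id_prefix = arm) {
  stopifnot(inherits(cfg, "arm_config"), n >= 1)
  rec <- simulate_arm_records(cfg, n)
  rec$patient_id <- sprintf("%s_%05d", id_prefix, seq_len(n))
  rec$arm <- arm
  rec$t_os <- NA_real_
  rec$os_event <- NA_integer_
  as_cohort(rec)
}

#' Simulate one patient (single-record cohort)
#' @inheritParams simulate_arm
#' @return A one-record `rmdor_cohort`.
#' @export
simulate_patient <- function(cfg, arm = "A") simulate_arm(cfg, 1L, arm = arm)

#' Simulate a two-arm trial cohort
#'
#' Reproducible given `(scenario, n_per_arm, seed)`: each arm is generated
#' from its own derived substream, so the arms' draws are mutually
#' independent and insensitive to the order of generation.
#'
#' @param scenario a [scenario_config()] or preset name (see
#'   [scenario_preset()]).
#' @param n_per_arm patients per arm.
#' @param seed integer root seed.
#' @return An `rmdor_cohort` with both arms.
#' @export
simulate_cohort <- function(scenario, n_per_arm, seed) {
  if (is.character(scenario)) scenario <- scenario_preset(scenario)
  stopifnot(inherits(scenario, "scenario_config"), n_per_arm >= 1)
  parts <- lapply(seq_along(scenario$arm_configs), function(i) {
    set.seed(derive_seed(seed, i))
    simulate_arm(scenario$arm_configs[[i]], n_per_arm,
                 arm = names(scenario$arm_configs)[i])
  })
  out <- do.call(rbind, lapply(parts, as.data.frame))
  as_cohort(out)
}

#' Inject uniform administrative censoring up to a horizon
#'
#' Emulates the limited follow-up and staggered accrual of a phase 2 trial:
#' each patient draws an independent censoring time `C ~ Uniform(lower, tau)`
#' and the observed PFS time becomes `min(t_event, C)` (censored when `C`
#' falls first).  Response and CR times later than the new observed time are
#' dropped, as they would not yet have been seen.
#'
#' @param x an `rmdor_cohort`.
#' @param tau censoring horizon in months, `> 0`.
#' @param seed optional integer seed.
#' @param lower lower bound of the censoring support (default 0; an
#'   accrual-window style `Uniform(lower, tau)` is also supported).
#' @return The censored `rmdor_cohort`.
#' @export
apply_admin_censoring <- function(x, tau, seed = NULL, lower = 0) {
  stopifnot(tau > 0, lower >= 0, lower < tau)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x)
  cens <- runif(n, lower, tau)
  new_event <- pmin(x$t_event, cens)
  x$pfs_event <- ifelse(cens < x$t_event, 0L, x$pfs_event)
  x$t_event <- new_event
  drop_cr <- !is.na(x$t_cr) & x$t_cr > new_event
  x$t_cr[drop_cr] <- NA_real_
  drop_resp <- !is.na(x$t_response) & x$t_response > new_event
  x$t_response[drop_resp] <- NA_real_
  x$first_response_type[drop_resp] <- NA_character_
  # a first response of type CR loses its t_cr only together with t_response
  validate_cohort(x)
  x
}
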