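# Resampling simulator of randomized phase 2 screening trials: draw many
# two-arm trials (from a scenario generator or by resampling a completed
# trial), inject uniform administrative censoring at each horizon, run the
# test battery, and tabulate rejection proportions.

BATTERY_TESTS <- c("LOGRANK_PFS", "CHISQ_ORR", "RMST_PFS",
                   "DOR", "DOCR", "DOPR")

#' Configure an operating-characteristics simulation
#'
#' @param source a [scenario_config()] (or preset name) to generate trials
#'   from, or an `rmdor_cohort` to resample patients from.
#' @param n_per_arm patients per arm in each simulated trial (50 and 100 are
#'   the conventional phase 2 sizes; any positive value is allowed).
#' @param n_replicates number of simulated trials (default 5000).
#' @param taus evaluation horizons in months (default `c(6, 9, 12)`); each
#'   trial is censored and analyzed separately at each horizon.
#' @param alphas two-sided significance levels (default `c(.05, .10)`).
#' @param tests subset of
#'   `c("LOGRANK_PFS", "CHISQ_ORR", "RMST_PFS", "DOR", "DOCR", "DOPR")`.
#' @param n_perm permutations per duration test (default 500 inside large
#'   runs; raise for final analyses).
#' @param n_boot bootstrap resamples per duration test (default 0: the
#'   rejection decision needs only the permutation p-value).
#' @param seed integer root seed; every replicate draws from its own derived
#'   substream, so results do not depend on execution order.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(source, n_per_arm = 50, n_replicates = 5000,
                              taus = c(6, 9, 12), alphas = c(0.05, 0.10),
                              tests = BATTERY_TESTS, n_perm = 500,
                              n_boot = 0, seed = 1L) {
  if (is.character(source)) source <- scenario_preset(source)
  stopifnot(inherits(source, "scenario_config") ||
              inherits(source, "rmdor_cohort"))
  if (inherits(source, "rmdor_cohort") && length(arms(source)) != 2L)
    stop("a resampling source cohort must have exactly 2 arms")
  bad <- setdiff(tests, BATTERY_TESTS)
  if (length(bad) > 0L)
    stop("unknown test(s): ", paste(bad, collapse = ", "))
  stopifnot(n_per_arm >= 1, n_replicates >= 1, all(taus > 0),
            all(alphas > 0 & alphas < 1), n_perm >= 1, n_boot >= 0)
  structure(list(source = source, n_per_arm = n_per_arm,
                 n_replicates = as.integer(n_replicates), taus = taus,
                 alphas = alphas, tests = tests, n_perm = as.integer(n_perm),
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Resample a randomized trial from a completed cohort
#'
#' Draws `n_per_arm` patients with replacement within each arm (equal
#' randomization), re-keying patient ids to stay unique.
#'
#' @param source an `rmdor_cohort` with the arms to resample.
#' @param n_per_arm patients per arm.
#' @return An `rmdor_cohort` of `2 * n_per_arm` records (for a two-arm
#'   source).  Uses the current RNG state.
#' @export
resample_trial <- function(source, n_per_arm) {
  stopifnot(inherits(source, "rmdor_cohort"), n_per_arm >= 1)
  parts <- lapply(arms(source), function(lab) {
    sub <- as.data.frame(source[source$arm == lab, , drop = FALSE])
    out <- sub[sample.int(nrow(sub), n_per_arm, replace = TRUE), , drop = FALSE]
    out$patient_id <- sprintf("%s_r%05d", lab, seq_len(n_per_arm))
    out
  })
  as_cohort(do.call(rbind, parts))
}

#' Run the test battery on one two-arm trial
#'
#' Applies the selected tests to an (already censored) trial: the log-rank
#' test of PFS and the chi-squared test of ORR once, and the RMST ratio and
#' restricted mean duration tests at each horizon in `taus`.  Degenerate
#' trials (no events, no responders) yield flagged `p = 1` results rather
#' than errors, so a simulation run survives every resample.
#'
#' @param trial a two-arm `rmdor_cohort`.
#' @param taus horizons (months) for the horizon-dependent tests.
#' @param tests subset of the battery (see [simulation_config()]).
#' @param n_boot,n_perm resampling sizes for the duration tests.
#' @param tau_context the horizon under which `trial` was censored, recorded
#'   on the horizon-free tests (log-rank, chi-squared); default `NA`.
#' @return A data frame with one row per test result: `test`, `tau`,
#'   `estimate`, `ci_low`, `ci_high`, `p_value`, `method`, `degenerate`.
#' @export
run_battery <- function(trial, taus, tests = BATTERY_TESTS, n_boot = 0,
                        n_perm = 500, tau_context = NA_real_) {
  labs <- arms(trial)
  if (length(labs) != 2L) stop("trial must have exactly 2 arms")
  a <- cohort_arm(trial, labs[1])
  b <- cohort_arm(trial, labs[2])
  res <- list()
  if ("LOGRANK_PFS" %in% tests) {
    r <- logrank_test(a$t_event, a$pfs_event, b$t_event, b$pfs_event)
    r$tau <- tau_context
    res <- c(res, list(r))
  }
  if ("CHISQ_ORR" %in% tests) {
    r <- orr_chisq_test(a, b)
    r$tau <- tau_context
    res <- c(res, list(r))
  }
  for (tau in taus) {
    if ("RMST_PFS" %in% tests) {
      r <- tryCatch(
        suppressWarnings(rmst_ratio_test(a$t_event, a$pfs_event,
                                         b$t_event, b$pfs_event, tau)),
        error = function(e) new_test_result("RMST_PFS", p_value = 1,
                                            tau = tau, method = "asymptotic",
                                            degenerate = TRUE))
      res <- c(res, list(r))
    }
    for (state in intersect(tests, c("DOR", "DOCR", "DOPR")))
      res <- c(res, list(duration_effect(a, b, tau, state = state,
                                         n_boot = n_boot, n_perm = n_perm)))
  }
  do.call(rbind, lapply(res, as.data.frame))
}

#' Operating characteristics of the test battery
#'
#' Simulates `n_replicates` randomized phase 2 trials, applies uniform
#' administrative censoring up to each horizon, runs the battery on each
#' censored copy, and tabulates the proportion of trials rejected at each
#' significance level.  Under a scenario whose arms truly differ the
#' proportion is the test's power; under a null scenario it is its type I
#' error.  All tests see the same censored data at a given horizon, so
#' comparisons share events and follow-up.
#'
#' @param config a [simulation_config()].
#' @param progress_every log progress to stderr every this many replicates
#'   (`0` silences; default 1000).
#' @return An `oc_table` data frame with columns `test`, `tau`, `alpha`,
#'   `n_per_arm`, `scenario`, `n_replicates`, `n_rejections`,
#'   `rejection_rate` and Wilson 95% Monte Carlo interval bounds
#'   `mc_ci_low`, `mc_ci_high`.  The count of degenerate (auto
#'   non-rejection) results per test/horizon is kept in the
#'   `"degenerate_counts"` attribute.
#' @export
operating_characteristics <- function(config, progress_every = 1000) {
  stopifnot(inherits(config, "simulation_config"))
  generate <- inherits(config$source, "scenario_config")
  scen_name <- if (generate) config$source$name else "resampled"
  K <- length(config$taus)
  tally <- list()
  degen <- list()
  for (r in seq_len(config$n_replicates)) {
    k0 <- (r - 1L) * (K + 1L)
    trial <- if (generate) {
      simulate_cohort(config$source, config$n_per_arm,
                      seed = derive_seed(config$seed, k0))
    } else {
      set.seed(derive_seed(config$seed, k0))
      resample_trial(config$source, config$n_per_arm)
    }
    for (j in seq_len(K)) {
      tau <- config$taus[j]
      set.seed(derive_seed(config$seed, k0 + j))
      cens <- apply_admin_censoring(trial, tau)
      bat <- run_battery(cens, taus = tau, tests = config$tests,
                         n_boot = config$n_boot, n_perm = config$n_perm,
                         tau_context = tau)
      for (i in seq_len(nrow(bat))) {
        key <- paste(bat$test[i], tau, sep = "@")
        if (is.null(tally[[key]])) {
          tally[[key]] <- setNames(integer(length(config$alphas)),
                                   as.character(config$alphas))
          degen[[key]] <- 0L
        }
        rej <- !bat$degenerate[i] & !is.na(bat$p_value[i]) &
          bat$p_value[i] <= config$alphas
        tally[[key]] <- tally[[key]] + as.integer(rej)
        degen[[key]] <- degen[[key]] + as.integer(bat$degenerate[i])
      }
    }
    if (progress_every > 0 && r %% progress_every == 0)
      message(sprintf("[%s] replicate %d/%d", scen_name, r,
                      config$n_replicates))
  }
  rows <- list()
  for (key in names(tally)) {
    parts <- strsplit(key, "@", fixed = TRUE)[[1]]
    for (a in seq_along(config$alphas)) {
      x <- tally[[key]][a]
      wil <- suppressWarnings(stats::prop.test(x, config$n_replicates,
                                               correct = FALSE)$conf.int)
      rows <- c(rows, list(data.frame(
        test = parts[1], tau = as.numeric(parts[2]),
        alpha = config$alphas[a], n_per_arm = config$n_per_arm,
        scenario = scen_name, n_replicates = config$n_replicates,
        n_rejections = unname(x),
        rejection_rate = unname(x) / config$n_replicates,
        mc_ci_low = wil[1], mc_ci_high = wil[2],
        stringsAsFactors = FALSE)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "degenerate_counts") <- unlist(degen)
  class(out) <- c("oc_table", "data.frame")
  out
}
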