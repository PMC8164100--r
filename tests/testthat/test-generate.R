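fixed_cfg <- function(p_resp = 1, onset = 2, dur = 8, ...) {
  arm_config(p_resp = p_resp, p_cr_given_resp = 0,
             dist_t_resp = dist_spec("fixed", value = onset),
             dist_resp_to_prog = dist_spec("fixed", value = dur),
             dist_nonresp_prog = dist_spec("exponential", rate = 0.3), ...)
}

test_that("distribution specs validate their parameters", {
  expect_error(dist_spec("exponential", shape = 1), "requires parameter")
  expect_error(dist_spec("weibull", shape = -1, scale = 2), "positive")
  expect_error(dist_spec("exponential", rate = 0), "positive")
  expect_silent(dist_spec("fixed", value = 0))
})

test_that("a deterministic configuration yields the predicted records", {
  set.seed(1)
  x <- simulate_arm(fixed_cfg(), 20)
  expect_true(all(x$t_response == 2))
  expect_true(all(x$t_event == 10))
  expect_true(all(x$pfs_event == 1L))
  expect_true(all(x$first_response_type == "PR"))

  set.seed(1)
  y <- simulate_arm(fixed_cfg(p_resp = 0), 20)
  expect_true(all(is.na(y$t_response)))
  expect_true(all(is.na(y$t_cr)))
})

test_that("never-responder progression follows its configured law", {
  cfg <- arm_config(p_resp = 0, p_cr_given_resp = 0,
                    dist_t_resp = dist_spec("fixed", value = 1),
                    dist_resp_to_prog = dist_spec("fixed", value = 1),
                    dist_nonresp_prog = dist_spec("exponential", rate = 0.25))
  set.seed(2)
  x <- simulate_arm(cfg, 20000)
  expect_equal(mean(x$t_event), 4, tolerance = 0.03)
})

test_that("every generated record passes validation over random configs", {
  set.seed(67)
  for (i in 1:10) {
    cfg <- arm_config(
      p_resp = runif(1), p_cr_given_resp = runif(1),
      dist_t_resp = dist_spec("exponential", rate = runif(1, 0.2, 1)),
      dist_pr_to_cr = if (i %% 2) "immediate"
                      else dist_spec("exponential", rate = runif(1, 0.1, 1)),
      dist_resp_to_prog = dist_spec("weibull", shape = runif(1, 0.7, 2),
                                    scale = runif(1, 2, 15)),
      dist_nonresp_prog = dist_spec("exponential", rate = runif(1, 0.1, 0.6)),
      dropout_rate = runif(1, 0, 0.1),
      assessment_interval = if (i %% 3 == 0) 1.5 else NULL
    )
    expect_silent(x <- simulate_arm(cfg, 200))
    expect_s3_class(validate_cohort(x), "rmdor_cohort")
  }
})

test_that("assessment snapping lands on the grid, never past the event", {
  cfg <- fixed_cfg(onset = 1.2, dur = 8, assessment_interval = 2)
  set.seed(3)
  x <- simulate_arm(cfg, 50)
  expect_true(all(x$t_response == 2))  # snapped up from 1.2
  cfg2 <- fixed_cfg(onset = 1.2, dur = 0.3, assessment_interval = 2)
  set.seed(3)
  y <- simulate_arm(cfg2, 50)
  expect_true(all(y$t_response <= y$t_event))
})

test_that("immediate conversion marks the first response as CR", {
  cfg <- arm_config(p_resp = 1, p_cr_given_resp = 1,
                    dist_t_resp = dist_spec("fixed", value = 2),
                    dist_pr_to_cr = "immediate",
                    dist_resp_to_prog = dist_spec("fixed", value = 5),
                    dist_nonresp_prog = dist_spec("exponential", rate = 0.3))
  set.seed(4)
  x <- simulate_arm(cfg, 10)
  expect_true(all(x$first_response_type == "CR"))
  expect_true(all(x$t_cr == x$t_response))
})

test_that("cohort generation is reproducible and arm-labelled", {
  a <- simulate_cohort("scenarioI", 50, seed = 123)
  b <- simulate_cohort("scenarioI", 50, seed = 123)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_setequal(arms(a), c("ICI", "control"))
  c2 <- simulate_cohort("scenarioI", 50, seed = 124)
  expect_false(identical(a$t_event, c2$t_event))
})

test_that("the null preset clones its arm configuration", {
  s <- scenario_preset("scenarioIII")
  expect_equal(s$truth_label, "null")
  expect_equal(unclass(s$arm_configs[[1]]), unclass(s$arm_configs[[2]]))
  expect_error(scenario_preset("scenarioIV"), "unknown scenario")
  # at large n the two arms' empirical ORRs converge
  x <- simulate_cohort("scenarioIII", 10000, seed = 9)
  rates <- vapply(arms(x), function(l) orr(cohort_arm(x, l))$rate, numeric(1))
  expect_equal(rates[[1]], rates[[2]], tolerance = 0.02)
})

test_that("parameter recovery: ORR and restricted mean DOR match the config", {
  cfg <- arm_config(p_resp = 0.35, p_cr_given_resp = 0,
                    dist_t_resp = dist_spec("exponential", rate = 0.5),
                    dist_resp_to_prog = dist_spec("exponential", rate = 0.08),
                    dist_nonresp_prog = dist_spec("weibull", shape = 1.3,
                                                  scale = 4))
  set.seed(71)
  x <- simulate_arm(cfg, 20000)
  expect_equal(orr(x)$rate, 0.35, tolerance = 0.015)
  p <- rm_partition(x, 12)
  expect_equal(p$dor, oracle_analytic_dor(cfg, 12), tolerance = 0.2)
})

test_that("uniform administrative censoring bounds and preserves records", {
  x <- cohort(patient_id = sprintf("p%d", 1:200), arm = "A",
              t_event = 20, pfs_event = 1)
  y <- apply_admin_censoring(x, 12, seed = 5)
  expect_true(all(y$t_event < 12))
  expect_true(all(y$pfs_event == 0L))

  # a huge horizon leaves bounded event times essentially untouched
  z <- apply_admin_censoring(x, 1e9, seed = 5)
  expect_true(all(z$t_event == 20))

  # accrual-window variant: support starts at `lower`
  w <- apply_admin_censoring(x, 12, seed = 5, lower = 6)
  expect_true(all(w$t_event >= 6 & w$t_event < 12))
})

test_that("censoring drops responses not yet observed", {
  x <- cohort(patient_id = c("a", "b"), arm = "A",
              t_response = c(8, 1), first_response_type = "PR",
              t_event = c(10, 10), pfs_event = 1)
  y <- apply_admin_censoring(x, 8, seed = 10)
  # patient "a" responded at month 8, past any U(0,8) censoring time
  expect_true(is.na(y$t_response[1]))
  expect_true(all(is.na(y$t_response) | y$t_response <= y$t_event))
  expect_true(all(is.na(y$first_response_type[is.na(y$t_response)])))
})

test_that("censoring fraction matches the numerical-integration oracle", {
  set.seed(73)
  tt <- rexp(20000, 0.2)
  x <- cohort(patient_id = sprintf("p%d", 1:20000), arm = "A",
              t_event = tt, pfs_event = 1)
  y <- apply_admin_censoring(x, 12, seed = 6)
  # P(C < T) for C ~ U(0,12): (1/12) * int_0^12 S_T(c) dc
  truth <- stats::integrate(function(c) exp(-0.2 * c) / 12, 0, 12)$value
  expect_equal(mean(y$pfs_event == 0L), truth, tolerance = 0.015)
})

test_that("scenario I reproduces its response-rate and median targets", {
  x <- simulate_cohort("scenarioI", 20000, seed = 77)
  a <- cohort_arm(x, "ICI"); b <- cohort_arm(x, "control")
  expect_equal(orr(a)$rate, 0.333, tolerance = 0.02)
  expect_equal(orr(b)$rate, 0.119, tolerance = 0.02)
  med <- function(arm) unname(summary(survival::survfit(
    survival::Surv(t_event, pfs_event) ~ 1, data = arm))$table["median"])
  expect_equal(med(a), 8.4, tolerance = 0.5)
  expect_equal(med(b), 3.4, tolerance = 0.5)
})

test_that("scenario II KM curves cross mid follow-up", {
  x <- simulate_cohort("scenarioII", 20000, seed = 78)
  a <- cohort_arm(x, "ICI"); b <- cohort_arm(x, "control")
  grid <- seq(0.5, 12, by = 0.05)
  d <- rmdor:::km_surv_at(km_fit(a$t_event, a$pfs_event), grid) -
    rmdor:::km_surv_at(km_fit(b$t_event, b$pfs_event), grid)
  crossings <- grid[which(diff(sign(d)) != 0)]
  expect_true(length(crossings) >= 1)
  expect_true(all(crossings >= 4 & crossings <= 8))
})
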