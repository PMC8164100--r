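test_that("composite times follow the first-of construction", {
  x <- cohort(patient_id = "p", arm = "A", t_response = 2,
              first_response_type = "PR", t_event = 10, pfs_event = 1)
  ct <- composite_times(x)
  expect_equal(ct$t0_resp, 2); expect_equal(ct$e0_resp, 1L)
  expect_equal(ct$t1, 10); expect_equal(ct$e1, 1L)
  # no CR observed: composite-CR time is the censored/evented PFS time
  expect_equal(ct$t0_cr, 10); expect_equal(ct$e0_cr, 1L)

  y <- cohort(patient_id = "q", arm = "A", t_event = 6, pfs_event = 0)
  ct <- composite_times(y)
  expect_equal(unlist(ct), c(t0_resp = 6, e0_resp = 0, t0_cr = 6,
                             e0_cr = 0, t1 = 6, e1 = 0))

  z <- cohort(patient_id = "r", arm = "A", t_response = 2,
              first_response_type = "PR", t_event = 8, pfs_event = 0)
  ct <- composite_times(z)
  expect_equal(ct$t0_resp, 2); expect_equal(ct$e0_resp, 1L)
  expect_equal(ct$t0_cr, 8); expect_equal(ct$e0_cr, 0L)
  expect_equal(ct$e1, 0L)
})

test_that("PBIR curve handles no responders and a single subject", {
  none <- cohort(patient_id = c("a", "b"), arm = "A",
                 t_event = c(3, 6), pfs_event = 1)
  expect_equal(pbir_curve(none, 1:10)$pbir, rep(0, 10))

  one <- cohort(patient_id = "a", arm = "A", t_response = 2,
                first_response_type = "PR", t_event = 10, pfs_event = 1)
  p <- pbir_curve(one, c(1, 1.99, 2, 5, 9.99, 10, 11))
  expect_equal(p$pbir, c(0, 0, 1, 1, 1, 0, 0))
})

test_that("PBIR equals the empirical in-response fraction when uncensored", {
  set.seed(19)
  for (i in 1:6) {
    arm <- random_arm(60, censor = FALSE)
    grid <- sort(runif(25, 0.1, 15))
    p <- pbir_curve(arm, grid)
    t_re <- ifelse(is.na(arm$t_response), Inf, arm$t_response)
    emp <- vapply(grid, function(t) mean(t_re <= t & t < arm$t_event),
                  numeric(1))
    expect_equal(p$pbir, emp, tolerance = 1e-12)
  }
})

test_that("the worked four-patient partition is exact", {
  p <- rm_partition(worked_cohort(), 12)
  expect_equal(p$rmst_pfs, 7.75)
  expect_equal(p$docr, 2.0)
  expect_equal(p$dopr, 2.5)
  expect_equal(p$dosd, 3.25)
  expect_equal(p$dor, 4.5)
})

test_that("degenerate partitions: no responders, immediate durable CR", {
  none <- cohort(patient_id = c("a", "b"), arm = "A",
                 t_event = c(3, 6), pfs_event = 1)
  expect_warning(p <- rm_partition(none, 12), "truncated")
  expect_equal(p$dor, 0); expect_equal(p$docr, 0); expect_equal(p$dopr, 0)
  expect_equal(p$dosd, p$rmst_pfs)

  # CR at t=0, progression after tau: the whole restricted mean is CR time
  allcr <- cohort(patient_id = c("a", "b"), arm = "A",
                  t_response = 0, first_response_type = "CR", t_cr = 0,
                  t_event = 15, pfs_event = 1)
  p <- rm_partition(allcr, 12)
  expect_equal(p$docr, 12); expect_equal(p$dor, 12)
  expect_equal(p$rmst_pfs, 12); expect_equal(p$dosd, 0)
})

test_that("partition additivity holds to numerical tolerance on censored data", {
  set.seed(23)
  for (i in 1:12) {
    arm <- random_arm(40)
    tau <- runif(1, 2, 14)
    p <- suppressWarnings(rm_partition(arm, tau))
    expect_lt(abs(p$dor - (p$docr + p$dopr)), 1e-9)
    expect_lt(abs(p$rmst_pfs - (p$dor + p$dosd)), 1e-9)
    expect_true(all(unlist(p[c("rmst_pfs", "dor", "docr", "dopr", "dosd")])
                    >= -1e-12))
  }
})

test_that("DOR equals the integrated PBIR curve", {
  set.seed(29)
  for (i in 1:6) {
    arm <- random_arm(50, censor = i %% 2 == 0)
    tau <- runif(1, 3, 12)
    p <- suppressWarnings(rm_partition(arm, tau))
    # integrate the right-continuous step difference exactly over its
    # breakpoints within [0, tau_effective] (the unclipped difference, so
    # the identity is exact even if estimation noise dips below zero)
    ct <- composite_times(arm)
    breaks <- sort(unique(c(0, ct$t1, ct$t0_resp, p$tau_effective)))
    breaks <- breaks[breaks <= p$tau_effective]
    vals <- rmdor:::km_surv_at(km_fit(ct$t1, ct$e1), breaks) -
      rmdor:::km_surv_at(km_fit(ct$t0_resp, ct$e0_resp), breaks)
    integral <- sum(vals[-length(vals)] * diff(breaks))
    expect_equal(p$dor, integral, tolerance = 1e-9)
  }
})

test_that("uncensored partitions equal the brute-force time-in-state oracle", {
  set.seed(31)
  for (i in 1:10) {
    arm <- random_arm(35, censor = FALSE)
    for (tau in c(4, 9, 13)) {
      p <- suppressWarnings(rm_partition(arm, tau))
      o <- oracle_state_means(arm, min(tau, max(arm$t_event)))
      for (f in names(o)) expect_equal(p[[f]], o[[f]], tolerance = 1e-9)
    }
  }
})

test_that("partition components are monotone in tau", {
  set.seed(37)
  arm <- random_arm(60)
  taus <- seq(1, 14, by = 0.5)
  mat <- vapply(taus, function(tau) {
    p <- suppressWarnings(rm_partition(arm, tau))
    unlist(p[c("rmst_pfs", "dor", "docr", "dopr", "dosd")])
  }, numeric(5))
  for (r in 1:5) expect_true(all(diff(mat[r, ]) >= -1e-9))
})

test_that("compiled and R KM areas agree exactly", {
  set.seed(41)
  for (i in 1:20) {
    tt <- round(rexp(30, 0.2), 2)   # rounding forces ties
    ee <- as.integer(runif(30) < 0.6)
    upto <- runif(1, 0.5, max(tt))   # the compiled path truncates at max(t)
    r_area <- rmdor:::km_area_r(km_fit(tt, ee), upto)
    c_area <- rmdor:::.km_area_cpp(tt, ee, upto)
    expect_equal(r_area, c_area, tolerance = 1e-12)
  }
})

test_that("bootstrap SEs are attached when requested", {
  set.seed(43)
  arm <- random_arm(40)
  p <- suppressWarnings(rm_partition(arm, 10, n_boot = 100, seed = 1))
  expect_named(p$boot_se, c("rmst_pfs", "dor", "docr", "dopr", "dosd"))
  expect_true(all(p$boot_se >= 0))
})

test_that("duration effect on an identical-copy arm is ratio 1, p = 1", {
  set.seed(47)
  arm <- random_arm(30, p_resp = 0.6)
  b <- as.data.frame(arm)
  b$patient_id <- paste0("b", b$patient_id)
  b$arm <- "B"
  r <- duration_effect(arm, as_cohort(b), 12, "DOR", n_boot = 50,
                       n_perm = 200, seed = 9)
  expect_equal(r$estimate, 1)
  expect_equal(r$p_value, 1)  # |diff*| >= 0 for every permutation
})

test_that("duration effect degenerates gracefully with no responders", {
  a <- cohort(patient_id = c("a1", "a2"), arm = "A", t_event = c(3, 5),
              pfs_event = 1)
  b <- cohort(patient_id = c("b1", "b2"), arm = "B", t_event = c(2, 6),
              pfs_event = 1)
  r <- duration_effect(a, b, 12, "DOR", n_perm = 50, seed = 1)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  expect_true(is.na(r$estimate))
})

test_that("the scenario II generator truth yields a strong DOR benefit", {
  x <- simulate_cohort("scenarioII", 5000, seed = 404)
  r <- duration_effect(cohort_arm(x, "ICI"), cohort_arm(x, "control"),
                       12, "DOR", n_boot = 200, n_perm = 199, seed = 2)
  expect_gt(r$estimate, 1)
  expect_lt(r$p_value, 0.01)
  expect_gt(r$ci_low, 1)
})

test_that("permutation p-values are approximately uniform under the null", {
  set.seed(53)
  ps <- vapply(1:1000, function(i) {
    a <- random_arm(30, arm = "A", p_resp = 0.3)
    b <- random_arm(30, arm = "B", p_resp = 0.3)
    duration_effect(a, b, 12, "DOR", n_boot = 0, n_perm = 99)$p_value
  }, numeric(1))
  # p is uniform on the add-one grid {1,...,100}/100
  expect_equal(mean(ps), 0.5, tolerance = 0.03)
  expect_equal(mean(ps <= 0.05), 0.05, tolerance = 0.02)
  expect_equal(mean(ps <= 0.25), 0.25, tolerance = 0.04)
})
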