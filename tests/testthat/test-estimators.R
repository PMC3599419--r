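ssmb_tab <- beta_table("SSMB", data.frame(peep = c(5, 10, 15),
                                          median_value = c(6, 8, 12),
                                          n_patients = 3, min = c(5, 6, 10),
                                          max = c(7, 12, 14), iqr = 1))
sssb_tab <- beta_table("SSSB", data.frame(peep = c(5, 10, 15),
                                          median_value = c(20, 28.8, 40),
                                          n_patients = 3, min = 10,
                                          max = 50, iqr = 5))

test_that("multiple-breath estimate is responsiveness times the population constant", {
  co <- manual_cohort(list(c(0.2, 0.5)), peeps = c(5, 10))
  est <- estimate_ssmb(co[[1]], ssmb_tab, 10)
  expect_equal(est$value, 0.3 / 5 * 8)
  expect_equal(est$inputs_used$responsiveness, 0.06)
  expect_equal(est$beta_applied$value, 8)

  # zero responsiveness gives a zero estimate
  co0 <- manual_cohort(list(c(0.4, 0.4)), peeps = c(5, 10))
  est0 <- estimate_ssmb(co0[[1]], ssmb_tab, 10)
  expect_equal(est0$value, 0)

  # a single step is not enough; the error directs to the other methods
  co1 <- manual_cohort(list(c(0.2)), peeps = 10)
  expect_error(estimate_ssmb(co1[[1]], ssmb_tab, 10), "single-breath")
})

test_that("multiple-breath estimates close the loop on a consistent cohort", {
  spec <- cohort_spec(n_patients = 10, peep_protocol = c(5, 10, 15),
                      master_seed = 3)
  profile <- c("10" = 8, "15" = 12)
  co <- make_eq8_consistent_cohort(profile, spec,
                                   dfrc_first = seq(0.1, 0.4, length.out = 10))
  tab <- calibrate_beta_ssmb(co)
  for (p in co) {
    truth <- attr(p, "true_dfrc")
    for (peep in c(10, 15)) {
      est <- estimate_ssmb(p, tab, peep)
      expect_rel_equal(est$value, unname(truth[as.character(peep)]), 1e-3)
    }
  }
})

test_that("single-breath estimate inverts its calibration example", {
  st <- manual_cohort(list(c(NA)), peeps = 10, vt = 0.5, dpaw = 12)[[1]]$steps[[1]]
  est <- estimate_sssb(st, sssb_tab)
  expect_equal(est$value, 28.8 * 0.25 / 12)  # 0.6 L
  expect_equal(est$beta_applied$value, 28.8)

  zero_tab <- beta_table("SSSB", data.frame(peep = 10, median_value = 0,
                                            n_patients = 1, min = 0, max = 0,
                                            iqr = 0))
  expect_equal(estimate_sssb(st, zero_tab)$value, 0)

  bad <- st
  bad$delta_paw <- 0
  expect_error(estimate_sssb(bad, sssb_tab), "driving pressure")
})

test_that("high tidal volume at equal compliance overestimates dFRC", {
  # the documented single-breath failure mode: a patient ventilated with
  # twice the cohort-typical Vt at the same elastance and the same true
  # recruitment receives a doubled estimate
  spec <- cohort_spec(n_patients = 8, master_seed = 5)
  co <- simulate_cohort(spec, n_breaths = 1)
  tab <- calibrate_beta1_sssb(co)
  typical <- simulate_patient(virtual_patient_params(seed = 98),
                              c(5, 10, 15))$steps[[2]]   # Vt 0.5, Ers 28
  outlier_params <- virtual_patient_params(vt_set = 1.0, seed = 99)
  outlier <- simulate_patient(outlier_params, c(5, 10, 15))$steps[[2]]
  est_typ <- estimate_sssb(typical, tab)
  est_out <- estimate_sssb(outlier, tab)
  truth <- true_dfrc(virtual_patient_params(), 10)  # same recruitment curve
  expect_rel_equal(est_out$value, 2 * est_typ$value, 1e-2)
  expect_gt(est_out$value - truth, est_typ$value - truth + 0.9 * est_typ$value)
})

test_that("single-compartment proxy is PEEP over fitted elastance", {
  b <- analytic_breath(ers = 20, rrs = 10, po = 10, set_peep = 10)
  est <- estimate_scsb(b)
  expect_rel_equal(est$value, 10 / 20, 1e-3)
  expect_rel_equal(est$inputs_used$ers, 20, 1e-3)

  # zero PEEP gives zero volume; the scale law doubles with PEEP
  expect_equal(estimate_scsb(b, set_peep = 0)$value, 0)
  expect_equal(estimate_scsb(b, set_peep = 20)$value,
               2 * estimate_scsb(b, set_peep = 10)$value)

  # constant elastance across PEEP: proxy exactly linear in PEEP
  # (recruitment midpoint below the protocol so the truth curve is concave
  # over the sampled range)
  p <- virtual_patient_params(ers_true = 25, peep_mid = 8, seed = 2)
  ds <- simulate_patient(p, c(5, 10, 15))
  vpo <- vapply(ds$steps, function(s) {
    estimate_scsb(s$breaths[[1]], set_peep = s$set_peep)$value
  }, numeric(1))
  expect_rel_equal(vpo, c(5, 10, 15) / 25, 1e-3)
  expect_lt(abs(vpo[3] - 3 * vpo[1]), 1e-3)

  # sigmoidal recruitment: proxy-versus-truth trace is concave
  # (truth rises slower than linearly at the upper PEEP levels)
  truth <- true_dfrc(p, c(5, 10, 15))
  slope_lo <- (truth[2] - truth[1]) / (vpo[2] - vpo[1])
  slope_hi <- (truth[3] - truth[2]) / (vpo[3] - vpo[2])
  expect_lt(slope_hi, slope_lo)
})

test_that("estimates below 5 cmH2O PEEP carry the low-PEEP caution flag", {
  st <- manual_cohort(list(c(NA)), peeps = 3)[[1]]$steps[[1]]
  tab3 <- beta_table("SSSB", data.frame(peep = 3, median_value = 20,
                                        n_patients = 1, min = 20, max = 20,
                                        iqr = 0))
  est <- estimate_sssb(st, tab3)
  expect_true("low_peep" %in% est$flags)
  est10 <- estimate_sssb(manual_cohort(list(c(NA)), peeps = 10)[[1]]$steps[[1]],
                         sssb_tab)
  expect_false("low_peep" %in% est10$flags)
})

test_that("combined method switches from single- to multiple-breath exactly once", {
  co <- manual_cohort(list(c(0.2, 0.5, 0.9)), peeps = c(5, 10, 15))
  p <- co[[1]]

  # one step available: identical to the single-breath estimate
  one <- patient_dataset(p$steps[1])
  cm1 <- estimate_cm(one, ssmb_tab, sssb_tab)
  ss1 <- estimate_sssb(one$steps[[1]], sssb_tab)
  expect_identical(cm1$value, ss1$value)
  expect_identical(cm1$inputs_used, ss1$inputs_used)
  expect_identical(cm1$beta_applied, ss1$beta_applied)
  expect_identical(cm1$branch, "SSSB")
  expect_identical(cm1$method, "CM")

  # three steps: identical to the multiple-breath estimate at the top PEEP
  cm3 <- estimate_cm(p, ssmb_tab, sssb_tab)
  sm3 <- estimate_ssmb(p, ssmb_tab, 15)
  expect_identical(cm3$value, sm3$value)
  expect_identical(cm3$inputs_used, sm3$inputs_used)
  expect_identical(cm3$branch, "SSMB")

  # streaming replay: the branch flips at the second step and never reverts
  branches <- vapply(1:3, function(k) {
    sofar <- patient_dataset(p$steps[seq_len(k)])
    estimate_cm(sofar, ssmb_tab, sssb_tab)$branch
  }, character(1))
  expect_identical(branches, c("SSSB", "SSMB", "SSMB"))
})

test_that("estimators are homogeneous of degree one in volume", {
  co <- manual_cohort(list(c(0.2, 0.5)), peeps = c(5, 10))
  co_scaled <- manual_cohort(list(2 * c(0.2, 0.5)), peeps = c(5, 10))
  tab <- calibrate_beta_ssmb(co)
  tab_scaled <- calibrate_beta_ssmb(co_scaled)
  # beta is a volume ratio, hence invariant; estimates scale with the data
  expect_equal(tab_scaled$table$median_value, tab$table$median_value)
  e1 <- estimate_ssmb(co[[1]], tab, 10)
  e2 <- estimate_ssmb(co_scaled[[1]], tab_scaled, 10)
  expect_equal(e2$value, 2 * e1$value)

  # single-breath side: scaling Vt and measured dFRC together
  co_s <- manual_cohort(list(c(0.6)), peeps = 10, vt = 0.5, dpaw = 12)
  co_s2 <- manual_cohort(list(c(1.2)), peeps = 10, vt = 1.0, dpaw = 12)
  t1 <- calibrate_beta1_sssb(co_s)
  t2 <- calibrate_beta1_sssb(co_s2)
  v1 <- estimate_sssb(co_s[[1]]$steps[[1]], t1)$value
  v2 <- estimate_sssb(co_s2[[1]]$steps[[1]], t2)$value
  expect_equal(v2, 2 * v1)
})
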