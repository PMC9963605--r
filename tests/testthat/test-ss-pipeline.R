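test_that("steady-state metrics obey the linear-PK identities per subject", {
  pop <- desven_population()
  reg <- dose_regimen(100, 24)
  st <- simulate_study(n_subjects = 6, seed = 77)
  est <- fit_study(st, pop, reg)
  ssm <- predict_steady_state(est, reg)
  ok <- est$converged
  # AUC over one steady-state interval = dose/CL (in ng/mL*h)
  expect_equal(ssm$auc_0_tau[ok], 1000 * 100 / est$CL[ok], tolerance = 1e-10)
  # trough never exceeds the peak
  expect_true(all(ssm$c_tau_ss[ok] <= ssm$cmax_ss[ok]))
  expect_true(all(ssm$auc_0_tau[ok] > 0))
  # accumulation: steady-state trough >= single-dose concentration at tau
  for (i in which(ok)) {
    p <- pk_params(est$ka[i], est$ktr[i], est$CL[i], est$V1[i])
    expect_gte(ssm$c_tau_ss[i], conc_single_dose(p, 100, 24))
  }
})

test_that("the closed-form steady state matches truncated superposition per subject", {
  pop <- desven_population()
  reg <- dose_regimen(100, 24)
  st <- simulate_study(n_subjects = 4, seed = 88)
  est <- fit_study(st, pop, reg)
  sched <- desven_schedule()[desven_schedule() <= 24]
  for (i in which(est$converged)) {
    p <- pk_params(est$ka[i], est$ktr[i], est$CL[i], est$V1[i])
    a <- steady_state_profile(p, reg, sched, method = "modes")
    b <- steady_state_profile(p, reg, sched, tol = 1e-10,
                              method = "superposition")
    expect_equal(a$conc, b$conc, tolerance = 1e-6)
  }
})

test_that("a zero-variability study yields the deterministic typical-ratio GMRs", {
  pop <- desven_population()
  pop0 <- pop_params(pop$typicals, iiv_sd = c(ka = 0, ktr = 0, CL = 0, V1 = 0),
                     iov_sd = c(ka = 0, ktr = 0, CL = 0), ruv_sd = 0, lloq = 1)
  cfg <- case_study_config()
  cfg$n_subjects <- 4
  cfg$population <- list(
    typicals = list(ka = pop$typicals$ka, ktr = pop$typicals$ktr,
                    CL = pop$typicals$CL, V1 = pop$typicals$V1, n_transit = 2),
    iiv_sd = list(ka = 0, ktr = 0, CL = 0, V1 = 0),
    iov_sd = list(ka = 0, ktr = 0, CL = 0), ruv_sd = 0, lloq = 1)
  rep <- run_case_study(cfg, seed = 9)
  typ <- pop$typicals
  p_t <- pk_params(typ$ka * 0.75, typ$ktr, typ$CL, typ$V1)
  # single-dose C-tau GMR equals the model ratio at 24 h
  gmr_ctau <- rep$be_single_alternative$pe[rep$be_single_alternative$metric == "c_tau"]
  expect_equal(gmr_ctau,
               100 * conc_single_dose(p_t, 100, 24) / conc_single_dose(typ, 100, 24),
               tolerance = 1e-6)
  # steady-state AUC GMR is exactly 100% (identical clearance)
  gmr_auc_ss <- rep$be_steady_state$pe[rep$be_steady_state$metric == "auc_0_tau"]
  expect_equal(gmr_auc_ss, 100, tolerance = 1e-4)
  # every CI collapses onto its point estimate
  expect_equal(rep$be_steady_state$lo, rep$be_steady_state$pe, tolerance = 1e-4)
})

test_that("with no residual error, single-dose AUCinf GMR equals steady-state AUC GMR", {
  pop <- desven_population()
  pop_ruv0 <- pop_params(pop$typicals, iiv_sd = pop$iiv_sd,
                         iov_sd = pop$iov_sd, ruv_sd = 0, lloq = 0.001)
  cfg <- case_study_config()
  cfg$n_subjects <- 8
  # a dense schedule keeps the trapezoidal extrapolation bias of the
  # single-dose AUC0-inf negligible, isolating the linear-PK identity
  cfg$schedule <- c(0, seq(0.5, 72, by = 0.5))
  cfg$population <- list(
    typicals = list(ka = pop$typicals$ka, ktr = pop$typicals$ktr,
                    CL = pop$typicals$CL, V1 = pop$typicals$V1, n_transit = 2),
    iiv_sd = as.list(pop$iiv_sd), iov_sd = as.list(pop$iov_sd),
    ruv_sd = 0, lloq = 0.001)
  rep <- run_case_study(cfg, seed = 10)
  gmr_sd <- rep$be_single_conventional$pe[
    rep$be_single_conventional$metric == "auc_0_inf"]
  gmr_ss <- rep$be_steady_state$pe[rep$be_steady_state$metric == "auc_0_tau"]
  # both reduce to clearance ratios; NCA extrapolation error is the only gap
  expect_equal(gmr_sd, gmr_ss, tolerance = 0.01)
})

test_that("the case-study report is deterministic and structurally complete", {
  cfg <- case_study_config()
  cfg$n_subjects <- 6
  r1 <- run_case_study(cfg, seed = 4)
  r2 <- run_case_study(cfg, seed = 4)
  expect_identical(r1$be_steady_state, r2$be_steady_state)
  expect_identical(r1$be_single_alternative, r2$be_single_alternative)
  expect_s3_class(r1, "case_study_report")
  expect_named(r1, c("seed", "config", "accumulation", "be_single_conventional",
                     "be_single_alternative", "be_steady_state", "sensitivity",
                     "n_converged"))
  expect_equal(nrow(r1$be_single_conventional), 3)
  expect_equal(nrow(r1$be_single_alternative), 14)
  expect_equal(nrow(r1$be_steady_state), 3)
  expect_true(all(c("abs_log_gmr", "cv") %in% names(r1$sensitivity)))
  expect_output(print(r1), "Accumulation")
})

test_that("the model-based accumulation screen flags the reference regimen", {
  # model computation at the published typicals: AUC over the first 24 h
  # covers well under 90% of AUC0-inf, so accumulation is significant
  p <- table3_params()
  reg <- dose_regimen(100, 24)
  ratio <- model_auc(p, reg, 0, 24) / model_auc(p, reg)
  expect_lt(ratio, 0.90)
  # and the pipeline screen agrees on simulated data
  cfg <- case_study_config(); cfg$n_subjects <- 8
  rep <- run_case_study(cfg, seed = 12)
  expect_true(rep$accumulation$significant)
})
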