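test_that("profile construction applies the BLQ policy", {
  # pre-dose BLQ becomes 0 at t=0; embedded BLQ points are dropped
  p <- conc_profile(c(0, 1, 2, 48, 72), c(NA, 5, 9, 2, NA),
                    blq = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(p$time, c(0, 1, 2, 48))
  expect_equal(p$conc, c(0, 5, 9, 2))
  expect_error(conc_profile(c(0, 1, 1), c(0, 1, 2)), "strictly increasing")
})

test_that("trapezoidal AUC handles exact shapes and interpolated bounds", {
  tri <- conc_profile(c(0, 1, 2), c(0, 1, 0))
  expect_equal(auc_linear(tri, 0, 2), 1.0)
  const <- conc_profile(c(2, 5, 9), c(3, 3, 3))
  expect_equal(auc_linear(const, 2, 9), 3 * 7)
  expect_equal(auc_linear(const, 2.5, 8), 3 * 5.5) # interior bounds
  expect_error(auc_linear(const, 0, 9), "outside")
  expect_error(auc_linear(const, 5, 5), "t_start")
})

test_that("NCA quantities match dense-grid oracles on random profiles", {
  set.seed(202)
  for (i in 1:100) {
    pr <- random_profile()
    t1 <- pr$time[1]; tl <- pr$time[nrow(pr)]
    expect_equal(auc_linear(pr, t1, tl),
                 dense_auc_oracle(pr$time, pr$conc, t1, tl),
                 tolerance = 1e-9)
    # pAUC additivity is exact for any interior cut
    cut <- runif(1, t1 + 0.05 * (tl - t1), tl - 0.05 * (tl - t1))
    pp <- pauc_pair(pr, cut)
    expect_equal(pp$pauc_early + pp$pauc_late, auc_linear(pr, t1, tl),
                 tolerance = 1e-12)
    # C at an arbitrary interior time matches direct interpolation
    tt <- runif(1, t1, tl)
    expect_equal(c_tau(pr, tt), approx(pr$time, pr$conc, xout = tt)$y)
    # HVD matches the dense-grid measure of {C >= Cmax/2}
    expect_equal(hvd(pr),
                 dense_hvd_oracle(pr$time, pr$conc, cmax_tmax(pr)$cmax / 2),
                 tolerance = 1e-3)
  }
})

test_that("Cmax/Tmax uses the earliest time on ties", {
  pr <- conc_profile(c(0, 1, 2, 3), c(0, 7, 7, 1))
  expect_equal(cmax_tmax(pr), list(cmax = 7, tmax = 1))
  rising <- conc_profile(c(0, 1, 2), c(0, 1, 5))
  expect_equal(cmax_tmax(rising)$tmax, 2)
})

test_that("terminal slope is exact on monoexponential tails and flags the rest", {
  tt <- c(0, 1, 2, 4, 8, 16, 24, 48)
  pr <- conc_profile(tt, 100 * exp(-0.1 * tt))
  lz <- lambda_z(pr)
  expect_true(lz$estimable)
  expect_equal(lz$lambda_z, 0.1, tolerance = 1e-10)
  # closed-form extrapolation for the monoexponential
  ai <- auc_inf(pr)
  expect_equal(ai$auc_0_inf, dense_auc_oracle(tt, 100 * exp(-0.1 * tt), 0, 48) +
                 100 * exp(-0.1 * 48) / 0.1)
  expect_gt(ai$auc_0_inf, ai$auc_0_t)
  # rising-only profile is non-estimable
  expect_false(lambda_z(conc_profile(0:5, 2^(0:5)))$estimable)
  # too few tail points
  expect_false(lambda_z(conc_profile(c(0, 1, 2, 3), c(0, 9, 5, 3)))$estimable)
})

test_that("flip-flop kinetics: the terminal slope recovers ka, and AUCinf the dose/CL", {
  pr <- typical_profile()
  lz <- lambda_z(pr)
  expect_true(lz$estimable)
  expect_equal(lz$lambda_z, 7.37e-2, tolerance = 0.02)
  # the linear trapezoid overestimates the widely spaced exponential tail
  # (24-48-72 h) of the reference schedule by a few percent; on a dense
  # schedule the NCA extrapolation converges to the model mass balance
  ai <- auc_inf(pr)
  expect_gt(ai$auc_0_inf, 1000 * 100 / 18.65)
  expect_equal(ai$auc_0_inf, 1000 * 100 / 18.65, tolerance = 0.06)
  dense <- typical_profile(schedule = c(0, seq(0.5, 72, by = 0.5)))
  expect_equal(auc_inf(dense)$auc_0_inf, 1000 * 100 / 18.65, tolerance = 0.01)
  # model-based C at 24 h equals the model solution there
  expect_equal(c_tau(pr, 24), conc_single_dose(table3_params(), 100, 24))
})

test_that("HVD geometry: crossings, constants, scale invariance", {
  tri <- conc_profile(c(0, 2, 4), c(0, 2, 0))
  expect_equal(hvd(tri), 2) # threshold 1 crossed at t = 1 and t = 3
  const <- conc_profile(c(1, 5, 9), c(4, 4, 4))
  expect_equal(hvd(const), 8)
  set.seed(31)
  pr <- random_profile()
  pr3 <- pr; pr3$conc <- pr$conc * 3
  expect_equal(hvd(pr3), hvd(pr))
  # two disjoint excursions above half-maximum are summed
  twin <- conc_profile(0:6, c(0, 10, 0, 1, 0, 10, 0))
  expect_equal(hvd(twin), 2)
})

test_that("metric scaling: AUC and C-tau are linear in concentration, HVD is not", {
  set.seed(32)
  pr <- random_profile()
  prs <- pr; prs$conc <- pr$conc * 2.5
  t1 <- pr$time[1]; tl <- pr$time[nrow(pr)]
  expect_equal(auc_linear(prs, t1, tl), 2.5 * auc_linear(pr, t1, tl))
  mid <- (t1 + tl) / 2
  expect_equal(c_tau(prs, mid), 2.5 * c_tau(pr, mid))
})

test_that("the accumulation screen applies the strict 90% rule per product", {
  mk <- function(r_ratio, t_ratio) {
    data.frame(treatment = rep(c("R", "T"), each = 3),
               auc_0_inf = rep(100, 6),
               pauc_0_24 = 100 * c(rep(r_ratio, 3), rep(t_ratio, 3)))
  }
  expect_true(accumulation_screen(mk(0.67, 0.66))$significant)
  expect_false(accumulation_screen(mk(0.95, 0.95))$significant)
  expect_false(accumulation_screen(mk(0.90, 0.66))$significant) # strict "<"
  # missing AUC0-inf rows are excluded with a warning
  tab <- mk(0.5, 0.5); tab$auc_0_inf[1] <- NA
  expect_warning(res <- accumulation_screen(tab), "excluded")
  expect_true(res$significant)
})

test_that("per-study NCA tables carry design labels and subject-specific t_last", {
  st <- simulate_study(n_subjects = 6, seed = 13)
  tab <- nca_table(st)
  expect_equal(nrow(tab), 12)
  expect_true(all(c("cmax", "auc_0_t", "c_tau", "hvd", "pauc_0_8", "pauc_24_t")
                  %in% names(tab)))
  expect_equal(tab$pauc_0_12 + tab$pauc_12_t, tab$auc_0_t, tolerance = 1e-12)
  # a profile whose 72 h sample is BLQ ends at 48 h
  st2 <- st
  i <- st2$subject == 1 & st2$period == 1 & st2$time_h == 72
  st2$conc[i] <- NA; st2$blq[i] <- TRUE
  tab2 <- nca_table(st2)
  expect_equal(tab2$t_last[1], 48)
})
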