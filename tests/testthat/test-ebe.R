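test_that("MAP fit recovers the typicals exactly from noise-free typical data", {
  pop <- desven_population()
  prof <- typical_profile()
  fit <- map_fit(data.frame(time_h = prof$time, conc = prof$conc,
                            blq = prof$time == 0), pop, 100, sigma = 0)
  expect_true(fit$converged)
  expect_equal(unname(fit$phi), rep(0, 4), tolerance = 1e-3)
  expect_equal(fit$params$CL, pop$typicals$CL, tolerance = 1e-3)
  expect_equal(fit$params$ka, pop$typicals$ka, tolerance = 1e-3)
})

test_that("dense noise-free sampling recovers a known individual within 1%", {
  pop <- desven_population()
  set.seed(606)
  eta <- rnorm(4, 0, unname(pop$iiv_sd))
  typ <- pop$typicals
  p <- pk_params(typ$ka * exp(eta[1]), typ$ktr * exp(eta[2]),
                 typ$CL * exp(eta[3]), typ$V1 * exp(eta[4]))
  tt <- seq(0.25, 72, by = 0.25)
  prof <- data.frame(time_h = tt, conc = conc_single_dose(p, 100, tt),
                     blq = FALSE)
  fit <- map_fit(prof, pop, 100, sigma = 0)
  expect_true(fit$converged)
  expect_equal(fit$params$ka, p$ka, tolerance = 0.01)
  expect_equal(fit$params$ktr, p$ktr, tolerance = 0.01)
  expect_equal(fit$params$CL, p$CL, tolerance = 0.01)
  expect_equal(fit$params$V1, p$V1, tolerance = 0.01)
})

test_that("vanishing prior variance pins the estimate at the typicals", {
  pop <- desven_population()
  pop_pin <- pop_params(pop$typicals,
                        iiv_sd = c(ka = 0, ktr = 0, CL = 0, V1 = 0),
                        iov_sd = c(ka = 0, ktr = 0, CL = 0),
                        ruv_sd = pop$ruv_sd, lloq = pop$lloq)
  st <- simulate_study(n_subjects = 2, seed = 33) # data from a variable population
  fit <- map_fit(st[st$subject == 1 & st$period == 1, ], pop_pin, 100)
  expect_true(fit$converged)
  expect_equal(fit$params$CL, pop$typicals$CL)
  expect_equal(fit$params$ka, pop$typicals$ka)
})

test_that("the unpenalized fit matches MAP in the flat-prior limit", {
  pop <- desven_population()
  st <- simulate_study(n_subjects = 2, seed = 44)
  prof <- st[st$subject == 1 & st$period == 1, ]
  nls_fit <- individual_nls(prof, 100, pop$typicals)
  expect_true(nls_fit$converged)
  # MAP with enormous prior SDs reproduces the unpenalized estimate
  pop_flat <- pop_params(pop$typicals,
                         iiv_sd = c(ka = 1e3, ktr = 1e3, CL = 1e3, V1 = 1e3),
                         iov_sd = c(ka = 1e3, ktr = 1e3, CL = 1e3),
                         ruv_sd = pop$ruv_sd, lloq = pop$lloq)
  map_flat <- map_fit(prof, pop_flat, 100)
  expect_equal(map_flat$params$CL, nls_fit$params$CL, tolerance = 1e-3)
  expect_equal(map_flat$params$ka, nls_fit$params$ka, tolerance = 1e-3)
  # noise-free data: exact self-recovery
  tt <- seq(0.5, 72, by = 0.5)
  exact <- data.frame(time_h = tt,
                      conc = conc_single_dose(pop$typicals, 100, tt),
                      blq = FALSE)
  rec <- individual_nls(exact, 100, pk_params(0.1, 10, 15, 70))
  expect_equal(rec$params$CL, pop$typicals$CL, tolerance = 1e-3)
  expect_error(individual_nls(exact[1:3, ], 100, pop$typicals), "at least")
})

test_that("shrinkage pulls the MAP estimate toward the prior", {
  # the MAP optimum always has a smaller weighted prior norm than the
  # unpenalized fit: from data(nls) + pen(nls) >= data(map) + pen(map)
  # and data(map) >= data(nls) it follows pen(map) <= pen(nls)
  pop <- desven_population()
  st <- simulate_study(n_subjects = 6, seed = 55,
                       effect = formulation_effect())
  w2 <- pop$iiv_sd[c("ka", "ktr", "CL", "V1")]^2 +
    c(pop$iov_sd[c("ka", "ktr", "CL")]^2, 0)
  checked <- 0
  for (s in 1:3) {
    prof <- st[st$subject == s & st$period == 1, ]
    m <- map_fit(prof, pop, 100)
    n <- individual_nls(prof, 100, pop$typicals)
    if (!m$converged || !n$converged) next
    pen_map <- sum(unname(m$phi)^2 / w2)
    pen_nls <- sum(unname(n$phi)^2 / w2)
    expect_lte(pen_map, pen_nls + 1e-6)
    checked <- checked + 1
  }
  expect_gte(checked, 2)
})

test_that("the reported optimum never exceeds the zero-effect objective", {
  pop <- desven_population()
  st <- simulate_study(n_subjects = 4, seed = 66)
  est <- fit_study(st, pop, dose_regimen(100, 24))
  expect_true(all(est$converged))
  # objective sanity is enforced inside the fit; spot-check one profile
  prof <- st[st$subject == 2 & st$period == 2, ]
  fit <- map_fit(prof, pop, 100)
  zero_obj <- {
    keep <- !prof$blq
    pred <- conc_single_dose(pop$typicals, 100, prof$time_h[keep])
    sum((log(prof$conc[keep]) - log(pred))^2) / pop$ruv_sd^2
  }
  expect_lte(fit$objective, zero_obj + 1e-8)
})

test_that("profiles with too few quantifiable points are rejected", {
  pop <- desven_population()
  expect_error(map_fit(data.frame(time_h = c(0, 1, 2), conc = c(NA, 5, 7),
                                  blq = c(TRUE, FALSE, FALSE)), pop, 100),
               "at least 4")
})
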