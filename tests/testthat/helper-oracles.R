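# Independent oracles used across the suite. Each reimplements the target
# quantity by a different route than the package (ODE integration, dense
# grids, brute-force sums, explicit design matrices) so agreement is
# informative.

# numerically integrate the full transit-chain state system (deSolve) and
# return central-compartment concentrations in ng/mL
ode_oracle <- function(params, dose, times, rtol = 1e-11) {
  n <- params$n_transit
  ke <- params$CL / params$V1
  k_out <- c(rep(params$ktr, n), params$ka, ke)
  rhs <- function(t, y, p) {
    inflow <- c(0, k_out[-length(k_out)] * y[-length(y)])
    list(inflow - k_out * y)
  }
  y0 <- c(dose, rep(0, n + 1))
  sol <- deSolve::ode(y0, unique(c(0, times)), rhs, NULL,
                      rtol = rtol, atol = 1e-14)
  idx <- match(times, sol[, 1])
  1000 * sol[idx, n + 3] / params$V1
}

# trapezoidal area of a piecewise-linear profile on a very fine grid
dense_auc_oracle <- function(time, conc, t1, t2, n_grid = 200001) {
  g <- seq(t1, t2, length.out = n_grid)
  g <- sort(unique(c(g, time[time > t1 & time < t2]))) # keep the kinks
  cg <- approx(time, conc, xout = g)$y
  sum(diff(g) * (cg[-1] + cg[-length(g)]) / 2)
}

# measure of {t : C(t) >= thr} for a piecewise-linear profile, by fine grid
dense_hvd_oracle <- function(time, conc, thr, n_grid = 2000001) {
  g <- seq(min(time), max(time), length.out = n_grid)
  cg <- approx(time, conc, xout = g)$y
  mean(cg >= thr) * (max(time) - min(time))
}

# a random positive piecewise-linear profile on random strictly
# increasing times (no BLQ), as a conc_profile data.frame
random_profile <- function(n_min = 6, n_max = 18) {
  n <- sample(n_min:n_max, 1)
  time <- sort(runif(n, 0, 72))
  time <- time + seq(0, 1e-3, length.out = n) # enforce strict increase
  conc <- runif(n, 0.1, 300)
  conc_profile(time, conc, blq = rep(FALSE, n))
}

# full-design-matrix least squares for the 2x2 crossover on log(value):
# fixed sequence, period, treatment, subject effects
crossover_ls_oracle <- function(data) {
  data <- data[!is.na(data$value), ]
  counts <- table(data$subject)
  data <- data[data$subject %in% names(counts)[counts == 2], ]
  fit <- lm(log(value) ~ factor(sequence) + factor(period) + factor(treatment) +
              factor(subject), data = data)
  ns <- table(unique(data[c("subject", "sequence")])$sequence)
  list(contrast = unname(coef(fit)[["factor(treatment)T"]]),
       mse = summary(fit)$sigma^2,
       df = fit$df.residual,
       n1 = unname(ns[["RT"]]), n2 = unname(ns[["TR"]]))
}

# a random balanced 2x2 crossover dataset on one lognormal metric
random_crossover_data <- function(n_per_seq = NULL) {
  if (is.null(n_per_seq)) n_per_seq <- sample(3:10, 1)
  n <- 2 * n_per_seq
  sequence <- rep(c("RT", "TR"), each = n_per_seq)
  subj_eff <- rnorm(n, 0, 0.4)
  trt_eff <- rnorm(1, 0, 0.2)
  per_eff <- rnorm(1, 0, 0.1)
  seq_eff <- rnorm(1, 0, 0.1)
  rows <- list()
  for (i in seq_len(n)) {
    for (per in 1:2) {
      trt <- substr(sequence[i], per, per)
      mu <- 5 + subj_eff[i] + (trt == "T") * trt_eff + (per == 2) * per_eff +
        (sequence[i] == "TR") * seq_eff
      rows[[length(rows) + 1]] <- data.frame(
        subject = i, sequence = sequence[i], period = per, treatment = trt,
        value = exp(mu + rnorm(1, 0, 0.15)))
    }
  }
  do.call(rbind, rows)
}

table3_params <- function() pk_params(ka = 7.37e-2, ktr = 18.5,
                                      CL = 18.65, V1 = 83.31, n_transit = 2L)

# noise-free typical profile on the reference schedule
typical_profile <- function(schedule = desven_schedule(), dose = 100,
                            params = table3_params()) {
  conc <- conc_single_dose(params, dose, schedule)
  conc_profile(schedule, ifelse(schedule == 0, NA, conc), blq = schedule == 0)
}
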