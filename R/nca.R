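#' Analyzed concentration series of one subject-period
#'
#' Builds the series that every NCA routine operates on: the pre-dose BLQ
#' sample enters as concentration 0 at `t = 0` (integration start), while
#' embedded (post-dose) BLQ samples are dropped, not zeroed — so a profile
#' whose 72 h sample is BLQ ends at 48 h. Times must be strictly
#' increasing.
#'
#' @param time Sampling times (h).
#' @param conc Concentrations (ng/mL); `NA` allowed for BLQ records.
#' @param blq Logical BLQ flags (default: `is.na(conc)`).
#' @return A data.frame with columns `time`, `conc` (the analyzed points).
#' @export
conc_profile <- function(time, conc, blq = is.na(conc)) {
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  stopifnot(length(time) == length(conc), length(blq) == length(conc))
  keep <- !blq
  t0 <- time == 0 & blq
  out <- data.frame(time = c(time[t0], time[keep]),
                    conc = c(rep(0, sum(t0)), conc[keep]))
  out <- out[order(out$time), , drop = FALSE]
  if (any(out$conc < 0)) stop("analyzed concentrations must be >= 0", call. = FALSE)
  rownames(out) <- NULL
  out
}

# linear interpolation of the analyzed series at time tt (within range)
.interp <- function(p, tt) {
  stats::approx(p$time, p$conc, xout = tt, method = "linear", ties = "ordered")$y
}

#' Linear trapezoidal AUC over an interval
#'
#' Area under the piecewise-linear interpolant of the analyzed points
#' between `t_start` and `t_end`, with linear interpolation when a bound
#' falls between samples.
#'
#' @param profile A [conc_profile()] data.frame.
#' @param t_start,t_end Integration bounds (h), within the observed range.
#' @return Area (ng/mL * h).
#' @export
auc_linear <- function(profile, t_start, t_end) {
  if (t_start >= t_end) stop("t_start must be < t_end", call. = FALSE)
  if (t_start < profile$time[1] || t_end > profile$time[nrow(profile)]) {
    stop(sprintf("bounds [%g, %g] outside observed range [%g, %g]",
                 t_start, t_end, profile$time[1], profile$time[nrow(profile)]),
         call. = FALSE)
  }
  inside <- profile$time > t_start & profile$time < t_end
  tt <- c(t_start, profile$time[inside], t_end)
  cc <- c(.interp(profile, t_start), profile$conc[inside], .interp(profile, t_end))
  sum(diff(tt) * (cc[-1] + cc[-length(cc)]) / 2)
}

#' Peak concentration and its time
#'
#' @param profile A [conc_profile()] data.frame.
#' @return A list with `cmax` (ng/mL) and `tmax` (h); the earliest time is
#'   returned on ties.
#' @export
cmax_tmax <- function(profile) {
  if (nrow(profile) < 1L) stop("no analyzed points", call. = FALSE)
  i <- which.max(profile$conc) # which.max takes the first maximum
  list(cmax = profile$conc[i], tmax = profile$time[i])
}

#' Terminal elimination slope
#'
#' Log-linear least-squares slope of the terminal phase. The terminal
#' subset is chosen, among all candidate tails of at least `min_points`
#' points strictly after Tmax (the Cmax point itself excluded), to
#' maximize the adjusted R-squared — the convention of standard
#' regulatory NCA software. Returns a non-estimable status when fewer than
#' `min_points` positive post-Tmax concentrations exist or the best slope
#' is not positive.
#'
#' @param profile A [conc_profile()] data.frame.
#' @param min_points Minimum number of tail points (default 3).
#' @return A list with `lambda_z` (1/h, `NA` if non-estimable),
#'   `n_points`, `adj_r2`, and `estimable`.
#' @export
lambda_z <- function(profile, min_points = 3) {
  tm <- cmax_tmax(profile)$tmax
  tail_idx <- which(profile$time > tm & profile$conc > 0)
  ne <- list(lambda_z = NA_real_, n_points = 0L, adj_r2 = NA_real_,
             estimable = FALSE)
  if (length(tail_idx) < min_points) return(ne)
  x_all <- profile$time[tail_idx]
  y_all <- log(profile$conc[tail_idx])
  best <- NULL
  for (start in 1:(length(tail_idx) - min_points + 1L)) {
    x <- x_all[start:length(x_all)]
    y <- y_all[start:length(y_all)]
    n <- length(x)
    sxx <- sum((x - mean(x))^2)
    if (sxx == 0) next
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    syy <- sum((y - mean(y))^2)
    r2 <- if (syy == 0) 1 else b^2 * sxx / syy
    adj <- if (n > 2) 1 - (1 - r2) * (n - 1) / (n - 2) else r2
    if (is.null(best) || adj > best$adj_r2 + 1e-12) {
      best <- list(slope = b, n = n, adj_r2 = adj)
    }
  }
  if (is.null(best) || best$slope >= 0) return(ne)
  list(lambda_z = -best$slope, n_points = best$n, adj_r2 = best$adj_r2,
       estimable = TRUE)
}

#' AUC extrapolated to infinity
#'
#' `AUC(0, t_last) + C_last / lambda_z`; non-estimable when the terminal
#' slope is (mirrors the exclusion of profiles where no extrapolation is
#' possible).
#'
#' @param profile A [conc_profile()] data.frame.
#' @param min_points Passed to [lambda_z()].
#' @return A list with `auc_0_inf` (`NA` if non-estimable), `auc_0_t`,
#'   `lambda_z`, `estimable`.
#' @export
auc_inf <- function(profile, min_points = 3) {
  lz <- lambda_z(profile, min_points)
  a0t <- auc_linear(profile, profile$time[1], profile$time[nrow(profile)])
  if (!lz$estimable) {
    return(list(auc_0_inf = NA_real_, auc_0_t = a0t, lambda_z = NA_real_,
                estimable = FALSE))
  }
  clast <- profile$conc[nrow(profile)]
  list(auc_0_inf = a0t + clast / lz$lambda_z, auc_0_t = a0t,
       lambda_z = lz$lambda_z, estimable = TRUE)
}

#' Concentration at the end of the dosing interval
#'
#' The observed value if `tau` is a sampled time; otherwise linearly
#' interpolated between the bracketing samples.
#'
#' @param profile A [conc_profile()] data.frame.
#' @param tau Dosing interval (h), within the observed range.
#' @return Concentration (ng/mL).
#' @export
c_tau <- function(profile, tau = 24) {
  if (tau > profile$time[nrow(profile)] || tau < profile$time[1]) {
    stop(sprintf("tau = %g outside observed range", tau), call. = FALSE)
  }
  .interp(profile, tau)
}

#' Paired partial AUCs at a cut-off
#'
#' Splits the AUC to the last measurable concentration at `cut` into an
#' early and a terminal segment sharing the boundary point, so the two
#' segments add exactly to `AUC(0, t_last)`.
#'
#' @param profile A [conc_profile()] data.frame.
#' @param cut Cut-off time (h), strictly inside `(t_first, t_last)`.
#' @return A list with `pauc_early` and `pauc_late` (ng/mL * h).
#' @export
pauc_pair <- function(profile, cut) {
  t1 <- profile$time[1]; tl <- profile$time[nrow(profile)]
  if (cut <= t1 || cut >= tl) {
    stop(sprintf("cut = %g must lie strictly inside (%g, %g)", cut, t1, tl),
         call. = FALSE)
  }
  list(pauc_early = auc_linear(profile, t1, cut),
       pauc_late = auc_linear(profile, cut, tl))
}

#' Half-value duration
#'
#' Total time the piecewise-linear interpolant of the analyzed points is
#' at or above half of Cmax; crossing times are found by linear
#' interpolation and multiple disjoint excursions are summed. Points
#' exactly at Cmax/2 count as "in". Scale-free in concentration.
#'
#' @param profile A [conc_profile()] data.frame.
#' @return Duration (h).
#' @export
hvd <- function(profile) {
  half <- cmax_tmax(profile)$cmax / 2
  tt <- profile$time; cc <- profile$conc
  total <- 0
  for (i in seq_len(length(tt) - 1L)) {
    c1 <- cc[i]; c2 <- cc[i + 1L]; dt <- tt[i + 1L] - tt[i]
    if (c1 >= half && c2 >= half) {
      total <- total + dt
    } else if (c1 >= half || c2 >= half) {
      # one crossing inside the segment
      frac <- if (c1 >= half) (c1 - half) / (c1 - c2) else (c2 - half) / (c2 - c1)
      total <- total + dt * frac
    }
  }
  total
}

#' All NCA metrics for one profile
#'
#' Computes the conventional metrics (Cmax, Tmax, AUC0-t, lambda_z,
#' AUC0-inf) and the curve-shape metrics (C-tau, paired partial AUCs at
#' each cut-off, HVD) for a single analyzed profile. Metrics whose
#' preconditions fail (e.g. non-estimable extrapolation, tau beyond the
#' last measurable sample) are `NA`.
#'
#' @param profile A [conc_profile()] data.frame.
#' @param tau Dosing interval (h) for C-tau.
#' @param cuts Partial-AUC cut-off times (h).
#' @param min_points Passed to [lambda_z()].
#' @return A one-row data.frame.
#' @export
nca_metrics <- function(profile, tau = 24, cuts = c(8, 10, 12, 16, 20, 24),
                        min_points = 3) {
  cm <- cmax_tmax(profile)
  ai <- auc_inf(profile, min_points)
  out <- data.frame(
    cmax = cm$cmax, tmax = cm$tmax,
    auc_0_t = ai$auc_0_t, lambda_z = ai$lambda_z, auc_0_inf = ai$auc_0_inf,
    c_tau = tryCatch(c_tau(profile, tau), error = function(e) NA_real_),
    hvd = hvd(profile),
    t_last = profile$time[nrow(profile)]
  )
  for (cut in cuts) {
    pp <- tryCatch(pauc_pair(profile, cut), error = function(e)
      list(pauc_early = NA_real_, pauc_late = NA_real_))
    out[[sprintf("pauc_0_%g", cut)]] <- pp$pauc_early
    out[[sprintf("pauc_%g_t", cut)]] <- pp$pauc_late
  }
  out
}

#' Per-subject-period NCA table for a study
#'
#' Applies [nca_metrics()] to every subject-period of a long-format study
#' dataset, carrying the design labels through.
#'
#' @param study A study data.frame (`subject`, `sequence`, `period`,
#'   `treatment`, `time_h`, `conc`, `blq`).
#' @inheritParams nca_metrics
#' @return A data.frame with one row per subject-period.
#' @export
nca_table <- function(study, tau = 24, cuts = c(8, 10, 12, 16, 20, 24),
                      min_points = 3) {
  keys <- unique(study[c("subject", "period")])
  keys <- keys[order(keys$subject, keys$period), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    rec <- study[study$subject == keys$subject[i] & study$period == keys$period[i], ]
    rec <- rec[order(rec$time_h), ]
    prof <- conc_profile(rec$time_h, rec$conc, rec$blq)
    cbind(
      data.frame(subject = keys$subject[i], sequence = rec$sequence[1],
                 period = keys$period[i], treatment = rec$treatment[1]),
      nca_metrics(prof, tau = tau, cuts = cuts, min_points = min_points)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Accumulation-significance screen
#'
#' Accumulation is significant when the mean single-dose AUC over one
#' dosing interval covers less than 90% of the mean AUC0-inf for both the
#' test and the reference product (strict inequality at the 0.90
#' boundary). Subjects with a missing AUC0-inf are excluded with a
#' warning.
#'
#' @param nca_tab A table from [nca_table()] containing `auc_0_inf`,
#'   `treatment`, and the interval AUC column named by `auc_tau_col`.
#' @param auc_tau_col Column holding the single-dose AUC over one dosing
#'   interval (default `"pauc_0_24"` for a 24 h interval).
#' @param threshold Screen threshold (default 0.90).
#' @return A list with per-product `ratio` (named `R`, `T`) and
#'   `significant`.
#' @export
accumulation_screen <- function(nca_tab, auc_tau_col = "pauc_0_24",
                                threshold = 0.90) {
  if (!auc_tau_col %in% names(nca_tab)) {
    stop(sprintf("column '%s' not found", auc_tau_col), call. = FALSE)
  }
  miss <- is.na(nca_tab$auc_0_inf) | is.na(nca_tab[[auc_tau_col]])
  if (any(miss)) {
    warning(sprintf("%d subject-period(s) without AUC0-inf excluded from the accumulation screen",
                    sum(miss)))
    nca_tab <- nca_tab[!miss, , drop = FALSE]
  }
  ratio <- vapply(c("R", "T"), function(trt) {
    sub <- nca_tab[nca_tab$treatment == trt, , drop = FALSE]
    mean(sub[[auc_tau_col]]) / mean(sub$auc_0_inf)
  }, numeric(1))
  list(ratio = ratio, significant = all(ratio < threshold))
}
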