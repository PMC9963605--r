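#' Fit the 2x2 crossover model for one log-transformed metric
#'
#' Ordinary least squares with fixed effects for sequence, period,
#' treatment and subject-within-sequence on the natural log of the metric.
#' For complete two-period data this is solved in closed form through the
#' within-subject period differences: with `d_i = ln y_{i,2} - ln y_{i,1}`,
#' the treatment contrast (T minus R, log scale) is
#' `(mean(d_RT) - mean(d_TR)) / 2` and the residual mean square is half
#' the pooled within-sequence variance of the `d_i` — identical to the
#' full-design-matrix OLS/REML solution for this balanced layout.
#' Subjects missing a period (or with a missing metric value in either
#' period) are dropped with a warning.
#'
#' @param data A data.frame with columns `subject`, `sequence`
#'   (`"RT"`/`"TR"`), `period` (1/2), `treatment` (`"R"`/`"T"`) and
#'   `value` (> 0).
#' @return A list with `contrast` (log scale), `mse`, `df`, `n1`, `n2`
#'   (per-sequence completer counts) and `n_dropped`.
#' @export
crossover_fit <- function(data) {
  need <- c("subject", "sequence", "period", "treatment", "value")
  if (!all(need %in% names(data))) {
    stop("data needs columns subject, sequence, period, treatment, value",
         call. = FALSE)
  }
  data <- data[!is.na(data$value), , drop = FALSE]
  if (any(data$value <= 0)) {
    stop("metric values must be > 0 for log-scale analysis", call. = FALSE)
  }
  counts <- table(data$subject)
  complete <- names(counts)[counts == 2]
  dropped <- length(counts) - length(complete)
  if (dropped > 0) {
    warning(sprintf("%d subject(s) without both periods dropped", dropped))
  }
  data <- data[data$subject %in% complete, , drop = FALSE]

  d <- se <- numeric(0)
  for (s in complete) {
    sub <- data[data$subject == s, ]
    sub <- sub[order(sub$period), ]
    if (!identical(sort(unique(sub$treatment)), c("R", "T"))) {
      stop("each complete subject must receive both R and T", call. = FALSE)
    }
    d <- c(d, log(sub$value[2]) - log(sub$value[1]))
    se <- c(se, sub$sequence[1])
  }
  n1 <- sum(se == "RT"); n2 <- sum(se == "TR")
  if (n1 < 2 || n2 < 2) stop("need >= 2 complete subjects per sequence", call. = FALSE)
  d1 <- d[se == "RT"]; d2 <- d[se == "TR"]
  contrast <- (mean(d1) - mean(d2)) / 2
  pooled <- (sum((d1 - mean(d1))^2) + sum((d2 - mean(d2))^2)) / (n1 + n2 - 2)
  list(contrast = contrast, mse = pooled / 2, df = n1 + n2 - 2L,
       n1 = n1, n2 = n2, n_dropped = dropped)
}

#' Average-bioequivalence assessment from a fitted contrast
#'
#' Converts the crossover fit into the regulatory summary: geometric mean
#' ratio `GMR = 100 exp(contrast)`, two one-sided-tests 90% confidence
#' interval `100 exp(contrast +/- t(0.95, df) * SE)` with
#' `SE = sqrt(mse (1/n1 + 1/n2) / 2)`, intra-subject coefficient of
#' variation `100 sqrt(exp(mse) - 1)`, and the acceptance decision. The
#' decision compares the CI limits rounded to two decimals against the
#' acceptance bounds, matching the regulatory convention implied by
#' "80.00-125.00%".
#'
#' @param contrast Treatment log-difference (T - R).
#' @param mse Residual mean square from [crossover_fit()].
#' @param df Residual degrees of freedom (> 0).
#' @param n1,n2 Per-sequence subject counts.
#' @param acceptance Lower/upper acceptance limits in percent.
#' @param metric Optional metric name carried into the result.
#' @return A one-row data.frame (metric, pe, lo, hi, cv, df, pass).
#' @export
be_assess <- function(contrast, mse, df, n1, n2,
                      acceptance = c(80.00, 125.00), metric = NA_character_) {
  if (df <= 0) stop("df must be > 0", call. = FALSE)
  se <- sqrt(mse * (1 / n1 + 1 / n2) / 2)
  tq <- qt(0.95, df)
  pe <- 100 * exp(contrast)
  lo <- 100 * exp(contrast - tq * se)
  hi <- 100 * exp(contrast + tq * se)
  data.frame(
    metric = metric, pe = pe, lo = lo, hi = hi,
    cv = 100 * sqrt(exp(mse) - 1), df = as.integer(df),
    pass = round(lo, 2) >= acceptance[1] & round(hi, 2) <= acceptance[2]
  )
}

#' Reconstruct a 90% confidence interval from published summary values
#'
#' Inverts [be_assess()] from a published point estimate and intra-subject
#' CV: the residual variance is recovered through the lognormal relation
#' `s2 = ln(1 + (cv/100)^2)`, the standard error as
#' `sqrt(s2 (1/n1 + 1/n2) / 2)`, and the limits as
#' `pe * exp(+/- t(1 - alpha/2 one-sided, df) * SE)` with
#' `df = n1 + n2 - 2`. With `alpha = 0.10` this uses the one-sided 0.95
#' t-quantile, the two-one-sided-tests convention.
#'
#' @param pe Point estimate (GMR, percent).
#' @param cv Intra-subject CV (percent).
#' @param n1,n2 Per-sequence subject counts.
#' @param alpha Significance level of the two one-sided tests (0.10 for a
#'   90% interval).
#' @return Named numeric `c(lo, hi)` in percent.
#' @examples
#' ci_from_summary(97.29, 19.21, 16, 16) # c(89.74, 105.48) to 2 decimals
#' @export
ci_from_summary <- function(pe, cv, n1, n2, alpha = 0.10) {
  if (pe <= 0 || cv < 0) stop("pe must be > 0 and cv >= 0", call. = FALSE)
  df <- n1 + n2 - 2
  s2 <- log(1 + (cv / 100)^2)
  se <- sqrt(s2 * (1 / n1 + 1 / n2) / 2)
  tq <- qt(1 - alpha / 2, df)
  c(lo = pe * exp(-tq * se), hi = pe * exp(tq * se))
}

#' Bioequivalence table over a set of metrics
#'
#' Runs [crossover_fit()] + [be_assess()] for each requested metric column
#' of a per-subject-period metrics table. Subjects missing a metric value
#' are dropped for that metric only; an entirely missing metric column is
#' skipped with a warning.
#'
#' @param metrics_tab A data.frame with design columns `subject`,
#'   `sequence`, `period`, `treatment` plus one column per metric.
#' @param metrics Character vector of metric column names.
#' @param acceptance Acceptance limits in percent.
#' @return A data.frame with one row per metric (see [be_assess()]), plus
#'   `n` (complete subjects analyzed).
#' @export
be_table <- function(metrics_tab, metrics, acceptance = c(80.00, 125.00)) {
  rows <- list()
  for (m in metrics) {
    if (!m %in% names(metrics_tab) || all(is.na(metrics_tab[[m]]))) {
      warning(sprintf("metric '%s' missing or empty; skipped", m))
      next
    }
    dat <- data.frame(subject = metrics_tab$subject,
                      sequence = metrics_tab$sequence,
                      period = metrics_tab$period,
                      treatment = metrics_tab$treatment,
                      value = metrics_tab[[m]])
    fit <- withCallingHandlers(
      crossover_fit(dat),
      warning = function(w) invokeRestart("muffleWarning")
    )
    row <- be_assess(fit$contrast, fit$mse, fit$df, fit$n1, fit$n2,
                     acceptance = acceptance, metric = m)
    row$n <- fit$n1 + fit$n2
    rows[[m]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
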