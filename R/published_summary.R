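#' Published bioequivalence summary rows for desvenlafaxine 100 mg
#'
#' The reported average-bioequivalence summaries of the desvenlafaxine
#' 100 mg prolonged-release crossover study that the synthetic generator
#' emulates: per metric, the geometric-mean-ratio point estimate, the
#' printed 90% confidence limits, the intra-subject CV (all percent) and
#' the BE conclusion, for the single-dose conventional metrics, the
#' single-dose curve-shape metrics, and the model-predicted steady-state
#' metrics (32 completers, 16 per sequence; the AUC0-inf row used 31
#' subjects because one profile had no estimable terminal slope). These
#' rows are inputs for [ci_from_summary()] — the deterministic CI
#' reconstruction — not outputs of this package.
#'
#' @return A data.frame with columns `analysis`, `metric`, `pe`, `lo`,
#'   `hi`, `cv`, `n`, `pass`.
#' @export
desven_be_summary <- function() {
  tab <- read.csv(text = "analysis,metric,pe,lo,hi,cv,n,pass
single_dose_conventional,auc_0_t,111.67,104.39,119.45,15.97,32,TRUE
single_dose_conventional,auc_0_inf,111.33,103.97,119.22,15.95,31,TRUE
single_dose_conventional,cmax,97.29,89.74,105.48,19.21,32,TRUE
single_dose_shape,c_tau,125.51,112.57,139.93,26.06,32,FALSE
single_dose_shape,pauc_0_8,90.18,83.36,97.56,18.69,32,TRUE
single_dose_shape,pauc_8_t,118.68,109.37,128.70,19.35,32,FALSE
single_dose_shape,pauc_0_10,92.05,85.39,99.24,17.86,32,TRUE
single_dose_shape,pauc_10_t,121.23,111.21,132.14,20.53,32,FALSE
single_dose_shape,pauc_0_12,94.91,88.14,102.19,17.56,32,TRUE
single_dose_shape,pauc_12_t,122.91,112.17,134.67,21.79,32,FALSE
single_dose_shape,pauc_0_16,101.08,94.30,108.33,16.45,32,TRUE
single_dose_shape,pauc_16_t,123.70,111.78,136.89,24.22,32,FALSE
single_dose_shape,pauc_0_20,106.04,99.29,113.24,15.58,32,TRUE
single_dose_shape,pauc_20_t,122.11,109.36,136.35,26.44,32,FALSE
single_dose_shape,pauc_0_24,108.90,102.15,116.09,15.16,32,TRUE
single_dose_shape,pauc_24_t,120.14,106.93,134.97,27.97,32,FALSE
single_dose_shape,hvd,123.79,110.19,139.07,27.96,32,FALSE
steady_state,auc_0_tau,106.37,99.30,113.94,16.31,32,TRUE
steady_state,cmax_ss,102.79,95.28,110.89,18.02,32,TRUE
steady_state,c_tau_ss,123.41,111.08,137.10,25.18,32,FALSE",
    stringsAsFactors = FALSE)
  tab$pass <- as.logical(tab$pass)
  tab
}
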