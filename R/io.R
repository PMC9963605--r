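#' Read a long-format study dataset
#'
#' Reads and validates the package's interchange format: a CSV with header
#' `subject,sequence,period,treatment,time_h,conc,blq` (one observation
#' record per row; `conc` empty for BLQ records). Malformed content is
#' reported with the offending row numbers.
#'
#' @param path Path to a CSV file.
#' @return A validated study data.frame.
#' @export
read_study <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "sequence", "period", "treatment", "time_h", "conc", "blq")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  df$blq <- as.logical(df$blq)
  bad_trt <- which(!df$treatment %in% c("R", "T"))
  if (length(bad_trt) > 0) {
    stop(sprintf("unknown treatment code at row(s) %s",
                 paste(utils::head(bad_trt, 5), collapse = ", ")), call. = FALSE)
  }
  bad_seq <- which(!df$sequence %in% c("RT", "TR"))
  if (length(bad_seq) > 0) {
    stop(sprintf("unknown sequence at row(s) %s",
                 paste(utils::head(bad_seq, 5), collapse = ", ")), call. = FALSE)
  }
  key <- paste(df$subject, df$period, df$time_h)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(sprintf("duplicate (subject, period, time) at row(s) %s",
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  mismatch <- which(substr(df$sequence, df$period, df$period) != df$treatment)
  if (length(mismatch) > 0) {
    stop(sprintf("treatment inconsistent with sequence/period at row(s) %s",
                 paste(utils::head(mismatch, 5), collapse = ", ")), call. = FALSE)
  }
  df[order(df$subject, df$period, df$time_h), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Write a study dataset
#'
#' @param study A study data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study <- function(study, path) {
  write.csv(study, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read or write a run configuration
#'
#' Configurations serialize to JSON (`.json`) or YAML (`.yaml`/`.yml`) and
#' round-trip through file unchanged.
#'
#' @param path File path; the extension selects the format.
#' @return For `read_config`, the configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  # numeric vectors survive both formats; restore the ones we know
  for (k in c("schedule", "cuts", "acceptance")) {
    if (!is.null(cfg[[k]])) cfg[[k]] <- as.numeric(unlist(cfg[[k]]))
  }
  cfg
}

#' @rdname read_config
#' @param config A configuration list (see [case_study_config()]).
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(config, path)
  } else {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Write a case-study report directory
#'
#' Writes a deterministic file set — the four result tables, the
#' accumulation screen, the configuration echo and a run log — and
#' returns a manifest listing every artifact with its MD5 content hash.
#' Writing the same report twice yields identical hashes.
#'
#' @param report A `case_study_report` from [run_case_study()].
#' @param dir Output directory (created if needed).
#' @return A data.frame manifest (`file`, `md5`), invisibly written to
#'   `manifest.csv` as well.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "case_study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(obj, file) {
    write.csv(obj, file.path(dir, file), row.names = FALSE, quote = FALSE, na = "")
    file
  }
  files <- c(
    wr(report$be_single_conventional, "be_single_conventional.csv"),
    wr(report$be_single_alternative, "be_single_alternative.csv"),
    wr(report$be_steady_state, "be_steady_state.csv"),
    wr(report$sensitivity, "sensitivity.csv"),
    wr(data.frame(treatment = names(report$accumulation$ratio),
                  ratio = as.numeric(report$accumulation$ratio),
                  significant = report$accumulation$significant),
       "accumulation.csv")
  )
  write_config(report$config, file.path(dir, "config.json"))
  files <- c(files, "config.json")
  cfg_md5 <- as.character(tools::md5sum(file.path(dir, "config.json")))
  log_lines <- c(
    sprintf("pkshape %s", as.character(utils::packageVersion("pkshape"))),
    sprintf("seed: %d", report$seed),
    sprintf("config_fingerprint: %s", cfg_md5),
    sprintf("n_converged: %d", report$n_converged),
    "stages: simulate nca accumulation be_single map_fit predict_ss be_steady_state"
  )
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  files <- c(files, "run_log.txt")
  manifest <- data.frame(
    file = files,
    md5 = as.character(tools::md5sum(file.path(dir, files))),
    stringsAsFactors = FALSE
  )
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(manifest)
}
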