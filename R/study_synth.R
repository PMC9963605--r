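#' Population model parameters
#'
#' Bundles the typical PK parameters with the variability components of a
#' population model: log-scale inter-individual standard deviations (IIV,
#' one per parameter), log-scale inter-occasion standard deviations (IOV,
#' on `ka`, `ktr` and `CL`; the central volume carries none), the residual
#' standard deviation of the additive-on-log-scale error model, and the
#' lower limit of quantification used to censor simulated observations.
#'
#' Percent variabilities as conventionally reported (e.g. "IIV 17%") map to
#' log-scale standard deviations as `sd = pct/100`.
#'
#' @param typicals A [pk_params()] object of typical values.
#' @param iiv_sd Named numeric (`ka`, `ktr`, `CL`, `V1`), log-scale SDs >= 0.
#' @param iov_sd Named numeric (`ka`, `ktr`, `CL`), log-scale SDs >= 0.
#' @param ruv_sd Residual SD on the log scale, >= 0.
#' @param lloq Lower limit of quantification (ng/mL), > 0.
#' @return An object of class `pop_params`.
#' @export
pop_params <- function(typicals, iiv_sd, iov_sd, ruv_sd, lloq) {
  stopifnot(inherits(typicals, "pk_params"))
  iiv_sd <- iiv_sd[c("ka", "ktr", "CL", "V1")]
  iov_sd <- iov_sd[c("ka", "ktr", "CL")]
  if (anyNA(iiv_sd) || anyNA(iov_sd)) {
    stop("iiv_sd needs names ka, ktr, CL, V1; iov_sd needs ka, ktr, CL",
         call. = FALSE)
  }
  if (any(c(iiv_sd, iov_sd, ruv_sd) < 0)) stop("SDs must be >= 0", call. = FALSE)
  if (!is.finite(lloq) || lloq <= 0) stop("lloq must be > 0", call. = FALSE)
  structure(list(typicals = typicals, iiv_sd = iiv_sd, iov_sd = iov_sd,
                 ruv_sd = ruv_sd, lloq = lloq),
            class = "pop_params")
}

#' Published population model for desvenlafaxine 100 mg prolonged release
#'
#' The population PK parameter estimates reported for desvenlafaxine
#' 100 mg prolonged-release tablets in healthy fasted volunteers after a
#' single dose (two transit compartments): typical values
#' ka = 7.37e-2 /h, ktr = 18.50 /h, CL = 18.65 L/h, V1 = 83.31 L; IIV of
#' 15/39/17/43% on ka/ktr/CL/V1; IOV of 13/27/14% on ka/ktr/CL; residual
#' SD 18% (additive on the log scale); LLOQ 1.00 ng/mL. This fixture is
#' the default population for the synthetic-study generator.
#'
#' @return A [pop_params()] object.
#' @export
desven_population <- function() {
  pop_params(
    typicals = pk_params(ka = 7.37e-2, ktr = 18.50, CL = 18.65, V1 = 83.31,
                         n_transit = 2L),
    iiv_sd = c(ka = 0.15, ktr = 0.39, CL = 0.17, V1 = 0.43),
    iov_sd = c(ka = 0.13, ktr = 0.27, CL = 0.14),
    ruv_sd = 0.18,
    lloq = 1.00
  )
}

#' Formulation (curve-shape) effect
#'
#' Multiplicative factors applied to the test product's absorption rate
#' constants. Disposition (`CL`, `V1`) is a property of the subject, not
#' the product, and is never modified; a formulation can only change how
#' fast drug is presented for absorption. Reference factors are identically
#' 1.
#'
#' @param ka_factor,ktr_factor Positive multiplicative factors on the test
#'   product's `ka` and `ktr`.
#' @return An object of class `formulation_effect`.
#' @export
formulation_effect <- function(ka_factor = 1, ktr_factor = 1) {
  if (any(c(ka_factor, ktr_factor) <= 0)) {
    stop("effect factors must be > 0", call. = FALSE)
  }
  structure(list(ka_factor = ka_factor, ktr_factor = ktr_factor),
            class = "formulation_effect")
}

#' Draw individual parameter sets from the population
#'
#' Inter-individual variability is exponential:
#' `parameter_i = typical * exp(eta_i)` with `eta_i ~ N(0, iiv_sd^2)`,
#' independent across parameters (diagonal covariance).
#'
#' @param pop A [pop_params()] object.
#' @param n Number of individuals (>= 1).
#' @param seed Optional integer seed; `NULL` continues the current stream.
#' @return A data.frame with columns `subject`, `eta_ka`, `eta_ktr`,
#'   `eta_CL`, `eta_V1`, `ka`, `ktr`, `CL`, `V1`.
#' @export
draw_individuals <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "pop_params"), n >= 1)
  local_seed(seed)
  typ <- pop$typicals
  eta <- vapply(c("ka", "ktr", "CL", "V1"),
                function(p) rnorm(n, 0, pop$iiv_sd[[p]]),
                numeric(n))
  eta <- matrix(eta, nrow = n,
                dimnames = list(NULL, c("ka", "ktr", "CL", "V1")))
  data.frame(
    subject = seq_len(n),
    eta_ka = eta[, "ka"], eta_ktr = eta[, "ktr"],
    eta_CL = eta[, "CL"], eta_V1 = eta[, "V1"],
    ka = typ$ka * exp(eta[, "ka"]),
    ktr = typ$ktr * exp(eta[, "ktr"]),
    CL = typ$CL * exp(eta[, "CL"]),
    V1 = typ$V1 * exp(eta[, "V1"])
  )
}

#' Apply inter-occasion variability for one occasion
#'
#' Occasion-level parameters are `individual * exp(kappa)` with
#' `kappa ~ N(0, iov_sd^2)` drawn independently per occasion for `ka`,
#' `ktr` and `CL`; `V1` carries no IOV.
#'
#' @param individuals A data.frame from [draw_individuals()].
#' @param occasion Occasion index (1 or 2; informational).
#' @param pop A [pop_params()] object.
#' @param seed Optional integer seed; `NULL` continues the current stream.
#' @return `individuals` with occasion-level `ka`, `ktr`, `CL` and added
#'   columns `occasion`, `kappa_ka`, `kappa_ktr`, `kappa_CL`.
#' @export
apply_occasion <- function(individuals, occasion, pop, seed = NULL) {
  stopifnot(inherits(pop, "pop_params"), occasion %in% c(1, 2))
  local_seed(seed)
  n <- nrow(individuals)
  out <- individuals
  out$occasion <- occasion
  for (p in c("ka", "ktr", "CL")) {
    kap <- rnorm(n, 0, pop$iov_sd[[p]])
    out[[paste0("kappa_", p)]] <- kap
    out[[p]] <- out[[p]] * exp(kap)
  }
  out
}

#' Simulate a 2x2 crossover bioequivalence study
#'
#' Generates a long-format synthetic study with the reference design:
#' block-randomized RT/TR sequences, subject-level IIV, occasion-level IOV
#' per period, the test product's absorption factors applied in the test
#' period, lognormal residual error
#' (`observed = prediction * exp(eps)`, `eps ~ N(0, ruv_sd^2)`), and LLOQ
#' censoring: observations below `lloq` are flagged BLQ and carry `NA`
#' concentration (the record is retained for audit). The pre-dose sample is
#' always BLQ since the true concentration is 0.
#'
#' @param n_subjects Even number of completers (block randomization).
#' @param pop A [pop_params()] object.
#' @param effect A [formulation_effect()] for the test product.
#' @param regimen A [dose_regimen()]; the crossover periods are single-dose.
#' @param schedule Sampling times (h), strictly increasing, starting at 0.
#' @param seed Optional integer seed; `NULL` continues the current stream.
#' @param block_size Randomization block size (2 or 4).
#' @return A data.frame with columns `subject`, `sequence`, `period`,
#'   `treatment`, `time_h`, `conc`, `blq`.
#' @examples
#' study <- simulate_study(n_subjects = 4, seed = 42)
#' head(study)
#' @export
simulate_study <- function(n_subjects = 32,
                           pop = desven_population(),
                           effect = formulation_effect(ka_factor = 0.75),
                           regimen = dose_regimen(dose = 100, tau = 24),
                           schedule = desven_schedule(),
                           seed = NULL,
                           block_size = 2) {
  stopifnot(inherits(pop, "pop_params"), inherits(effect, "formulation_effect"),
            inherits(regimen, "dose_regimen"))
  check_schedule(schedule)
  if (n_subjects < 2 || n_subjects %% 2 != 0) {
    stop("n_subjects must be even for balanced block randomization", call. = FALSE)
  }
  if (!block_size %in% c(2, 4) || n_subjects %% block_size != 0) {
    stop("block_size must be 2 or 4 and divide n_subjects", call. = FALSE)
  }
  local_seed(seed)

  # block randomization of sequences
  seqs <- unlist(lapply(seq_len(n_subjects / block_size), function(b) {
    sample(rep(c("RT", "TR"), block_size / 2))
  }))

  ind <- draw_individuals(pop, n_subjects)
  occ <- list(apply_occasion(ind, 1, pop), apply_occasion(ind, 2, pop))

  typ <- pop$typicals
  rows <- vector("list", n_subjects * 2L)
  for (i in seq_len(n_subjects)) {
    for (per in 1:2) {
      trt <- substr(seqs[i], per, per)
      o <- occ[[per]][i, ]
      ka <- o$ka; ktr <- o$ktr
      if (trt == "T") {
        ka <- ka * effect$ka_factor
        ktr <- ktr * effect$ktr_factor
      }
      p <- pk_params(ka = ka, ktr = ktr, CL = o$CL, V1 = o$V1,
                     n_transit = typ$n_transit)
      pred <- conc_single_dose(p, regimen$dose, schedule)
      obs <- pred * exp(rnorm(length(schedule), 0, pop$ruv_sd))
      blq <- obs < pop$lloq
      rows[[(i - 1L) * 2L + per]] <- data.frame(
        subject = i, sequence = seqs[i], period = per, treatment = trt,
        time_h = schedule, conc = ifelse(blq, NA_real_, obs), blq = blq
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
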