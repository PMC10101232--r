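#' Sparse therapeutic-drug-monitoring sampling design
#'
#' Describes the sparse steady-state sampling emulated by
#' [simulate_observations()]: every subject contributes one steady-state
#' trough (30 min before a dose), a configurable fraction contributes a
#' second sample, and a second sample is a peak (1 h after the end of an
#' infusion) with probability `peak_fraction`, otherwise a later trough.
#'
#' @param second_fraction probability that a subject contributes a second
#'   sample.  The default 0.32 reproduces roughly 214 observations from 162
#'   subjects.
#' @param peak_fraction probability that a second sample is a peak rather
#'   than a trough (one study hospital also drew peaks).
#' @param lloq lower limit of quantification (ug/ml); observations below it
#'   are flagged (and optionally censored) when set.  `NA` disables
#'   below-quantification handling, the default, since assay limits of
#'   0.5-4 ug/ml are rarely binding for troughs.
#' @return an object of class `obs_design`.
#' @export
obs_design <- function(second_fraction = 0.32, peak_fraction = 0.10,
                       lloq = NA_real_) {
  stopifnot(second_fraction >= 0, second_fraction <= 1,
            peak_fraction >= 0, peak_fraction <= 1)
  structure(list(second_fraction = second_fraction,
                 peak_fraction = peak_fraction, lloq = lloq),
            class = "obs_design")
}

residual_sd <- function(f, model) {
  switch(model$error_model,
         proportional = model$resid_b * abs(f),
         constant = rep(model$resid_a, length(f)),
         combined = sqrt(model$resid_a^2 + (model$resid_b * f)^2))
}

#' Simulate sparse steady-state concentration data for a cohort
#'
#' Draws lognormal individual parameters for every subject, doses each
#' subject per its regimen from time 0, and samples trough (and occasional
#' peak) concentrations once the subject is at steady state, defined as the
#' later of five typical (population-predicted) half-lives and 72 h of
#' dosing.  Troughs are
#' drawn exactly 30 min before a dose; peaks 1 h after an infusion ends.
#' Residual error follows the model's error model (proportional by default,
#' `y = f * (1 + b * eps)`).  The generating random effects are attached as
#' `attr(x, "etas")` for parameter-recovery experiments.
#'
#' @param cohort a [sample_cohort()] data frame.
#' @param model the generating [vanc_model()].
#' @param design an [obs_design()].
#' @param regimens optional data frame with columns `dose_per_kg`,
#'   `interval`, `infusion_duration`, one row per subject.  By default each
#'   subject gets its `reference` regimen.
#' @param reference dosing reference used when `regimens` is missing.
#' @param dose_per_kg point dose passed to [reference_regimen()].
#' @param seed integer seed; the output is deterministic given the seed.
#' @return an event table (class `event_table`): a long data frame with
#'   columns `ID`, `TIME`, `EVID` (1 dose, 0 observation), `AMT`, `RATE`,
#'   `DUR`, `DV`, `OCC` and the covariate columns `WT`, `PMA`, `PNA`, `GA`,
#'   `SCR`, `SEX`.
#' @export
simulate_observations <- function(cohort, model = vanc_model(),
                                  design = obs_design(),
                                  regimens = NULL,
                                  reference = "neofax", dose_per_kg = 15,
                                  seed = 1L) {
  stopifnot(inherits(model, "vanc_model"), inherits(design, "obs_design"))
  n <- nrow(cohort)
  if (n == 0) stop("empty cohort")
  set.seed(as.integer(seed))
  if (is.null(regimens)) {
    regl <- lapply(seq_len(n), function(i)
      reference_regimen(cohort[i, ], reference, dose_per_kg))
    regimens <- data.frame(
      dose_per_kg = vapply(regl, `[[`, 0, "dose_per_kg"),
      interval = vapply(regl, `[[`, 0, "interval"),
      infusion_duration = vapply(regl, `[[`, 0, "infusion_duration"))
  }
  stopifnot(nrow(regimens) == n)

  tp <- typical_parameters(cohort, model)
  eta_cl <- rnorm(n, 0, model$omega_cl)
  eta_v <- rnorm(n, 0, model$omega_v)
  cl_i <- tp$cl * exp(eta_cl)
  v_i <- tp$v * exp(eta_v)
  second <- runif(n) < design$second_fraction
  second_is_peak <- runif(n) < design$peak_fraction

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tau <- regimens$interval[i]
    tinf <- regimens$infusion_duration[i]
    dose <- regimens$dose_per_kg[i] * cohort$weight[i]
    rate <- dose / tinf
    # steady-state waiting time from the *typical* half-life: sampling
    # times must not depend on a subject's own random effects, or the
    # times themselves become informative of eta and bias any standard
    # marginal-likelihood fit (and no clinician knows individual t1/2
    # before the first level anyway)
    thalf <- log(2) / (tp$cl[i] / tp$v[i])
    t_ss <- max(5 * thalf, 72)
    m <- ceiling(t_ss / tau)              # first dose index (0-based) at ss
    obs_t <- m * tau - 0.5                # trough 30 min before dose m
    obs_occ <- "trough"
    if (second[i]) {
      if (second_is_peak[i]) {
        obs_t <- c(obs_t, m * tau + tinf + 1)
        obs_occ <- c(obs_occ, "peak")
      } else {
        obs_t <- c(obs_t, (m + 1) * tau - 0.5)
        obs_occ <- c(obs_occ, "trough")
      }
    }
    n_dose <- floor(max(obs_t) / tau) + 1
    dose_t <- tau * (seq_len(n_dose) - 1)
    f <- vapply(obs_t, function(tt)
      sum(infusion_conc(tt - dose_t, rate, tinf, cl_i[i], v_i[i])), 0)
    eps <- rnorm(length(f))
    y <- f + residual_sd(f, model) * eps
    y <- pmax(y, 0)
    rows[[i]] <- data.frame(
      ID = cohort$subject_id[i],
      TIME = c(dose_t, obs_t),
      EVID = c(rep(1L, n_dose), rep(0L, length(obs_t))),
      AMT = c(rep(dose, n_dose), rep(NA_real_, length(obs_t))),
      RATE = c(rep(rate, n_dose), rep(NA_real_, length(obs_t))),
      DUR = c(rep(tinf, n_dose), rep(NA_real_, length(obs_t))),
      DV = c(rep(NA_real_, n_dose), y),
      OCC = c(rep(NA_character_, n_dose), obs_occ),
      WT = cohort$weight[i], PMA = cohort$pma[i], PNA = cohort$pna[i],
      GA = cohort$ga[i], SCR = cohort$scr[i], SEX = cohort$sex[i])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$ID, out$TIME, -out$EVID), ]
  rownames(out) <- NULL
  if (!is.na(design$lloq)) {
    blq <- out$EVID == 0 & out$DV < design$lloq
    out$BLQ <- ifelse(out$EVID == 0, as.integer(blq), NA_integer_)
  }
  class(out) <- c("event_table", "data.frame")
  attr(out, "etas") <- data.frame(subject_id = cohort$subject_id,
                                  eta_cl = eta_cl, eta_v = eta_v,
                                  cl_i = cl_i, v_i = v_i)
  out
}

#' Split an event table into training and validation sets by subject
#'
#' Subjects (never individual observations) are assigned at random:
#' `round(fraction * n)` subjects form the training set and the remainder
#' the validation set.  The two tables are disjoint, exhaustive, and
#' deterministic given the seed.
#'
#' @param table an `event_table`.
#' @param fraction training fraction, strictly between 0 and 1.
#' @param seed integer seed.
#' @return a list with elements `train` and `validation`.
#' @export
split_dataset <- function(table, fraction = 0.7, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1")
  ids <- unique(table$ID)
  if (length(ids) < 2) stop("need at least two subjects to split")
  set.seed(as.integer(seed))
  n_train <- round(fraction * length(ids))
  n_train <- min(max(n_train, 1), length(ids) - 1)
  train_ids <- sample(ids, n_train)
  keep_attrs <- function(x, id_set) {
    out <- x[x$ID %in% id_set, ]
    rownames(out) <- NULL
    class(out) <- c("event_table", "data.frame")
    et <- attr(x, "etas")
    if (!is.null(et)) attr(out, "etas") <- et[et$subject_id %in% id_set, ]
    out
  }
  list(train = keep_attrs(table, train_ids),
       validation = keep_attrs(table, setdiff(ids, train_ids)))
}
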