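#' Specification of a virtual VLBW neonatal cohort
#'
#' Describes the joint covariate distribution of a very-low-birth-weight
#' cohort: truncated-normal marginals for current body weight, postmenstrual
#' age and serum creatinine tied together by a Gaussian copula, plus a
#' uniform postnatal age.  The defaults reproduce the pooled demographics of
#' the modelled study population (weight 1.0 +/- 0.29 kg, PMA 30.0 +/- 3.2
#' weeks, Scr 0.64 +/- 0.22 mg/dl) truncated to the simulation ranges
#' 0.46-2.2 kg, 22-42 weeks and 0.2-1.2 mg/dl.  Latent normal parameters are
#' moment-matched so that the *truncated* marginals hit the requested mean
#' and sd.
#'
#' @param n number of neonates.
#' @param weight_mean,weight_sd target mean and sd of body weight (kg).
#' @param pma_mean,pma_sd target mean and sd of postmenstrual age (weeks).
#' @param scr_mean,scr_sd target mean and sd of serum creatinine (mg/dl,
#'   Jaffe scale).
#' @param pna_range inclusive range of postnatal age (days); sampled
#'   uniformly on the integers.
#' @param ranges named list of truncation bounds for `weight`, `pma`, `scr`.
#' @param copula_corr 3x3 positive-definite correlation matrix of the
#'   Gaussian copula in the order (weight, pma, scr).  The default couples
#'   weight to maturation (0.7) and creatinine weakly negatively to PMA
#'   (-0.2).
#' @param seed integer seed making [sample_cohort()] deterministic.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n,
                        weight_mean = 1.0, weight_sd = 0.29,
                        pma_mean = 30.0, pma_sd = 3.2,
                        scr_mean = 0.64, scr_sd = 0.22,
                        pna_range = c(1, 30),
                        ranges = list(weight = c(0.46, 2.2),
                                      pma = c(22, 42),
                                      scr = c(0.2, 1.2)),
                        copula_corr = matrix(c(1, 0.7, 0,
                                               0.7, 1, -0.2,
                                               0, -0.2, 1), 3, 3),
                        seed = 1L) {
  stopifnot(length(n) == 1, n >= 0, n == floor(n))
  stopifnot(weight_sd > 0, pma_sd > 0, scr_sd > 0)
  stopifnot(is.list(ranges), all(c("weight", "pma", "scr") %in% names(ranges)))
  targets <- list(weight = c(weight_mean, weight_sd),
                  pma = c(pma_mean, pma_sd),
                  scr = c(scr_mean, scr_sd))
  for (nm in names(targets)) {
    r <- ranges[[nm]]
    if (length(r) != 2 || r[1] >= r[2])
      stop("invalid truncation range for ", nm)
    m <- targets[[nm]][1]
    if (m <= r[1] || m >= r[2])
      stop("target mean for ", nm, " lies outside its truncation range")
  }
  if (!isTRUE(all.equal(copula_corr, t(copula_corr))) ||
      any(eigen(copula_corr, symmetric = TRUE,
                only.values = TRUE)$values <= 1e-10))
    stop("copula_corr must be a symmetric positive-definite matrix")
  if (pna_range[1] < 0 || pna_range[1] > pna_range[2])
    stop("invalid pna_range")
  structure(list(n = as.integer(n), targets = targets, ranges = ranges,
                 pna_range = pna_range, copula_corr = copula_corr,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# mean and sd of a normal(mu, s) truncated to [lo, hi]
truncnorm_moments <- function(mu, s, lo, hi) {
  a <- (lo - mu) / s; b <- (hi - mu) / s
  z <- pnorm(b) - pnorm(a)
  m <- mu + s * (dnorm(a) - dnorm(b)) / z
  v <- s^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / z -
                ((dnorm(a) - dnorm(b)) / z)^2)
  c(mean = m, sd = sqrt(v))
}

# latent (mu, s) such that the truncated marginal has the target moments
truncnorm_match <- function(target_mean, target_sd, lo, hi) {
  obj <- function(p) {
    mm <- truncnorm_moments(p[1], exp(p[2]), lo, hi)
    sum((mm - c(target_mean, target_sd))^2)
  }
  p <- optim(c(target_mean, log(target_sd)), obj,
             control = list(reltol = 1e-12))$par
  c(mu = p[1], sigma = exp(p[2]))
}

#' Sample a virtual VLBW cohort
#'
#' Draws covariate profiles from the joint distribution described by a
#' [cohort_spec()].  Latent Gaussian-copula vectors are mapped through the
#' moment-matched marginal scales and out-of-range vectors are rejected and
#' redrawn (no clipping, so the bounds carry no probability atoms).
#' Postnatal age is uniform on the configured integer range, gestational age
#' is `pma - pna/7`, birth weight is back-calculated from current weight
#' assuming 0.2%/day net gain, and `elbw` flags birth weight below 1 kg.
#'
#' @param spec a [cohort_spec()].
#' @return a data frame of class `vanc_cohort` with columns `subject_id`,
#'   `weight`, `pma`, `pna`, `ga`, `scr`, `sex`, `birth_weight`, `elbw`.
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cols <- c("subject_id", "weight", "pma", "pna", "ga", "scr", "sex",
            "birth_weight", "elbw")
  if (spec$n == 0) {
    out <- data.frame(subject_id = integer(), weight = numeric(),
                      pma = numeric(), pna = integer(), ga = numeric(),
                      scr = numeric(), sex = character(),
                      birth_weight = numeric(), elbw = logical())
    class(out) <- c("vanc_cohort", "data.frame")
    return(out)
  }
  set.seed(spec$seed)
  lat <- lapply(names(spec$targets), function(nm) {
    t <- spec$targets[[nm]]; r <- spec$ranges[[nm]]
    truncnorm_match(t[1], t[2], r[1], r[2])
  })
  names(lat) <- names(spec$targets)
  lo <- vapply(spec$ranges[c("weight", "pma", "scr")], `[`, 0, 1)
  hi <- vapply(spec$ranges[c("weight", "pma", "scr")], `[`, 0, 2)
  acc <- matrix(numeric(0), 0, 3)
  guard <- 0
  while (nrow(acc) < spec$n) {
    m <- max(spec$n * 2L, 1000L)
    z <- MASS::mvrnorm(m, mu = rep(0, 3), Sigma = spec$copula_corr)
    x <- cbind(lat$weight[1] + lat$weight[2] * z[, 1],
               lat$pma[1] + lat$pma[2] * z[, 2],
               lat$scr[1] + lat$scr[2] * z[, 3])
    keep <- x[, 1] >= lo[1] & x[, 1] <= hi[1] &
      x[, 2] >= lo[2] & x[, 2] <= hi[2] &
      x[, 3] >= lo[3] & x[, 3] <= hi[3]
    acc <- rbind(acc, x[keep, , drop = FALSE])
    guard <- guard + 1
    if (guard > 1000) stop("rejection sampling failed; check ranges")
  }
  acc <- acc[seq_len(spec$n), , drop = FALSE]
  pna <- sample(seq(spec$pna_range[1], spec$pna_range[2]), spec$n,
                replace = TRUE)
  sex <- sample(c("male", "female", "missing"), spec$n, replace = TRUE,
                prob = c(0.46, 0.33, 0.21))
  birth_weight <- acc[, 1] / (1 + 0.002 * pna)
  out <- data.frame(subject_id = seq_len(spec$n),
                    weight = acc[, 1], pma = acc[, 2], pna = pna,
                    ga = acc[, 2] - pna / 7, scr = acc[, 3], sex = sex,
                    birth_weight = birth_weight, elbw = birth_weight < 1.0)
  class(out) <- c("vanc_cohort", "data.frame")
  out
}

#' Initial dosing regimen from a neonatal dosing reference
#'
#' Looks up the empirical starting regimen a NICU would prescribe, following
#' the three tabulated reference policies: NeoFax (PMA x PNA), Lexicomp
#' age-directed (PMA x PNA), or Lexicomp kidney-function-based dosing
#' (GA x Scr).  Where the reference prints a dose range (10-15 mg/kg) the
#' configured point dose is used.  Creatinine is rounded to one decimal
#' before the kidney-function lookup, matching the table's resolution.
#'
#' @param cov a single covariate profile (one row of a [sample_cohort()]
#'   data frame, or any list with the needed fields).
#' @param reference which dosing reference to apply.
#' @param dose_per_kg point dose (mg/kg) used where the reference prints a
#'   range.
#' @param infusion_duration infusion duration (h) attached to the regimen.
#' @return a [regimen()].
#' @export
reference_regimen <- function(cov,
                              reference = c("neofax", "lexicomp_age",
                                            "lexicomp_renal"),
                              dose_per_kg = 15, infusion_duration = 1) {
  reference <- match.arg(reference)
  pma <- cov$pma; pna <- cov$pna
  if (reference == "neofax") {
    if (is.null(pma) || is.null(pna) || is.na(pma) || is.na(pna))
      stop("neofax lookup needs pma and pna")
    iv <- if (pma <= 29) {
      if (pna <= 14) 18 else 12
    } else if (pma < 37) {
      if (pna <= 14) 12 else 8
    } else if (pma < 45) {
      if (pna <= 7) 12 else 8
    } else 6
    return(regimen(dose_per_kg, iv, infusion_duration))
  }
  if (reference == "lexicomp_age") {
    if (is.null(pma) || is.null(pna) || is.na(pma) || is.na(pna))
      stop("lexicomp_age lookup needs pma and pna")
    if (pma > 45) stop("pma outside the lexicomp age-directed table")
    iv <- if (pma <= 29) {
      if (pna <= 21) 18 else 12
    } else if (pma < 37) {
      if (pna <= 14) 12 else 8
    } else {
      if (pna <= 7) 12 else 8
    }
    return(regimen(15, iv, infusion_duration))
  }
  # lexicomp_renal: GA x Scr lookup
  ga <- cov$ga; scr <- cov$scr
  if (is.null(ga) || is.null(scr) || is.na(ga) || is.na(scr))
    stop("lexicomp_renal lookup needs ga and scr")
  r <- round(scr, 1)
  if (ga <= 28) {
    if (r < 0.5) return(regimen(15, 12, infusion_duration))
    if (r <= 0.7) return(regimen(20, 24, infusion_duration))
    if (r <= 1.0) return(regimen(15, 24, infusion_duration))
    if (r <= 1.4) return(regimen(10, 24, infusion_duration))
    return(regimen(15, 48, infusion_duration))
  }
  if (r < 0.7) return(regimen(15, 12, infusion_duration))
  if (r <= 0.9) return(regimen(20, 24, infusion_duration))
  if (r <= 1.2) return(regimen(15, 24, infusion_duration))
  if (r <= 1.6) return(regimen(10, 24, infusion_duration))
  regimen(15, 48, infusion_duration)
}
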