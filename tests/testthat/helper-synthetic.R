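# Shared fixtures, built in code at test time.

table3_model <- function(...) vanc_model(...)

# a small deterministic cohort for unit tests
tiny_cohort <- function(n = 12, seed = 42) {
  sample_cohort(cohort_spec(n, seed = seed))
}

# rich, nearly noise-free dataset for identifiable-limit checks:
# every subject sampled densely around steady state, including on-infusion
# and post-infusion points that pin V as well as Cl
rich_dataset <- function(n = 30, model = vanc_model(), seed = 1,
                         obs_times = c(72.5, 73.5, 75, 78, 83.5)) {
  set.seed(seed)
  co <- sample_cohort(cohort_spec(n, seed = seed))
  tp <- typical_parameters(co, model)
  tau <- 12
  rows <- lapply(seq_len(n), function(i) {
    eta1 <- rnorm(1, 0, model$omega_cl)
    eta2 <- rnorm(1, 0, model$omega_v)
    cl <- tp$cl[i] * exp(eta1)
    v <- tp$v[i] * exp(eta2)
    dose <- 15 * co$weight[i]
    nd <- floor(max(obs_times) / tau) + 1
    dose_t <- tau * (seq_len(nd) - 1)
    f <- vapply(obs_times, function(tt)
      sum(vancneo:::infusion_conc(tt - dose_t, dose, 1, cl, v)), 0)
    y <- pmax(f * (1 + model$resid_b * rnorm(length(f))), 1e-3)
    k <- length(obs_times)
    data.frame(ID = i, TIME = c(dose_t, obs_times),
               EVID = c(rep(1L, nd), rep(0L, k)),
               AMT = c(rep(dose, nd), rep(NA, k)),
               RATE = c(rep(dose, nd), rep(NA, k)),
               DUR = c(rep(1, nd), rep(NA, k)),
               DV = c(rep(NA, nd), y), OCC = NA_character_,
               WT = co$weight[i], PMA = co$pma[i], PNA = co$pna[i],
               GA = co$ga[i], SCR = co$scr[i], SEX = "male")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("event_table", "data.frame")
  out
}

# single-subject event table with explicit dose/observation times
one_subject_table <- function(dose_mg = 15, tau = 12, tinf = 1,
                              obs_times = 83.5, dv = 10,
                              wt = 0.93, pma = 30, scr = 0.6) {
  nd <- floor(max(obs_times) / tau) + 1
  dose_t <- tau * (seq_len(nd) - 1)
  k <- length(obs_times)
  out <- data.frame(ID = 1L, TIME = c(dose_t, obs_times),
                    EVID = c(rep(1L, nd), rep(0L, k)),
                    AMT = c(rep(dose_mg, nd), rep(NA, k)),
                    RATE = c(rep(dose_mg / tinf, nd), rep(NA, k)),
                    DUR = c(rep(tinf, nd), rep(NA, k)),
                    DV = c(rep(NA, nd), dv), OCC = NA_character_,
                    WT = wt, PMA = pma, PNA = 10, GA = pma - 10 / 7,
                    SCR = scr, SEX = "female")
  out <- out[order(out$TIME, -out$EVID), ]
  class(out) <- c("event_table", "data.frame")
  out
}
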