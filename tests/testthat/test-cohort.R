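test_that("cohort sampling hits the target marginals inside the bounds", {
  co <- sample_cohort(cohort_spec(10000, seed = 9))
  expect_equal(nrow(co), 10000)
  expect_equal(mean(co$weight), 1.0, tolerance = 0.012)
  expect_equal(mean(co$scr), 0.64, tolerance = 0.012)
  expect_equal(mean(co$pma), 30.0, tolerance = 0.15)
  expect_true(all(co$weight >= 0.46 & co$weight <= 2.2))
  expect_true(all(co$pma >= 22 & co$pma <= 42))
  expect_true(all(co$scr >= 0.2 & co$scr <= 1.2))
  expect_true(all(co$pma >= co$ga))
  # extremely-low-birth-weight share near the study's 58%
  expect_gt(mean(co$elbw), 0.53)
  expect_lt(mean(co$elbw), 0.63)
  # weight tracks maturation through the copula
  expect_gt(cor(co$weight, co$pma), 0.5)
})

test_that("cohort sampling is deterministic and validates its spec", {
  a <- sample_cohort(cohort_spec(50, seed = 3))
  b <- sample_cohort(cohort_spec(50, seed = 3))
  expect_identical(a, b)
  expect_equal(nrow(sample_cohort(cohort_spec(0))), 0)
  expect_error(cohort_spec(10, weight_mean = 3), "outside")
  expect_error(cohort_spec(10, copula_corr = matrix(c(1, 2, 0, 2, 1, 0,
                                                      0, 0, 1), 3, 3)),
               "positive-definite")
})

test_that("reference regimens follow the dosing tables", {
  expect_equal(unclass(reference_regimen(list(pma = 28, pna = 10),
                                         "neofax"))[c(1, 2)],
               list(dose_per_kg = 15, interval = 18))
  expect_equal(reference_regimen(list(pma = 33, pna = 20),
                                 "neofax")$interval, 8)
  expect_equal(reference_regimen(list(pma = 46, pna = 3),
                                 "neofax")$interval, 6)
  r <- reference_regimen(list(ga = 27, scr = 0.9), "lexicomp_renal")
  expect_equal(r$dose_per_kg, 15)
  expect_equal(r$interval, 24)
  expect_equal(reference_regimen(list(ga = 30, scr = 0.8),
                                 "lexicomp_renal")$interval, 24)
  expect_equal(reference_regimen(list(pma = 31, pna = 20),
                                 "lexicomp_age")$interval, 8)
  expect_error(reference_regimen(list(pma = 47, pna = 3), "lexicomp_age"),
               "outside")
})

test_that("noise-free simulation reproduces the typical model exactly", {
  co <- tiny_cohort(8)
  m0 <- vanc_model(omega_cl = 0, omega_v = 0, resid_b = 1e-12)
  ev <- simulate_observations(co, m0, seed = 4)
  fd <- vancneo:::prepare_fit_data(ev)
  typ <- typical_parameters(fd$cov, m0)
  f <- vancneo:::pred_conc(fd, typ$cl, typ$v)
  expect_equal(ev$DV[ev$EVID == 0], f, tolerance = 1e-6)
})

test_that("sampling design: trough timing, counts, steady state", {
  co <- sample_cohort(cohort_spec(162, seed = 21))
  ev <- simulate_observations(co, vanc_model(), seed = 22)
  n_obs <- sum(ev$EVID == 0)
  expect_gt(n_obs, 185)   # 162 x 1.32 = 214 expected
  expect_lt(n_obs, 245)
  obs <- ev[ev$EVID == 0 & ev$OCC == "trough", ]
  for (j in seq_len(nrow(obs))) {
    dt <- ev$TIME[ev$ID == obs$ID[j] & ev$EVID == 1]
    tau <- median(diff(sort(dt)))
    # every trough is exactly 30 min before a scheduled dose time
    expect_equal((obs$TIME[j] + 0.5) %% tau, 0, tolerance = 1e-9)
    # and at/after 72 h of dosing
    expect_gte(obs$TIME[j], 72 - 0.5)
  }
  # deterministic given seed
  ev2 <- simulate_observations(co, vanc_model(), seed = 22)
  expect_identical(ev$DV, ev2$DV)
})

test_that("observed variance grows with residual error as the moments say", {
  # one covariate profile replicated; lognormal Cl variability only
  co <- sample_cohort(cohort_spec(1, seed = 5))
  co <- co[rep(1, 4000), ]
  co$subject_id <- seq_len(nrow(co))
  vars <- sapply(c(0.1, 0.3, 0.6), function(b) {
    m <- vanc_model(omega_cl = 0.28, omega_v = 0, resid_b = b)
    ev <- simulate_observations(co, m,
                                design = obs_design(second_fraction = 0),
                                seed = 31)
    var(ev$DV[ev$EVID == 0])
  })
  expect_true(all(diff(vars) > 0))
  # analytic approximation  Var ~ f^2 (e^{w^2} - 1 + b^2 e^{w^2}) with the
  # trough's Cl elasticity folded into an effective w
  m <- vanc_model(omega_cl = 0.28, omega_v = 0, resid_b = 0.3)
  ev <- simulate_observations(co, m,
                              design = obs_design(second_fraction = 0),
                              seed = 31)
  y <- ev$DV[ev$EVID == 0]
  fd <- vancneo:::prepare_fit_data(ev)
  typ <- typical_parameters(fd$cov, m)
  f0 <- vancneo:::pred_conc(fd, typ$cl, typ$v)[1]
  el <- local({ # trough elasticity wrt eta_cl by finite difference
    d <- 1e-4
    f1 <- vancneo:::pred_conc(fd, typ$cl * exp(d), typ$v)[1]
    (log(f1) - log(f0)) / d
  })
  w2 <- (el * 0.28)^2
  approx_var <- f0^2 * exp(w2) * (exp(w2) - 1 + 0.3^2 * exp(w2))
  expect_equal(var(y), approx_var, tolerance = 0.30)
})

test_that("subject-level split is disjoint, exhaustive and deterministic", {
  co <- sample_cohort(cohort_spec(236, seed = 8))
  ev <- simulate_observations(co, vanc_model(), seed = 9)
  sp <- split_dataset(ev, 0.7, seed = 10)
  tr <- unique(sp$train$ID); va <- unique(sp$validation$ID)
  expect_equal(length(tr), round(0.7 * 236))
  expect_length(intersect(tr, va), 0)
  expect_setequal(c(tr, va), unique(ev$ID))
  sp2 <- split_dataset(ev, 0.7, seed = 10)
  expect_identical(sp$train$ID, sp2$train$ID)
  expect_error(split_dataset(ev, 1.0), "strictly between")
  expect_error(split_dataset(ev, 0), "strictly between")
})
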