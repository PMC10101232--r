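test_that("rich low-noise data recover the generating fixed effects", {
  m0 <- vanc_model(omega_cl = 1e-3, omega_v = 1e-3, resid_b = 0.05)
  ev <- rich_dataset(n = 40, model = m0, seed = 11)
  f <- fit_population(ev, init = vanc_model(omega_cl = 0.1, omega_v = 0.1,
                                            resid_b = 0.1),
                      estimate = c("cl_ref", "v_ref", "scr_exp",
                                   "omega_cl", "omega_v", "resid_b"),
                      seed = 1)
  expect_true(f$converged)
  expect_equal(f$theta[["cl_ref"]], 0.09, tolerance = 0.05)
  expect_equal(f$theta[["v_ref"]], 0.81, tolerance = 0.05)
  expect_equal(f$theta[["scr_exp"]], 0.48, tolerance = 0.2)
  expect_lt(f$theta[["omega_cl"]], 0.05)
})

test_that("the fitted objective is reproducible and order-invariant", {
  co <- tiny_cohort(25, seed = 14)
  ev <- simulate_observations(co, vanc_model(), seed = 15)
  est <- c("cl_ref", "v_ref", "omega_cl", "resid_b")
  f1 <- fit_population(ev, init = vanc_model(), estimate = est, seed = 1)
  f2 <- fit_population(ev, init = vanc_model(), estimate = est, seed = 1)
  expect_equal(f1$ofv, f2$ofv, tolerance = 1e-8)
  # permute subjects and relabel ids
  ids <- unique(ev$ID)
  perm <- rev(ids)
  ev2 <- do.call(rbind, lapply(perm, function(id) {
    d <- ev[ev$ID == id, ]
    d$ID <- 1000L + id
    d
  }))
  class(ev2) <- c("event_table", "data.frame")
  f3 <- fit_population(ev2, init = vanc_model(), estimate = est, seed = 1)
  expect_equal(f3$ofv, f1$ofv, tolerance = 1e-4)
  expect_equal(f3$theta[["cl_ref"]], f1$theta[["cl_ref"]], tolerance = 1e-3)
})

test_that("omitting a real creatinine effect worsens the objective", {
  co <- sample_cohort(cohort_spec(120, seed = 16))
  ev <- simulate_observations(co, vanc_model(), seed = 17)
  est <- c("cl_ref", "v_ref", "scr_exp", "omega_cl", "omega_v", "resid_b")
  full <- fit_population(ev, init = vanc_model(), estimate = est, seed = 1)
  red <- fit_population(ev, init = vanc_model(),
                        forms = list(scr_on_cl = FALSE,
                                     pma_form = "sigmoid"),
                        estimate = setdiff(est, "scr_exp"), seed = 1)
  expect_gt(red$ofv, full$ofv)
  lrt <- lrt_step(full, red)
  expect_equal(lrt$df, 1)
  expect_equal(lrt$decision, "include")
})

test_that("empirical Bayes estimates behave at the prior and data limits", {
  m <- vanc_model()
  # no observations: prior mode, individual == typical
  tab <- one_subject_table()
  doses_only <- tab[tab$EVID == 1, ]
  class(doses_only) <- c("event_table", "data.frame")
  eb0 <- estimate_ebe(doses_only, m)
  expect_equal(eb0$eta_cl, 0)
  expect_equal(eb0$eta_v, 0)
  typ <- typical_parameters(data.frame(weight = 0.93, pma = 30, scr = 0.6),
                            m)
  expect_equal(eb0$cl_i, typ$cl)
  # observation exactly at the typical prediction: etas near zero
  fd <- vancneo:::prepare_fit_data(tab)
  f_typ <- vancneo:::pred_conc(fd, typ$cl, typ$v)
  tab$DV[tab$EVID == 0] <- f_typ
  # "near zero": with proportional error the conditional mode is not
  # exactly 0 even at a perfect observation (the 2*log sigma(f) term pulls
  # mildly toward lower concentrations), but it stays small
  eb1 <- estimate_ebe(tab, m)
  expect_lt(abs(eb1$eta_cl), 0.06)
  expect_lt(abs(eb1$eta_v), 0.06)
  # observation at twice the typical prediction: lower clearance inferred
  tab$DV[tab$EVID == 0] <- 2 * f_typ
  eb2 <- estimate_ebe(tab, m)
  expect_lt(eb2$eta_cl, 0)
})

test_that("EBE shrinkage toward zero grows with residual error", {
  co <- sample_cohort(cohort_spec(80, seed = 18))
  sds <- sapply(c(0.1, 0.3, 0.6), function(b) {
    m <- vanc_model(resid_b = b)
    ev <- simulate_observations(co, m, seed = 19)
    sd(estimate_ebe(ev, m)$eta_cl)
  })
  expect_true(all(diff(sds) < 0))
})

test_that("likelihood-ratio decisions follow the chi-square threshold", {
  f <- structure(list(ofv = 100, estimated = letters[1:5]),
                 class = "vanc_fit")
  r <- structure(list(ofv = 100, estimated = letters[1:4]),
                 class = "vanc_fit")
  expect_equal(lrt_step(f, r)$p_value, 1)
  expect_equal(lrt_step(f, r)$decision, "exclude")
  r$ofv <- 103.85   # just above the chi-square(1) 95th percentile 3.841
  expect_equal(lrt_step(f, r)$decision, "include")
  expect_lt(lrt_step(f, r)$p_value, 0.05)
  r$ofv <- 103.80
  expect_equal(lrt_step(f, r)$decision, "exclude")
  r$ofv <- 99
  expect_warning(out <- lrt_step(f, r), "higher OFV")
  expect_equal(out$decision, "exclude")
})

test_that("information-based RSE scales as one over root n", {
  co <- tiny_cohort(40, seed = 20)
  ev <- simulate_observations(co, vanc_model(), seed = 21)
  est <- c("cl_ref", "omega_cl", "resid_b")
  f1 <- fit_population(ev, init = vanc_model(), estimate = est, seed = 1)
  r1 <- compute_rse(f1, method = "fisher")
  # duplicate every subject: information doubles, RSE shrinks by ~1/sqrt(2)
  ev2 <- ev
  ev2$ID <- ev2$ID + 1000L
  both <- rbind(ev, ev2)
  class(both) <- c("event_table", "data.frame")
  f2 <- fit_population(both, init = f1$model, estimate = est, seed = 1)
  r2 <- compute_rse(f2, method = "fisher")
  expect_equal(unname(r2["cl_ref"] / r1["cl_ref"]), 1 / sqrt(2),
               tolerance = 0.12)
  expect_error(compute_rse(f1, method = "bootstrap", n_boot = 0),
               "n_boot")
})
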