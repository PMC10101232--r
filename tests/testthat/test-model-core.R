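test_that("maturation fraction is one half at the half-maturation age", {
  expect_identical(maturation_fraction(26.3, 4.42, 26.3), 0.5)
  for (h in c(0.3, 1, 4.42, 12))
    expect_equal(maturation_fraction(17.9, h, 17.9), 0.5)
})

test_that("maturation fraction saturates and increases with PMA", {
  expect_gt(maturation_fraction(1e6, 4.42, 26.3), 1 - 1e-6)
  pma <- seq(20, 48, by = 0.25)
  f <- maturation_fraction(pma, 4.42, 26.3)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
  # frozen value from independent log-space evaluation:
  # 1/(1 + exp(4.42 * log(26.3/29.8))) = 0.6346534
  expect_equal(maturation_fraction(29.8, 4.42, 26.3), 0.6346534,
               tolerance = 1e-6)
  expect_error(maturation_fraction(-1, 4.42, 26.3), "positive")
  expect_error(maturation_fraction(30, -2, 26.3), "positive")
  expect_error(maturation_fraction(30, 4.42, 0), "positive")
})

test_that("typical parameters reproduce the published covariate equations", {
  m <- vanc_model()
  # mature limit at the reference covariates
  ref <- typical_parameters(data.frame(weight = 0.93, pma = 1e9, scr = 0.6),
                            m)
  expect_equal(ref$cl, 0.09, tolerance = 1e-12)
  expect_equal(ref$v, 0.81, tolerance = 1e-12)
  # linear weight scaling of V
  half <- typical_parameters(data.frame(weight = 0.465, pma = 30, scr = 0.6),
                             m)
  expect_equal(half$v, 0.405, tolerance = 1e-12)
  # creatinine power term: (0.6/0.15)^0.48 = 1.945461
  lo <- typical_parameters(data.frame(weight = 0.93, pma = 30, scr = 0.15),
                           m)
  hi <- typical_parameters(data.frame(weight = 0.93, pma = 30, scr = 0.6),
                           m)
  expect_equal(lo$cl / hi$cl, 4^0.48, tolerance = 1e-12)
  expect_error(
    typical_parameters(data.frame(weight = 0.93, pma = 30, scr = 0), m),
    "scr")
})

test_that("clearance is monotone in covariates and V ignores pma and scr", {
  m <- vanc_model()
  base <- data.frame(weight = 1, pma = 30, scr = 0.6)
  up_pma <- typical_parameters(transform(base, pma = 34), m)
  up_wt <- typical_parameters(transform(base, weight = 1.4), m)
  up_scr <- typical_parameters(transform(base, scr = 1.0), m)
  ref <- typical_parameters(base, m)
  expect_gt(up_pma$cl, ref$cl)
  expect_gt(up_wt$cl, ref$cl)
  expect_lt(up_scr$cl, ref$cl)
  expect_equal(up_pma$v, ref$v)
  expect_equal(up_scr$v, ref$v)
})

test_that("creatinine assay conversion matches the printed formula", {
  expect_equal(convert_scr_enzymatic_to_jaffe(0), 0.122)
  expect_equal(convert_scr_enzymatic_to_jaffe(1.05), 1.122)
  expect_equal(convert_scr_enzymatic_to_jaffe(0.903), 0.982, tolerance = 1e-3)
  expect_error(convert_scr_enzymatic_to_jaffe(-0.1), "non-negative")
})

test_that("concentration profile matches Runge-Kutta ODE integration", {
  skip_if_not_installed("deSolve")
  cl <- 0.09; v <- 0.81; tinf <- 1
  for (tau in c(8, 12, 18)) {
    reg <- regimen(15, tau, tinf, n_doses = 6)
    times <- seq(0, 6 * tau, by = 0.25)
    rate_in <- function(t) {
      tin <- t %% tau
      ifelse(t < 6 * tau & tin < tinf, 15 / tinf, 0)
    }
    ode <- deSolve::ode(c(C = 0), times, function(t, y, p)
      list(rate_in(t) / v - (cl / v) * y[1]),
      parms = NULL, method = "ode45", rtol = 1e-10, atol = 1e-12)
    f <- concentration_profile(reg, cl, v, times, weight = 1)
    i <- ode[, "C"] > 1e-3
    expect_lt(max(abs(f[i] - ode[i, "C"]) / ode[i, "C"]), 0.001)
  }
})

test_that("concentration profile is zero before dosing and linear in dose", {
  reg <- regimen(15, 12, 1, n_doses = 1)
  expect_identical(concentration_profile(reg, 0.09, 0.81, 0), 0)
  t <- c(0.5, 2, 11.9)
  f1 <- concentration_profile(reg, 0.09, 0.81, t)
  reg2 <- regimen(30, 12, 1, n_doses = 1)
  expect_equal(concentration_profile(reg2, 0.09, 0.81, t), 2 * f1)
  expect_error(regimen(15, 12, infusion_duration = 12), "shorter")
})

test_that("steady-state metrics match the closed forms and the profile", {
  # AUC identity: daily dose over clearance
  m <- steady_state_metrics(regimen(15, 12), cl = 0.075, v = 0.81,
                            weight = 1)
  expect_equal(m$auc24, 400, tolerance = 1e-12)
  m2 <- steady_state_metrics(regimen(17.5, 12), cl = 0.09, v = 0.81,
                             weight = 0.93)
  expect_equal(m2$auc24, 2 * 17.5 * 0.93 / 0.09, tolerance = 1e-12)
  # washout: trough vanishes for very long intervals
  mw <- steady_state_metrics(regimen(15, 2000, 1), cl = 0.09, v = 0.81)
  expect_lt(mw$trough, 1e-6)
  # trough/peak agree with the dose-superposition limit (>= 15 half-lives)
  cl <- 0.06; v <- 0.9; tau <- 12
  thalf <- log(2) / (cl / v)
  nd <- ceiling(20 * thalf / tau)
  reg <- regimen(15, tau, 1, n_doses = nd)
  t_tr <- nd * tau          # end of the last interval
  t_pk <- (nd - 1) * tau + 2
  prof <- concentration_profile(reg, cl, v, c(t_tr, t_pk), weight = 1)
  ss <- steady_state_metrics(regimen(15, tau, 1), cl, v, weight = 1)
  expect_equal(prof[1], ss$trough, tolerance = 1e-3)
  expect_equal(prof[2], ss$peak, tolerance = 1e-3)
})

test_that("closed-form AUC equals trapezoidal integration of the profile", {
  cl <- 0.07; v <- 0.75; tau <- 12
  thalf <- log(2) / (cl / v)
  nd <- ceiling(20 * thalf / tau) + 2
  reg <- regimen(15, tau, 1, n_doses = nd)
  t0 <- (nd - 2) * tau      # a steady-state 24 h window
  tt <- seq(t0, t0 + 24, by = 0.01)
  f <- concentration_profile(reg, cl, v, tt, weight = 1)
  auc_trap <- sum((f[-1] + f[-length(f)]) / 2 * diff(tt))
  ss <- steady_state_metrics(regimen(15, tau, 1), cl, v, weight = 1)
  expect_lt(abs(auc_trap - ss$auc24) / ss$auc24, 0.005)
})
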