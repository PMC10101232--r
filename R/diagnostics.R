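# Simulation-based model evaluation: VPC, NPDE and weighted residuals.

# Nominal sampling-occasion label per observation: trough/peak x interval.
# Sparse TDM designs are dose-interval aligned, so binning by occasion is
# more stable than binning by clock time.
occasion_bins <- function(data) {
  obs <- data[data$EVID == 0, ]
  dose <- data[data$EVID == 1, ]
  lab <- character(nrow(obs))
  for (j in seq_len(nrow(obs))) {
    dt <- dose[dose$ID == obs$ID[j], ]
    tau <- if (nrow(dt) > 1) stats::median(diff(sort(dt$TIME))) else 24
    prev <- max(dt$TIME[dt$TIME < obs$TIME[j]])
    tinf <- if ("DUR" %in% names(dt) && any(is.finite(dt$DUR)))
      dt$DUR[which.max(dt$TIME[dt$TIME < obs$TIME[j]])] else 1
    if (!is.finite(tinf)) tinf <- 1
    since <- obs$TIME[j] - prev
    kind <- if (since <= tinf + 1.5) "peak" else "trough"
    if ("OCC" %in% names(obs) && !is.na(obs$OCC[j])) kind <- obs$OCC[j]
    lab[j] <- sprintf("%s q%g", kind, tau)
  }
  lab
}

#' Visual predictive check
#'
#' Simulates `n_sim` replicates of the dataset under its own dosing and
#' sampling design, then compares the observed 10th/50th/90th percentiles
#' per sampling-occasion bin with the 90% confidence interval of the same
#' percentiles across simulated replicates.  Bins with fewer than 5
#' observations are merged into their neighbour with a warning.
#'
#' @param data an event table.
#' @param model the [vanc_model()] to evaluate.
#' @param n_sim number of simulated replicate datasets (>= 100; the
#'   published analysis used 1,000).
#' @param seed integer seed.
#' @param probs percentiles to check.
#' @param ci_level confidence level of the simulated percentile bands.
#' @return an object of class `vanc_vpc`: a data frame with one row per
#'   bin x percentile (`bin`, `prob`, `observed`, `lo`, `med`, `hi`,
#'   `n_obs`, `covered`) plus a `coverage` attribute, the fraction of
#'   percentile points inside their band.
#' @export
vpc <- function(data, model, n_sim = 1000, seed = 1L,
                probs = c(0.1, 0.5, 0.9), ci_level = 0.9) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  stopifnot(inherits(model, "vanc_model"))
  set.seed(as.integer(seed))
  obs <- data[data$EVID == 0, ]
  bins <- occasion_bins(data)
  # merge sparse bins into the largest neighbour
  repeat {
    tab <- table(bins)
    small <- names(tab)[tab < 5]
    if (length(small) == 0 || length(tab) == 1) break
    warning("bin '", small[1], "' has fewer than 5 observations; merged")
    big <- names(tab)[which.max(tab)]
    bins[bins == small[1]] <- big
  }
  sims <- simulate_dv_matrix(data, model, n_sim)
  alpha <- (1 - ci_level) / 2
  out <- list()
  for (b in unique(bins)) {
    i <- which(bins == b)
    oq <- quantile(obs$DV[i], probs, names = FALSE)
    sq <- apply(sims[i, , drop = FALSE], 2, quantile, probs = probs,
                names = FALSE)
    if (length(probs) == 1) sq <- matrix(sq, nrow = 1)
    lo <- apply(sq, 1, quantile, probs = alpha)
    hi <- apply(sq, 1, quantile, probs = 1 - alpha)
    md <- apply(sq, 1, stats::median)
    out[[b]] <- data.frame(bin = b, prob = probs, observed = oq,
                           lo = lo, med = md, hi = hi, n_obs = length(i),
                           covered = oq >= lo & oq <= hi)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("vanc_vpc", "data.frame")
  attr(res, "coverage") <- mean(res$covered)
  attr(res, "n_sim") <- n_sim
  res
}

#' @export
plot.vanc_vpc <- function(x, ...) {
  xb <- factor(x$bin)
  at <- as.integer(xb) + (x$prob - 0.5) / 2
  plot(at, x$observed, pch = 19, xaxt = "n",
       xlab = "sampling occasion", ylab = "concentration (ug/ml)",
       ylim = range(c(x$lo, x$hi, x$observed)), ...)
  axis(1, at = seq_along(levels(xb)), labels = levels(xb))
  arrows(at, x$lo, at, x$hi, angle = 90, code = 3, length = 0.04,
         col = "steelblue")
  points(at, x$med, pch = 3, col = "steelblue")
  legend("topleft", bty = "n", pch = c(19, 3),
         col = c("black", "steelblue"),
         legend = c("observed percentile", "simulated percentile (90% CI)"))
  invisible(x)
}

#' Normalized prediction distribution errors
#'
#' Standard decorrelated prediction-discrepancy algorithm: `n_sim`
#' replicates of each subject's observation vector are simulated under the
#' model; observed and simulated vectors are decorrelated with the Cholesky
#' factor of the simulated within-subject covariance; the empirical rank of
#' each decorrelated observation among its simulations, with seeded uniform
#' tie-breaking, is mapped to a normal score.  Under a correct model the
#' NPDE are approximately N(0, 1).
#'
#' @param data an event table.
#' @param model the [vanc_model()] to evaluate.
#' @param n_sim number of simulations per subject (>= 500).
#' @param seed integer seed.
#' @return an object of class `vanc_npde`: list with `npde` (one value per
#'   observation), `mean`, `sd`, and `normality_p` (Shapiro-Wilk).
#' @export
npde <- function(data, model, n_sim = 1000, seed = 1L) {
  if (n_sim < 500) stop("n_sim must be at least 500")
  stopifnot(inherits(model, "vanc_model"))
  set.seed(as.integer(seed))
  obs <- data[data$EVID == 0, ]
  sims <- simulate_dv_matrix(data, model, n_sim)
  ids <- unique(obs$ID)
  val <- numeric(nrow(obs))
  for (id in ids) {
    i <- which(obs$ID == id)
    y <- obs$DV[i]
    s <- sims[i, , drop = FALSE]
    mu <- rowMeans(s)
    if (length(i) == 1) {
      ystar <- y - mu
      sstar <- s - mu
    } else {
      V <- stats::cov(t(s))
      L <- tryCatch(chol(V), error = function(e) {
        warning("singular simulated covariance for subject ", id,
                "; ridge-regularized")
        chol(V + diag(1e-8 + 1e-6 * mean(diag(V)), nrow(V)))
      })
      ystar <- backsolve(L, y - mu, transpose = TRUE)
      sstar <- backsolve(L, s - mu, transpose = TRUE)
    }
    for (r in seq_along(i)) {
      less <- sum(sstar[r, ] < ystar[r])
      eq <- sum(sstar[r, ] == ystar[r])
      pde <- (less + runif(1) * (1 + eq)) / (n_sim + 1)
      val[i[r]] <- qnorm(pde)
    }
  }
  sw <- if (length(val) >= 3 && length(val) <= 5000)
    stats::shapiro.test(val)$p.value else NA_real_
  structure(list(npde = val, mean = mean(val), sd = sd(val),
                 normality_p = sw, n_sim = n_sim),
            class = "vanc_npde")
}

#' @export
print.vanc_npde <- function(x, ...) {
  cat(sprintf("NPDE over %d observations (%d simulations):\n",
              length(x$npde), x$n_sim))
  cat(sprintf("  mean %.3f, sd %.3f (null: mean 0, sd 1)\n", x$mean, x$sd))
  cat(sprintf("  Shapiro-Wilk normality p = %.3g\n", x$normality_p))
  invisible(x)
}

#' @export
plot.vanc_npde <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  qqnorm(x$npde, main = "NPDE Q-Q"); qqline(x$npde)
  hist(x$npde, freq = FALSE, main = "NPDE", xlab = "npde")
  curve(dnorm(x), add = TRUE, col = "steelblue")
  invisible(x)
}

#' Goodness-of-fit weighted residuals
#'
#' Population weighted residuals PWRES = (obs - population prediction) /
#' population-model sd, where the population sd combines a first-order
#' approximation of the random-effect variance with the residual error; and
#' individual weighted residuals IWRES = (obs - individual prediction) /
#' residual sd at the individual prediction.
#'
#' @param fit a converged `vanc_fit`.
#' @param data an event table; defaults to the fitted data.
#' @return a data frame with one row per observation: `ID`, `TIME`, `DV`,
#'   `pred_pop`, `pred_ind`, `pwres`, `iwres`.
#' @export
gof_residuals <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "vanc_fit"))
  if (!fit$converged) stop("fit did not converge")
  if (is.null(data)) data <- fit$data
  model <- fit$model
  fd <- prepare_fit_data(data)
  typ <- typical_parameters(fd$cov, model)
  f0 <- pred_conc(fd, typ$cl, typ$v)
  # first-order variance: grad of f wrt (eta_cl, eta_v) at 0
  d <- 1e-4
  f_cl <- pred_conc(fd, typ$cl * exp(d), typ$v)
  f_v <- pred_conc(fd, typ$cl, typ$v * exp(d))
  g1 <- (f_cl - f0) / d
  g2 <- (f_v - f0) / d
  var_pop <- (g1 * model$omega_cl)^2 + (g2 * model$omega_v)^2 +
    residual_sd(f0, model)^2
  eb <- estimate_ebe(data, model)
  eb <- eb[match(fd$ids, eb$subject_id), ]
  f_ind <- pred_conc(fd, eb$cl_i, eb$v_i)
  sd_ind <- residual_sd(f_ind, model)
  pwres <- (fd$y - f0) / sqrt(var_pop)
  iwres <- (fd$y - f_ind) / sd_ind
  zero <- f_ind <= 0 | sd_ind <= 0
  if (any(zero)) {
    warning(sum(zero), " observation(s) with zero prediction; ",
            "residual undefined")
    iwres[zero] <- NA_real_
  }
  obs <- data[data$EVID == 0, ]
  data.frame(ID = obs$ID, TIME = obs$TIME, DV = obs$DV,
             pred_pop = f0, pred_ind = f_ind, pwres = pwres, iwres = iwres)
}

#' @export
plot.vanc_fit <- function(x, ...) {
  g <- gof_residuals(x)
  op <- par(mfrow = c(2, 2)); on.exit(par(op))
  lim <- range(c(g$DV, g$pred_pop, g$pred_ind))
  plot(g$pred_pop, g$DV, xlab = "population prediction", ylab = "observed",
       xlim = lim, ylim = lim); abline(0, 1, col = "steelblue")
  plot(g$pred_ind, g$DV, xlab = "individual prediction", ylab = "observed",
       xlim = lim, ylim = lim); abline(0, 1, col = "steelblue")
  plot(g$TIME, g$pwres, xlab = "time (h)", ylab = "PWRES")
  abline(h = 0, col = "steelblue")
  plot(g$TIME, g$iwres, xlab = "time (h)", ylab = "IWRES")
  abline(h = 0, col = "steelblue")
  invisible(x)
}
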