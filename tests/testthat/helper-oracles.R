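# Independent oracles used across the suite.  These deliberately take a
# different computational route from the package internals (lm() fits,
# explicit segment loops, exhaustive enumeration) so agreement is evidence,
# not tautology.

# --- terminal-slope oracle: enumerate every trailing window, fit with lm(),
# pick max adjusted R^2 with negative slope (ties -> more points) ----------
oracle_lambda_z <- function(times, concs, min_points = 3) {
  cmax <- max(concs)
  tmax <- times[which(concs == cmax)[1]]
  sel <- if (times[1] == tmax) times >= tmax else times > tmax
  sel <- sel & concs > 0
  tt <- times[sel]; cc <- concs[sel]
  n <- length(tt)
  if (n < min_points) return(NULL)
  best <- NULL
  for (k in seq(n, min_points)) {
    idx <- seq(n - k + 1, n)
    f <- lm(log(cc[idx]) ~ tt[idx])
    adj <- summary(f)$adj.r.squared
    sl <- unname(coef(f)[2])
    if (sl >= 0) next
    if (is.null(best) || adj > best$adj) best <- list(adj = adj, lambda = -sl,
                                                     n = k, t_first = tt[idx[1]])
  }
  best
}

# --- NCA oracle: explicit segment-by-segment trapezoid sums + lm-based
# terminal fit --------------------------------------------------------------
oracle_nca <- function(times, concs, min_points = 3) {
  auc <- 0; aumc <- 0
  for (i in seq_len(length(times) - 1)) {
    dt <- times[i + 1] - times[i]
    auc <- auc + dt * (concs[i] + concs[i + 1]) / 2
    aumc <- aumc + dt * (times[i] * concs[i] + times[i + 1] * concs[i + 1]) / 2
  }
  lam <- oracle_lambda_z(times, concs, min_points)
  clast <- concs[length(concs)]; tlast <- times[length(times)]
  out <- list(auc_0_t = auc, aumc_0_t = aumc, lambda = lam)
  if (!is.null(lam)) {
    out$auc_0_inf <- auc + clast / lam$lambda
    out$aumc_0_inf <- aumc + clast * tlast / lam$lambda + clast / lam$lambda^2
    out$t_half <- log(2) / lam$lambda
  }
  out
}

# --- weighted calibration oracle: solve the 2x2 weighted normal equations --
oracle_wls <- function(x, y, w) {
  A <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2)
  b <- c(sum(w * y), sum(w * x * y))
  solve(A, b)   # (intercept, slope)
}

# --- hypergeometric tail by exhaustive enumeration of all C(N, n) draws ----
# universe = 1..N, pathway = 1..K; returns P[overlap >= k]
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# --- BH step-up computed by hand over the sorted p-values ------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  for (i in seq(m - 1, 1)) if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q_sorted, 1)
  out
}

# --- fixture builders ------------------------------------------------------
make_profile <- function(times, concs, lloq = 1e-9, dose = NA_real_,
                         subject = "S1", analyte = "A", blq = NULL) {
  conc_profile(subject, analyte, times, concs, blq = blq, dose = dose,
               lloq = lloq)
}

# random decaying profile with lognormal noise (tmax at the first point)
random_decay_profile <- function(n = 8, ke = NULL) {
  times <- sort(runif(n, 0.5, 24))
  if (is.null(ke)) ke <- runif(1, 0.05, 0.8)
  c0 <- runif(1, 50, 500)
  concs <- c0 * exp(-ke * times) * exp(rnorm(n, 0, 0.15))
  concs[1] <- max(concs) + 1          # guarantee the peak is first
  list(times = times, concs = concs, ke = ke)
}

# noise-free study config with censoring disabled (lloq far below any conc)
uncensored_config <- function(seed, n_subjects = 6, error_prop = 0.1) {
  an <- default_pk_analytes()
  for (i in seq_along(an)) an[[i]]$lloq <- 1e-9
  sim_pk_config(analytes = an, n_subjects = n_subjects,
                error_prop = error_prop, error_add = 0, seed = seed)
}
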