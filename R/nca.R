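#' Maximum concentration and its time
#'
#' Returns the maximum quantifiable concentration and the earliest sampling
#' time attaining it.  BLQ observations never qualify as the maximum.
#'
#' @param profile a [conc_profile()].
#' @return A named list with `cmax` (ng/mL) and `tmax` (h).
#' @export
find_cmax_tmax <- function(profile) {
  u <- usable_points(profile)
  list(cmax = u$cmax, tmax = u$tmax)
}

# Per-segment trapezoid areas for C(t) and t*C(t).
# method "linear": arithmetic trapezoid throughout.
# method "linuplogdown": logarithmic trapezoid on strictly decreasing
# positive segments (exponential interpolation), linear otherwise.
segment_areas <- function(times, concs, method) {
  n <- length(times)
  if (n < 2L) return(list(auc = 0, aumc = 0))
  t1 <- times[-n]; t2 <- times[-1L]
  c1 <- concs[-n]; c2 <- concs[-1L]
  dt <- t2 - t1

  auc_lin  <- dt * (c1 + c2) / 2
  aumc_lin <- dt * (t1 * c1 + t2 * c2) / 2
  if (method == "linear") return(list(auc = sum(auc_lin), aumc = sum(aumc_lin)))

  logdown <- c1 > c2 & c2 > 0
  auc <- auc_lin; aumc <- aumc_lin
  if (any(logdown)) {
    k <- log(c1[logdown] / c2[logdown]) / dt[logdown]
    auc[logdown] <- (c1[logdown] - c2[logdown]) / k
    aumc[logdown] <- (t1[logdown] * c1[logdown] - t2[logdown] * c2[logdown]) / k +
      (c1[logdown] - c2[logdown]) / k^2
  }
  list(auc = sum(auc), aumc = sum(aumc))
}

#' Area under the curve to the last quantifiable time
#'
#' Piecewise trapezoidal integration of the concentration-time curve and its
#' first moment from the first usable time to the last quantifiable time.
#' With `method = "linuplogdown"` declining positive segments use the
#' logarithmic trapezoid \eqn{(C_1-C_2)\Delta t/\ln(C_1/C_2)}; segments that
#' rise, are flat, or touch zero fall back to the linear rule.
#'
#' @param profile a [conc_profile()].
#' @param method `"linear"` (default) or `"linuplogdown"`.
#' @return Named list with `auc` (ng·h/mL) and `aumc` (ng·h²/mL).
#' @export
auc_0_t <- function(profile, method = c("linear", "linuplogdown")) {
  method <- match.arg(method)
  u <- usable_points(profile)
  if (length(u$times) < 2L)
    abort_pk("insufficient_data", "need at least 2 usable points for AUC")
  segment_areas(u$times, u$concs, method)
}

# Closed-form simple linear regression of log(conc) on time over one window.
loglin_fit <- function(times, logc) {
  n <- length(times)
  mx <- mean(times); my <- mean(logc)
  sxx <- sum((times - mx)^2)
  sxy <- sum((times - mx) * (logc - my))
  syy <- sum((logc - my)^2)
  slope <- sxy / sxx
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else 1
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  list(slope = slope, intercept = my - slope * mx, r2 = r2, adj_r2 = adj, n = n)
}

#' Terminal elimination rate constant (lambda-z)
#'
#' Log-linear regression of the terminal phase.  Candidate windows are the
#' trailing `k` quantifiable positive points strictly after Tmax, for
#' `k = min_points, ..., n`; the fit maximizing the adjusted R-squared (ties
#' resolved toward more points) with a negative slope is returned.  When the
#' peak is the first quantifiable observation (no absorption phase observed)
#' the peak itself is eligible, as is conventional for profiles in monotone
#' decline.
#'
#' @param profile a [conc_profile()].
#' @param min_points minimum number of regression points (default 3).
#' @return An object of class `lambda_z_fit`: `lambda_z` (1/h), `intercept`
#'   (log scale), `n_points`, `adj_r2`, `t_first`, `t_last`.
#' @export
fit_lambda_z <- function(profile, min_points = 3L) {
  min_points <- max(3L, as.integer(min_points))
  u <- usable_points(profile)
  after <- if (u$times[1L] == u$tmax) u$times >= u$tmax else u$times > u$tmax
  sel <- after & u$concs > 0
  tt <- u$times[sel]; cc <- u$concs[sel]
  n <- length(tt)
  if (n == 0L)
    abort_pk("terminal_phase_not_estimable",
             "no post-peak decline: Tmax is the last quantifiable time")
  if (n < min_points)
    abort_pk("insufficient_data",
             sprintf("only %d post-Tmax points; %d required", n, min_points))

  logc <- log(cc)
  best <- NULL
  for (k in seq(n, min_points)) {            # largest window first: ties -> more points
    idx <- seq(n - k + 1L, n)
    f <- loglin_fit(tt[idx], logc[idx])
    if (f$slope >= 0) next
    if (is.null(best) || f$adj_r2 > best$adj_r2) best <- c(f, list(idx = idx))
  }
  if (is.null(best))
    abort_pk("terminal_phase_not_estimable",
             "no candidate window gives a declining log-linear fit")

  structure(
    list(lambda_z = -best$slope, intercept = best$intercept,
         n_points = best$n, adj_r2 = min(max(best$adj_r2, 0), 1),
         t_first = tt[best$idx[1L]], t_last = tt[best$idx[length(best$idx)]]),
    class = "lambda_z_fit")
}

#' @export
print.lambda_z_fit <- function(x, ...) {
  cat(sprintf("<lambda_z_fit> lambda_z = %.5g /h (t1/2 = %.4g h), %d points on [%g, %g] h, adj R2 = %.4f\n",
              x$lambda_z, log(2) / x$lambda_z, x$n_points, x$t_first, x$t_last, x$adj_r2))
  invisible(x)
}

#' Non-compartmental analysis of one profile
#'
#' Computes the standard extravascular NCA parameter set: Cmax, Tmax,
#' AUC/AUMC to the last quantifiable time and extrapolated to infinity,
#' mean residence times, terminal half-life, apparent clearance and volume,
#' and the extrapolated AUC percentage.  Terminal-phase parameters are set
#' to `NA` (and the failure recorded in `$lambda_z_error`) when lambda-z is
#' not estimable; dose-based parameters are `NA` when the dose is unknown.
#'
#' Extrapolation uses the observed Clast:
#' \eqn{AUC_{0-\infty} = AUC_{0-t} + C_{last}/\lambda_z},
#' \eqn{AUMC_{0-\infty} = AUMC_{0-t} + C_{last} t_{last}/\lambda_z +
#' C_{last}/\lambda_z^2}.  With dose in mg/kg and concentrations in ng/mL,
#' CLz/F is reported in L/h/kg and Vz/F in L/kg.
#'
#' @inheritParams auc_0_t
#' @inheritParams fit_lambda_z
#' @return An object of class `nca_result` (also a plain list).
#' @examples
#' p <- conc_profile("R1", "A", times = c(1, 2, 3), concs = c(10, 5, 2.5),
#'                   lloq = 0.1)
#' run_nca(p)$auc_0_inf   # 11.25 + 2.5/log(2)
#' @export
run_nca <- function(profile, method = c("linear", "linuplogdown"),
                    min_points = 3L) {
  method <- match.arg(method)
  u <- usable_points(profile)
  areas <- auc_0_t(profile, method)

  fit <- tryCatch(fit_lambda_z(profile, min_points), herbipk_error = identity)
  lam_err <- NULL
  if (inherits(fit, "condition")) { lam_err <- conditionMessage(fit); fit <- NULL }

  auc_inf <- aumc_inf <- t_half <- mrt_inf <- vz_f <- clz_f <- pct_extra <- NA_real_
  if (!is.null(fit)) {
    lz <- fit$lambda_z
    auc_inf <- areas$auc + u$clast / lz
    aumc_inf <- areas$aumc + u$clast * u$tlast / lz + u$clast / lz^2
    t_half <- log(2) / lz
    mrt_inf <- aumc_inf / auc_inf
    pct_extra <- 100 * (1 - areas$auc / auc_inf)
    if (!is.na(profile$dose)) {
      # dose [mg/kg] / AUC [ng*h/mL] = 1e3 L/(h*kg)
      clz_f <- profile$dose / auc_inf * 1000
      vz_f <- clz_f / lz
    }
  }

  structure(
    list(subject_id = profile$subject_id, analyte_id = profile$analyte_id,
         cmax = u$cmax, tmax = u$tmax, t_half = t_half,
         auc_0_t = areas$auc, auc_0_inf = auc_inf,
         aumc_0_t = areas$aumc, aumc_0_inf = aumc_inf,
         mrt_0_t = areas$aumc / areas$auc, mrt_0_inf = mrt_inf,
         vz_f = vz_f, clz_f = clz_f, pct_extrapolated = pct_extra,
         lambda_fit = fit, lambda_z_error = lam_err, method = method),
    class = "nca_result")
}

nca_param_names <- c("cmax", "tmax", "t_half", "auc_0_t", "auc_0_inf",
                     "aumc_0_t", "aumc_0_inf", "mrt_0_t", "mrt_0_inf",
                     "vz_f", "clz_f", "pct_extrapolated")

#' @export
as.data.frame.nca_result <- function(x, ...) {
  out <- data.frame(subject_id = x$subject_id, analyte = x$analyte_id,
                    stringsAsFactors = FALSE)
  for (p in nca_param_names) out[[p]] <- x[[p]]
  out$lambda_z <- if (is.null(x$lambda_fit)) NA_real_ else x$lambda_fit$lambda_z
  out
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> subject %s, analyte %s (%s trapezoid)\n",
              x$subject_id, x$analyte_id, x$method))
  df <- as.data.frame(x)[, c(nca_param_names, "lambda_z")]
  print(signif(unlist(df), 4))
  if (!is.null(x$lambda_z_error))
    cat("terminal phase not estimated:", x$lambda_z_error, "\n")
  invisible(x)
}
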