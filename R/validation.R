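#' Weighted linear calibration fit
#'
#' Fits the calibration line (analyte/IS peak-area ratio versus nominal
#' concentration) by weighted linear least squares.  The default
#' \eqn{1/x^2} weighting is the usual choice for bioanalytical data whose
#' error is roughly proportional to concentration; it equalizes the relative
#' influence of low and high calibrators.  The reported `r` is the weighted
#' Pearson correlation under the same weights.
#'
#' @param nominal_concs calibration concentrations (ng/mL), >= 6 distinct
#'   positive levels.
#' @param response_ratios peak-area ratios aligned to `nominal_concs`.
#' @param weighting `"1/x^2"` (default), `"1/x"`, or `"none"`.
#' @param analyte_id optional label carried through to the result.
#' @param min_levels minimum number of distinct levels (default 6; lower it
#'   only for synthetic fixtures).
#' @return A `calibration_fit`: `slope`, `intercept`, `r`, `weighting`,
#'   `valid` (slope > 0), `analyte_id`.
#' @export
fit_calibration <- function(nominal_concs, response_ratios,
                            weighting = c("1/x^2", "1/x", "none"),
                            analyte_id = NA_character_, min_levels = 6L) {
  weighting <- match.arg(weighting)
  x <- as.numeric(nominal_concs)
  y <- as.numeric(response_ratios)
  if (length(x) != length(y) || anyNA(x) || anyNA(y))
    abort_pk("config", "nominal_concs and response_ratios must align without NA")
  if (any(x <= 0) || any(y <= 0))
    abort_pk("config", "calibration concentrations and ratios must be positive")
  if (length(unique(x)) < max(2L, min_levels))
    abort_pk(if (length(unique(x)) < 2L) "rank_deficient" else "config",
             sprintf("need >= %d distinct calibration levels, got %d",
                     max(2L, min_levels), length(unique(x))))

  w <- switch(weighting, "1/x^2" = 1 / x^2, "1/x" = 1 / x, none = rep(1, length(x)))
  fit <- lm(y ~ x, weights = w)
  cw <- cov.wt(cbind(x, y), wt = w / sum(w), cor = TRUE)
  slope <- unname(coef(fit)[2L])
  r <- cw$cor[1L, 2L]
  if (!is.finite(r)) r <- NA_real_          # zero response variance

  structure(
    list(slope = slope, intercept = unname(coef(fit)[1L]),
         r = r, weighting = weighting,
         valid = is.finite(slope) && slope > 0 && !is.na(r),
         analyte_id = analyte_id),
    class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit>%s y = %.6gx %+.6g, r = %.4f (%s weighting)%s\n",
              if (is.na(x$analyte_id)) "" else paste0(" ", x$analyte_id),
              x$slope, x$intercept, x$r, x$weighting,
              if (x$valid) "" else "  [INVALID: slope <= 0]"))
  invisible(x)
}

#' Back-calculate a concentration from a calibration fit
#'
#' Inverts the calibration line: `(response - intercept) / slope`.  Negative
#' results are reported as-is with attribute `negative = TRUE` rather than
#' clamped, so that QC summaries can flag them.
#'
#' @param fit a [fit_calibration()] result (or any list with `slope` and
#'   `intercept`).
#' @param response_ratio observed analyte/IS peak-area ratio(s).
#' @return Concentration(s) in ng/mL, with attribute `negative` when any
#'   value is below zero.
#' @export
back_calculate <- function(fit, response_ratio) {
  if (!is.numeric(fit$slope) || fit$slope == 0)
    abort_pk("rank_deficient", "calibration slope is zero; cannot invert")
  conc <- (as.numeric(response_ratio) - fit$intercept) / fit$slope
  if (any(conc < 0)) attr(conc, "negative") <- TRUE
  conc
}

#' Precision and accuracy of a QC batch
#'
#' Precision is the relative standard deviation (sample SD / mean, in
#' percent); accuracy is the mean measured concentration as a percentage of
#' nominal.
#'
#' @param measured replicate measured concentrations (ng/mL), >= 3.
#' @param nominal nominal (spiked) concentration (ng/mL), > 0.
#' @return Named list: `precision_rsd` (%), `accuracy_pct` (%), `n`.
#' @examples
#' qc_statistics(c(9, 10, 11), 10)   # RSD 10%, accuracy 100%
#' @export
qc_statistics <- function(measured, nominal) {
  measured <- as.numeric(measured)
  stopifnot_scalar_number(nominal, "nominal", positive = TRUE)
  if (length(measured) < 3L)
    abort_pk("config", "at least 3 replicates are required")
  m <- mean(measured)
  if (m <= 0)
    abort_pk("undefined_precision", "mean measured concentration is <= 0")
  list(precision_rsd = 100 * sd(measured) / m,
       accuracy_pct = 100 * m / nominal,
       n = length(measured))
}

#' Extraction recovery and matrix effect
#'
#' Recovery compares analyte response in samples spiked before extraction
#' with samples spiked after extraction; the matrix effect compares
#' post-extraction-spiked samples with neat solutions.
#'
#' @param extracted mean peak area, spiked before extraction.
#' @param post_spiked mean peak area, spiked after extraction.
#' @param neat mean peak area in neat solvent.
#' @return Named list: `recovery_pct`, `matrix_effect_pct`.
#' @export
recovery_and_matrix <- function(extracted, post_spiked, neat) {
  for (v in list(c(extracted, "extracted"), c(post_spiked, "post_spiked"),
                 c(neat, "neat"))) {
    x <- as.numeric(v[1L])
    if (!is.finite(x) || x <= 0)
      abort_pk("invalid_reference", sprintf("'%s' mean peak area must be > 0", v[2L]))
  }
  list(recovery_pct = 100 * extracted / post_spiked,
       matrix_effect_pct = 100 * post_spiked / neat)
}

#' Regulatory acceptance check for QC statistics
#'
#' Applies the standard bioanalytical acceptance windows: at the LLOQ,
#' accuracy within 80--120% of nominal and RSD <= 20%; at all other levels,
#' accuracy within 85--115% and RSD <= 15%.  Bounds are treated as closed
#' (a value exactly on the boundary passes).
#'
#' @param accuracy_pct accuracy as percent of nominal.
#' @param precision_rsd relative standard deviation in percent.
#' @param level QC level; `"LLOQ"` selects the wider window.
#' @return A list with `pass` (logical) and `checks`, a data frame listing
#'   each criterion, its bound, the observed value, verdict and reason.
#' @export
acceptance_check <- function(accuracy_pct, precision_rsd,
                             level = c("LQC", "MQC", "HQC", "LLOQ")) {
  level <- match.arg(level)
  lo <- if (level == "LLOQ") 80 else 85
  hi <- if (level == "LLOQ") 120 else 115
  rsd_max <- if (level == "LLOQ") 20 else 15

  checks <- data.frame(
    criterion = c("accuracy_low", "accuracy_high", "precision"),
    bound = c(sprintf(">= %g%%", lo), sprintf("<= %g%%", hi),
              sprintf("<= %g%%", rsd_max)),
    observed = c(accuracy_pct, accuracy_pct, precision_rsd),
    pass = c(accuracy_pct >= lo, accuracy_pct <= hi, precision_rsd <= rsd_max),
    stringsAsFactors = FALSE)
  checks$reason <- ifelse(checks$pass, "", c(
    sprintf("accuracy below %g%%", lo),
    sprintf("accuracy above %g%%", hi),
    sprintf("precision above %g%%", rsd_max)))
  list(pass = all(checks$pass), level = level, checks = checks)
}

#' Signal-to-noise check for the lower limit of quantification
#'
#' Passes when the signal-to-noise ratio strictly exceeds 10.
#'
#' @param signal peak signal intensity.
#' @param noise baseline noise, > 0.
#' @return A list with `pass` and `sn_ratio`.
#' @export
lloq_check <- function(signal, noise) {
  if (!is.finite(noise) || noise <= 0)
    abort_pk("invalid_noise", "noise must be > 0")
  sn <- signal / noise
  list(pass = sn > 10, sn_ratio = sn)
}

#' Validation report over calibration, QC and peak-area tables
#'
#' Convenience wrapper running [fit_calibration()], [qc_statistics()] +
#' [acceptance_check()] and [recovery_and_matrix()] over the long-format
#' tables read by [read_calibration_table()], [read_qc_table()] and
#' [read_area_table()].
#'
#' @param cal data frame `analyte, nominal_ng_ml, response_ratio` (optional).
#' @param qc data frame `analyte, level, condition, nominal_ng_ml,
#'   measured_ng_ml` (optional).
#' @param areas data frame `analyte, role, level, peak_area` with roles
#'   `extracted`, `post_spiked`, `neat` (optional).
#' @param weighting calibration weighting, see [fit_calibration()].
#' @return A list of data frames: `calibration`, `qc`, `recovery`.
#' @export
validation_report <- function(cal = NULL, qc = NULL, areas = NULL,
                              weighting = "1/x^2") {
  out <- list(calibration = NULL, qc = NULL, recovery = NULL)

  if (!is.null(cal)) {
    out$calibration <- do.call(rbind, lapply(split(cal, cal$analyte), function(d) {
      f <- fit_calibration(d$nominal_ng_ml, d$response_ratio,
                           weighting = weighting, analyte_id = d$analyte[1L],
                           min_levels = min(6L, length(unique(d$nominal_ng_ml))))
      data.frame(analyte = d$analyte[1L], slope = f$slope,
                 intercept = f$intercept, r = f$r, weighting = f$weighting,
                 valid = f$valid, stringsAsFactors = FALSE)
    }))
    rownames(out$calibration) <- NULL
  }

  if (!is.null(qc)) {
    key <- interaction(qc$analyte, qc$level, qc$condition, drop = TRUE)
    out$qc <- do.call(rbind, lapply(split(qc, key), function(d) {
      st <- qc_statistics(d$measured_ng_ml, d$nominal_ng_ml[1L])
      lv <- if (toupper(d$level[1L]) %in% c("LQC", "MQC", "HQC", "LLOQ"))
        toupper(d$level[1L]) else "LQC"
      ac <- acceptance_check(st$accuracy_pct, st$precision_rsd, lv)
      data.frame(analyte = d$analyte[1L], level = d$level[1L],
                 condition = d$condition[1L], nominal_ng_ml = d$nominal_ng_ml[1L],
                 n = st$n, precision_rsd = st$precision_rsd,
                 accuracy_pct = st$accuracy_pct, pass = ac$pass,
                 stringsAsFactors = FALSE)
    }))
    rownames(out$qc) <- NULL
  }

  if (!is.null(areas)) {
    key <- interaction(areas$analyte, areas$level, drop = TRUE)
    out$recovery <- do.call(rbind, lapply(split(areas, key), function(d) {
      m <- tapply(d$peak_area, d$role, mean)
      rm_ <- recovery_and_matrix(m[["extracted"]], m[["post_spiked"]], m[["neat"]])
      data.frame(analyte = d$analyte[1L], level = d$level[1L],
                 recovery_pct = rm_$recovery_pct,
                 matrix_effect_pct = rm_$matrix_effect_pct,
                 stringsAsFactors = FALSE)
    }))
    rownames(out$recovery) <- NULL
  }
  out
}
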