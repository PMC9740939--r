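#' Construct a single-analyte concentration-time profile
#'
#' A `conc_profile` holds one subject's concentration-time series for one
#' analyte, together with the administered dose (per body weight, on the
#' extract-equivalent scale) and the assay's lower limit of quantification
#' (LLOQ).  Observations below the LLOQ are carried as censored (BLQ) flags
#' rather than dropped, so that downstream analyses can apply their own
#' substitution rules.
#'
#' @param subject_id,analyte_id identifiers (length-1 character or coercible).
#' @param times sampling times in hours; strictly increasing, non-negative.
#' @param concs concentrations in ng/mL aligned to `times`; non-negative.
#' @param blq logical vector flagging below-LLOQ observations.  Defaults to
#'   `concs < lloq`.
#' @param dose administered dose per body weight (mg/kg); `NA` if unknown,
#'   in which case clearance and volume terms are not computed.
#' @param lloq lower limit of quantification (ng/mL), > 0.
#'
#' @return An object of class `conc_profile`.
#' @examples
#' conc_profile("R1", "TSG", times = c(0.25, 0.5, 1, 2),
#'              concs = c(500, 700, 300, 80), lloq = 0.5)
#' @export
conc_profile <- function(subject_id, analyte_id, times, concs, blq = NULL,
                         dose = NA_real_, lloq) {
  subject_id <- as.character(subject_id)[1L]
  analyte_id <- as.character(analyte_id)[1L]
  times <- as.numeric(times)
  concs <- as.numeric(concs)
  stopifnot_scalar_number(lloq, "lloq", positive = TRUE)
  if (is.null(blq)) blq <- concs < lloq
  blq <- as.logical(blq)

  n <- length(times)
  if (n < 3L || length(concs) != n || length(blq) != n)
    abort_pk("config", "times, concs and blq must have equal length >= 3")
  if (anyNA(times) || anyNA(concs) || anyNA(blq))
    abort_pk("config", "times, concs and blq must not contain NA")
  if (any(times < 0) || any(diff(times) <= 0))
    abort_pk("config", "times must be non-negative and strictly increasing")
  if (any(concs < 0))
    abort_pk("config", "concentrations must be non-negative")
  if (any(!blq & concs < lloq))
    abort_pk("config", "quantifiable (non-BLQ) concentrations must be >= lloq")
  if (!is.na(dose) && dose <= 0)
    abort_pk("invalid_dose", "dose must be > 0 (or NA if unknown)")

  structure(
    list(subject_id = subject_id, analyte_id = analyte_id,
         times = times, concs = concs, blq = blq,
         dose = as.numeric(dose)[1L], lloq = lloq),
    class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat(sprintf("<conc_profile> subject %s, analyte %s (%d samples, LLOQ %g ng/mL)\n",
              x$subject_id, x$analyte_id, length(x$times), x$lloq))
  print(data.frame(time_h = x$times, conc_ng_ml = x$concs, blq = x$blq),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.conc_profile <- function(x, ...) {
  data.frame(subject_id = x$subject_id, analyte = x$analyte_id,
             time_h = x$times, conc_ng_ml = x$concs, blq = x$blq,
             stringsAsFactors = FALSE)
}

# BLQ substitution rules applied ahead of integration / regression:
#   * all points BLQ              -> no-quantifiable-data error
#   * BLQ before (or at) Tmax     -> value 0, kept
#   * trailing BLQ after tlast    -> dropped
#   * interior BLQ (Tmax..tlast)  -> treated as missing, dropped
# Returns times/concs actually usable plus the peak location.
usable_points <- function(profile) {
  quant <- !profile$blq
  if (!any(quant))
    abort_pk("no_quantifiable_data",
             sprintf("profile %s/%s has no quantifiable observations",
                     profile$subject_id, profile$analyte_id))
  q_times <- profile$times[quant]
  q_concs <- profile$concs[quant]
  cmax <- max(q_concs)
  tmax <- q_times[which(q_concs == cmax)[1L]]      # earliest time at the max
  tlast <- q_times[length(q_times)]

  keep <- quant | (profile$blq & profile$times < tmax)
  keep <- keep & (profile$times <= tlast)
  times <- profile$times[keep]
  concs <- ifelse(profile$blq[keep], 0, profile$concs[keep])

  list(times = times, concs = concs,
       cmax = cmax, tmax = tmax, tlast = tlast,
       clast = q_concs[length(q_concs)])
}
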