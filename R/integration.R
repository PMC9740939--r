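#' AUC-proportional weighting coefficients
#'
#' Each analyte's weight is its AUC share of the total,
#' \eqn{w_j = AUC_j / \sum_k AUC_k}, so the weights are positive and sum to
#' one.  The weights are dimensionless and invariant to a common rescaling
#' of all AUCs.
#'
#' @param aucs named numeric vector of AUC values (ng·h/mL), one per analyte;
#'   all strictly positive.
#' @param basis which exposure measure the AUCs represent
#'   (`"auc_0_inf"`, default, or `"auc_0_t"`); recorded as metadata.
#' @param scope provenance of the AUCs (`"pooled-mean"`, default, or
#'   `"per-subject"`); recorded as metadata.
#' @return A `weight_vector`: named numeric weights with attributes `basis`
#'   and `scope`.
#' @examples
#' compute_weights(c(A = 2, B = 3, C = 5))
#' @export
compute_weights <- function(aucs, basis = c("auc_0_inf", "auc_0_t"),
                            scope = c("pooled-mean", "per-subject")) {
  basis <- match.arg(basis)
  scope <- match.arg(scope)
  if (length(aucs) < 1L)
    abort_pk("invalid_auc", "at least one analyte AUC is required")
  if (is.null(names(aucs)) || any(!nzchar(names(aucs))))
    abort_pk("invalid_auc", "aucs must be a fully named vector")
  bad <- names(aucs)[!is.finite(aucs) | aucs <= 0]
  if (length(bad))
    abort_pk("invalid_auc",
             sprintf("non-positive or missing AUC for analyte(s): %s",
                     paste(bad, collapse = ", ")),
             analytes = bad)
  w <- aucs / sum(aucs)
  structure(w, basis = basis, scope = scope, class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(sprintf("<weight_vector> basis = %s, scope = %s\n",
              attr(x, "basis"), attr(x, "scope")))
  print(setNames(sprintf("%.4g%%", 100 * as.numeric(x)), names(x)), quote = FALSE)
  invisible(x)
}

#' Weighted integrated concentration-time profile
#'
#' Builds the integrated profile \eqn{c_T(t) = \sum_j w_j c_j(t)} from one
#' profile per analyte for the same subject on an identical nominal time
#' grid.  BLQ observations contribute zero to the sum; the integrated
#' point is flagged BLQ only when every component is BLQ there.  The
#' integrated LLOQ is recorded as \eqn{\min_j w_j \cdot LLOQ_j}, the smallest
#' weighted contribution a single quantifiable component can make, so that
#' integrated points with any quantifiable component remain non-censored.
#'
#' @param profiles list of [conc_profile()] objects, one per analyte, same
#'   subject and time grid.
#' @param weights a [compute_weights()] result covering exactly the supplied
#'   analytes.
#' @return A `conc_profile` for pseudo-analyte `"integrated"`, with the
#'   weight vector attached as attribute `weights_used`.
#' @export
integrate_profiles <- function(profiles, weights) {
  if (!length(profiles)) abort_pk("config", "no profiles supplied")
  if (!inherits(weights, "weight_vector"))
    weights <- compute_weights(weights)
  analytes <- vapply(profiles, function(p) p$analyte_id, character(1))
  if (anyDuplicated(analytes))
    abort_pk("config", "duplicate analyte among profiles")
  if (!setequal(analytes, names(weights)))
    abort_pk("weight_coverage",
             sprintf("weights cover {%s} but profiles supply {%s}",
                     paste(sort(names(weights)), collapse = ","),
                     paste(sort(analytes), collapse = ",")))
  ref <- profiles[[1L]]
  for (p in profiles[-1L]) {
    if (length(p$times) != length(ref$times) || any(p$times != ref$times)) {
      off <- union(setdiff(p$times, ref$times), setdiff(ref$times, p$times))
      abort_pk("grid_alignment",
               sprintf("time grid of %s differs from %s at: %s",
                       p$analyte_id, ref$analyte_id,
                       paste(off, collapse = ", ")),
               times = off)
    }
    if (p$subject_id != ref$subject_id)
      abort_pk("config", "profiles belong to different subjects")
  }

  w <- as.numeric(weights)[match(analytes, names(weights))]
  cmat <- vapply(profiles, function(p) ifelse(p$blq, 0, p$concs),
                 numeric(length(ref$times)))
  bmat <- vapply(profiles, function(p) p$blq, logical(length(ref$times)))
  ct <- as.numeric(cmat %*% w)
  blq <- apply(bmat, 1L, all)
  lloq_t <- min(w * vapply(profiles, function(p) p$lloq, numeric(1)))

  out <- conc_profile(ref$subject_id, "integrated", ref$times,
                      concs = ct, blq = blq, dose = ref$dose, lloq = lloq_t)
  attr(out, "weights_used") <- weights
  out
}

#' Full integrated pharmacokinetic study
#'
#' Runs the complete AUC-weighted integration workflow on a multi-analyte
#' study: per-subject, per-analyte NCA; AUC-proportional weights (from the
#' pooled mean AUC across subjects by default, or per subject); the weighted
#' integrated profile per subject; NCA on each integrated profile; and
#' mean ± SD summaries per parameter for every analyte and the integrated
#' data.  Subjects missing any analyte on the common grid are excluded with
#' a warning.
#'
#' @param profiles list of [conc_profile()] objects covering
#'   subjects × analytes (e.g. from [load_concentration_table()] or
#'   [simulate_pk_study()]).
#' @inheritParams compute_weights
#' @inheritParams run_nca
#' @return An object of class `integrated_study` with elements
#'   `nca` (per subject × analyte parameter data frame, including the
#'   integrated pseudo-analyte), `weights` (the pooled [compute_weights()]
#'   result, or a per-subject list), `integrated_profiles`, and `summary`
#'   (mean ± SD per parameter, analytes in columns).
#' @export
integrated_study <- function(profiles,
                             basis = c("auc_0_inf", "auc_0_t"),
                             scope = c("pooled-mean", "per-subject"),
                             method = c("linear", "linuplogdown"),
                             min_points = 3L) {
  basis <- match.arg(basis)
  scope <- match.arg(scope)
  method <- match.arg(method)

  subjects <- vapply(profiles, function(p) p$subject_id, character(1))
  analytes <- vapply(profiles, function(p) p$analyte_id, character(1))
  all_analytes <- sort(unique(analytes))
  keep_subj <- character(0)
  for (s in unique(subjects)) {
    have <- analytes[subjects == s]
    if (setequal(have, all_analytes) && !anyDuplicated(have)) {
      keep_subj <- c(keep_subj, s)
    } else {
      warn_pk("incomplete_subject",
              sprintf("subject %s lacks analyte(s) %s; excluded", s,
                      paste(setdiff(all_analytes, have), collapse = ", ")))
    }
  }
  if (!length(keep_subj))
    abort_pk("insufficient_data", "no subject has a complete analyte set")

  prof_tbl <- split(profiles[subjects %in% keep_subj],
                    subjects[subjects %in% keep_subj])

  nca_list <- list()
  auc_by_subject <- list()    # subject -> named vector of basis AUCs
  for (s in keep_subj) {
    res <- lapply(prof_tbl[[s]], run_nca, method = method, min_points = min_points)
    names(res) <- vapply(prof_tbl[[s]], function(p) p$analyte_id, character(1))
    nca_list[[s]] <- res
    auc_by_subject[[s]] <- vapply(res, function(r) r[[basis]], numeric(1))[all_analytes]
  }

  auc_mat <- do.call(rbind, auc_by_subject)   # subjects x analytes
  if (scope == "pooled-mean") {
    mean_auc <- colMeans(auc_mat, na.rm = TRUE)
    pooled_w <- compute_weights(mean_auc, basis = basis, scope = scope)
    weights_for <- function(s) pooled_w
    weights_out <- pooled_w
  } else {
    weights_out <- list()
    weights_for <- function(s) {
      aucs <- auc_by_subject[[s]]
      if (anyNA(aucs))
        abort_pk("invalid_auc",
                 sprintf("subject %s: %s missing for analyte(s) %s", s, basis,
                         paste(all_analytes[is.na(aucs)], collapse = ", ")))
      compute_weights(aucs, basis = basis, scope = scope)
    }
  }

  integrated_profiles <- list()
  for (s in keep_subj) {
    w <- weights_for(s)
    if (scope == "per-subject") weights_out[[s]] <- w
    ip <- integrate_profiles(prof_tbl[[s]], w)
    integrated_profiles[[s]] <- ip
    nca_list[[s]][["integrated"]] <- run_nca(ip, method = method,
                                             min_points = min_points)
  }

  nca_df <- do.call(rbind, lapply(nca_list, function(res)
    do.call(rbind, lapply(res, as.data.frame))))
  rownames(nca_df) <- NULL

  structure(
    list(nca = nca_df, weights = weights_out,
         integrated_profiles = integrated_profiles,
         summary = summarize_nca_table(nca_df,
                                       c(all_analytes, "integrated")),
         basis = basis, scope = scope, method = method,
         subjects = keep_subj, analytes = all_analytes),
    class = "integrated_study")
}

# mean +/- sd (sample SD, n-1) per parameter, analytes in columns.
summarize_nca_table <- function(nca_df, analyte_order) {
  params <- nca_param_names
  out <- data.frame(parameter = params, stringsAsFactors = FALSE)
  for (a in analyte_order) {
    sub <- nca_df[nca_df$analyte == a, , drop = FALSE]
    out[[a]] <- vapply(params, function(p) {
      v <- sub[[p]]
      v <- v[is.finite(v)]
      if (!length(v)) return(NA_character_)
      sprintf("%s ± %s", signif(mean(v), 4),
              signif(if (length(v) > 1) sd(v) else 0, 4))
    }, character(1))
  }
  out
}

#' @export
print.integrated_study <- function(x, ...) {
  cat(sprintf("<integrated_study> %d subjects, analytes: %s\n",
              length(x$subjects), paste(x$analytes, collapse = ", ")))
  cat(sprintf("weights (basis %s, scope %s):\n", x$basis, x$scope))
  if (inherits(x$weights, "weight_vector")) print(x$weights)
  cat("\nParameter summary (mean ± SD):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
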