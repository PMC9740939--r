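#' Assemble (or load) an end-to-end pipeline configuration
#'
#' A pipeline config names the input files and the analysis options for
#' [run_pipeline()].  It can be built in code or loaded from YAML; it
#' round-trips through [yaml::write_yaml()] unchanged.
#'
#' @param conc path to the long-format concentration CSV (required).
#' @param analytes named list keyed by analyte with `dose` (mg/kg) and
#'   `lloq` (ng/mL).
#' @param cal,qc,areas optional paths to calibration / QC / peak-area CSVs
#'   for the validation stage.
#' @param compound_targets,disease_targets,ppi,gmt optional paths to the
#'   network-stage inputs (target lists, PPI edge TSV, GMT gene sets).
#' @param method,min_points NCA options, see [run_nca()].
#' @param basis,scope integration options, see [compute_weights()].
#' @param ease,score_cutoff enrichment / edge-filter options, see
#'   [enrich_pathways()] and [interaction_network()].
#' @param seed integer seed recorded in the run manifest.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(conc, analytes,
                            cal = NULL, qc = NULL, areas = NULL,
                            compound_targets = NULL, disease_targets = NULL,
                            ppi = NULL, gmt = NULL,
                            method = "linear", min_points = 3L,
                            basis = "auc_0_inf", scope = "pooled-mean",
                            ease = FALSE, score_cutoff = NULL, seed = 1L) {
  cfg <- list(conc = conc, analytes = analytes, cal = cal, qc = qc,
              areas = areas, compound_targets = compound_targets,
              disease_targets = disease_targets, ppi = ppi, gmt = gmt,
              method = match.arg(method, c("linear", "linuplogdown")),
              min_points = as.integer(min_points),
              basis = match.arg(basis, c("auc_0_inf", "auc_0_t")),
              scope = match.arg(scope, c("pooled-mean", "per-subject")),
              ease = isTRUE(ease), score_cutoff = score_cutoff,
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, null = "null",
                       digits = NA)
  unname(tools::md5sum(tmp))
}

write_stage_csv <- function(df, path, manifest_meta) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", manifest_meta$config_hash,
                     manifest_meta$seed), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full integrated-PK + network-pharmacology pipeline
#'
#' Executes, in order: the bioanalytical validation stage (if calibration /
#' QC / area tables are configured), per-analyte NCA with AUC-weighted
#' integration, and the network-pharmacology stage (if target / PPI /
#' gene-set inputs are configured).  Each output CSV carries the config
#' hash and seed in a leading comment line; a JSON manifest records the
#' per-stage status and row counts.  A stage failure halts the run with a
#' stage-labelled error; outputs written so far are retained and the
#' manifest marks the failure point.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(config_hash = config_hash(config), seed = config$seed)
  manifest <- list(config_hash = meta$config_hash, seed = config$seed,
                   package_version = as.character(utils::packageVersion("herbipk")),
                   stages = list())
  results <- list()

  run_stage <- function(name, fn) {
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       message = conditionMessage(res))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      abort_pk("stage", sprintf("stage '%s' failed: %s", name,
                                conditionMessage(res)), stage = name)
    }
    res
  }

  # -- validation stage (optional) ------------------------------------
  if (!is.null(config$cal) || !is.null(config$qc) || !is.null(config$areas)) {
    rep <- run_stage("validation", function() {
      validation_report(
        cal = if (!is.null(config$cal)) read.csv(config$cal, stringsAsFactors = FALSE),
        qc = if (!is.null(config$qc)) read.csv(config$qc, stringsAsFactors = FALSE),
        areas = if (!is.null(config$areas)) read.csv(config$areas, stringsAsFactors = FALSE))
    })
    results$validation <- rep
    vr <- do.call(rbind, c(
      if (!is.null(rep$qc)) list(data.frame(section = "qc", rep$qc[, c("analyte", "level")],
        value1 = rep$qc$precision_rsd, value2 = rep$qc$accuracy_pct,
        detail = ifelse(rep$qc$pass, "pass", "fail"))),
      if (!is.null(rep$calibration)) list(data.frame(section = "calibration",
        analyte = rep$calibration$analyte, level = "-",
        value1 = rep$calibration$slope, value2 = rep$calibration$r,
        detail = rep$calibration$weighting)),
      if (!is.null(rep$recovery)) list(data.frame(section = "recovery",
        rep$recovery[, c("analyte", "level")],
        value1 = rep$recovery$recovery_pct, value2 = rep$recovery$matrix_effect_pct,
        detail = "recovery_pct/matrix_effect_pct"))))
    write_stage_csv(vr, file.path(out_dir, "validation_report.csv"), meta)
    manifest$stages$validation <- list(status = "ok", rows = nrow(vr))
  } else {
    manifest$stages$validation <- list(status = "skipped")
  }

  # -- PK stage --------------------------------------------------------
  study <- run_stage("pk", function() {
    profiles <- load_concentration_table(config$conc, config$analytes)
    integrated_study(profiles, basis = config$basis, scope = config$scope,
                     method = config$method, min_points = config$min_points)
  })
  results$study <- study
  write_stage_csv(study$nca, file.path(out_dir, "nca_by_subject.csv"), meta)
  write_stage_csv(study$summary, file.path(out_dir, "pk_summary.csv"), meta)
  if (inherits(study$weights, "weight_vector")) {
    wdf <- data.frame(analyte = names(study$weights),
                      weight = as.numeric(study$weights),
                      weight_pct = 100 * as.numeric(study$weights))
  } else {
    wdf <- do.call(rbind, lapply(names(study$weights), function(s)
      data.frame(subject_id = s, analyte = names(study$weights[[s]]),
                 weight = as.numeric(study$weights[[s]]),
                 weight_pct = 100 * as.numeric(study$weights[[s]]))))
  }
  write_stage_csv(wdf, file.path(out_dir, "weights.csv"), meta)
  manifest$stages$pk <- list(status = "ok", rows = nrow(study$nca),
                             subjects = length(study$subjects))

  # -- network stage (optional) ---------------------------------------
  have_net <- !is.null(config$compound_targets) && !is.null(config$disease_targets) &&
    !is.null(config$ppi) && !is.null(config$gmt)
  if (have_net) {
    net <- run_stage("network", function() {
      compound <- read_target_list(config$compound_targets, "compound")
      disease <- read_target_list(config$disease_targets, "disease")
      network <- read_ppi_edges(config$ppi, score_cutoff = config$score_cutoff)
      genesets <- read_gmt(config$gmt)
      common <- intersect_targets(compound, disease)
      sub <- subnetwork(network, common)
      metrics <- topology_metrics(sub)
      key <- select_key_targets(metrics)
      enr <- enrich_pathways(intersect(common$targets, network$nodes),
                             genesets, universe = network$nodes,
                             ease = config$ease)
      list(common = common, subnetwork = sub, metrics = metrics,
           key_targets = key, enrichment = enr)
    })
    results$network <- net
    write_stage_csv(net$metrics, file.path(out_dir, "node_metrics.csv"), meta)
    write_stage_csv(net$enrichment, file.path(out_dir, "enrichment.csv"), meta)
    write_sif(net$subnetwork, file.path(out_dir, "subnetwork.sif"))
    manifest$stages$network <- list(status = "ok",
                                    common_targets = length(net$common),
                                    pathways = nrow(net$enrichment))
  } else {
    manifest$stages$network <- list(status = "skipped")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
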