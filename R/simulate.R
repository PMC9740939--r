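# Evaluate RNG-dependent code under a fixed seed without disturbing the
# caller's RNG state; all generators are pure functions of (config, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

#' Default kinetic presets for the five absorbed constituents
#'
#' Presets for the five absorbed constituents of Polygonum multiflorum
#' extract (TSG, EG, PG, AE, EM).  For each analyte, `(ka, ke, scale)` is
#' chosen so that the noise-free one-compartment oral curve reproduces
#' literature-scale mean AUC0-inf, terminal half-life and Tmax in rats
#' after an 18 g/kg oral extract dose; `scale = F*D/V` so AUC0-inf equals
#' `scale/ke` exactly.  LLOQs match the validated assay (0.125 ng/mL for
#' EG, 0.500 ng/mL otherwise).
#'
#' @return Named list of per-analyte kinetic parameter lists
#'   (`ka`, `ke`, `scale`, `lloq`), suitable for [sim_pk_config()].
#' @export
default_pk_analytes <- function() {
  ref <- list(
    #          t_half  auc0inf    ka  lloq
    TSG = list(t_half = 2.22, auc = 758.2, ka = 16, lloq = 0.500),
    EG  = list(t_half = 6.47, auc = 345.8, ka = 9,  lloq = 0.125),
    PG  = list(t_half = 12.3, auc = 205.0, ka = 25, lloq = 0.500),
    AE  = list(t_half = 6.42, auc = 70.28, ka = 22, lloq = 0.500),
    EM  = list(t_half = 11.1, auc = 1041,  ka = 38, lloq = 0.500))
  lapply(ref, function(a) {
    ke <- log(2) / a$t_half
    list(ka = a$ka, ke = ke, scale = a$auc * ke, lloq = a$lloq)
  })
}

#' Configuration for a simulated multi-analyte PK study
#'
#' Defines the generative model behind [simulate_pk_study()]: per-analyte
#' one-compartment oral kinetics
#' \eqn{C(t) = scale \cdot k_a/(k_a - k_e)(e^{-k_e t} - e^{-k_a t})} with
#' lognormal inter-individual variability on `ka`, `ke` and `scale`,
#' proportional-plus-additive Gaussian assay error, and LLOQ censoring.
#' Defaults emulate a rat study of the five absorbed constituents of
#' Polygonum multiflorum extract: 6 subjects sampled at 5, 15 and 30 min
#' and 1, 2, 4, 8, 12 and 24 h after an 18 g/kg oral dose, with 20%
#' inter-individual CV and 10% proportional assay error.
#'
#' @param analytes named list; each element a list with `ka` (1/h), `ke`
#'   (1/h, different from `ka`), `scale` (ng/mL; equals F·D/V so that the
#'   noise-free AUC0-inf is `scale/ke`), `lloq` (ng/mL).
#' @param n_subjects number of subjects (default 6).
#' @param times sampling grid in hours (default the 9-point rat schedule).
#' @param iiv_cv lognormal inter-individual CV applied to ka, ke and scale
#'   (default 0.2).
#' @param error_prop proportional assay error CV (default 0.10).
#' @param error_add additive assay error SD in ng/mL (default 0).
#' @param dose administered dose per body weight (mg/kg extract-equivalent,
#'   default 18000).
#' @param seed integer RNG seed; recorded in all outputs.
#' @return A `sim_pk_config` list.
#' @export
sim_pk_config <- function(analytes = default_pk_analytes(), n_subjects = 6L,
                          times = c(0.083, 0.25, 0.5, 1, 2, 4, 8, 12, 24),
                          iiv_cv = 0.2, error_prop = 0.10, error_add = 0,
                          dose = 18000, seed = 1L) {
  if (!length(analytes) || is.null(names(analytes)))
    abort_pk("config", "'analytes' must be a non-empty named list", field = "analytes")
  for (nm in names(analytes)) {
    a <- analytes[[nm]]
    for (f in c("ka", "ke", "scale", "lloq"))
      stopifnot_scalar_number(a[[f]], paste0(nm, "$", f), positive = TRUE)
    if (a$ka == a$ke)
      abort_pk("config", sprintf("analyte %s: ka must differ from ke", nm),
               field = "ka")
  }
  if (as.integer(n_subjects) < 1L)
    abort_pk("config", "'n_subjects' must be >= 1", field = "n_subjects")
  times <- as.numeric(times)
  if (length(times) < 3L || any(times <= 0) || any(diff(times) <= 0))
    abort_pk("config", "'times' must be >= 3 strictly increasing positive times",
             field = "times")
  for (f in c("iiv_cv", "error_prop", "error_add")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      abort_pk("config", sprintf("'%s' must be a single number >= 0", f), field = f)
  }
  stopifnot_scalar_number(dose, "dose", positive = TRUE)
  structure(list(analytes = analytes, n_subjects = as.integer(n_subjects),
                 times = times, iiv_cv = iiv_cv, error_prop = error_prop,
                 error_add = error_add, dose = dose, seed = as.integer(seed)),
            class = "sim_pk_config")
}

one_cpt_oral <- function(t, ka, ke, scale)
  scale * ka / (ka - ke) * (exp(-ke * t) - exp(-ka * t))

#' Simulate a multi-analyte plasma concentration study
#'
#' Draws per-subject kinetic parameters from lognormal distributions around
#' the configured typical values, evaluates the one-compartment oral model
#' on the sampling grid, adds proportional-plus-additive Gaussian assay
#' error, and censors observations below the analyte LLOQ (reported as 0
#' with `blq = TRUE`).  The per-subject true AUC0-inf (`scale/ke`) and
#' terminal half-life are returned alongside for parameter-recovery checks.
#'
#' @param config a [sim_pk_config()].
#' @return A list with `data` (long-format data frame `subject_id, analyte,
#'   time_h, conc_ng_ml, blq`), `truth` (per subject × analyte parameters),
#'   `profiles` (list of [conc_profile()], subjects with no quantifiable
#'   data omitted), and `config`.
#' @export
simulate_pk_study <- function(config = sim_pk_config()) {
  stopifnot(inherits(config, "sim_pk_config"))
  with_seed(config$seed, {
    sdlog <- sqrt(log(1 + config$iiv_cv^2))
    rows <- list(); truths <- list(); profiles <- list()
    for (s in seq_len(config$n_subjects)) {
      sid <- sprintf("S%02d", s)
      for (an in names(config$analytes)) {
        a <- config$analytes[[an]]
        ka <- a$ka * exp(rnorm(1, -sdlog^2 / 2, sdlog))
        ke <- a$ke * exp(rnorm(1, -sdlog^2 / 2, sdlog))
        sc <- a$scale * exp(rnorm(1, -sdlog^2 / 2, sdlog))
        if (ka == ke) ke <- ke * (1 + 1e-9)
        ct <- one_cpt_oral(config$times, ka, ke, sc)
        obs <- ct * (1 + rnorm(length(ct), 0, config$error_prop)) +
          rnorm(length(ct), 0, config$error_add)
        obs <- pmax(obs, 0)
        blq <- obs < a$lloq
        obs[blq] <- 0
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, analyte = an, time_h = config$times,
          conc_ng_ml = obs, blq = blq, stringsAsFactors = FALSE)
        truths[[length(truths) + 1L]] <- data.frame(
          subject_id = sid, analyte = an, ka = ka, ke = ke, scale = sc,
          auc_0_inf = sc / ke, t_half = log(2) / ke,
          stringsAsFactors = FALSE)
        if (!all(blq))
          profiles[[paste(sid, an, sep = ".")]] <- conc_profile(
            sid, an, config$times, obs, blq = blq,
            dose = config$dose, lloq = a$lloq)
      }
    }
    list(data = do.call(rbind, rows), truth = do.call(rbind, truths),
         profiles = profiles, config = config)
  })
}

#' Simulate quality-control validation batches
#'
#' Generates replicate measured concentrations around each nominal level
#' with a known multiplicative bias and CV:
#' `measured = nominal * (bias/100) * (1 + (cv/100) * Z)`, truncated at 0.
#'
#' @param nominal_levels named numeric vector of nominal concentrations
#'   (ng/mL); names become the QC level labels.
#' @param true_bias accuracy ground truth in percent (100 = unbiased).
#' @param true_cv replicate CV ground truth in percent, >= 0.
#' @param n_replicates replicates per level, >= 3.
#' @param analyte analyte label.
#' @param condition condition label (e.g. `"intra-day"`).
#' @param seed integer RNG seed.
#' @return Data frame `analyte, level, condition, nominal_ng_ml,
#'   measured_ng_ml` with attribute `truth = list(bias, cv)`.
#' @export
simulate_validation_batch <- function(nominal_levels, true_bias = 100,
                                      true_cv = 5, n_replicates = 6L,
                                      analyte = "SIM", condition = "intra-day",
                                      seed = 1L) {
  if (true_cv < 0)
    abort_pk("config", "'true_cv' must be >= 0", field = "true_cv")
  if (as.integer(n_replicates) < 3L)
    abort_pk("config", "'n_replicates' must be >= 3", field = "n_replicates")
  if (is.null(names(nominal_levels)))
    names(nominal_levels) <- paste0("L", seq_along(nominal_levels))
  with_seed(seed, {
    out <- do.call(rbind, lapply(names(nominal_levels), function(lv) {
      nom <- nominal_levels[[lv]]
      meas <- pmax(nom * (true_bias / 100) *
                     (1 + (true_cv / 100) * rnorm(n_replicates)), 0)
      data.frame(analyte = analyte, level = lv, condition = condition,
                 nominal_ng_ml = nom, measured_ng_ml = meas,
                 stringsAsFactors = FALSE)
    }))
    attr(out, "truth") <- list(bias = true_bias, cv = true_cv, seed = seed)
    out
  })
}

#' Simulate an offline network-pharmacology study
#'
#' Builds a gene universe, compound and disease target sets sharing exactly
#' `overlap` members, an Erdős–Rényi PPI network over the universe (plus a
#' guaranteed path spanning the intersection so the common-target
#' subnetwork is connected), one pathway planted to contain
#' `planted_overlap` intersection genes, and uniformly drawn decoy
#' pathways.
#'
#' @param n_universe universe size.
#' @param n_compound,n_disease target set sizes.
#' @param overlap size of the compound ∩ disease intersection.
#' @param planted_pathway_size genes in the planted pathway.
#' @param planted_overlap intersection genes planted into that pathway,
#'   <= `min(planted_pathway_size, overlap)`.
#' @param n_decoy_pathways number of uniformly drawn decoy pathways (same
#'   size as the planted one).
#' @param edge_density Erdős–Rényi edge probability.
#' @param seed integer RNG seed.
#' @return A list: `compound`, `disease` ([target_set()]s), `network`
#'   ([interaction_network()]), `genesets` (named list, planted pathway
#'   first), `truth` (planted pathway id, intersection members, seed).
#' @export
simulate_network_study <- function(n_universe = 200L, n_compound = 60L,
                                   n_disease = 80L, overlap = 20L,
                                   planted_pathway_size = 25L,
                                   planted_overlap = 16L,
                                   n_decoy_pathways = 30L,
                                   edge_density = 0.05, seed = 1L) {
  if (overlap > min(n_compound, n_disease))
    abort_pk("config", "'overlap' exceeds a target set size", field = "overlap")
  if (planted_overlap > min(planted_pathway_size, overlap))
    abort_pk("config",
             "'planted_overlap' exceeds planted_pathway_size or overlap",
             field = "planted_overlap")
  if (n_compound + n_disease - overlap > n_universe)
    abort_pk("config", "universe too small for the requested sets",
             field = "n_universe")
  with_seed(seed, {
    universe <- sprintf("G%04d", seq_len(n_universe))
    pool <- sample(universe)
    common <- pool[seq_len(overlap)]
    comp_only <- pool[overlap + seq_len(n_compound - overlap)]
    dis_only <- pool[n_compound + seq_len(n_disease - overlap)]
    compound <- target_set("compound", c(common, comp_only))
    disease <- target_set("disease", c(common, dis_only))

    # Erdős–Rényi edges over the universe
    idx <- which(upper.tri(matrix(0, n_universe, n_universe)), arr.ind = TRUE)
    pick <- runif(nrow(idx)) < edge_density
    ed <- data.frame(node_a = universe[idx[pick, 1L]],
                     node_b = universe[idx[pick, 2L]],
                     score = round(runif(sum(pick), 0.4, 1), 3),
                     stringsAsFactors = FALSE)
    if (length(common) > 1L) {         # spanning path over the intersection
      sp <- data.frame(node_a = common[-length(common)], node_b = common[-1L],
                       score = 0.999, stringsAsFactors = FALSE)
      ed <- rbind(ed, sp)
    }
    network <- interaction_network(ed, nodes = universe)

    planted <- c(sample(common, planted_overlap),
                 sample(setdiff(universe, common),
                        planted_pathway_size - planted_overlap))
    genesets <- c(list(PW_PLANTED = sort(planted)),
                  setNames(lapply(seq_len(n_decoy_pathways), function(i)
                    sort(sample(universe, planted_pathway_size))),
                    sprintf("PW_DECOY%03d", seq_len(n_decoy_pathways))))

    list(compound = compound, disease = disease, network = network,
         genesets = genesets,
         truth = list(planted_pathway = "PW_PLANTED",
                      intersection = sort(common), seed = seed))
  })
}
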