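conc_cols <- c("subject_id", "analyte", "time_h", "conc_ng_ml", "blq")

#' Read a long-format concentration table into profiles
#'
#' Expects a UTF-8 comma-separated file with header
#' `subject_id,analyte,time_h,conc_ng_ml,blq`.  Rows are grouped by
#' subject × analyte, sorted by time, and turned into [conc_profile()]
#' objects using the per-analyte dose and LLOQ from `config`.
#'
#' @param path CSV file path, or a data frame with the same columns.
#' @param config named list keyed by analyte, each element a list with
#'   `dose` (mg/kg; may be `NA`) and `lloq` (ng/mL); e.g. the `analytes`
#'   element of a pipeline YAML config.
#' @return Named list of `conc_profile` (`"<subject>.<analyte>"`).
#' @export
load_concentration_table <- function(path, config) {
  df <- if (is.data.frame(path)) path else {
    raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    raw
  }
  missing <- setdiff(conc_cols, names(df))
  if (length(missing))
    abort_pk("schema", sprintf("missing column(s): %s",
                               paste(missing, collapse = ", ")),
             columns = missing)
  for (col in c("time_h", "conc_ng_ml")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (anyNA(v)) {
      line <- c(bad, which(is.na(df[[col]])))[1L] + 1L   # +1 for header
      abort_pk("parse", sprintf("non-numeric '%s' at line %d", col, line),
               line = line)
    }
    df[[col]] <- v
  }
  df$blq <- as.logical(toupper(as.character(df$blq)) %in% c("TRUE", "T", "1")) |
    df$blq == TRUE

  key <- paste(df$subject_id, df$analyte, df$time_h, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    abort_pk("duplicate_record",
             sprintf("duplicate record for subject %s, analyte %s, time %g h",
                     d$subject_id, d$analyte, d$time_h))
  }

  out <- list()
  for (grp in split(df, paste(df$subject_id, df$analyte, sep = "."))) {
    grp <- grp[order(grp$time_h), , drop = FALSE]
    an <- grp$analyte[1L]
    cf <- config[[an]]
    if (is.null(cf) || is.null(cf$lloq))
      abort_pk("config", sprintf("no dose/lloq config for analyte '%s'", an),
               field = an)
    out[[paste(grp$subject_id[1L], an, sep = ".")]] <- conc_profile(
      grp$subject_id[1L], an, grp$time_h, grp$conc_ng_ml, blq = grp$blq,
      dose = if (is.null(cf$dose)) NA_real_ else cf$dose, lloq = cf$lloq)
  }
  out[order(names(out))]
}

#' Write profiles back to the long-format CSV dialect
#'
#' Inverse of [load_concentration_table()]; `load ∘ write` is the identity
#' on the profile contents.
#'
#' @param profiles list of [conc_profile()] (or a long-format data frame).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(profiles, path) {
  df <- if (is.data.frame(profiles)) profiles else
    do.call(rbind, lapply(profiles, as.data.frame))
  write.csv(df[, conc_cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write gene sets in GMT format
#'
#' Broad-convention GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>member...`.
#'
#' @param path GMT file path.
#' @return For `read_gmt`, a named list of character vectors (description
#'   kept as attribute `description`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list(); desc <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      abort_pk("parse", sprintf("GMT line with fewer than 3 fields: %s",
                                substr(ln, 1, 40)))
    out[[f[1L]]] <- f[-(1:2)]
    desc[f[1L]] <- f[2L]
  }
  attr(out, "description") <- desc
  out
}

#' @rdname read_gmt
#' @param genesets named list of character vectors.
#' @export
write_gmt <- function(genesets, path) {
  desc <- attr(genesets, "description")
  lines <- vapply(names(genesets), function(nm) {
    d <- if (!is.null(desc) && nm %in% names(desc)) desc[[nm]] else "na"
    paste(c(nm, d, genesets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a target list (one identifier per line, or TSV with a label column)
#'
#' @param path file path; lines starting with `#` are skipped.  A
#'   two-column TSV is read as `label<TAB>target`, keeping all targets.
#' @param label label for the resulting set (default: file name).
#' @return A [target_set()].
#' @export
read_target_list <- function(path, label = tools::file_path_sans_ext(basename(path))) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, function(f) f[[length(f)]], character(1))
  target_set(label, ids)
}

#' Read a PPI edge list (STRING-export compatible TSV)
#'
#' Tab-separated `node_a<TAB>node_b[<TAB>score]`; a header line is detected
#' and skipped when the third field is non-numeric.
#'
#' @param path TSV/SIF-style edge file.
#' @inheritParams interaction_network
#' @return An [interaction_network()].
#' @export
read_ppi_edges <- function(path, score_cutoff = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) && ncol(df) >= 3L &&
      is.na(suppressWarnings(as.numeric(df[1L, 3L])))) df <- df[-1L, , drop = FALSE]
  names(df)[1:2] <- c("node_a", "node_b")
  if (ncol(df) >= 3L) { names(df)[3L] <- "score"; df$score <- as.numeric(df$score) }
  interaction_network(df, score_cutoff = score_cutoff)
}

#' Write a network as a Cytoscape-loadable SIF file
#'
#' One `node_a pp node_b` line per edge; isolated nodes are written as
#' bare node lines.
#'
#' @param network an [interaction_network()].
#' @param path output path.
#' @export
write_sif <- function(network, path) {
  lines <- sprintf("%s\tpp\t%s", network$edges$node_a, network$edges$node_b)
  iso <- setdiff(network$nodes, c(network$edges$node_a, network$edges$node_b))
  writeLines(c(lines, iso), path)
  invisible(path)
}
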