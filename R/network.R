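#' Construct a normalized target set
#'
#' Gene/protein identifiers are upper-cased, trimmed, deduplicated and
#' sorted, so that set operations are case-insensitive and order-free.
#'
#' @param label a short label (compound, disease, ...).
#' @param targets character vector of identifiers.
#' @return A `target_set` with elements `label` and `targets`.
#' @export
target_set <- function(label, targets) {
  targets <- toupper(trimws(as.character(targets)))
  targets <- sort(unique(targets[nzchar(targets) & !is.na(targets)]))
  structure(list(label = as.character(label)[1L], targets = targets),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set> %s: %d targets\n", x$label, length(x$targets)))
  invisible(x)
}

#' @export
length.target_set <- function(x) length(x$targets)

as_target_chr <- function(x) if (inherits(x, "target_set")) x$targets else
  target_set("tmp", x)$targets

#' Intersection of compound and disease target sets
#'
#' Case-normalized set intersection; a disjoint result is valid but raises
#' a warning.
#'
#' @param compound,disease [target_set()] objects (or character vectors).
#' @return A `target_set` labelled `"<compound> ∩ <disease>"`.
#' @export
intersect_targets <- function(compound, disease) {
  a <- if (inherits(compound, "target_set")) compound else target_set("compound", compound)
  b <- if (inherits(disease, "target_set")) disease else target_set("disease", disease)
  if (!length(a$targets) || !length(b$targets))
    abort_pk("empty_set", "both target sets must be non-empty")
  common <- intersect(a$targets, b$targets)
  if (!length(common))
    warn_pk("disjoint_targets",
            sprintf("'%s' and '%s' share no targets", a$label, b$label))
  target_set(paste(a$label, b$label, sep = " ∩ "), common)
}

#' Construct a protein-protein interaction network
#'
#' Accepts an edge table (columns `node_a`, `node_b`, optional `score` in
#' [0,1], STRING-export style).  Identifiers are case-normalized;
#' self-loops and duplicate (unordered) edges are removed; edges below
#' `score_cutoff` are dropped.  Isolated nodes may be supplied via `nodes`.
#'
#' @param edges data frame with two identifier columns (first two columns
#'   are used) and an optional numeric `score` column.
#' @param nodes optional character vector of additional (isolated) nodes.
#' @param score_cutoff keep edges with `score >= score_cutoff`; default
#'   `NULL` keeps all edges.
#' @return An `interaction_network`: `nodes` (character) and `edges`
#'   (data frame `node_a`, `node_b`, `score`).
#' @export
interaction_network <- function(edges, nodes = NULL, score_cutoff = NULL) {
  if (!is.data.frame(edges) || ncol(edges) < 2L)
    abort_pk("config", "edges must be a data frame with two identifier columns")
  a <- toupper(trimws(as.character(edges[[1L]])))
  b <- toupper(trimws(as.character(edges[[2L]])))
  score <- if ("score" %in% names(edges)) as.numeric(edges$score)
           else if (ncol(edges) >= 3L && is.numeric(edges[[3L]])) as.numeric(edges[[3L]])
           else rep(NA_real_, length(a))
  if (!is.null(score_cutoff)) {
    keep <- is.na(score) | score >= score_cutoff
    a <- a[keep]; b <- b[keep]; score <- score[keep]
  }
  keep <- a != b                               # drop self-loops
  a <- a[keep]; b <- b[keep]; score <- score[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)           # canonical unordered form
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  ed <- data.frame(node_a = lo[!dup], node_b = hi[!dup], score = score[!dup],
                   stringsAsFactors = FALSE)
  all_nodes <- sort(unique(c(ed$node_a, ed$node_b,
                             toupper(trimws(as.character(nodes))))))
  all_nodes <- all_nodes[nzchar(all_nodes)]
  structure(list(nodes = all_nodes, edges = ed), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges[, c("node_a", "node_b")],
                                directed = FALSE,
                                vertices = data.frame(name = network$nodes))
}

#' Induced subnetwork on a node subset
#'
#' @param network an [interaction_network()].
#' @param nodes node identifiers (or a [target_set()]).
#' @return An `interaction_network` restricted to `nodes` (nodes absent from
#'   the network are ignored).
#' @export
subnetwork <- function(network, nodes) {
  keep <- intersect(network$nodes, as_target_chr(nodes))
  ed <- network$edges[network$edges$node_a %in% keep &
                        network$edges$node_b %in% keep, , drop = FALSE]
  structure(list(nodes = keep, edges = ed), class = "interaction_network")
}

#' Degree and closeness centrality per node
#'
#' Degree is the number of incident edges.  Closeness follows the
#' Wasserman-Faust convention for possibly disconnected graphs: within a
#' node's connected component, \eqn{(n_c - 1)/\sum d}, scaled by
#' \eqn{(n_c - 1)/(n - 1)} so that nodes in small components are penalized.
#' `closeness = "harmonic"` instead averages reciprocal distances over all
#' other nodes (unreachable nodes contribute 0).
#'
#' @param network an [interaction_network()].
#' @param closeness `"wf"` (Wasserman-Faust, default) or `"harmonic"`.
#' @return Data frame `node`, `degree`, `closeness`.
#' @export
topology_metrics <- function(network, closeness = c("wf", "harmonic")) {
  closeness <- match.arg(closeness)
  if (!length(network$nodes)) abort_pk("empty_set", "network has no nodes")
  g <- as_igraph(network)
  n <- length(network$nodes)
  deg <- igraph::degree(g)
  d <- igraph::distances(g)

  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    if (n == 1L) return(0)
    if (closeness == "harmonic") return(sum(1 / di[is.finite(di) & di > 0]) / (n - 1))
    reach <- di[is.finite(di)]
    nc <- length(reach) + 1L                    # component size
    if (nc == 1L) return(0)                     # isolated node
    ((nc - 1) / sum(reach)) * ((nc - 1) / (n - 1))
  }, numeric(1))

  data.frame(node = network$nodes, degree = as.numeric(deg[network$nodes]),
             closeness = clo, stringsAsFactors = FALSE)
}

#' Select key targets from subnetwork topology
#'
#' A node is retained when both its degree and its closeness exceed the
#' subnetwork mean of that metric; results are ranked by degree, then
#' closeness, descending.  When no node exceeds both means (e.g. all
#' metrics equal) the selection is empty and a warning is raised.
#'
#' @param metrics data frame from [topology_metrics()].
#' @return The selected rows of `metrics`, ranked.
#' @export
select_key_targets <- function(metrics) {
  stopifnot(all(c("node", "degree", "closeness") %in% names(metrics)))
  sel <- metrics$degree > mean(metrics$degree) &
    metrics$closeness > mean(metrics$closeness)
  out <- metrics[sel, , drop = FALSE]
  if (!nrow(out)) {
    warn_pk("no_key_targets", "no node exceeds both metric means")
    return(out)
  }
  out[order(-out$degree, -out$closeness, out$node), , drop = FALSE]
}

#' Hypergeometric pathway over-representation analysis
#'
#' For each gene set, tests whether its overlap with the query is larger
#' than expected under uniform draws from the universe:
#' \eqn{p = P[X \ge k]} with
#' \eqn{X \sim \mathrm{Hypergeom}(N = |universe|, K = |pathway|, n = |query|)}.
#' Gene sets are intersected with the universe before testing.  An optional
#' EASE-style conservative variant discounts one overlapping gene
#' (\eqn{P[X \ge k - 1]} evaluated at \eqn{k-1} successes).  p-values are
#' Benjamini-Hochberg adjusted across all tested pathways and results are
#' sorted by ascending p.
#'
#' @param query [target_set()] or character vector; must be a subset of
#'   `universe`.
#' @param genesets named list of character vectors (e.g. [read_gmt()]).
#' @param universe character vector of all eligible identifiers.
#' @param ease logical; apply the EASE discount (default `FALSE`).
#' @return Data frame `pathway_id`, `pathway_size`, `overlap_count`,
#'   `overlap_ids` (comma-separated), `p_value`, `q_value`.
#' @export
enrich_pathways <- function(query, genesets, universe, ease = FALSE) {
  q <- as_target_chr(query)
  uni <- sort(unique(toupper(trimws(as.character(universe)))))
  offenders <- setdiff(q, uni)
  if (length(offenders))
    abort_pk("universe_violation",
             sprintf("query identifiers outside the universe: %s",
                     paste(offenders, collapse = ", ")),
             offenders = offenders)
  if (!length(genesets)) abort_pk("config", "no gene sets supplied")
  if (is.null(names(genesets)) || any(!nzchar(names(genesets))))
    abort_pk("config", "genesets must be a named list")

  N <- length(uni); n <- length(q)
  rows <- lapply(names(genesets), function(id) {
    gs <- intersect(toupper(trimws(genesets[[id]])), uni)
    K <- length(gs)
    ov <- intersect(gs, q)
    k <- length(ov)
    kk <- if (ease) max(k - 1L, 0L) else k
    p <- if (kk == 0L) 1 else stats::phyper(kk - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = id, pathway_size = K, overlap_count = k,
               overlap_ids = paste(ov, collapse = ","),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment
#' \eqn{q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j}, capped at 1, returned in the
#' input order.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same order as input.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (!length(p) || anyNA(p) || any(p <= 0 | p > 1))
    abort_pk("invalid_p", "all p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}
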