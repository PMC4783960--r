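#' Construct a protein-protein interaction network object
#'
#' A `ppi_network` is a simple undirected graph: canonical edges (no
#' self-loops, no parallel edges) with an optional composite-LR weight and a
#' provenance tag, plus a node table.
#'
#' @param edges Data frame with columns `a`, `b` and optionally `lr`,
#'   `provenance`.
#' @param nodes Optional character vector of node IDs; endpoints are always
#'   included.
#' @return Object of class `ppi_network` with elements `nodes` (data frame)
#'   and `edges` (data frame).
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(edges)) {
    edges <- data.frame(a = character(), b = character(), lr = numeric(),
                        provenance = character(), stringsAsFactors = FALSE)
  }
  cp <- canonical_pairs(edges$a, edges$b, drop_self = FALSE, dedupe = FALSE)
  edges$a <- cp$a
  edges$b <- cp$b
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  if (is.null(edges$lr)) edges$lr <- NA_real_
  if (is.null(edges$provenance)) edges$provenance <- "unspecified"
  edges <- edges[!duplicated(pair_key(edges$a, edges$b)), , drop = FALSE]
  rownames(edges) <- NULL
  node_ids <- sort(unique(c(nodes, edges$a, edges$b)))
  structure(list(nodes = data.frame(node = node_ids, stringsAsFactors = FALSE),
                 edges = edges),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("PPI network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    cat("  provenance:",
        paste(names(table(x$edges$provenance)),
              table(x$edges$provenance), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Convert a `ppi_network` to an igraph graph
#' @param net A `ppi_network`.
#' @return An undirected `igraph` graph with the same nodes and edges.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Assemble the predicted network from gold positives and passed predictions
#'
#' Union of the gold-standard positive edges and the predictions that passed
#' the likelihood-ratio cutoff. Duplicate edges collapse to one, keeping the
#' maximum composite LR and provenance `"both"`.
#'
#' @param gsp Data frame of gold-positive pairs (columns `a`, `b`).
#' @param predictions Prediction data frame from [predict_network()]; rows
#'   with `passed == FALSE` are dropped if a `passed` column is present.
#' @return A `ppi_network` with edge provenance `"gold"`, `"predicted"` or
#'   `"both"`.
#' @export
assemble_network <- function(gsp, predictions) {
  if (!is.null(predictions$passed)) {
    predictions <- predictions[predictions$passed, , drop = FALSE]
  }
  gold_keys <- if (nrow(gsp)) pair_key(gsp$a, gsp$b) else character()
  pred_keys <- if (nrow(predictions)) pair_key(predictions$a, predictions$b) else character()
  gold <- data.frame(a = gsp$a, b = gsp$b, lr = NA_real_,
                     provenance = ifelse(gold_keys %in% pred_keys, "both", "gold"),
                     stringsAsFactors = FALSE)
  lr <- if (is.null(predictions$composite_lr)) rep(NA_real_, nrow(predictions)) else predictions$composite_lr
  pred <- data.frame(a = predictions$a, b = predictions$b, lr = lr,
                     provenance = rep("predicted", nrow(predictions)),
                     stringsAsFactors = FALSE)
  # keep prediction rows first so duplicated edges retain the scored copy,
  # then restore the "both" tag from the gold table
  both <- pred_keys %in% gold_keys
  pred$provenance[both] <- "both"
  all_edges <- rbind(pred, gold)
  ppi_network(all_edges)
}

#' Per-node degree of a PPI network
#'
#' Degree is the number of incident edges; on a simple graph this equals the
#' number of interacting partner proteins.
#'
#' @param net A `ppi_network`.
#' @return Named integer vector over all nodes (isolated nodes have 0).
#' @export
ppi_degree <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  g <- as_igraph(net)
  deg <- igraph::degree(g, loops = FALSE)
  out <- as.integer(deg)
  names(out) <- igraph::V(g)$name
  out[net$nodes$node]
}

#' Extract the neighborhood sub-network around seed proteins
#'
#' Returns the sub-graph induced on the seed proteins plus their direct
#' neighbors (all edges among that node set). Seeds present in the network
#' but isolated are retained as nodes; seeds absent from the network are
#' dropped, and it is an error if none is present.
#'
#' @param net A `ppi_network`.
#' @param seeds Character vector of seed (e.g. known apoptotic) proteins.
#' @return A `ppi_network`; its node table gains a logical `is_seed` column.
#' @export
extract_subnetwork <- function(net, seeds) {
  stopifnot(inherits(net, "ppi_network"), length(seeds) > 0)
  seeds <- unique(as.character(seeds))
  present <- intersect(seeds, net$nodes$node)
  if (!length(present)) stop("no seed protein is present in the network")
  touch <- net$edges$a %in% present | net$edges$b %in% present
  keep <- union(present, c(net$edges$a[touch], net$edges$b[touch]))
  sub_edges <- net$edges[net$edges$a %in% keep & net$edges$b %in% keep, , drop = FALSE]
  out <- ppi_network(sub_edges, nodes = keep)
  out$nodes$is_seed <- out$nodes$node %in% present
  out
}

#' Identify hub proteins under the four-criteria standard
#'
#' Evaluates, per node: (1) degree at or above a cutoff (global default 300;
#' a sub-network analysis conventionally uses 30); (2) number of edges to
#' known apoptotic proteins at or above a cutoff (default 300; 200 is the
#' conventional novel-hub standard); (3) membership in the network's dense
#' area, formalized as the k-core with `k = dense_k` (default 3); (4)
#' differential expression under apoptotic stress (status `"up"` or
#' `"down"`). The hub verdict is the conjunction of the criteria named in
#' `criteria`; each criterion can be toggled independently. All thresholds
#' use `>=` semantics.
#'
#' @param net A `ppi_network`.
#' @param apoptotic Character vector of known apoptotic proteins (used by
#'   criterion 2).
#' @param de_status Optional named character vector (`"up"`, `"down"`,
#'   `"none"`) per gene/protein; missing nodes count as `"none"`.
#' @param degree_cutoff Criterion-1 threshold (default 300).
#' @param apoptotic_partner_cutoff Criterion-2 threshold (default 300).
#' @param dense_k Coreness threshold defining the dense area (default 3).
#' @param criteria Character subset of
#'   `c("degree", "apoptotic", "dense", "de")` to enforce; default the first
#'   three (differential expression is typically layered on afterwards).
#' @return Object of class `hub_report`: a data frame with per-node degree,
#'   apoptotic partner count, dense-area membership, DE status, the four
#'   criterion verdicts and the conjunction `is_hub`.
#' @export
identify_hubs <- function(net, apoptotic = character(), de_status = NULL,
                          degree_cutoff = 300, apoptotic_partner_cutoff = 300,
                          dense_k = 3,
                          criteria = c("degree", "apoptotic", "dense")) {
  stopifnot(inherits(net, "ppi_network"),
            degree_cutoff >= 0, apoptotic_partner_cutoff >= 0, dense_k >= 0)
  criteria <- match.arg(criteria, c("degree", "apoptotic", "dense", "de"),
                        several.ok = TRUE)
  nodes <- net$nodes$node
  deg <- ppi_degree(net)
  apoptotic <- unique(as.character(apoptotic))
  # partners in the apoptotic set, counted over incident edges
  ap_count <- integer(length(nodes))
  names(ap_count) <- nodes
  if (nrow(net$edges)) {
    ea <- net$edges$a
    eb <- net$edges$b
    ta <- table(factor(ea[eb %in% apoptotic], levels = nodes))
    tb <- table(factor(eb[ea %in% apoptotic], levels = nodes))
    ap_count <- as.integer(ta + tb)
    names(ap_count) <- nodes
  }
  g <- as_igraph(net)
  core <- igraph::coreness(g)
  dense <- core[nodes] >= dense_k
  de <- rep("none", length(nodes))
  if (!is.null(de_status)) {
    hit <- match(nodes, names(de_status))
    de[!is.na(hit)] <- as.character(de_status)[hit[!is.na(hit)]]
  }
  rep_df <- data.frame(
    node = nodes,
    degree = unname(deg[nodes]),
    apoptotic_partners = unname(ap_count[nodes]),
    dense_area = unname(dense),
    de_status = de,
    crit_degree = unname(deg[nodes]) >= degree_cutoff,
    crit_apoptotic = unname(ap_count[nodes]) >= apoptotic_partner_cutoff,
    crit_dense = unname(dense),
    crit_de = de %in% c("up", "down"),
    stringsAsFactors = FALSE
  )
  verdict <- rep(TRUE, nrow(rep_df))
  if ("degree" %in% criteria) verdict <- verdict & rep_df$crit_degree
  if ("apoptotic" %in% criteria) verdict <- verdict & rep_df$crit_apoptotic
  if ("dense" %in% criteria) verdict <- verdict & rep_df$crit_dense
  if ("de" %in% criteria) verdict <- verdict & rep_df$crit_de
  rep_df$is_hub <- verdict
  attr(rep_df, "criteria") <- criteria
  attr(rep_df, "cutoffs") <- c(degree = degree_cutoff,
                               apoptotic = apoptotic_partner_cutoff,
                               dense_k = dense_k)
  class(rep_df) <- c("hub_report", "data.frame")
  rep_df
}

#' @export
print.hub_report <- function(x, ...) {
  cat("Hub report:", nrow(x), "nodes,", sum(x$is_hub), "hubs under criteria {",
      paste(attr(x, "criteria"), collapse = ", "), "}\n")
  if (any(x$is_hub)) {
    print.data.frame(x[x$is_hub, c("node", "degree", "apoptotic_partners",
                                   "dense_area", "de_status")],
                     row.names = FALSE)
  }
  invisible(x)
}

#' Write a network's edges as a SIF file
#'
#' Simple interaction format: `a <TAB> interaction-type <TAB> b`, one edge
#' per line, for use in external graph viewers.
#'
#' @param net A `ppi_network`.
#' @param path Output file path.
#' @param type Interaction type label (default `"pp"`).
#' @return Invisibly, the path.
#' @export
write_sif <- function(net, path, type = "pp") {
  stopifnot(inherits(net, "ppi_network"))
  lines <- sprintf("%s\t%s\t%s", net$edges$a, type, net$edges$b)
  writeLines(lines, path)
  invisible(path)
}
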