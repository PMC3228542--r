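#' Build an annotated network view of scored interactions
#'
#' Nodes are proteins, edges are interactions. Node attributes mirror the
#' network-rendering semantics of the search interface: `partner_count`
#' (node size is proportional to the number of interaction partners),
#' `disease_flag` (protein implicated in an OMIM-registered disease),
#' `drug_target_flag` (protein targeted by an approved drug) and
#' `structure_flag` (protein occurs in at least one interaction with a
#' solved complex structure). Edge attributes carry the all-attribute
#' druggability `score`, its display `band` colour, and
#' `complex_structure_flag` (thick-line semantics: the complex structure
#' of the interaction has been solved).
#'
#' @param records PPI attribute table (deduplicated; edges are its
#'   canonical pairs).
#' @param results Optional score source: a wide table keyed by `ppi` with
#'   an `all` column, or a [druggability()] object.
#' @param store Optional [annotation_store()] for the disease and
#'   drug-target flags.
#' @return An [igraph::graph] with the node and edge attributes above.
#' @export
network_view <- function(records, results = NULL, store = NULL) {
  records <- dedupe_ppis(records)
  g <- igraph::graph_from_data_frame(
    records[, c("protein_a", "protein_b"), drop = FALSE],
    directed = FALSE)
  nodes <- igraph::V(g)$name

  partner_count <- vapply(nodes, function(p) {
    partners <- c(records$protein_b[records$protein_a == p],
                  records$protein_a[records$protein_b == p])
    length(unique(partners))
  }, integer(1))
  igraph::V(g)$partner_count <- partner_count

  if (!is.null(store)) {
    igraph::V(g)$disease_flag <- vapply(nodes, function(p)
      length(store_lookup(store, p, "diseases")) > 0, logical(1))
    igraph::V(g)$drug_target_flag <- vapply(nodes, function(p)
      length(store_lookup(store, p, "drugs")) > 0, logical(1))
  } else {
    igraph::V(g)$disease_flag <- rep(FALSE, length(nodes))
    igraph::V(g)$drug_target_flag <- rep(FALSE, length(nodes))
  }

  solved <- if ("pdb_entry" %in% names(records)) {
    !is.na(records$pdb_entry)
  } else {
    rep(FALSE, nrow(records))
  }
  solved_proteins <- unique(c(records$protein_a[solved],
                              records$protein_b[solved]))
  igraph::V(g)$structure_flag <- nodes %in% solved_proteins

  # edges are created in record order by graph_from_data_frame
  igraph::E(g)$pair_key <- records$pair_key
  igraph::E(g)$complex_structure_flag <- solved
  if (!is.null(results)) {
    res <- results_table(results)
    score_col <- if ("all" %in% names(res)) "all" else
      setdiff(names(res), "ppi")[1]
    s <- res[[score_col]][match(records$pair_key, res$ppi)]
  } else {
    s <- rep(NA_real_, nrow(records))
  }
  igraph::E(g)$score <- s
  igraph::E(g)$band <- classify_band(s)
  g
}

#' Export an annotated interaction network to file
#'
#' Serializes the [network_view()] graph as GraphML (lossless round-trip
#' of node and edge attributes), as a simple SIF interaction file
#' (`protein_a pp protein_b`), or as a tab-separated edge list with the
#' edge attributes as columns.
#'
#' @inheritParams network_view
#' @param path Output file.
#' @param format `"graphml"`, `"sif"` or `"edgelist"`.
#' @return The graph, invisibly.
#' @export
export_network <- function(records, path, results = NULL, store = NULL,
                           format = c("graphml", "sif", "edgelist")) {
  format <- match.arg(format)
  g <- network_view(records, results = results, store = store)
  if (format == "graphml") {
    # flag attributes as 0/1 so GraphML round-trips them numerically
    for (at in c("disease_flag", "drug_target_flag", "structure_flag")) {
      g <- igraph::set_vertex_attr(g, at,
                                   value = as.integer(
                                     igraph::vertex_attr(g, at)))
    }
    g <- igraph::set_edge_attr(g, "complex_structure_flag",
                               value = as.integer(
                                 igraph::E(g)$complex_structure_flag))
    tryCatch(igraph::write_graph(g, path, format = "graphml"),
             error = function(e) {
               stop("failed to write GraphML to '", path, "': ",
                    conditionMessage(e), call. = FALSE)
             })
  } else if (format == "sif") {
    ends <- igraph::as_edgelist(g)
    lines <- if (nrow(ends)) paste(ends[, 1], "pp", ends[, 2]) else
      character(0)
    tryCatch(writeLines(lines, path),
             error = function(e) {
               stop("failed to write SIF to '", path, "': ",
                    conditionMessage(e), call. = FALSE)
             })
  } else {
    ends <- igraph::as_edgelist(g)
    df <- data.frame(protein_a = ends[, 1], protein_b = ends[, 2],
                     pair_key = igraph::E(g)$pair_key,
                     score = igraph::E(g)$score,
                     band = igraph::E(g)$band,
                     complex_structure_flag =
                       igraph::E(g)$complex_structure_flag,
                     stringsAsFactors = FALSE)
    tryCatch(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                row.names = FALSE, na = "NA"),
             error = function(e) {
               stop("failed to write edge list to '", path, "': ",
                    conditionMessage(e), call. = FALSE)
             })
  }
  invisible(g)
}
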