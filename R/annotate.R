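#' Protein annotation store
#'
#' Protein-keyed maps feeding attribute derivation: OMIM disease
#' identifiers, biological pathway names, GO terms, gene-expression body
#' sites, FDA-approved drugs, experimentally assayed chemicals and paralogs
#' per protein, plus curated instance counts per sequence motif. Lookups
#' for unknown proteins return the empty set, never an error -- an
#' unannotated protein simply contributes zero counts.
#'
#' @param diseases,pathways,go_terms,expression_sites,drugs,chemicals,paralogs
#'   Named lists mapping protein identifier to a character vector of values
#'   (or two-column data frames in long `(protein, value)` format).
#' @param motif_instances Named integer vector: curated instance count per
#'   motif identifier.
#' @return A list of class `"annotation_store"`.
#' @export
annotation_store <- function(diseases = list(), pathways = list(),
                             go_terms = list(), expression_sites = list(),
                             drugs = list(), chemicals = list(),
                             paralogs = list(),
                             motif_instances = integer(0)) {
  as_map <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(ncol(x) >= 2)
      x <- split(as.character(x[[2]]), as.character(x[[1]]))
    }
    lapply(x, function(v) unique(as.character(v)))
  }
  structure(list(diseases = as_map(diseases),
                 pathways = as_map(pathways),
                 go_terms = as_map(go_terms),
                 expression_sites = as_map(expression_sites),
                 drugs = as_map(drugs),
                 chemicals = as_map(chemicals),
                 paralogs = as_map(paralogs),
                 motif_instances = motif_instances),
            class = "annotation_store")
}

#' @export
print.annotation_store <- function(x, ...) {
  facets <- setdiff(names(x), "motif_instances")
  cat("Annotation store\n")
  for (f in facets) cat(sprintf("  %s: %d proteins\n", f, length(x[[f]])))
  cat(sprintf("  motif_instances: %d motifs\n", length(x$motif_instances)))
  invisible(x)
}

#' Look up one annotation facet for a protein
#'
#' @param store An [annotation_store()].
#' @param protein Protein identifier.
#' @param facet Facet name, e.g. `"pathways"`.
#' @return Character vector of values; empty for unknown proteins.
#' @export
store_lookup <- function(store, protein, facet) {
  stopifnot(inherits(store, "annotation_store"))
  if (!facet %in% setdiff(names(store), "motif_instances")) {
    stop("unknown annotation facet: ", facet, call. = FALSE)
  }
  v <- store[[facet]][[protein]]
  if (is.null(v)) character(0) else v
}

#' Read a long-format annotation table
#'
#' Tab-separated two-column `(protein, value)` text, one row per
#' annotation, as exported from the source databases.
#'
#' @param path File path.
#' @return Named list mapping protein to its set of values, suitable for
#'   [annotation_store()].
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  split(as.character(df[[2]]), as.character(df[[1]]))
}

#' OMIM disease co-annotation score
#'
#' Scored 1 if both interacting proteins are implicated in OMIM-registered
#' diseases -- not necessarily the same disease -- and 0 if only one, or
#' neither, is implicated.
#'
#' @param diseases_a,diseases_b Character vectors of disease identifiers
#'   for the two proteins (empty when unannotated).
#' @return 0 or 1.
#' @export
omim_score <- function(diseases_a, diseases_b) {
  as.integer(length(diseases_a) > 0 && length(diseases_b) > 0)
}

#' PPI network
#'
#' An undirected interaction network over protein nodes; self-loops are
#' permitted and an edge is identified by its canonical pair key.
#'
#' @param edges Data frame with columns `protein_a`, `protein_b` (an edge
#'   list), or a character vector of canonical pair keys.
#' @param nodes Optional additional isolated nodes.
#' @return A list of class `"ppi_network"` with elements `nodes` (character)
#'   and `edges` (character keys).
#' @export
ppi_network <- function(edges, nodes = character(0)) {
  if (is.character(edges)) {
    parts <- strsplit(edges, PAIR_SEP, fixed = TRUE)
    stopifnot(all(lengths(parts) == 2L))
    edges <- data.frame(protein_a = vapply(parts, `[`, "", 1L),
                        protein_b = vapply(parts, `[`, "", 2L),
                        stringsAsFactors = FALSE)
  }
  keys <- unique(canonicalize_pair(edges$protein_a, edges$protein_b))
  nodes <- sort(unique(c(edges$protein_a, edges$protein_b,
                         as.character(nodes))))
  structure(list(nodes = nodes, edges = sort(keys)), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("PPI network:", length(x$nodes), "proteins,",
      length(x$edges), "interactions\n")
  invisible(x)
}

network_edge_ends <- function(network) {
  parts <- strsplit(network$edges, PAIR_SEP, fixed = TRUE)
  data.frame(a = vapply(parts, `[`, "", 1L),
             b = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Number of interaction partners of a protein
#'
#' Counts the distinct partner proteins of `p` in the network (the "hub
#' degree" attribute). A self-interaction contributes one partner: the
#' protein is its own partner once. Unknown proteins have degree 0.
#'
#' @param network A [ppi_network()].
#' @param p Protein identifier.
#' @return Non-negative integer count.
#' @export
ppi_degree <- function(network, p) {
  stopifnot(inherits(network, "ppi_network"))
  ends <- network_edge_ends(network)
  partners <- c(ends$b[ends$a == p], ends$a[ends$b == p])
  length(unique(partners))
}

#' Count annotations of a protein in one facet
#'
#' Cardinality of a protein's pathway, approved-drug, assayed-chemical or
#' paralog set after set-union across sources; 0 for unknown proteins.
#'
#' @param store An [annotation_store()].
#' @param p Protein identifier.
#' @param facet One of `"pathways"`, `"drugs"`, `"chemicals"`, `"paralogs"`.
#' @return Non-negative integer count.
#' @export
count_annotations <- function(store, p, facet) {
  facet <- match.arg(facet, c("pathways", "drugs", "chemicals", "paralogs"))
  length(store_lookup(store, p, facet))
}

jaccard_index <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (length(a) == 0 || length(b) == 0) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

#' GO-term identity score between two interacting proteins
#'
#' Measures how similar in annotated biological function the two partners
#' of a PPI are. The default formula is the Jaccard index over the two GO
#' term sets: 1 for identical non-empty sets, 0 for disjoint sets or when
#' either protein has no GO annotation. An alternative set-similarity
#' function can be supplied via `method`.
#'
#' @param terms_a,terms_b Character vectors of GO term identifiers.
#' @param method Function of two sets returning a similarity in `[0, 1]`;
#'   defaults to the Jaccard index.
#' @return Score in `[0, 1]`, symmetric in its arguments.
#' @export
go_identity_score <- function(terms_a, terms_b, method = jaccard_index) {
  method(terms_a, terms_b)
}

#' Expression-profile similarity between two genes
#'
#' Genes are compared by the sets of body sites in which they are expressed
#' (binary expressed/not-expressed profiles over a shared site vocabulary).
#' The default score is the Jaccard index of the two expressed-site sets;
#' identical non-empty profiles score 1, disjoint profiles 0.
#'
#' @param sites_a,sites_b Character vectors of body-site labels in which
#'   the two genes are expressed.
#' @param vocabulary Optional character vector of admissible site labels;
#'   profiles containing labels outside it are a validation error.
#' @param method Set-similarity function, defaults to the Jaccard index.
#' @return Score in `[0, 1]`, symmetric in its arguments.
#' @export
expression_similarity <- function(sites_a, sites_b, vocabulary = NULL,
                                  method = jaccard_index) {
  if (!is.null(vocabulary)) {
    bad <- setdiff(unique(c(sites_a, sites_b)), vocabulary)
    if (length(bad)) {
      stop("expression sites outside the shared vocabulary: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  method(sites_a, sites_b)
}

#' Is a sequence motif eligible for profile construction?
#'
#' A motif qualifies for a hidden-Markov-model profile only when its number
#' of curated instances is at least 2 (a single instance cannot be
#' aligned).
#'
#' @param instance_count Non-negative integer count of curated instances.
#' @return Logical.
#' @export
motif_profile_eligible <- function(instance_count) {
  stopifnot(all(instance_count >= 0))
  instance_count >= 2
}

#' Read sequence-similarity hits in tabular alignment format
#'
#' Consumes 12-column tab-separated alignment output (query id, subject id,
#' percent identity, alignment length, mismatches, gap opens, query
#' start/end, subject start/end, e-value, bit score). Subject identifiers
#' are parsed as `<pdb_entry>_<chain>`.
#'
#' @param path File path.
#' @return Data frame with columns `protein`, `pdb_entry`, `chain`,
#'   `percent_identity`.
#' @export
read_similarity_hits <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3) {
    stop("similarity hit table must have >= 3 tab-separated columns",
         call. = FALSE)
  }
  subject <- as.character(df[[2]])
  m <- regmatches(subject, regexec("^(.+)_([^_]+)$", subject))
  bad <- lengths(m) != 3L
  if (any(bad)) {
    stop("subject ids must look like <pdb_entry>_<chain>: ",
         paste(utils::head(subject[bad]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(protein = as.character(df[[1]]),
                    pdb_entry = vapply(m, `[`, "", 2L),
                    chain = vapply(m, `[`, "", 3L),
                    percent_identity = as.numeric(df[[3]]),
                    stringsAsFactors = FALSE)
  if (any(out$percent_identity < 0 | out$percent_identity > 100)) {
    stop("percent identity must lie in [0, 100]", call. = FALSE)
  }
  out
}

#' Read a chain-contact table
#'
#' Tab-separated `(pdb_entry, chain_x, chain_y)` rows listing unordered
#' pairs of polypeptide chains in physical contact within a PDB entry
#' (interface information). The relation is symmetric in the two chains.
#'
#' @param path File path.
#' @return Data frame with columns `pdb_entry`, `chain_x`, `chain_y`.
#' @export
read_contact_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("pdb_entry", "chain_x", "chain_y")
  if (!all(req %in% names(df))) {
    stop("contact table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  df
}

chains_in_contact <- function(contacts, entry, cx, cy) {
  any(contacts$pdb_entry == entry &
        ((contacts$chain_x == cx & contacts$chain_y == cy) |
           (contacts$chain_x == cy & contacts$chain_y == cx)))
}

#' Map a PPI to a solved complex structure
#'
#' A PPI is considered to have a solved tertiary structure when both
#' proteins hit distinct polypeptide chains of the same PDB entry with
#' sequence identity >= 80%, and those two chains are in physical contact
#' in that entry. If several entries qualify, the one maximizing the
#' smaller of the two identities is chosen, ties broken by
#' lexicographically smallest entry id, then chain pair.
#'
#' @param a,b Protein identifiers (a self-pair `a == b` is legal; the two
#'   chains must still be distinct, as in a homodimer structure).
#' @param hits Similarity hit table ([read_similarity_hits()]).
#' @param contacts Chain-contact table ([read_contact_table()]).
#' @return A one-row data frame `pdb_entry`, `chain_a`, `chain_b`,
#'   `identity_a`, `identity_b`, or `NULL` when no entry qualifies.
#' @export
map_ppi_to_structure <- function(a, b, hits, contacts) {
  ha <- hits[hits$protein == a & hits$percent_identity >= 80, , drop = FALSE]
  hb <- hits[hits$protein == b & hits$percent_identity >= 80, , drop = FALSE]
  if (nrow(ha) == 0 || nrow(hb) == 0) return(NULL)
  cand <- merge(ha, hb, by = "pdb_entry",
                suffixes = c("_a", "_b"))
  cand <- cand[cand$chain_a != cand$chain_b, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  ok <- vapply(seq_len(nrow(cand)), function(i) {
    chains_in_contact(contacts, cand$pdb_entry[i],
                      cand$chain_a[i], cand$chain_b[i])
  }, logical(1))
  cand <- cand[ok, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  min_id <- pmin(cand$percent_identity_a, cand$percent_identity_b)
  ord <- order(-min_id, cand$pdb_entry, cand$chain_a, cand$chain_b)
  best <- cand[ord[1L], , drop = FALSE]
  data.frame(pdb_entry = best$pdb_entry,
             chain_a = best$chain_a, chain_b = best$chain_b,
             identity_a = best$percent_identity_a,
             identity_b = best$percent_identity_b,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Schema of the attributes derived from annotation tables
#'
#' The attribute set emitted by [build_attribute_rows()]: per-pocket
#' structural descriptors; approved-drug and assayed-chemical counts per
#' partner; and the functional block (OMIM co-annotation, network degree
#' per partner, pathway counts, GO-term identity, expression-profile
#' similarity, paralog counts per partner).
#'
#' @param include_chemicals Include the assayed-chemical counts in the
#'   drug/chemical category (default `TRUE`).
#' @return A [attribute_schema()].
#' @export
derived_schema <- function(include_chemicals = TRUE) {
  structural <- c("volume", "accessible_surface_area", "compactness",
                  "planarity", "narrowness", "curvature", "roughness")
  drug <- c("n_drugs_a", "n_drugs_b")
  if (include_chemicals) drug <- c(drug, "n_chemicals_a", "n_chemicals_b")
  functional <- c("omim", "degree_a", "degree_b", "n_pathways_a",
                  "n_pathways_b", "go_identity", "expression_similarity",
                  "n_paralogs_a", "n_paralogs_b")
  attribute_schema(
    name = c(structural, drug, functional),
    category = c(rep("structural", length(structural)),
                 rep("drug_chemical", length(drug)),
                 rep("functional", length(functional))),
    kind = c(rep("continuous", length(structural)),
             rep("count", length(drug)),
             "binary", "count", "count", "count", "count",
             "continuous", "continuous", "count", "count"))
}

#' Derive PPI attribute rows from annotation tables
#'
#' Composes the derivation rules into one attribute row per non-redundant
#' interaction: the functional and drug/chemical attributes are always
#' computed (an unannotated protein contributes zeros), while the structure
#' assignment is attempted via [map_ppi_to_structure()] and left missing
#' when no complex structure qualifies. Pocket-level structural descriptors
#' live in a separate pocket table and are joined at scoring time; the
#' PPI-level structural attribute columns are emitted as `NA`.
#'
#' @param pairs Data frame with columns `protein_a`, `protein_b` and
#'   optionally `species` (defaults to `"human"`).
#' @param store An [annotation_store()].
#' @param network A [ppi_network()] used for the degree attributes.
#' @param hits,contacts Optional structure-mapping inputs; when `NULL`, no
#'   structures are assigned.
#' @param schema Attribute schema to emit; defaults to [derived_schema()].
#' @return A canonical, deduplicated PPI attribute table.
#' @export
build_attribute_rows <- function(pairs, store, network,
                                 hits = NULL, contacts = NULL,
                                 schema = derived_schema()) {
  stopifnot(inherits(store, "annotation_store"),
            inherits(network, "ppi_network"))
  if (!"species" %in% names(pairs)) pairs$species <- "human"
  pairs <- dedupe_ppis(pairs[, c("protein_a", "protein_b", "species")])
  n <- nrow(pairs)
  want <- schema$name

  degree_cache <- new.env(parent = emptyenv())
  deg <- function(p) {
    if (is.null(degree_cache[[p]])) degree_cache[[p]] <- ppi_degree(network, p)
    degree_cache[[p]]
  }

  out <- pairs
  out$pdb_entry <- NA_character_
  out$chain_a <- NA_character_
  out$chain_b <- NA_character_
  out$identity_a <- NA_real_
  out$identity_b <- NA_real_
  for (col in want) out[[col]] <- NA_real_

  for (i in seq_len(n)) {
    a <- pairs$protein_a[i]
    b <- pairs$protein_b[i]
    val <- list(
      omim = omim_score(store_lookup(store, a, "diseases"),
                        store_lookup(store, b, "diseases")),
      degree_a = deg(a), degree_b = deg(b),
      n_pathways_a = count_annotations(store, a, "pathways"),
      n_pathways_b = count_annotations(store, b, "pathways"),
      n_drugs_a = count_annotations(store, a, "drugs"),
      n_drugs_b = count_annotations(store, b, "drugs"),
      n_chemicals_a = count_annotations(store, a, "chemicals"),
      n_chemicals_b = count_annotations(store, b, "chemicals"),
      n_paralogs_a = count_annotations(store, a, "paralogs"),
      n_paralogs_b = count_annotations(store, b, "paralogs"),
      go_identity = go_identity_score(store_lookup(store, a, "go_terms"),
                                      store_lookup(store, b, "go_terms")),
      expression_similarity = expression_similarity(
        store_lookup(store, a, "expression_sites"),
        store_lookup(store, b, "expression_sites")))
    for (col in intersect(names(val), want)) out[[col]][i] <- val[[col]]
    if (!is.null(hits) && !is.null(contacts)) {
      asg <- map_ppi_to_structure(a, b, hits, contacts)
      if (!is.null(asg)) {
        out$pdb_entry[i] <- asg$pdb_entry
        out$chain_a[i] <- asg$chain_a
        out$chain_b[i] <- asg$chain_b
        out$identity_a[i] <- asg$identity_a
        out$identity_b[i] <- asg$identity_b
      }
    }
  }
  canonicalize_ppis(out)
}
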