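# Controlled species vocabulary. Cross-species interactions carry a sorted
# composite label joined by "+", e.g. "HIV+human".
PPI_SPECIES <- c("human", "mouse", "rat", "HIV", "other")

PAIR_SEP <- "/"

#' Canonical key for an unordered protein pair
#'
#' Protein-protein interactions are unordered: (A, B) and (B, A) denote the
#' same interaction, and self-interactions (A, A) are legal. The canonical
#' key orders the two identifiers lexicographically and joins them with
#' `"/"`, so reversed duplicates collapse to one key.
#'
#' @param a,b Character vectors of protein identifiers (recycled to a common
#'   length). Identifiers must be non-empty, non-`NA`, and must not contain
#'   `"/"` (the key separator).
#' @return Character vector of canonical pair keys, e.g. `"GRB2/VAV1"`;
#'   a self-pair yields `"GRB2/GRB2"`.
#' @examples
#' canonicalize_pair("TP53", "MDM2")  # "MDM2/TP53"
#' canonicalize_pair("GRB2", "GRB2")  # self-pair
#' @export
canonicalize_pair <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  check_protein_id(c(a, b))
  swap <- b < a
  key_a <- ifelse(swap, b, a)
  key_b <- ifelse(swap, a, b)
  paste(key_a, key_b, sep = PAIR_SEP)
}

check_protein_id <- function(x) {
  if (any(is.na(x)) || any(!nzchar(x))) {
    stop("protein identifiers must be non-empty and non-NA", call. = FALSE)
  }
  if (any(grepl(PAIR_SEP, x, fixed = TRUE))) {
    stop("protein identifiers must not contain '", PAIR_SEP,
         "' (reserved as the pair-key separator)", call. = FALSE)
  }
  invisible(x)
}

check_species <- function(x) {
  parts <- strsplit(as.character(x), "+", fixed = TRUE)
  bad <- !vapply(parts, function(p) length(p) >= 1 && all(p %in% PPI_SPECIES),
                 logical(1))
  if (any(bad)) {
    stop("unknown species label(s): ", paste(unique(x[bad]), collapse = ", "),
         "; allowed: ", paste(PPI_SPECIES, collapse = ", "),
         " (composites joined by '+')", call. = FALSE)
  }
  invisible(x)
}

#' Composite species label for an interaction
#'
#' A within-species interaction keeps its species label; a cross-species
#' interaction (e.g. a human protein bound by an HIV protein) is labelled
#' with the sorted composite of both species joined by `"+"`.
#'
#' @param species_a,species_b Species labels of the two proteins.
#' @return Character vector of interaction species labels.
#' @examples
#' species_label("human", "HIV")  # "HIV+human"
#' @export
species_label <- function(species_a, species_b) {
  n <- max(length(species_a), length(species_b))
  species_a <- rep_len(as.character(species_a), n)
  species_b <- rep_len(as.character(species_b), n)
  check_species(species_a)
  check_species(species_b)
  mapply(function(x, y) {
    paste(sort(unique(c(x, y))), collapse = "+")
  }, species_a, species_b, USE.NAMES = FALSE)
}

#' Attribute schema for PPI scoring
#'
#' The classifier consumes named numeric attributes, each tagged with the
#' category it belongs to -- `structural` (pocket physicochemistry and
#' shape), `drug_chemical` (drug/assayed-chemical counts) or `functional`
#' (disease, network, pathway, similarity and paralog information) -- and a
#' kind (`continuous`, `count` or `binary`). The active schema decides which
#' columns of an attribute table are features and which assessment modes a
#' record is eligible for.
#'
#' @param name Character vector of unique attribute names.
#' @param category One of `"structural"`, `"drug_chemical"`, `"functional"`
#'   per attribute.
#' @param kind One of `"continuous"`, `"count"`, `"binary"` per attribute.
#' @return A data frame of class `"ppi_schema"` with columns
#'   `name`, `category`, `kind`.
#' @seealso [derived_schema()] for the schema produced by
#'   [build_attribute_rows()], [read_attribute_schema()] for file I/O.
#' @export
attribute_schema <- function(name, category, kind) {
  name <- as.character(name)
  category <- as.character(category)
  kind <- as.character(kind)
  if (anyDuplicated(name)) {
    stop("attribute names must be unique", call. = FALSE)
  }
  if (!all(category %in% c("structural", "drug_chemical", "functional"))) {
    stop("category must be structural, drug_chemical or functional",
         call. = FALSE)
  }
  if (!all(kind %in% c("continuous", "count", "binary"))) {
    stop("kind must be continuous, count or binary", call. = FALSE)
  }
  out <- data.frame(name = name, category = category, kind = kind,
                    stringsAsFactors = FALSE)
  class(out) <- c("ppi_schema", "data.frame")
  out
}

#' @export
print.ppi_schema <- function(x, ...) {
  cat("PPI attribute schema:", nrow(x), "attributes\n")
  tab <- table(x$category)
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
            collapse = "\n"), "\n")
  invisible(x)
}

schema_names <- function(schema, category = NULL) {
  if (is.null(category)) schema$name else schema$name[schema$category %in% category]
}

#' Read or write an attribute schema as JSON
#'
#' The schema file is a JSON array of objects with fields `name`,
#' `category` and `kind`; it round-trips bit-identically.
#'
#' @param path File path.
#' @param schema A [attribute_schema()] object.
#' @return `read_attribute_schema()` returns a `ppi_schema`;
#'   `write_attribute_schema()` returns `path` invisibly.
#' @export
read_attribute_schema <- function(path) {
  x <- jsonlite::fromJSON(path)
  attribute_schema(x$name, x$category, x$kind)
}

#' @rdname read_attribute_schema
#' @export
write_attribute_schema <- function(schema, path) {
  stopifnot(inherits(schema, "ppi_schema"))
  jsonlite::write_json(
    data.frame(name = schema$name, category = schema$category,
               kind = schema$kind, stringsAsFactors = FALSE),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

# Columns of a PPI table that are not attributes.
PPI_ID_COLS <- c("protein_a", "protein_b", "species", "source",
                 "pdb_entry", "chain_a", "chain_b",
                 "identity_a", "identity_b", "pair_key")

# Attribute columns named with paired _a/_b suffixes refer to the first and
# second protein of the pair; canonicalization must swap them when it swaps
# the proteins.
paired_columns <- function(cols) {
  a_cols <- grep("_a$", cols, value = TRUE)
  a_cols <- setdiff(a_cols, PPI_ID_COLS)
  base <- sub("_a$", "", a_cols)
  b_cols <- paste0(base, "_b")
  keep <- b_cols %in% cols
  list(a = a_cols[keep], b = b_cols[keep])
}

#' Put a PPI attribute table into canonical pair order
#'
#' Rows where `protein_b` sorts before `protein_a` have the two proteins
#' swapped, along with the structure chain/identity columns and every paired
#' attribute column (`<x>_a`/`<x>_b`), and a `pair_key` column is (re)built.
#'
#' @param records Data frame with at least `protein_a` and `protein_b`
#'   columns.
#' @return The table with proteins in canonical (lexicographic) order and a
#'   `pair_key` column.
#' @export
canonicalize_ppis <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("protein_a", "protein_b") %in% names(records)))
  if (nrow(records) == 0) {
    records$pair_key <- character(0)
    return(records)
  }
  check_protein_id(c(records$protein_a, records$protein_b))
  swap <- records$protein_b < records$protein_a
  if (any(swap)) {
    pc <- paired_columns(names(records))
    swap_cols_a <- c("protein_a", intersect(c("chain_a", "identity_a"),
                                            names(records)), pc$a)
    swap_cols_b <- c("protein_b", intersect(c("chain_b", "identity_b"),
                                            names(records)), pc$b)
    # align: chain_a<->chain_b etc. positional pairing
    tmp <- records[swap, swap_cols_a, drop = FALSE]
    records[swap, swap_cols_a] <- records[swap, swap_cols_b, drop = FALSE]
    records[swap, swap_cols_b] <- tmp
  }
  records$pair_key <- paste(records$protein_a, records$protein_b,
                            sep = PAIR_SEP)
  records
}

#' Collapse a PPI table to non-redundant interactions
#'
#' Reversed duplicates and exact repeats of the same unordered pair are
#' merged into a single record per canonical pair key. When duplicate
#' records disagree on an attribute, the first non-missing value wins; if
#' several non-missing values conflict, rows are ordered lexicographically
#' by their `source` column (input order when there is none), the first
#' value is kept and a warning is issued. Output rows are sorted by pair
#' key, so the result is deterministic.
#'
#' @param records A PPI attribute table (see [read_ppi_table()]).
#' @return The deduplicated table, one row per canonical pair, sorted by
#'   `pair_key`.
#' @export
dedupe_ppis <- function(records) {
  records <- canonicalize_ppis(records)
  if (nrow(records) <= 1) {
    return(records[order(records$pair_key), , drop = FALSE])
  }
  ord <- if ("source" %in% names(records)) {
    order(records$pair_key, records$source)
  } else {
    order(records$pair_key)
  }
  records <- records[ord, , drop = FALSE]
  keys <- records$pair_key
  first <- !duplicated(keys)
  out <- records[first, , drop = FALSE]
  if (all(first)) {
    rownames(out) <- NULL
    return(out)
  }
  value_cols <- setdiff(names(records), "pair_key")
  groups <- split(seq_len(nrow(records)), match(keys, keys[first]))
  conflicts <- character(0)
  for (gi in which(lengths(groups) > 1L)) {
    idx <- groups[[gi]]
    for (col in value_cols) {
      v <- records[[col]][idx]
      present <- !is.na(v)
      if (!any(present)) next
      vp <- v[present]
      if (length(unique(vp)) > 1L) {
        conflicts <- c(conflicts,
                       sprintf("%s [%s]", keys[idx[1]], col))
      }
      out[[col]][gi] <- vp[1L]
    }
  }
  if (length(conflicts)) {
    warning("conflicting duplicate attribute values; kept first after ",
            "sorting sources: ", paste(conflicts, collapse = ", "),
            call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Validate a PPI table against an attribute schema
#'
#' Report-only check: flags attribute columns absent from the schema, type
#' violations (negative counts, binary values outside \{0, 1\}, non-numeric
#' attribute columns), and determines which of the four assessment modes
#' each record is eligible for. A record is eligible for a single-category
#' mode when every attribute of that category is present (non-missing);
#' `structural` additionally requires a structure assignment and at least
#' one pocket; `all` requires eligibility for all three categories.
#'
#' @param records PPI attribute table.
#' @param schema [attribute_schema()].
#' @param pockets Optional pocket table (see [read_pocket_table()]) used to
#'   decide structural eligibility.
#' @return A list of class `"ppi_validation"` with elements
#'   `unknown_attributes` (character), `type_violations` (data frame with
#'   `pair_key`, `attribute`, `problem`), and `eligible_modes` (named list,
#'   per pair key, of mode names).
#' @export
validate_against_schema <- function(records, schema, pockets = NULL) {
  stopifnot(inherits(schema, "ppi_schema"), nrow(schema) > 0)
  records <- canonicalize_ppis(records)
  if (!is.null(pockets)) pockets <- canonicalize_ppis(pockets)
  attr_cols <- setdiff(names(records), PPI_ID_COLS)
  unknown <- setdiff(attr_cols, schema$name)
  known <- intersect(attr_cols, schema$name)

  viol <- list()
  for (col in known) {
    kind <- schema$kind[match(col, schema$name)]
    v <- records[[col]]
    if (!is.numeric(v) && !is.logical(v)) {
      viol[[length(viol) + 1L]] <- data.frame(
        pair_key = records$pair_key, attribute = col,
        problem = "non-numeric", stringsAsFactors = FALSE)
      next
    }
    v <- as.numeric(v)
    bad <- switch(kind,
      count = which(!is.na(v) & (v < 0 | v != floor(v))),
      binary = which(!is.na(v) & !(v %in% c(0, 1))),
      integer(0))
    if (length(bad)) {
      viol[[length(viol) + 1L]] <- data.frame(
        pair_key = records$pair_key[bad], attribute = col,
        problem = paste("invalid", kind), stringsAsFactors = FALSE)
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(pair_key = character(0), attribute = character(0),
               problem = character(0), stringsAsFactors = FALSE)

  eligible <- lapply(seq_len(nrow(records)), function(i) {
    eligible_modes_row(records[i, , drop = FALSE], schema, pockets)
  })
  names(eligible) <- records$pair_key

  structure(list(unknown_attributes = unknown,
                 type_violations = violations,
                 eligible_modes = eligible),
            class = "ppi_validation")
}

category_complete <- function(record, schema, category) {
  cols <- schema_names(schema, category)
  cols_here <- intersect(cols, names(record))
  length(cols) > 0 && length(cols_here) == length(cols) &&
    all(!is.na(unlist(record[1, cols_here])))
}

has_structure <- function(record, pockets = NULL) {
  ok <- "pdb_entry" %in% names(record) && !is.na(record$pdb_entry[1])
  if (!ok) return(FALSE)
  if (is.null(pockets)) return(TRUE)
  any(pockets$pair_key == record$pair_key[1])
}

eligible_modes_row <- function(record, schema, pockets = NULL) {
  modes <- character(0)
  struct_ok <- has_structure(record, pockets)
  if (struct_ok) modes <- c(modes, "structural")
  if (category_complete(record, schema, "drug_chemical"))
    modes <- c(modes, "drug_chemical")
  if (category_complete(record, schema, "functional"))
    modes <- c(modes, "functional")
  if (all(c("structural", "drug_chemical", "functional") %in% modes))
    modes <- c(modes, "all")
  modes
}

#' @export
print.ppi_validation <- function(x, ...) {
  cat("PPI table validation\n")
  cat("  unknown attributes:",
      if (length(x$unknown_attributes))
        paste(x$unknown_attributes, collapse = ", ") else "none", "\n")
  cat("  type violations:", nrow(x$type_violations), "\n")
  tab <- table(unlist(x$eligible_modes))
  if (length(tab)) {
    cat("  mode eligibility:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Read and write PPI attribute tables
#'
#' Tab-separated UTF-8 with a header row; columns `protein_a`, `protein_b`,
#' `species`, then one column per attribute (plus optional `source` and
#' structure columns `pdb_entry`, `chain_a`, `chain_b`, `identity_a`,
#' `identity_b`). Missing values are encoded as `NA`: an absent attribute is
#' semantically distinct from a zero count. Tables are canonicalized on
#' read.
#'
#' @param path File path.
#' @param records Data frame to write.
#' @return `read_ppi_table()` returns the canonicalized data frame;
#'   `write_ppi_table()` returns `path` invisibly.
#' @export
read_ppi_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  req <- c("protein_a", "protein_b", "species")
  if (!all(req %in% names(df))) {
    stop("PPI table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  check_species(df$species)
  # attributes are stored as double precision; MISSING stays NA
  for (col in setdiff(names(df), PPI_ID_COLS)) {
    if (is.numeric(df[[col]]) || is.logical(df[[col]])) {
      df[[col]] <- as.numeric(df[[col]])
    }
  }
  canonicalize_ppis(df)
}

#' @rdname read_ppi_table
#' @export
write_ppi_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a pocket descriptor table
#'
#' One row per candidate ligand-binding pocket detected on a PPI interface,
#' keyed by `protein_a`, `protein_b`, `pdb_entry`, `chain`, `pocket_id`,
#' followed by structural descriptor columns (volume in cubic Angstroms,
#' accessible surface area in square Angstroms, compactness, planarity,
#' narrowness, curvature, roughness, amino-acid composition fractions).
#' Volume and area must be non-negative; composition fractions, when
#' present as columns prefixed `aa_`, must sum to 1 per pocket (tolerance
#' 1e-6).
#'
#' @param path File path.
#' @param pockets Data frame to write.
#' @return Data frame with a `pair_key` column added.
#' @export
read_pocket_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  req <- c("protein_a", "protein_b", "pdb_entry", "chain", "pocket_id")
  if (!all(req %in% names(df))) {
    stop("pocket table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  validate_pockets(canonicalize_ppis(df))
}

#' @rdname read_pocket_table
#' @export
write_pocket_table <- function(pockets, path) {
  utils::write.table(pockets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

validate_pockets <- function(pockets) {
  for (col in intersect(c("volume", "accessible_surface_area"),
                        names(pockets))) {
    if (any(!is.na(pockets[[col]]) & pockets[[col]] < 0)) {
      stop("pocket ", col, " must be non-negative", call. = FALSE)
    }
  }
  aa_cols <- grep("^aa_", names(pockets), value = TRUE)
  if (length(aa_cols)) {
    sums <- rowSums(pockets[, aa_cols, drop = FALSE])
    if (any(!is.na(sums) & abs(sums - 1) > 1e-6)) {
      stop("amino-acid composition fractions must sum to 1 per pocket",
           call. = FALSE)
    }
  }
  pockets
}
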