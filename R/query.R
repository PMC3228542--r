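#' Search criteria over scored interaction records
#'
#' Criteria combine conjunctively: a record must satisfy every criterion
#' that is set. Keyword fields (`pathway_keyword`, `protein`, `disease`,
#' `go_term`, `drug`) are matched as case-insensitive substrings over the
#' relevant names/labels, quoted-phrase style. The expression criterion
#' requires both genes of the interaction to be expressed at the named
#' body site.
#'
#' @param species Interaction species label (exact match, e.g. `"human"`).
#' @param pathway_keyword Substring to find in the pathway names of either
#'   partner.
#' @param expression_site Body-site label at which both genes must be
#'   expressed.
#' @param structure_solved If `TRUE`, require a mapped complex structure;
#'   if `FALSE`, require none; `NULL` leaves it unconstrained.
#' @param protein Substring matched against either protein identifier.
#' @param disease,go_term,drug Substrings matched against either partner's
#'   disease / GO-term / approved-drug annotations.
#' @param min_score Named numeric vector of per-mode score thresholds,
#'   e.g. `c(all = 0.9)`; requires a results table when filtering.
#' @return A list of class `"search_criteria"`.
#' @export
search_criteria <- function(species = NULL, pathway_keyword = NULL,
                            expression_site = NULL, structure_solved = NULL,
                            protein = NULL, disease = NULL, go_term = NULL,
                            drug = NULL, min_score = NULL) {
  crit <- list(species = species, pathway_keyword = pathway_keyword,
               expression_site = expression_site,
               structure_solved = structure_solved, protein = protein,
               disease = disease, go_term = go_term, drug = drug,
               min_score = min_score)
  if (all(vapply(crit, is.null, logical(1)))) {
    stop("at least one search criterion must be set", call. = FALSE)
  }
  if (!is.null(min_score)) {
    stopifnot(is.numeric(min_score), !is.null(names(min_score)),
              all(names(min_score) %in%
                    c("structural", "drug_chemical", "functional", "all")),
              all(min_score >= 0 & min_score <= 1))
  }
  structure(crit, class = "search_criteria")
}

has_keyword <- function(values, keyword) {
  any(grepl(keyword, values, ignore.case = TRUE, fixed = FALSE))
}

#' Filter PPI records by search criteria
#'
#' Evaluates the conjunction of all set criteria against each record,
#' consulting the annotation store for pathway, expression, disease, GO
#' and drug criteria and a results table for score thresholds. Output is
#' sorted by pair key, so filtering is deterministic and order-independent.
#'
#' @param records PPI attribute table.
#' @param store An [annotation_store()] (required for annotation-backed
#'   criteria).
#' @param criteria A [search_criteria()].
#' @param results Optional wide score table (see [render_report()]) keyed
#'   by `ppi`, required when `criteria$min_score` is set.
#' @return The subset of `records` satisfying all criteria, sorted by
#'   `pair_key`.
#' @export
filter_records <- function(records, store = NULL, criteria,
                           results = NULL) {
  stopifnot(inherits(criteria, "search_criteria"))
  records <- canonicalize_ppis(records)
  if (nrow(records) == 0) return(records)
  needs_store <- !vapply(criteria[c("pathway_keyword", "expression_site",
                                    "disease", "go_term", "drug")],
                         is.null, logical(1))
  if (any(needs_store) && is.null(store)) {
    stop("these criteria require an annotation store: ",
         paste(names(needs_store)[needs_store], collapse = ", "),
         call. = FALSE)
  }
  keep <- rep(TRUE, nrow(records))
  if (!is.null(criteria$species)) {
    keep <- keep & records$species == criteria$species
  }
  if (!is.null(criteria$structure_solved)) {
    solved <- "pdb_entry" %in% names(records) & !is.na(records$pdb_entry)
    keep <- keep & (solved == criteria$structure_solved)
  }
  if (!is.null(criteria$protein)) {
    keep <- keep & (grepl(criteria$protein, records$protein_a,
                          ignore.case = TRUE) |
                      grepl(criteria$protein, records$protein_b,
                            ignore.case = TRUE))
  }
  both_facet <- function(facet, keyword, both = FALSE) {
    vapply(seq_len(nrow(records)), function(i) {
      in_a <- has_keyword(store_lookup(store, records$protein_a[i], facet),
                          keyword)
      in_b <- has_keyword(store_lookup(store, records$protein_b[i], facet),
                          keyword)
      if (both) in_a && in_b else in_a || in_b
    }, logical(1))
  }
  if (!is.null(criteria$pathway_keyword)) {
    keep <- keep & both_facet("pathways", criteria$pathway_keyword)
  }
  if (!is.null(criteria$expression_site)) {
    site <- criteria$expression_site
    keep <- keep & vapply(seq_len(nrow(records)), function(i) {
      site %in% store_lookup(store, records$protein_a[i],
                             "expression_sites") &&
        site %in% store_lookup(store, records$protein_b[i],
                               "expression_sites")
    }, logical(1))
  }
  if (!is.null(criteria$disease)) {
    keep <- keep & both_facet("diseases", criteria$disease)
  }
  if (!is.null(criteria$go_term)) {
    keep <- keep & both_facet("go_terms", criteria$go_term)
  }
  if (!is.null(criteria$drug)) {
    keep <- keep & both_facet("drugs", criteria$drug)
  }
  if (!is.null(criteria$min_score)) {
    if (is.null(results)) {
      stop("min_score criteria require a results table", call. = FALSE)
    }
    for (mode in names(criteria$min_score)) {
      s <- results[[mode]][match(records$pair_key, results$ppi)]
      keep <- keep & !is.na(s) & s >= criteria$min_score[[mode]]
    }
  }
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$pair_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

results_table <- function(results) {
  if (inherits(results, "druggability")) {
    df <- results$results
    out <- data.frame(ppi = df$pair_key, stringsAsFactors = FALSE)
    out[[results$config$mode]] <- df$score
    out
  } else {
    stopifnot(is.data.frame(results), "ppi" %in% names(results))
    results
  }
}

#' Count interactions at or above a score threshold
#'
#' @param results A wide score table with a `ppi` column and one column
#'   per assessment mode (as produced by [render_report()] or shipped in
#'   the Table 4 fixture), or a [druggability()] object.
#' @param mode Assessment mode column to threshold.
#' @param threshold Inclusive score threshold (non-negative; thresholds
#'   above 1 match nothing).
#' @return Number of interactions with `score >= threshold` in that mode;
#'   unscored (`NA`) entries never count.
#' @examples
#' t4 <- load_fixture("table4_lung_cancer_scores")
#' count_by_threshold(t4, "all", 0.9)  # 17
#' @export
count_by_threshold <- function(results, mode, threshold) {
  stopifnot(threshold >= 0)
  res <- results_table(results)
  if (!mode %in% names(res)) {
    stop("no scores for mode: ", mode, call. = FALSE)
  }
  s <- res[[mode]]
  sum(!is.na(s) & s >= threshold)
}

#' Top-scoring interaction in one assessment mode
#'
#' @inheritParams count_by_threshold
#' @return A list with `unit_id` (pair key) and `score`; ties are broken
#'   by lexicographically smallest pair key.
#' @examples
#' t4 <- load_fixture("table4_lung_cancer_scores")
#' top_result(t4, "all")  # GRB2/VAV1, 0.9662
#' @export
top_result <- function(results, mode) {
  res <- results_table(results)
  if (!mode %in% names(res)) {
    stop("no scores for mode: ", mode, call. = FALSE)
  }
  s <- res[[mode]]
  keep <- !is.na(s)
  if (!any(keep)) stop("no scored results in mode: ", mode, call. = FALSE)
  res <- res[keep, , drop = FALSE]
  s <- s[keep]
  ord <- order(-s, res$ppi)
  list(unit_id = res$ppi[ord[1L]], score = s[ord[1L]])
}

#' Per-species composition of an interaction set
#'
#' Converts per-species interaction counts to percentages of the total.
#' Display percentages are rounded to the nearest integer (88.12% prints
#' as 88%); the exact values are retained in `percent_exact`.
#'
#' @param counts Named numeric vector of per-species counts, or a data
#'   frame whose first two columns are species and count.
#' @return Data frame `species`, `count`, `percent` (integer display),
#'   `percent_exact`.
#' @examples
#' species_summary(load_fixture("table2_species_counts"))
#' @export
species_summary <- function(counts) {
  if (is.data.frame(counts)) {
    species <- as.character(counts[[1]])
    n <- as.numeric(counts[[2]])
  } else {
    species <- names(counts)
    n <- as.numeric(counts)
  }
  if (any(n < 0)) stop("counts must be non-negative", call. = FALSE)
  total <- sum(n)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  exact <- 100 * n / total
  data.frame(species = species, count = n,
             percent = round(exact), percent_exact = exact,
             stringsAsFactors = FALSE)
}

#' Tabulate druggability scores across the four assessment modes
#'
#' Builds the main results summary: one row per interaction with the four
#' per-mode druggability scores side by side, a display band per mode, and
#' `NA` where the interaction was not scored in a mode (for instance, no
#' structural or all-attribute score without a mapped complex structure).
#'
#' @param ... One or more [druggability()] objects (at most one per mode),
#'   or a single wide data frame already keyed by `ppi`.
#' @param path Optional file: the table is written tab-separated.
#' @return Wide data frame `ppi`, `structural`, `drug_chemical`,
#'   `functional`, `all`, `band_structural`, ..., invisibly when written.
#' @export
render_report <- function(..., path = NULL) {
  fits <- list(...)
  modes <- c("structural", "drug_chemical", "functional", "all")
  if (length(fits) == 1 && is.data.frame(fits[[1]]) &&
      !inherits(fits[[1]], "druggability")) {
    wide <- fits[[1]]
    stopifnot("ppi" %in% names(wide))
  } else {
    stopifnot(all(vapply(fits, inherits, logical(1), "druggability")))
    keys <- sort(unique(unlist(lapply(fits, function(f)
      c(f$results$pair_key, f$unscored)))))
    wide <- data.frame(ppi = keys, stringsAsFactors = FALSE)
    for (m in modes) wide[[m]] <- NA_real_
    for (f in fits) {
      m <- f$config$mode
      wide[[m]][match(f$results$pair_key, wide$ppi)] <- f$results$score
    }
  }
  for (m in intersect(modes, names(wide))) {
    wide[[paste0("band_", m)]] <- classify_band(wide[[m]])
  }
  wide <- wide[order(wide$ppi), , drop = FALSE]
  rownames(wide) <- NULL
  if (!is.null(path)) {
    utils::write.table(wide, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    return(invisible(wide))
  }
  wide
}
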