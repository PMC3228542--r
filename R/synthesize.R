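#' Configuration of the synthetic attribute-table generator
#'
#' The generator emulates the statistical structure the scorer assumes: a
#' small positive set of known drug-target interactions, a large unlabeled
#' pool in which some units ("planted") share the positives' attribute
#' distribution while the rest are background, category-tagged features of
#' mixed kinds, and structure-bearing units carrying 1-4 interface pockets
#' of which exactly one "good" pocket carries the signal (so pocket
#' max-aggregation is exercised). Positive units always carry a structure
#' and pockets -- by definition a known drug-target PPI has a solved
#' complex with a validated ligand pocket -- while a fraction
#' `missingness` of pool units lack structural data, as most catalogued
#' interactions do.
#'
#' @param n_positives Number of positive units (default 30, the size of
#'   the known drug-target set).
#' @param n_background,n_planted Pool composition.
#' @param n_features Named integer vector: features per category.
#' @param n_informative Named integer vector: how many leading features of
#'   each category carry the positive shift; the rest are pure noise.
#' @param effect_size Shift of positives/planted units from background on
#'   the informative features, in background-s.d. units.
#' @param missingness Fraction of pool units lacking structure/pockets.
#' @param seed Integer seed; generation is deterministic per seed.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_positives = 30L, n_background = 150L,
                         n_planted = 50L,
                         n_features = c(structural = 7L, drug_chemical = 4L,
                                        functional = 8L),
                         n_informative = c(structural = 3L,
                                           drug_chemical = 2L,
                                           functional = 4L),
                         effect_size = 2, missingness = 0.9,
                         seed = 1L) {
  cats <- c("structural", "drug_chemical", "functional")
  stopifnot(n_positives >= 0, n_background >= 0, n_planted >= 0,
            all(cats %in% names(n_features)),
            all(cats %in% names(n_informative)),
            all(n_features[cats] >= 1),
            all(n_informative[cats] >= 0),
            all(n_informative[cats] <= n_features[cats]),
            effect_size >= 0, missingness >= 0, missingness <= 1)
  structure(list(n_positives = as.integer(n_positives),
                 n_background = as.integer(n_background),
                 n_planted = as.integer(n_planted),
                 n_features = n_features[cats],
                 n_informative = n_informative[cats],
                 effect_size = effect_size,
                 missingness = missingness,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Baseline rates of the non-continuous feature kinds.
SYNTH_COUNT_LAMBDA <- 3
SYNTH_BINARY_P <- 0.2

synthetic_schema <- function(config) {
  nf <- config$n_features
  mk <- function(cat, prefix, kinds) {
    data.frame(name = sprintf("%s_%d", prefix, seq_len(nf[[cat]])),
               category = cat, kind = kinds, stringsAsFactors = FALSE)
  }
  fun_kinds <- rep("continuous", nf[["functional"]])
  fun_kinds[1] <- "binary"
  if (nf[["functional"]] >= 3) {
    fun_kinds[2:(1 + nf[["functional"]] %/% 3)] <- "count"
  }
  df <- rbind(mk("structural", "str", "continuous"),
              mk("drug_chemical", "drug", "count"),
              mk("functional", "fun", fun_kinds))
  attribute_schema(df$name, df$category, df$kind)
}

# One feature value per unit: background at the baseline, shifted units
# moved by delta background-s.d. units.
synth_feature <- function(n, kind, shifted, delta) {
  d <- ifelse(shifted, delta, 0)
  switch(kind,
    continuous = stats::rnorm(n, mean = d, sd = 1),
    count = stats::rpois(n, lambda = SYNTH_COUNT_LAMBDA +
                           d * sqrt(SYNTH_COUNT_LAMBDA)),
    binary = stats::rbinom(n, 1, pmin(0.95, SYNTH_BINARY_P +
                             d * sqrt(SYNTH_BINARY_P * (1 - SYNTH_BINARY_P)))))
}

#' Generate a synthetic PPI attribute table with known ground truth
#'
#' Draws background features from their baseline distributions (standard
#' normal for continuous attributes, Poisson for counts, Bernoulli for
#' binary flags) and shifts positives and planted pool units by
#' `effect_size` background standard deviations on the informative subset
#' of each category. Structure-bearing units receive 1-4 pockets whose
#' descriptors are the structural features; only one pocket per shifted
#' unit carries the shift.
#'
#' @param config A [synth_config()].
#' @return List with `records` (PPI attribute table), `pockets` (pocket
#'   descriptor table), `positives` (character pair keys), `labels` (data
#'   frame `pair_key`, `role` in positive/planted/background), `schema`
#'   and `config`.
#' @export
generate_attribute_table <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  schema <- synthetic_schema(config)
  n <- config$n_positives + config$n_planted + config$n_background
  if (n == 0) stop("config generates no units", call. = FALSE)
  role <- c(rep("positive", config$n_positives),
            rep("planted", config$n_planted),
            rep("background", config$n_background))
  with_preserved_rng({
    set.seed(config$seed)
    prot_a <- sprintf("SP%05d", seq(1, 2 * n, by = 2))
    prot_b <- sprintf("SP%05d", seq(2, 2 * n, by = 2))
    records <- data.frame(protein_a = prot_a, protein_b = prot_b,
                          species = "human", stringsAsFactors = FALSE)
    shifted <- role != "background"
    informative <- unlist(lapply(
      c("structural", "drug_chemical", "functional"), function(cat) {
        nm <- schema_names(schema, cat)
        utils::head(nm, config$n_informative[[cat]])
      }))
    for (j in seq_len(nrow(schema))) {
      nm <- schema$name[j]
      records[[nm]] <- synth_feature(
        n, schema$kind[j],
        shifted & nm %in% informative, config$effect_size)
    }
    # structure: positives always; pool units with prob 1 - missingness
    has_struct <- role == "positive" |
      stats::runif(n) >= config$missingness
    records$pdb_entry <- ifelse(has_struct,
                                sprintf("S%03d", seq_len(n) %% 1000),
                                NA_character_)
    records$chain_a <- ifelse(has_struct, "A", NA_character_)
    records$chain_b <- ifelse(has_struct, "B", NA_character_)
    records$identity_a <- ifelse(has_struct, 100, NA_real_)
    records$identity_b <- ifelse(has_struct, 100, NA_real_)

    struct_cols <- schema_names(schema, "structural")
    pocket_rows <- list()
    for (i in which(has_struct)) {
      n_pockets <- sample.int(4L, 1L)
      good <- if (shifted[i]) 1L else 0L
      for (p in seq_len(n_pockets)) {
        vals <- if (p == good) {
          # the good pocket reuses the unit's own (shifted) descriptors
          as.list(records[i, struct_cols, drop = FALSE])
        } else {
          v <- lapply(struct_cols, function(col) {
            k <- schema$kind[match(col, schema$name)]
            synth_feature(1L, k, FALSE, 0)
          })
          names(v) <- struct_cols
          v
        }
        pocket_rows[[length(pocket_rows) + 1L]] <- c(
          list(protein_a = records$protein_a[i],
               protein_b = records$protein_b[i],
               pdb_entry = records$pdb_entry[i],
               chain = "B",
               pocket_id = sprintf("B%d", p)),
          vals)
      }
    }
    pockets <- if (length(pocket_rows)) {
      do.call(rbind, lapply(pocket_rows, function(r)
        as.data.frame(r, stringsAsFactors = FALSE)))
    } else {
      empty <- data.frame(protein_a = character(0), protein_b = character(0),
                          pdb_entry = character(0), chain = character(0),
                          pocket_id = character(0))
      for (col in struct_cols) empty[[col]] <- numeric(0)
      empty
    }
    # PPI-level structural columns are per-pocket quantities: missing here
    for (col in struct_cols) records[[col]] <- NA_real_
    records <- canonicalize_ppis(records)
    pockets <- canonicalize_ppis(pockets)
    labels <- data.frame(pair_key = records$pair_key, role = role,
                         stringsAsFactors = FALSE)
    list(records = records, pockets = pockets,
         positives = records$pair_key[role == "positive"],
         labels = labels, schema = schema, config = config)
  })
}

#' Generate a toy PPI network
#'
#' Random networks for exercising the degree attribute and network export:
#' an Erdos-Renyi graph with edge probability `p`, or a star with one hub.
#' Self-loops can be added (each node with probability `p` in the
#' Erdos-Renyi model; on the hub in the star model).
#'
#' @param n_nodes Number of proteins (>= 1); nodes are named `N001`, ...
#' @param model `"erdos_renyi"` or `"star"`.
#' @param p Edge probability for the Erdos-Renyi model.
#' @param self_loops Add self-interactions as described above.
#' @param seed Integer seed.
#' @return A [ppi_network()].
#' @export
generate_toy_network <- function(n_nodes, model = c("erdos_renyi", "star"),
                                 p = 0.1, self_loops = FALSE, seed = 1L) {
  model <- match.arg(model)
  stopifnot(n_nodes >= 1)
  nodes <- sprintf("N%03d", seq_len(n_nodes))
  with_preserved_rng({
    set.seed(as.integer(seed))
    edges <- if (model == "star") {
      if (n_nodes == 1) {
        data.frame(protein_a = character(0), protein_b = character(0))
      } else {
        data.frame(protein_a = nodes[1], protein_b = nodes[-1],
                   stringsAsFactors = FALSE)
      }
    } else {
      cmb <- if (n_nodes >= 2) utils::combn(nodes, 2) else
        matrix(character(0), nrow = 2)
      keep <- stats::runif(ncol(cmb)) < p
      data.frame(protein_a = cmb[1, keep], protein_b = cmb[2, keep],
                 stringsAsFactors = FALSE)
    }
    if (self_loops) {
      loops <- if (model == "star") nodes[1] else
        nodes[stats::runif(n_nodes) < p]
      if (length(loops)) {
        edges <- rbind(edges,
                       data.frame(protein_a = loops, protein_b = loops,
                                  stringsAsFactors = FALSE))
      }
    }
    ppi_network(edges, nodes = nodes)
  })
}

FIXTURE_FILES <- c(
  table2_species_counts = "table2_species_counts.tsv",
  table4_lung_cancer_scores = "table4_lung_cancer_scores.tsv")

#' Load a packaged fixture table
#'
#' Two published worked examples ship with the package as tab-separated
#' resources: `table2_species_counts`, the census of stored interactions
#' by species (63,010 of the 71,500 non-redundant PPIs are human-human),
#' and `table4_lung_cancer_scores`, the 17 lung-cancer-related PPIs
#' assessed as highly druggable, with their druggability scores in all
#' four assessment modes.
#'
#' @param name Fixture name, one of `"table2_species_counts"`,
#'   `"table4_lung_cancer_scores"`.
#' @return Data frame of the fixture rows.
#' @export
load_fixture <- function(name) {
  if (!name %in% names(FIXTURE_FILES)) {
    stop("unknown fixture: ", name, "; available: ",
         paste(names(FIXTURE_FILES), collapse = ", "), call. = FALSE)
  }
  path <- system.file("extdata", FIXTURE_FILES[[name]], package = "ppidrug",
                      mustWork = TRUE)
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
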