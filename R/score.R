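#' Configuration of the ensemble druggability scorer
#'
#' Controls the ensemble procedure: `n_iterations` random training sets
#' are formed from the fixed positives plus negatives sampled from the
#' unlabeled pool at `neg_pos_ratio` negatives per positive, a
#' radial-basis-function SVM is trained on each, and every pool unit's
#' score is the fraction of models voting it positive.
#'
#' @param n_iterations Number of random training/prediction rounds
#'   (default 10000).
#' @param neg_pos_ratio Negatives sampled per positive (default 1, i.e.
#'   class-balanced training sets).
#' @param kernel Kernel family; only `"radial"` (RBF) is supported.
#' @param cost Soft-margin regularization constant C (default 1).
#' @param gamma RBF kernel width; `NULL` (default) means 1 / number of
#'   features.
#' @param mode Which attribute category feeds the classifier:
#'   `"structural"`, `"drug_chemical"`, `"functional"` or `"all"`.
#' @param master_seed Integer master seed; per-iteration seeds are derived
#'   deterministically from it, so runs are reproducible and iterations
#'   order-independent.
#' @param scale Standardize features per iteration using training-set
#'   mean/s.d. (default `TRUE`).
#' @return A list of class `"scoring_config"`.
#' @export
scoring_config <- function(n_iterations = 10000L, neg_pos_ratio = 1,
                           kernel = "radial", cost = 1, gamma = NULL,
                           mode = c("all", "structural", "drug_chemical",
                                    "functional"),
                           master_seed = 1L, scale = TRUE) {
  mode <- match.arg(mode)
  n_iterations <- as.integer(n_iterations)
  neg_pos_ratio <- as.numeric(neg_pos_ratio)
  cost <- as.numeric(cost)
  if (!is.null(gamma)) gamma <- as.numeric(gamma)
  stopifnot(n_iterations >= 1L, neg_pos_ratio > 0,
            identical(kernel, "radial"), cost > 0,
            is.null(gamma) || gamma > 0)
  structure(list(n_iterations = n_iterations,
                 neg_pos_ratio = neg_pos_ratio,
                 kernel = kernel, cost = cost, gamma = gamma,
                 mode = mode, master_seed = as.integer(master_seed),
                 scale = isTRUE(scale)),
            class = "scoring_config")
}

#' @export
print.scoring_config <- function(x, ...) {
  cat("Ensemble scoring configuration\n")
  cat(sprintf("  iterations: %d  neg:pos ratio: %g  mode: %s\n",
              x$n_iterations, x$neg_pos_ratio, x$mode))
  cat(sprintf("  kernel: %s  C: %g  gamma: %s  scale: %s  seed: %d\n",
              x$kernel, x$cost,
              if (is.null(x$gamma)) "1/d" else format(x$gamma),
              x$scale, x$master_seed))
  invisible(x)
}

#' Read a scoring configuration from JSON or YAML
#'
#' @param path File path; any subset of the [scoring_config()] fields may
#'   be given, the rest take their defaults.
#' @return A `scoring_config`.
#' @export
read_scoring_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(scoring_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad)) {
    stop("unknown scoring config fields: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(scoring_config, vals)
}

# Deterministic, order-independent child seed for iteration i; kept below
# 2^31 so set.seed() accepts it.
child_seed <- function(master_seed, i) {
  m <- 2147483647
  as.integer((((master_seed %% m) * 48271) %% m + (i * 62089911) %% m) %% m)
}

#' Scoring units
#'
#' A scoring unit is one row to be classified: a whole PPI in the
#' drug/chemical and functional modes, or a single interface pocket in the
#' structural and all-attribute modes. Internally units are a data frame
#' with a `unit_id` column followed by numeric feature columns.
#'
#' @param unit_id Character vector of unit identifiers.
#' @param x Numeric matrix or data frame of features (one row per unit).
#' @return Data frame of class `"scoring_units"`.
#' @export
scoring_units <- function(unit_id, x) {
  x <- as.data.frame(x)
  stopifnot(length(unit_id) == nrow(x), !anyDuplicated(unit_id))
  if (!all(vapply(x, is.numeric, logical(1)))) {
    stop("all features must be numeric", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("scoring units must not contain missing features; ",
         "exclude ineligible units upstream", call. = FALSE)
  }
  out <- cbind(data.frame(unit_id = as.character(unit_id),
                          stringsAsFactors = FALSE), x)
  class(out) <- c("scoring_units", "data.frame")
  out
}

units_matrix <- function(units) {
  m <- as.matrix(units[, setdiff(names(units), "unit_id"), drop = FALSE])
  rownames(m) <- units$unit_id
  storage.mode(m) <- "double"
  m
}

#' Assemble one random training set
#'
#' Every positive unit is labelled +1; `ceiling(ratio * n_positives)`
#' negatives are drawn uniformly without replacement from the test pool
#' and labelled -1. The draw is deterministic given `iteration_seed`.
#' Positives and pool must not share unit ids.
#'
#' @param positives,test_pool [scoring_units()].
#' @param ratio Negatives per positive.
#' @param iteration_seed Integer seed for this draw.
#' @return List with `x` (feature matrix), `y` (factor with levels
#'   `neg`, `pos`) and `negative_ids` (unit ids drawn as negatives).
#' @export
assemble_training_set <- function(positives, test_pool, ratio = 1,
                                  iteration_seed = 1L) {
  n_pos <- nrow(positives)
  n_neg <- as.integer(ceiling(ratio * n_pos))
  if (length(intersect(positives$unit_id, test_pool$unit_id))) {
    stop("positives and test pool overlap by unit_id", call. = FALSE)
  }
  if (nrow(test_pool) < n_neg) {
    stop("test pool too small: need ", n_neg, " negatives, have ",
         nrow(test_pool), call. = FALSE)
  }
  idx <- with_preserved_rng({
    set.seed(as.integer(iteration_seed))
    sample.int(nrow(test_pool), n_neg)
  })
  x <- rbind(units_matrix(positives),
             units_matrix(test_pool)[idx, , drop = FALSE])
  y <- factor(c(rep("pos", n_pos), rep("neg", n_neg)),
              levels = c("neg", "pos"))
  list(x = x, y = y, negative_ids = test_pool$unit_id[idx])
}

with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Train one SVM and collect its positive votes
#'
#' Fits a soft-margin RBF-kernel SVM on a training set (after
#' standardizing each feature by the training-set mean and s.d. when
#' `config$scale` is on, with the same parameters applied to the pool) and
#' predicts every test-pool unit. A degenerate training set (e.g. all
#' feature vectors identical across both classes) yields a warning and no
#' positive votes, but the iteration still counts.
#'
#' @param training List from [assemble_training_set()].
#' @param test_pool [scoring_units()] to predict.
#' @param config A [scoring_config()].
#' @return Logical vector, one element per pool unit: voted positive?
#' @export
train_and_vote <- function(training, test_pool, config = scoring_config()) {
  x <- training$x
  pool_x <- units_matrix(test_pool)
  if (config$scale) {
    mu <- colMeans(x)
    sdev <- apply(x, 2, stats::sd)
    sdev[!is.finite(sdev) | sdev == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sdev, "/")
    pool_x <- sweep(sweep(pool_x, 2, mu), 2, sdev, "/")
  }
  if (all(apply(training$x, 2, function(col) length(unique(col)) == 1L))) {
    warning("degenerate training set: all feature vectors identical ",
            "across both classes; iteration counted with no positive votes",
            call. = FALSE)
    return(rep(FALSE, nrow(test_pool)))
  }
  gamma <- if (is.null(config$gamma)) 1 / ncol(x) else config$gamma
  fit <- tryCatch(
    e1071::svm(x, training$y, kernel = "radial", cost = config$cost,
               gamma = gamma, scale = FALSE),
    error = function(e) e)
  if (inherits(fit, "error")) {
    warning("degenerate training set (", conditionMessage(fit),
            "); iteration counted with no positive votes", call. = FALSE)
    return(rep(FALSE, nrow(test_pool)))
  }
  pred <- tryCatch(stats::predict(fit, pool_x), error = function(e) NULL)
  if (is.null(pred)) return(rep(FALSE, nrow(test_pool)))
  as.character(pred) == "pos"
}

#' Vote fraction to druggability score
#'
#' The druggability score of a unit is the number of ensemble models that
#' judged it positive divided by the number of models: e.g. 9999 positive
#' votes out of 10000 models give 0.9999. Scores range from 0
#' (non-druggable) to 1 (highly druggable) and are exact multiples of
#' `1 / n_iterations`.
#'
#' @param votes Integer vector of positive-vote counts.
#' @param n_iterations Ensemble size.
#' @return Numeric scores in `[0, 1]`.
#' @export
druggability_score <- function(votes, n_iterations) {
  n_iterations <- as.integer(n_iterations)
  stopifnot(n_iterations >= 1L)
  if (any(votes < 0 | votes > n_iterations | votes != floor(votes))) {
    stop("votes must be integers in [0, n_iterations]", call. = FALSE)
  }
  votes / n_iterations
}

#' Display color band of a druggability score
#'
#' Scores are banded for display: `red` for scores >= 0.99, `magenta` for
#' [0.9, 0.99), `hotpink` for [0.8, 0.9), `pink` for [0.7, 0.8), and
#' `none` below 0.7. The 0.9 cut separating the top two bands matches the
#' average score of the known drug-target positives; the lower cuts are
#' display conventions.
#'
#' @param score Numeric vector in `[0, 1]`; `NA` maps to `NA`.
#' @return Character vector of band labels.
#' @export
classify_band <- function(score) {
  ok <- is.na(score) | (score >= 0 & score <= 1)
  if (!all(ok)) stop("scores must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_character_, length(score))
  known <- !is.na(score)
  s <- score[known]
  out[known] <- ifelse(s >= 0.99, "red",
                ifelse(s >= 0.9, "magenta",
                ifelse(s >= 0.8, "hotpink",
                ifelse(s >= 0.7, "pink", "none"))))
  out
}

#' Run the full ensemble over a test pool
#'
#' Executes `config$n_iterations` assemble/train/vote rounds with
#' per-iteration seeds derived from the master seed, tallies for each pool
#' unit how many models judged it positive, and converts tallies to
#' druggability scores. Bitwise reproducible for a fixed configuration.
#'
#' @param positives Positive-class [scoring_units()] (known drug-target
#'   interactions or their pockets).
#' @param test_pool Unlabeled [scoring_units()] to be scored; also the
#'   reservoir from which each round's negatives are drawn.
#' @param config A [scoring_config()].
#' @return Data frame with columns `unit_id`, `votes`, `n_iterations`,
#'   `score`, `band`, in pool order.
#' @export
score_all <- function(positives, test_pool, config = scoring_config()) {
  stopifnot(inherits(config, "scoring_config"))
  feats_p <- setdiff(names(positives), "unit_id")
  feats_t <- setdiff(names(test_pool), "unit_id")
  if (!identical(sort(feats_p), sort(feats_t))) {
    stop("positives and test pool must share the same feature columns",
         call. = FALSE)
  }
  test_pool <- test_pool[, c("unit_id", feats_p)]
  votes <- integer(nrow(test_pool))
  for (i in seq_len(config$n_iterations)) {
    training <- assemble_training_set(positives, test_pool,
                                      ratio = config$neg_pos_ratio,
                                      iteration_seed =
                                        child_seed(config$master_seed, i))
    votes <- votes + train_and_vote(training, test_pool, config)
  }
  data.frame(unit_id = test_pool$unit_id,
             votes = votes,
             n_iterations = config$n_iterations,
             score = druggability_score(votes, config$n_iterations),
             band = classify_band(druggability_score(votes,
                                                     config$n_iterations)),
             stringsAsFactors = FALSE)
}

#' Aggregate pocket-level scores to one PPI-level structural score
#'
#' Pockets are scored individually; the structural druggability score of a
#' PPI is the maximum over its pockets, and the contributing pocket is
#' recorded. A PPI with no scored pockets has no structural score
#' (unscored), not a score of 0.
#'
#' @param pocket_results Data frame of pocket-level results for one PPI
#'   with columns `unit_id` (or `pocket_id`) and `score`.
#' @return One-row data frame `score`, `band`, `pocket_id`, or `NULL`
#'   when there are no pocket results.
#' @export
aggregate_pocket_scores <- function(pocket_results) {
  if (is.null(pocket_results) || nrow(pocket_results) == 0) return(NULL)
  ids <- if ("pocket_id" %in% names(pocket_results))
    pocket_results$pocket_id else pocket_results$unit_id
  ord <- order(-pocket_results$score, ids)
  best <- ord[1L]
  data.frame(score = pocket_results$score[best],
             band = classify_band(pocket_results$score[best]),
             pocket_id = ids[best],
             stringsAsFactors = FALSE)
}

pocket_unit_id <- function(pair_key, pocket_id) {
  paste(pair_key, pocket_id, sep = "::")
}

# Build scoring units for one mode from a PPI table (+ pocket table).
# Units: PPIs for drug_chemical/functional; pockets for structural/all.
build_units <- function(records, schema, mode, pockets = NULL) {
  records <- canonicalize_ppis(records)
  if (mode %in% c("drug_chemical", "functional")) {
    cols <- schema_names(schema, mode)
    miss <- setdiff(cols, names(records))
    if (length(miss)) {
      stop("attribute table lacks ", mode, " columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    keep <- stats::complete.cases(records[, cols, drop = FALSE])
    units <- scoring_units(records$pair_key[keep],
                           records[keep, cols, drop = FALSE])
    return(list(units = units,
                ppi = records$pair_key[keep],
                pocket = rep(NA_character_, sum(keep)),
                excluded = records$pair_key[!keep]))
  }
  # structural / all: one unit per pocket of each structure-bearing PPI
  if (is.null(pockets) || nrow(pockets) == 0) {
    return(list(units = NULL, ppi = character(0), pocket = character(0),
                excluded = records$pair_key))
  }
  pockets <- canonicalize_ppis(pockets)
  struct_cols <- intersect(schema_names(schema, "structural"),
                           names(pockets))
  if (length(struct_cols) == 0) {
    stop("pocket table carries none of the schema's structural attributes",
         call. = FALSE)
  }
  other_cols <- if (mode == "all") {
    schema_names(schema, c("drug_chemical", "functional"))
  } else character(0)
  if (length(other_cols) &&
      length(miss <- setdiff(other_cols, names(records)))) {
    stop("attribute table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  has_struct <- !is.na(records$pdb_entry)
  pk <- pockets[pockets$pair_key %in% records$pair_key[has_struct], ,
                drop = FALSE]
  if (nrow(pk) == 0) {
    return(list(units = NULL, ppi = character(0), pocket = character(0),
                excluded = records$pair_key))
  }
  feat <- pk[, struct_cols, drop = FALSE]
  if (length(other_cols)) {
    ridx <- match(pk$pair_key, records$pair_key)
    feat <- cbind(feat, records[ridx, other_cols, drop = FALSE])
  }
  ok <- stats::complete.cases(feat)
  pk <- pk[ok, , drop = FALSE]
  feat <- feat[ok, , drop = FALSE]
  if (nrow(pk) == 0) {
    return(list(units = NULL, ppi = character(0), pocket = character(0),
                excluded = records$pair_key))
  }
  units <- scoring_units(pocket_unit_id(pk$pair_key, pk$pocket_id), feat)
  list(units = units, ppi = pk$pair_key, pocket = pk$pocket_id,
       excluded = setdiff(records$pair_key, pk$pair_key))
}

#' Assess the druggability of protein-protein interactions
#'
#' The main fitting function: builds scoring units for the configured
#' assessment mode from an attribute table (and pocket table), separates
#' the declared positives from the unlabeled pool, runs the random-negative
#' SVM ensemble, and aggregates pocket-level votes to PPI-level scores
#' where the mode scores pockets. In `structural` and `all` modes each
#' structure-bearing PPI contributes one unit per interface pocket and the
#' PPI score is the maximum over its pockets; PPIs without a mapped
#' complex structure are ineligible for those modes and reported as
#' unscored.
#'
#' @param records PPI attribute table (see [read_ppi_table()] or
#'   [build_attribute_rows()]).
#' @param positives Character vector of canonical pair keys defining the
#'   positive class (known drug-target PPIs). Positives are never scored
#'   as test instances.
#' @param schema [attribute_schema()] naming the feature columns.
#' @param config [scoring_config()]; `config$mode` picks the attribute
#'   category.
#' @param pockets Optional pocket descriptor table, required for
#'   `structural` and `all` modes.
#' @return An object of class `"druggability"`: a list with `results`
#'   (PPI-level data frame: `pair_key`, `mode`, `votes`, `n_iterations`,
#'   `score`, `band`, `pocket_id`), `unit_results` (unit-level votes),
#'   `unscored` (ineligible pair keys), `positives`, `config` and
#'   `schema`.
#' @examples
#' syn <- generate_attribute_table(synth_config(
#'   n_positives = 10, n_background = 40, n_planted = 10,
#'   effect_size = 3, seed = 1))
#' cfg <- scoring_config(n_iterations = 50, mode = "functional",
#'                       master_seed = 1)
#' fit <- druggability(syn$records, syn$positives, syn$schema, cfg)
#' head(as.data.frame(fit))
#' @export
druggability <- function(records, positives, schema,
                         config = scoring_config(), pockets = NULL) {
  stopifnot(inherits(schema, "ppi_schema"),
            inherits(config, "scoring_config"))
  mode <- config$mode
  built <- build_units(records, schema, mode, pockets)
  if (is.null(built$units) || nrow(built$units) == 0) {
    stop("no units are eligible for mode '", mode, "'", call. = FALSE)
  }
  is_pos <- built$ppi %in% positives
  if (!any(is_pos)) {
    stop("none of the declared positives is eligible for mode '", mode,
         "'", call. = FALSE)
  }
  pos_units <- built$units[is_pos, , drop = FALSE]
  class(pos_units) <- class(built$units)
  pool_units <- built$units[!is_pos, , drop = FALSE]
  class(pool_units) <- class(built$units)
  if (nrow(pool_units) == 0) {
    stop("test pool is empty after removing positives", call. = FALSE)
  }
  unit_res <- score_all(pos_units, pool_units, config)
  unit_res$pair_key <- built$ppi[!is_pos]
  unit_res$pocket_id <- built$pocket[!is_pos]

  if (mode %in% c("structural", "all")) {
    agg <- lapply(split(unit_res, unit_res$pair_key), function(d) {
      best <- aggregate_pocket_scores(
        data.frame(pocket_id = d$pocket_id, score = d$score,
                   stringsAsFactors = FALSE))
      data.frame(pair_key = d$pair_key[1], mode = mode,
                 votes = d$votes[match(best$pocket_id, d$pocket_id)],
                 n_iterations = config$n_iterations,
                 score = best$score, band = best$band,
                 pocket_id = best$pocket_id, stringsAsFactors = FALSE)
    })
    results <- do.call(rbind, agg)
  } else {
    results <- data.frame(pair_key = unit_res$pair_key, mode = mode,
                          votes = unit_res$votes,
                          n_iterations = unit_res$n_iterations,
                          score = unit_res$score, band = unit_res$band,
                          pocket_id = NA_character_,
                          stringsAsFactors = FALSE)
  }
  results <- results[order(results$pair_key), , drop = FALSE]
  rownames(results) <- NULL
  structure(list(results = results,
                 unit_results = unit_res,
                 unscored = sort(unique(setdiff(built$excluded, positives))),
                 positives = sort(unique(built$ppi[is_pos])),
                 config = config,
                 schema = schema),
            class = "druggability")
}

#' @export
print.druggability <- function(x, ...) {
  cat(sprintf(
    "Druggability assessment (%s mode): %d scored PPIs, %d positives, %d unscored\n",
    x$config$mode, nrow(x$results), length(x$positives),
    length(x$unscored)))
  cat(sprintf("  ensemble: %d RBF-SVM models, neg:pos ratio %g, seed %d\n",
              x$config$n_iterations, x$config$neg_pos_ratio,
              x$config$master_seed))
  top <- x$results[order(-x$results$score, x$results$pair_key), ,
                   drop = FALSE]
  n_show <- min(5L, nrow(top))
  cat("  top scores:\n")
  for (i in seq_len(n_show)) {
    cat(sprintf("    %-24s %6.4f  %s\n", top$pair_key[i], top$score[i],
                top$band[i]))
  }
  invisible(x)
}

#' @export
summary.druggability <- function(object, ...) {
  res <- object$results
  bands <- factor(res$band, levels = c("red", "magenta", "hotpink",
                                       "pink", "none"))
  out <- list(mode = object$config$mode,
              n_scored = nrow(res),
              n_positives = length(object$positives),
              n_unscored = length(object$unscored),
              band_counts = table(bands),
              n_highly_druggable = sum(res$score >= 0.9),
              score_summary = summary(res$score))
  class(out) <- "summary.druggability"
  out
}

#' @export
print.summary.druggability <- function(x, ...) {
  cat(sprintf("Druggability assessment summary (%s mode)\n", x$mode))
  cat(sprintf("  scored: %d  positives: %d  unscored: %d\n",
              x$n_scored, x$n_positives, x$n_unscored))
  cat(sprintf("  highly druggable (score >= 0.9): %d\n",
              x$n_highly_druggable))
  cat("  bands:",
      paste(sprintf("%s=%d", names(x$band_counts),
                    as.integer(x$band_counts)), collapse = " "), "\n")
  cat("  score distribution:\n")
  print(x$score_summary)
  invisible(x)
}

#' @export
as.data.frame.druggability <- function(x, ...) {
  x$results
}

#' @param x A `druggability` object.
#' @param ... Passed to [graphics::hist()].
#' @describeIn druggability Histogram of PPI-level scores with the display
#'   band cut-offs marked.
#' @export
plot.druggability <- function(x, ...) {
  s <- x$results$score
  graphics::hist(s, breaks = seq(0, 1, by = 0.05),
                 main = sprintf("Druggability scores (%s mode)",
                                x$config$mode),
                 xlab = "druggability score", col = "grey85", ...)
  cuts <- c(0.7, 0.8, 0.9, 0.99)
  cols <- c("pink", "hotpink", "magenta", "red")
  graphics::abline(v = cuts, col = cols, lty = 2, lwd = 2)
  invisible(x)
}
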