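test_that("scoring configuration validates and loads from YAML/JSON", {
  cfg <- scoring_config()
  expect_identical(cfg$n_iterations, 10000L)
  expect_identical(cfg$neg_pos_ratio, 1)
  expect_identical(cfg$kernel, "radial")
  expect_error(scoring_config(n_iterations = 0))
  expect_error(scoring_config(neg_pos_ratio = -1))
  expect_error(scoring_config(kernel = "linear"))

  fy <- tempfile(fileext = ".yaml")
  writeLines(c("n_iterations: 500", "mode: functional", "master_seed: 7"), fy)
  cfg_y <- read_scoring_config(fy)
  expect_identical(cfg_y$n_iterations, 500L)
  expect_identical(cfg_y$mode, "functional")
  fj <- tempfile(fileext = ".json")
  writeLines('{"n_iterations": 250, "cost": 2}', fj)
  cfg_j <- read_scoring_config(fj)
  expect_identical(cfg_j$n_iterations, 250L)
  expect_identical(cfg_j$cost, 2)
  writeLines("bogus_field: 1", fy)
  expect_error(read_scoring_config(fy), "unknown")
})

test_that("per-iteration child seeds are deterministic and below 2^31", {
  s1 <- vapply(1:1000, function(i) ppidrug:::child_seed(42L, i), integer(1))
  s2 <- vapply(1:1000, function(i) ppidrug:::child_seed(42L, i), integer(1))
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 < 2^31))
  expect_gt(length(unique(s1)), 990)  # effectively no collisions
})

test_that("training sets are balanced, seeded and disjoint from positives", {
  pos <- make_gaussian_units(30, 0, prefix = "pos", seed = 1)
  pool <- make_gaussian_units(1000, 0, prefix = "bg", seed = 2)
  tr <- assemble_training_set(pos, pool, ratio = 1, iteration_seed = 99)
  expect_identical(sum(tr$y == "pos"), 30L)
  expect_identical(sum(tr$y == "neg"), 30L)
  expect_identical(nrow(tr$x), 60L)
  expect_true(all(tr$negative_ids %in% pool$unit_id))
  tr2 <- assemble_training_set(pos, pool, ratio = 1, iteration_seed = 99)
  expect_identical(tr$negative_ids, tr2$negative_ids)
  tr3 <- assemble_training_set(pos, pool, ratio = 1, iteration_seed = 100)
  expect_false(identical(tr$negative_ids, tr3$negative_ids))
  # fractional ratios round the negative count up
  tr15 <- assemble_training_set(pos, pool, ratio = 1.5, iteration_seed = 1)
  expect_identical(sum(tr15$y == "neg"), 45L)

  expect_error(assemble_training_set(pos, pos, ratio = 1), "overlap")
  small <- make_gaussian_units(10, 0, prefix = "bg", seed = 3)
  expect_error(assemble_training_set(pos, small, ratio = 1), "too small")
})

test_that("negative sampling is uniform over the pool", {
  pos <- make_gaussian_units(30, 0, prefix = "pos", seed = 1)
  pool <- make_gaussian_units(100, 0, prefix = "bg", seed = 2)
  draws <- 10000L
  tallies <- integer(100)
  names(tallies) <- pool$unit_id
  for (i in seq_len(draws)) {
    ids <- assemble_training_set(pos, pool, ratio = 1,
                                 iteration_seed =
                                   ppidrug:::child_seed(7L, i))$negative_ids
    tallies[ids] <- tallies[ids] + 1L
  }
  freq <- tallies / draws
  se <- sqrt(0.3 * 0.7 / draws)
  expect_true(all(abs(freq - 0.30) <= 3 * se))
})

test_that("votes follow class structure in the separable limit", {
  pos <- make_gaussian_units(10, 10, prefix = "pos", seed = 1)
  pool <- rbind(make_gaussian_units(20, -10, prefix = "bg", seed = 2),
                make_gaussian_units(5, 10, prefix = "nearpos", seed = 3))
  class(pool) <- c("scoring_units", "data.frame")
  tr <- assemble_training_set(pos, pool, ratio = 1, iteration_seed = 5)
  votes <- train_and_vote(tr, pool, scoring_config(n_iterations = 1,
                                                   mode = "functional"))
  near <- grepl("^nearpos", pool$unit_id)
  out_of_sample <- !pool$unit_id %in% tr$negative_ids
  expect_true(all(votes[near & out_of_sample]))
  expect_false(any(votes[!near & out_of_sample]))
})

test_that("a degenerate training set warns but the run completes", {
  x <- matrix(1, nrow = 10, ncol = 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  pos <- scoring_units(paste0("p", 1:10), x)
  pool <- scoring_units(paste0("q", 1:10), x)
  tr <- assemble_training_set(pos, pool, ratio = 1, iteration_seed = 1)
  expect_warning(votes <- train_and_vote(tr, pool, scoring_config()),
                 "degenerate")
  expect_identical(length(votes), 10L)
})

test_that("single-model predictions match a nearest-class-mean oracle on a separable toy set", {
  # 20 points, two tight clusters far apart in 2 features
  set.seed(4)
  pos_x <- matrix(rnorm(10 * 2, mean = 4, sd = 0.3), ncol = 2,
                  dimnames = list(NULL, c("f1", "f2")))
  neg_x <- matrix(rnorm(10 * 2, mean = -4, sd = 0.3), ncol = 2,
                  dimnames = list(NULL, c("f1", "f2")))
  pos <- scoring_units(paste0("p", 1:10), pos_x)
  pool <- scoring_units(paste0("q", 1:10), neg_x)
  test_x <- rbind(pos_x + 0.5, neg_x - 0.5)
  test_units <- scoring_units(paste0("t", 1:20), test_x)
  tr <- assemble_training_set(pos, pool, ratio = 1, iteration_seed = 2)
  votes <- train_and_vote(tr, test_units, scoring_config())
  oracle <- oracle_nearest_mean(tr$x, tr$y, test_x)
  expect_identical(votes, oracle == "pos")
})

test_that("vote counts convert exactly to druggability scores", {
  expect_identical(druggability_score(9999L, 10000L), 0.9999)
  expect_identical(druggability_score(0L, 10000L), 0)
  expect_identical(druggability_score(10000L, 10000L), 1)
  expect_equal(druggability_score(c(1, 2, 3), 4), c(0.25, 0.5, 0.75))
  expect_error(druggability_score(-1, 100), "votes")
  expect_error(druggability_score(101, 100), "votes")
  expect_error(druggability_score(1.5, 100), "votes")
})

test_that("display bands use the published half-open score bins", {
  expect_identical(classify_band(0.9662), "magenta")
  expect_identical(classify_band(0.99), "red")
  expect_identical(classify_band(1), "red")
  expect_identical(classify_band(0.9), "magenta")
  expect_identical(classify_band(0.8999), "hotpink")
  expect_identical(classify_band(0.8), "hotpink")
  expect_identical(classify_band(0.7), "pink")
  expect_identical(classify_band(0.65), "none")
  expect_identical(classify_band(0), "none")
  expect_identical(classify_band(NA_real_), NA_character_)
  expect_error(classify_band(1.2), "0, 1")
  expect_error(classify_band(-0.1), "0, 1")
})

test_that("ensemble runs are reproducible and score granularity is exact", {
  pos <- make_gaussian_units(10, 1, prefix = "pos", seed = 1)
  pool <- make_gaussian_units(40, 0, prefix = "bg", seed = 2)
  cfg <- scoring_config(n_iterations = 50, mode = "functional",
                        master_seed = 31)
  r1 <- score_all(pos, pool, cfg)
  r2 <- score_all(pos, pool, cfg)
  expect_identical(r1, r2)
  expect_true(all(r1$score >= 0 & r1$score <= 1))
  expect_true(all(abs(r1$score * 50 - round(r1$score * 50)) < 1e-12))
  r3 <- score_all(pos, pool, scoring_config(n_iterations = 50,
                                            mode = "functional",
                                            master_seed = 32))
  expect_false(identical(r1$votes, r3$votes))
})

test_that("ensemble votes match a brute-force per-iteration tally", {
  pos <- make_gaussian_units(8, 1.5, prefix = "pos", seed = 5)
  pool <- make_gaussian_units(30, 0, prefix = "bg", seed = 6)
  cfg <- scoring_config(n_iterations = 25, mode = "functional",
                        master_seed = 17)
  res <- score_all(pos, pool, cfg)
  tally <- integer(nrow(pool))
  for (i in seq_len(cfg$n_iterations)) {
    tr <- assemble_training_set(pos, pool, ratio = cfg$neg_pos_ratio,
                                iteration_seed =
                                  ppidrug:::child_seed(cfg$master_seed, i))
    tally <- tally + train_and_vote(tr, pool, cfg)
  }
  expect_identical(res$votes, tally)
  expect_identical(res$score, tally / cfg$n_iterations)
})

test_that("pocket scores aggregate to the PPI by maximum", {
  pr <- data.frame(pocket_id = c("C1", "B2", "B3"),
                   score = c(0.7431, 0.31, 0.05), stringsAsFactors = FALSE)
  best <- aggregate_pocket_scores(pr)
  expect_identical(best$score, 0.7431)
  expect_identical(best$pocket_id, "C1")
  expect_identical(best$band, "pink")
  one <- aggregate_pocket_scores(data.frame(pocket_id = "B1", score = 0.42))
  expect_identical(one$score, 0.42)
  expect_null(aggregate_pocket_scores(NULL))
  expect_null(aggregate_pocket_scores(data.frame(pocket_id = character(0),
                                                 score = numeric(0))))
  # ties resolve to the lexicographically smallest pocket id
  tie <- aggregate_pocket_scores(data.frame(pocket_id = c("B2", "B1"),
                                            score = c(0.5, 0.5)))
  expect_identical(tie$pocket_id, "B1")
})

test_that("structural and all modes score pockets and report max per PPI", {
  syn <- generate_attribute_table(synth_config(
    n_positives = 8, n_background = 30, n_planted = 8,
    effect_size = 3, missingness = 0.5, seed = 21))
  cfg <- scoring_config(n_iterations = 40, mode = "all", master_seed = 3)
  fit <- druggability(syn$records, syn$positives, syn$schema, cfg,
                      pockets = syn$pockets)
  expect_s3_class(fit, "druggability")
  res <- fit$results
  # every scored PPI carries the pocket that won the max-aggregation
  expect_true(all(!is.na(res$pocket_id)))
  for (k in res$pair_key) {
    units <- fit$unit_results[fit$unit_results$pair_key == k, ]
    expect_identical(res$score[res$pair_key == k], max(units$score))
  }
  # PPIs without a mapped structure are reported unscored, not zero
  no_struct <- syn$records$pair_key[is.na(syn$records$pdb_entry)]
  no_struct <- setdiff(no_struct, syn$positives)
  expect_true(all(no_struct %in% fit$unscored))
  expect_false(any(no_struct %in% res$pair_key))
})

test_that("positives are never scored as test instances", {
  syn <- generate_attribute_table(synth_config(
    n_positives = 10, n_background = 30, n_planted = 0,
    effect_size = 1, missingness = 1, seed = 9))
  cfg <- scoring_config(n_iterations = 20, mode = "functional",
                        master_seed = 2)
  fit <- druggability(syn$records, syn$positives, syn$schema, cfg)
  expect_identical(length(intersect(fit$results$pair_key, syn$positives)), 0L)
  expect_setequal(fit$positives, syn$positives)
})
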