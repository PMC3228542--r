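# Independent brute-force oracles used to cross-check the implementation.

# O(n^2) count of distinct unordered pairs.
oracle_n_unique_pairs <- function(a, b) {
  n <- length(a)
  dup <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (dup[i]) next
    for (j in seq_len(i - 1L)) {
      same <- (a[i] == a[j] && b[i] == b[j]) ||
        (a[i] == b[j] && b[i] == a[j])
      if (same) {
        dup[i] <- TRUE
        break
      }
    }
  }
  sum(!dup)
}

# Brute-force neighbor enumeration; a self-loop makes the protein its own
# partner once.
oracle_degree <- function(edges, p) {
  partners <- character(0)
  for (i in seq_len(nrow(edges))) {
    if (edges$protein_a[i] == p) partners <- c(partners, edges$protein_b[i])
    if (edges$protein_b[i] == p) partners <- c(partners, edges$protein_a[i])
  }
  length(unique(partners))
}

# Nearest-class-mean classifier: oracle for the separable limit.
oracle_nearest_mean <- function(train_x, train_y, test_x) {
  mu_pos <- colMeans(train_x[train_y == "pos", , drop = FALSE])
  mu_neg <- colMeans(train_x[train_y == "neg", , drop = FALSE])
  apply(test_x, 1, function(r) {
    if (sum((r - mu_pos)^2) < sum((r - mu_neg)^2)) "pos" else "neg"
  })
}

# Rank-based AUC of scores for planted units vs background.
rank_auc <- function(pos_scores, neg_scores) {
  mean(outer(pos_scores, neg_scores, ">") +
         0.5 * outer(pos_scores, neg_scores, "=="))
}

# Small scoring-unit sets drawn around class centers.
make_gaussian_units <- function(n, center, d = 3, prefix = "u", seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * d, mean = center), nrow = n)
  colnames(x) <- paste0("f", seq_len(d))
  scoring_units(paste0(prefix, seq_len(n)), x)
}
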