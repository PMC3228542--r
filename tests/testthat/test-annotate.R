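test_that("disease co-annotation scores 1 only when both partners are implicated", {
  expect_identical(omim_score(c("D1"), c("D2")), 1L)  # different diseases count
  expect_identical(omim_score(c("D1"), character(0)), 0L)
  expect_identical(omim_score(character(0), character(0)), 0L)
  # symmetry
  expect_identical(omim_score(c("D1"), character(0)),
                   omim_score(character(0), c("D1")))
})

test_that("partner counts follow the self-loop-counts-once rule", {
  tri <- ppi_network(data.frame(protein_a = c("A", "A", "B"),
                                protein_b = c("B", "C", "C")))
  expect_identical(ppi_degree(tri, "A"), 2L)
  empty <- ppi_network(data.frame(protein_a = character(0),
                                  protein_b = character(0)))
  expect_identical(ppi_degree(empty, "A"), 0L)
  # star on hub H with 7 leaves plus an H-H self-loop
  star <- data.frame(protein_a = c(rep("H", 7), "H"),
                     protein_b = c(paste0("L", 1:7), "H"),
                     stringsAsFactors = FALSE)
  expect_identical(oracle_degree(star, "H"), 8L)
  expect_identical(ppi_degree(ppi_network(star), "H"), 8L)
})

test_that("degree matches brute-force neighbor counts on random graphs", {
  for (seed in 1:5) {
    net <- generate_toy_network(sample(10:50, 1), "erdos_renyi", p = 0.15,
                                self_loops = TRUE, seed = seed)
    ends <- ppidrug:::network_edge_ends(net)
    edges <- data.frame(protein_a = ends$a, protein_b = ends$b,
                        stringsAsFactors = FALSE)
    for (p in net$nodes) {
      expect_identical(ppi_degree(net, p), oracle_degree(edges, p))
    }
  }
})

test_that("annotation counts are set cardinalities, zero for unknowns", {
  store <- annotation_store(
    drugs = list(GRB2 = "DB00061"),
    pathways = list(P1 = c("kegg:apoptosis", "pid:p53", "kegg:apoptosis",
                           "pid:adhesion")))
  expect_identical(count_annotations(store, "GRB2", "drugs"), 1L)
  expect_identical(count_annotations(store, "VAV1", "drugs"), 0L)
  expect_identical(count_annotations(store, "P1", "pathways"), 3L)
  expect_error(count_annotations(store, "GRB2", "bogus"))
})

test_that("GO identity score is Jaccard by default and symmetric", {
  expect_identical(go_identity_score(c("g1", "g2"), c("g1", "g2")), 1)
  expect_identical(go_identity_score(c("g1"), c("g2")), 0)
  expect_identical(go_identity_score(character(0), c("g1")), 0)
  expect_equal(go_identity_score(c("g1", "g2"), c("g2", "g3")), 1 / 3)
  expect_identical(go_identity_score(c("g1", "g2"), c("g2", "g3")),
                   go_identity_score(c("g2", "g3"), c("g1", "g2")))
  # pluggable strategy
  expect_identical(go_identity_score("a", "b", method = function(x, y) 0.42),
                   0.42)
})

test_that("expression similarity over site sets handles the 44-site vocabulary", {
  vocab <- sprintf("site%02d", 1:44)
  a <- vocab[1:34]                      # expressed in 34/44 body sites
  b <- c(vocab[1:30], vocab[35:36])     # 32 sites, 30 shared
  expect_equal(expression_similarity(a, b, vocabulary = vocab), 30 / 36)
  expect_identical(expression_similarity(a, a, vocabulary = vocab), 1)
  expect_identical(expression_similarity(vocab[1:3], vocab[10:12]), 0)
  expect_identical(expression_similarity(a, b), expression_similarity(b, a))
  expect_error(expression_similarity(c("site01", "elbow"), a,
                                     vocabulary = vocab), "vocabulary")
})

test_that("motif profile eligibility requires at least two curated instances", {
  expect_true(motif_profile_eligible(2))
  expect_false(motif_profile_eligible(1))
  expect_false(motif_profile_eligible(0))
  expect_error(motif_profile_eligible(-1))
})

test_that("structure mapping enforces identity, distinct chains and contact", {
  hits <- data.frame(protein = c("a", "b"), pdb_entry = "1XYZ",
                     chain = c("A", "B"), percent_identity = c(95, 85),
                     stringsAsFactors = FALSE)
  contacts <- data.frame(pdb_entry = "1XYZ", chain_x = "A", chain_y = "B",
                         stringsAsFactors = FALSE)
  asg <- map_ppi_to_structure("a", "b", hits, contacts)
  expect_identical(asg$pdb_entry, "1XYZ")
  expect_identical(c(asg$chain_a, asg$chain_b), c("A", "B"))

  low <- hits; low$percent_identity <- c(95, 79)
  expect_null(map_ppi_to_structure("a", "b", low, contacts))
  # exactly 80 is inclusive
  at80 <- hits; at80$percent_identity <- c(95, 80)
  expect_false(is.null(map_ppi_to_structure("a", "b", at80, contacts)))

  same_chain <- data.frame(protein = c("a", "b"), pdb_entry = "1XYZ",
                           chain = "A", percent_identity = 95,
                           stringsAsFactors = FALSE)
  expect_null(map_ppi_to_structure("a", "b", same_chain, contacts))
  # contact symmetry: reversed chain order in the table still matches
  rev_contacts <- data.frame(pdb_entry = "1XYZ", chain_x = "B",
                             chain_y = "A", stringsAsFactors = FALSE)
  expect_false(is.null(map_ppi_to_structure("a", "b", hits, rev_contacts)))
  expect_null(map_ppi_to_structure("a", "b", hits,
                                   contacts[0, , drop = FALSE]))
})

test_that("structure-mapping ties pick the best worst-identity entry, then id", {
  hits <- data.frame(
    protein = c("a", "b", "a", "b", "a", "b"),
    pdb_entry = c("2AAA", "2AAA", "1BBB", "1BBB", "3CCC", "3CCC"),
    chain = rep(c("A", "B"), 3),
    percent_identity = c(99, 82, 90, 90, 90, 90),
    stringsAsFactors = FALSE)
  contacts <- data.frame(pdb_entry = c("2AAA", "1BBB", "3CCC"),
                         chain_x = "A", chain_y = "B",
                         stringsAsFactors = FALSE)
  asg <- map_ppi_to_structure("a", "b", hits, contacts)
  # min identities: 2AAA -> 82, 1BBB/3CCC -> 90; tie broken by entry id
  expect_identical(asg$pdb_entry, "1BBB")
})

test_that("structure mapping never violates its conditions on random inputs", {
  for (seed in 1:20) {
    set.seed(seed)
    entries <- sprintf("E%02d", 1:4)
    chains <- c("A", "B", "C")
    hits <- data.frame(
      protein = sample(c("a", "b"), 12, replace = TRUE),
      pdb_entry = sample(entries, 12, replace = TRUE),
      chain = sample(chains, 12, replace = TRUE),
      percent_identity = runif(12, 60, 100),
      stringsAsFactors = FALSE)
    contacts <- data.frame(
      pdb_entry = sample(entries, 5, replace = TRUE),
      chain_x = sample(chains, 5, replace = TRUE),
      chain_y = sample(chains, 5, replace = TRUE),
      stringsAsFactors = FALSE)
    asg <- map_ppi_to_structure("a", "b", hits, contacts)
    if (!is.null(asg)) {
      expect_gte(asg$identity_a, 80)
      expect_gte(asg$identity_b, 80)
      expect_true(asg$chain_a != asg$chain_b)
      expect_true(ppidrug:::chains_in_contact(contacts, asg$pdb_entry,
                                              asg$chain_a, asg$chain_b))
      # the chosen chains really are hits of the right proteins
      expect_true(any(hits$protein == "a" & hits$pdb_entry == asg$pdb_entry &
                        hits$chain == asg$chain_a))
      expect_true(any(hits$protein == "b" & hits$pdb_entry == asg$pdb_entry &
                        hits$chain == asg$chain_b))
    }
  }
})

test_that("tabular alignment hits parse entry_chain subjects", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c(
    "GRB2\t1GCQ_B\t95.2\t120\t5\t1\t1\t120\t1\t120\t1e-50\t250",
    "VAV1\t1GCQ_C\t85.0\t110\t8\t2\t5\t110\t3\t112\t1e-40\t200"), f)
  hits <- read_similarity_hits(f)
  expect_identical(hits$pdb_entry, c("1GCQ", "1GCQ"))
  expect_identical(hits$chain, c("B", "C"))
  expect_equal(hits$percent_identity, c(95.2, 85.0))
  writeLines("GRB2\tnochain\t95\t1\t1\t1\t1\t1\t1\t1\t1\t1", f)
  expect_error(read_similarity_hits(f), "pdb_entry")
})

test_that("derived attribute rows compose the counting and scoring rules", {
  store <- annotation_store(
    diseases = list(A = "omim:1", B = "omim:2"),
    pathways = list(A = c("kegg:x", "pid:y"), B = "kegg:x"),
    go_terms = list(A = c("GO:1", "GO:2"), B = c("GO:2", "GO:3")),
    expression_sites = list(A = c("lung", "liver"), B = c("lung", "brain")),
    drugs = list(A = "DB1"),
    paralogs = list(B = c("B2", "B3")))
  net <- ppi_network(data.frame(protein_a = c("A", "A", "B"),
                                protein_b = c("B", "C", "C")))
  pairs <- data.frame(protein_a = c("A", "B", "C"),
                      protein_b = c("B", "A", "D"),
                      stringsAsFactors = FALSE)
  rows <- build_attribute_rows(pairs, store, net)
  expect_identical(nrow(rows), 2L)  # reversed duplicate collapses
  ab <- rows[rows$pair_key == "A/B", ]
  expect_identical(ab$omim, 1)
  expect_identical(ab$degree_a, 2)
  expect_identical(ab$n_pathways_a, 2)
  expect_identical(ab$n_drugs_a, 1)
  expect_identical(ab$n_drugs_b, 0)
  expect_identical(ab$n_paralogs_b, 2)
  expect_equal(ab$go_identity, 1 / 3)
  expect_equal(ab$expression_similarity, 1 / 3)
  # no structure inputs: structural attributes and assignment all missing
  expect_true(is.na(ab$pdb_entry))
  expect_true(all(is.na(ab$volume)))
  cd <- rows[rows$pair_key == "C/D", ]
  expect_identical(cd$omim, 0L + 0)
  expect_identical(cd$n_drugs_a, 0)
})

test_that("derived rows pick up structure assignments when inputs qualify", {
  store <- annotation_store()
  net <- ppi_network(data.frame(protein_a = "A", protein_b = "B"))
  hits <- data.frame(protein = c("A", "B"), pdb_entry = "1XYZ",
                     chain = c("A", "B"), percent_identity = c(90, 88),
                     stringsAsFactors = FALSE)
  contacts <- data.frame(pdb_entry = "1XYZ", chain_x = "A", chain_y = "B",
                         stringsAsFactors = FALSE)
  rows <- build_attribute_rows(
    data.frame(protein_a = "A", protein_b = "B", stringsAsFactors = FALSE),
    store, net, hits = hits, contacts = contacts)
  expect_identical(rows$pdb_entry, "1XYZ")
  expect_identical(rows$identity_a, 90)
})
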