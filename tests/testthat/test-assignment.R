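# shared fixture: host protein H1 {X,Y}, bacterial B1 {X,Z} (X cross-phylum),
# plus two same-genus species sharing peptides within Phylum1
cross_split_fixture <- function() {
  tree <- toy_tree()
  X <- make_pep(100); Y <- make_pep(101); Z <- make_pep(102)
  db <- toy_db(c("H1", "B1"), c("hsp", "s1"),
               list(c(X, Y), c(X, Z)), tree = tree)
  list(tree = tree, db = db, index = build_peptide_index(db),
       X = X, Y = Y, Z = Z)
}

test_that("peptide LCA assignment annotates source taxa, LCA and status", {
  fx <- cross_split_fixture()
  asg <- assign_peptide_lca(c(fx$X, fx$Y, fx$Z, "NOTAPEPK"),
                            fx$index, fx$tree)
  tab <- asg$table
  expect_identical(asg$unmatched, "NOTAPEPK")
  # peptide in exactly one species: LCA is that species, status unique
  expect_identical(tab$lca[tab$peptide == fx$Y], "hsp")
  expect_identical(tab$status[tab$peptide == fx$Y],
                   "unique-to-one-split-taxon")
  # host+bacterial peptide: LCA root, two split taxa, excluded status
  expect_identical(tab$lca[tab$peptide == fx$X], "root")
  expect_identical(tab$status[tab$peptide == fx$X], "cross-split-shared")
  expect_gte(tab$n_split_taxa[tab$peptide == fx$X], 2L)
})

test_that("a peptide shared by two congeneric species gets the genus LCA", {
  tree <- toy_tree()
  sh <- make_pep(200)
  db <- toy_db(c("P1", "P2"), c("s1", "s2"),
               list(c(sh, make_pep(201)), c(sh, make_pep(202))),
               tree = tree)
  asg <- assign_peptide_lca(sh, build_peptide_index(db), tree)
  expect_identical(asg$table$lca, "g1")
  expect_identical(asg$table$status, "unique-to-one-split-taxon")
})

test_that("taxon-peptide tree counts each peptide once at its LCA", {
  tree <- toy_tree()
  uniq <- vapply(300:302, make_pep, character(1)) # unique to s1
  sh <- vapply(303:304, make_pep, character(1))   # shared s1/s2 (genus g1)
  db <- toy_db(c("P1", "P2"), c("s1", "s2"),
               list(c(uniq, sh), c(sh, make_pep(305))), tree = tree)
  idx <- build_peptide_index(db)
  asg <- assign_peptide_lca(c(uniq, sh), idx, tree)
  tpt <- build_taxon_peptide_tree(asg, tree, prune_genera_without_unique = FALSE)
  cnt <- stats::setNames(tpt$counts$attributed_count, tpt$counts$taxon_id)
  expect_equal(unname(cnt["s1"]), 3L)
  expect_equal(unname(cnt["g1"]), 2L)
  expect_equal(sum(tpt$counts$attributed_count), 5L)
})

test_that("genus pruning removes exactly genera without genus-or-below peptides", {
  fx <- cross_split_fixture()
  # only the cross-phylum peptide observed: nothing attributed below root
  asg_all_shared <- assign_peptide_lca(fx$X, fx$index, fx$tree)
  tpt0 <- build_taxon_peptide_tree(asg_all_shared, fx$tree,
                                   prune_genera_without_unique = FALSE)
  below_root <- tpt0$counts$taxon_id != "root"
  expect_true(all(tpt0$counts$attributed_count[below_root] == 0L))
  expect_equal(sum(tpt0$counts$attributed_count), 1L)

  # with pruning on, every genus disappears and the peptides counted inside
  # pruned subtrees are listed, not re-attributed
  asg <- assign_peptide_lca(c(fx$X, fx$Y, fx$Z), fx$index, fx$tree)
  tpt <- build_taxon_peptide_tree(asg, fx$tree)
  expect_setequal(tpt$pruned_genera, c("g2", "g3"))
  expect_false(any(tpt$pruned_genera %in% tpt$counts$taxon_id))
  expect_true(all(c("hgen", "g1") %in% tpt$counts$taxon_id))
  # Y (hsp) and Z (s1) stay; genera g2/g3 subtrees are gone
  expect_false(any(c("s3", "s4") %in% tpt$counts$taxon_id))
})

test_that("protein groups never bridge the split rank and respect uniqueness", {
  fx <- cross_split_fixture()
  pg <- group_proteins_split_by_taxonomy(fx$db, c(fx$X, fx$Y, fx$Z),
                                         fx$index, fx$tree)
  expect_equal(nrow(pg$summary), 2L)
  h <- pg$groups[[which(pg$summary$leading_accession == "H1")]]
  b <- pg$groups[[which(pg$summary$leading_accession == "B1")]]
  expect_identical(h$identifying_peptides, fx$Y)
  expect_identical(b$identifying_peptides, fx$Z)
  expect_identical(h$split_taxon, "hphy")
  expect_identical(b$split_taxon, "p1")
  # the cross-phylum peptide X identifies neither group
  expect_false(fx$X %in% c(h$identifying_peptides, b$identifying_peptides))
})

test_that("identical peptide sets merge; subsets are subsumed greedily", {
  tree <- toy_tree()
  p <- vapply(400:404, make_pep, character(1))
  db <- toy_db(c("P1", "P2", "P3", "P4"), c("s1", "s1", "s1", "s2"),
               list(c(p[1], p[2], p[3]), # P1: superset
                    c(p[1], p[2], p[3]), # P2: identical to P1 -> merged
                    c(p[1], p[2]),       # P3: subset -> subsumed
                    c(p[4], p[5])),      # P4: distinct protein
               tree = tree)
  idx <- build_peptide_index(db)
  pg <- group_proteins_split_by_taxonomy(db, p, idx, tree)
  expect_equal(nrow(pg$summary), 2L)
  big <- pg$groups[[which(pg$summary$leading_accession == "P1")]]
  expect_setequal(big$members, c("P1", "P2", "P3"))
  expect_setequal(big$identifying_peptides, p[1:3])
  # all peptides here identify exactly one group -> all unique
  expect_setequal(big$unique_peptides, p[1:3])
})

test_that("a protein whose every peptide is cross-split-shared is not reported", {
  tree <- toy_tree()
  X <- make_pep(500)
  db <- toy_db(c("H1", "B1"), c("hsp", "s1"), list(X, X), tree = tree)
  pg <- group_proteins_split_by_taxonomy(db, X, build_peptide_index(db),
                                         tree)
  expect_equal(nrow(pg$summary), 0L)
})

test_that("min_peptides_per_group drops thin groups", {
  fx <- cross_split_fixture()
  pg <- group_proteins_split_by_taxonomy(
    fx$db, c(fx$X, fx$Y, fx$Z), fx$index, fx$tree,
    grouping_params(min_peptides_per_group = 2))
  expect_equal(nrow(pg$summary), 0L)
})

test_that("split guarantee holds on simulated data with heavy within-genus copying", {
  cfg <- simulation_config(seed = 2024, n_phyla = 3, genera_per_phylum = 2,
                           species_per_genus = 2, proteins_per_species = 4,
                           protein_length_mean = 150, protein_length_sd = 20,
                           cross_species_copy_prob = 0.8,
                           point_mutation_rate = 0.01)
  sim <- simulate_dataset(cfg)
  observed <- sim$evidence$peptide
  pg <- group_proteins_split_by_taxonomy(sim$db, observed, sim$index,
                                         sim$tree)
  nodes <- sim$tree$nodes
  for (g in pg$groups) {
    member_taxa <- unname(sim$index$acc_taxon[g$members])
    projs <- vapply(member_taxa, oracle_split_projection, character(1),
                    nodes = nodes, split_rank = "phylum")
    expect_identical(unname(unique(projs)), g$split_taxon)
    for (pep in g$identifying_peptides) {
      acc <- sim$index$pairs$accession[sim$index$pairs$peptide == pep]
      pp <- unique(vapply(unname(sim$index$acc_taxon[acc]),
                          oracle_split_projection, character(1),
                          nodes = nodes, split_rank = "phylum"))
      expect_length(pp, 1L)
    }
  }
  # every unique peptide identifies exactly one group
  uniq <- unlist(lapply(pg$groups, `[[`, "unique_peptides"))
  expect_false(anyDuplicated(uniq) > 0)
  tally <- table(unlist(lapply(pg$groups, `[[`, "identifying_peptides")))
  expect_true(all(tally[uniq] == 1L))
})

test_that("grouping an index without taxa fails loudly", {
  db <- sequence_db("A1", "AAAAAAKCCCCCCK")
  idx <- build_peptide_index(db)
  expect_error(assign_peptide_lca("AAAAAAK", idx, toy_tree()),
               "without taxon annotation")
})
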