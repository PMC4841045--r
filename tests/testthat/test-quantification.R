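# one-genus fixture: n peptides of species s1 (genus g1) in one sample
one_genus_quant <- function(n, intensities, top_n = 10,
                            mode = "per-sample") {
  tree <- toy_tree()
  peps <- vapply(600 + seq_len(n), make_pep, character(1))
  db <- toy_db("P1", "s1", list(peps), tree = tree)
  idx <- build_peptide_index(db)
  ev <- make_evidence(peps, intensities)
  genus_abundance_topn(ev, idx, tree,
                       genus_quant_params(top_n = top_n, mode = mode))
}

test_that("evidence files are parsed, filtered and validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "Sequence\tProteins\tReverse\tPotential contaminant\tIntensity S1\tIntensity S2",
    "AAAAAAK\tP1\t\t\t10\t0",
    "CCCCCCK\tP2;P3\t\t\t5\t7",
    "DDDDDDK\tREV1\t+\t\t3\t3",
    "EEEEEEK\tCON1\t\t+\t2\t2",
    "FFFFFFK\tP4\t\t\t1\t4"), f)
  ev <- read_evidence(f)
  expect_equal(length(ev$peptide), 3L) # 1 reverse + 1 contaminant removed
  rep <- attr(ev, "removal_report")
  expect_equal(rep$n[rep$reason == "reverse"], 1L)
  expect_equal(rep$n[rep$reason == "contaminant"], 1L)
  expect_identical(ev$proteins[[2]], c("P2", "P3"))
  expect_identical(ev$samples, c("S1", "S2"))

  # filters requested but no flag columns: unchanged, with a warning
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Sequence\tIntensity S1", "AAAAAAK\t10"), f2)
  expect_warning(ev2 <- read_evidence(f2, filter_contaminants = FALSE),
                 "Reverse")
  expect_equal(length(ev2$peptide), 1L)

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Sequence\tIntensity S1", "AAAAAAK\t-3"), f3)
  expect_error(suppressWarnings(read_evidence(f3)), "negative intensity")
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Peptide\tIntensity S1", "AAAAAAK\t3"), f4)
  expect_error(read_evidence(f4), "Sequence")
})

test_that("duplicate evidence rows aggregate by summing intensities", {
  m <- matrix(c(1, 2, 4, 8), ncol = 2, dimnames = list(NULL, c("S1", "S2")))
  ev <- evidence_table(c("AAAAAAK", "AAAAAAK"), m)
  expect_equal(length(ev$peptide), 1L)
  expect_equal(unname(ev$intensity[1, ]), c(3, 12))
  expect_error(evidence_table("AAAAAAK",
                              matrix(-1, dimnames = list(NULL, "S1"))),
               "nonnegative")
})

test_that("top-N genus abundance matches hand-computed fixtures", {
  # 12 pool peptides with intensities 1..12: top ten sum to 78 - 1 - 2 = 75
  q12 <- one_genus_quant(12, 1:12)
  expect_equal(unname(q12$abundance["g1", "S1"]), 75)
  # exactly ten pool peptides: all are summed
  q10 <- one_genus_quant(10, 1:10)
  expect_equal(unname(q10$abundance["g1", "S1"]), 55)
  # nine pool peptides: the genus is excluded from quantification
  q9 <- one_genus_quant(9, 1:9)
  expect_false("g1" %in% rownames(q9$abundance))
  expect_true("g1" %in% q9$excluded$genus)
  expect_equal(q9$excluded$n_peptides[q9$excluded$genus == "g1"], 9L)
})

test_that("zero intensity means unobserved and never fills a top-N slot", {
  # 10 pool peptides but only 4 nonzero: abundance is the sum of those 4
  q <- one_genus_quant(10, c(5, 6, 7, 8, rep(0, 6)))
  expect_equal(unname(q$abundance["g1", "S1"]), 26)
})

test_that("global-median mode selects one peptide set across samples", {
  m <- cbind(S1 = c(10, 1, 5, 0), S2 = c(12, 2, 6, 100))
  tree <- toy_tree()
  peps <- vapply(700:703, make_pep, character(1))
  db <- toy_db("P1", "s1", list(peps), tree = tree)
  idx <- build_peptide_index(db)
  ev <- evidence_table(peps, m)
  q <- genus_abundance_topn(ev, idx, tree,
                            genus_quant_params(top_n = 2,
                                               mode = "global-median"))
  # medians: 11, 1.5, 5.5, 50 -> peptides 4 and 1 selected once
  expect_equal(unname(q$abundance["g1", ]), c(10 + 0, 12 + 100))
})

test_that("genus pools honor all-peptides vs unique-only membership", {
  tree <- toy_tree()
  sh <- make_pep(800) # shared between g1 (s1) and g2 (s3)
  u1 <- make_pep(801)
  db <- toy_db(c("P1", "P2"), c("s1", "s3"),
               list(c(sh, u1), sh), tree = tree)
  idx <- build_peptide_index(db)
  ev <- make_evidence(c(sh, u1), c(5, 3))
  q_all <- genus_abundance_topn(ev, idx, tree,
                                genus_quant_params(top_n = 1))
  expect_equal(unname(q_all$n_peptides[c("g1", "g2")]), c(2L, 1L))
  q_unique <- genus_abundance_topn(
    ev, idx, tree, genus_quant_params(top_n = 1, pool = "unique-only"))
  expect_equal(unname(q_unique$n_peptides[c("g1", "g2")]), c(1L, 0L))
})

test_that("top-N abundance matches the full-sort oracle on random tables", {
  cfg <- simulation_config(seed = 11, n_phyla = 2, genera_per_phylum = 2,
                           species_per_genus = 2, proteins_per_species = 2,
                           protein_length_mean = 120, protein_length_sd = 15,
                           cross_species_copy_prob = 0.5,
                           include_human_like_outgroup = FALSE)
  sim <- simulate_dataset(cfg)
  all_peps <- index_peptides(sim$index)
  withr::with_seed(303, {
    for (i in 1:10) {
      peps <- sample(all_peps, min(60, length(all_peps)))
      m <- matrix(stats::rexp(length(peps) * 2) *
                    stats::rbinom(length(peps) * 2, 1, 0.8),
                  ncol = 2, dimnames = list(NULL, c("S1", "S2")))
      ev <- evidence_table(peps, m)
      top_n <- sample(2:6, 1)
      q <- genus_abundance_topn(ev, sim$index, sim$tree,
                                genus_quant_params(top_n = top_n))
      orc <- oracle_genus_abundance(ev, sim$index, sim$tree, top_n)
      expect_setequal(rownames(q$abundance), names(orc$abundance))
      expect_equal(unname(q$n_peptides[names(orc$pool_n)]),
                   unname(orc$pool_n))
      for (g in names(orc$abundance)) {
        expect_equal(q$abundance[g, ], orc$abundance[[g]])
      }
    }
  })
})

test_that("abundances scale linearly and never shrink when the pool grows", {
  q1 <- one_genus_quant(12, 1:12)
  for (cc in c(0.5, 3)) {
    qc <- one_genus_quant(12, cc * (1:12))
    expect_equal(qc$abundance, cc * q1$abundance)
  }
  # adding a peptide to the pool never decreases abundance
  q_plus <- one_genus_quant(13, c(1:12, 6))
  expect_gte(q_plus$abundance["g1", "S1"], q1$abundance["g1", "S1"])
})

test_that("state comparisons recover ratios and flag missing genera", {
  tree <- toy_tree()
  peps <- vapply(900:911, make_pep, character(1))
  db <- toy_db("P1", "s1", list(peps), tree = tree)
  idx <- build_peptide_index(db)
  base <- as.numeric(1:12)
  m <- cbind(A1 = base, A2 = base, B1 = base / 2, B2 = base / 2)
  ev <- evidence_table(peps, m)
  q <- genus_abundance_topn(ev, idx, tree)
  grouping <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  fc <- fold_change_between_states(q, grouping)
  expect_equal(fc$ratio[fc$genus == "g1"], 2)
  # identical states give ratio 1
  fc1 <- fold_change_between_states(q, c(A1 = "X", A2 = "Y"))
  expect_equal(fc1$ratio[fc1$genus == "g1"], 1)
  expect_error(fold_change_between_states(q, c(A1 = "A")), "at least one")
  # a genus absent in one state is flagged not-evaluable
  m0 <- cbind(A1 = base, B1 = rep(0, 12))
  q0 <- genus_abundance_topn(evidence_table(peps, m0), idx, tree)
  fc0 <- fold_change_between_states(q0, c(A1 = "A", B1 = "B"))
  expect_false(fc0$evaluable[fc0$genus == "g1"])
  expect_true(is.na(fc0$ratio[fc0$genus == "g1"]))
})

test_that("core membership histogram counts donors per protein", {
  pres <- rbind(d1 = c(p1 = TRUE, p2 = TRUE, p3 = FALSE),
                d2 = c(p1 = TRUE, p2 = FALSE, p3 = TRUE))
  colnames(pres) <- c("p1", "p2", "p3")
  out <- core_membership_histogram(pres)
  expect_equal(out$histogram, c(`1` = 2L, `2` = 1L))
  expect_identical(out$core, "p1")
  expect_equal(out$n_detected, 3L)
  expect_equal(unname(out$percent), c(200 / 3, 100 / 3))
  # single donor: everything in bin 1
  one <- core_membership_histogram(pres[1, , drop = FALSE])
  expect_equal(one$histogram, c(`1` = 2L))
  expect_setequal(one$core, c("p1", "p2"))
  expect_error(core_membership_histogram(pres[, 0]), "at least one")
})

test_that("cumulative abundance fraction is monotone and exact", {
  ab <- c(a = 8, b = 1, c = 1)
  expect_equal(cumulative_abundance_fraction(ab, 1), 0.8)
  expect_equal(cumulative_abundance_fraction(ab, 3), 1.0)
  expect_equal(cumulative_abundance_fraction(ab, 10), 1.0)
  eq <- stats::setNames(rep(2, 5), letters[1:5])
  for (k in 1:5) {
    expect_equal(cumulative_abundance_fraction(eq, k), k / 5)
  }
  fr <- vapply(1:3, cumulative_abundance_fraction, numeric(1),
               abundances = ab)
  expect_true(all(diff(fr) >= 0))
  expect_error(cumulative_abundance_fraction(c(a = 0, b = 0), 1), "zero")
})

test_that("bacterial fraction by rank tracks the running composition", {
  allh <- bacterial_fraction_by_rank(rep("human", 10))
  expect_true(all(allh$cumulative_pct == 0))
  allb <- bacterial_fraction_by_rank(rep("bacterial", 10))
  expect_true(all(allb$cumulative_pct == 100))
  alt <- bacterial_fraction_by_rank(rep(c("human", "bacterial"), 10))
  expect_true(all(alt$cumulative_pct[seq(2, 20, 2)] == 50))
  win <- bacterial_fraction_by_rank(rep(c("human", "bacterial"), 100),
                                    window = 100)
  expect_equal(win$windowed$pct_bacterial, c(50, 50))
  expect_error(bacterial_fraction_by_rank("viral"), "unknown origin")
})

test_that("within-sample Z-scoring standardizes every column", {
  m <- cbind(S1 = c(1, 3), S2 = c(10, 20))
  z <- zscore_within_sample(m)
  expect_equal(unname(z[, "S1"]), c(-1, 1))
  expect_equal(colMeans(z), c(S1 = 0, S2 = 0))
  expect_equal(apply(z, 2, function(v) sqrt(mean((v - mean(v))^2))),
               c(S1 = 1, S2 = 1))
  # idempotent on standardized input
  expect_equal(zscore_within_sample(z), z, tolerance = 1e-12)
  expect_error(zscore_within_sample(cbind(S1 = c(2, 2))), "S1")
})

test_that("log-scale R-squared matches the closed form and drops nonpositives", {
  expect_equal(pairwise_log_r2(c(1, 10, 100), c(1, 10, 100))$r2, 1)
  expect_equal(pairwise_log_r2(c(1, 10, 100), 2 * c(1, 10, 100))$r2, 1)
  # log10 pairs (0,1,2) vs (0,2,1): r = (1/3)/(2/3) = 0.5, r2 = 0.25
  expect_equal(pairwise_log_r2(c(1, 10, 100), c(1, 100, 10))$r2, 0.25)
  out <- pairwise_log_r2(c(1, 10, 100, 0), c(1, 10, 100, 5))
  expect_equal(out$n_used, 3L)
  expect_equal(out$n_dropped, 1L)
  expect_error(pairwise_log_r2(c(1, 2, 0), c(1, 2, 3)), "at least 3")
})
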