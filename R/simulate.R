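# Synthetic-data generator: balanced ranked taxonomies, multi-species
# protein databases with tunable within-genus sequence identity, and
# multi-sample log-normal intensity evidence with planted genus abundances.
# Everything is a pure function of (config, seed).

#' Simulation configuration
#'
#' Defaults describe a small two-state oral-microbiome-like study: a
#' bacterial taxonomy of `n_phyla * genera_per_phylum` genera with
#' `species_per_genus` species each plus a host-like outgroup under its own
#' superkingdom, `proteins_per_species` proteins of realistic tryptic
#' composition per species, within-genus sequence identity controlled by
#' `cross_species_copy_prob` (probability that a protein is a point-mutated
#' copy of a same-genus neighbor, planting genus-shared peptides), and two
#' sample states whose per-genus abundances differ by `fold_changes`
#' (state B = fold x state A). Peptide observation is Bernoulli with
#' `detection_prob` per sample; intensities carry multiplicative log-normal
#' noise with standard deviation `intensity_noise_sd` on the log scale.
#'
#' @param seed Integer seed; identical config + seed reproduce outputs
#'   exactly.
#' @param n_phyla,genera_per_phylum,species_per_genus Tree shape (all >= 1).
#' @param proteins_per_species Proteins simulated per species.
#' @param protein_length_mean,protein_length_sd Protein length distribution
#'   (amino acids; lengths are truncated below at 50).
#' @param cross_species_copy_prob Probability a protein is a mutated copy of
#'   a same-genus neighbor species' protein.
#' @param point_mutation_rate Per-residue substitution probability in copies.
#' @param include_human_like_outgroup Add a host branch (own superkingdom,
#'   phylum, genus, species) so host-vs-bacteria sharing is exercised.
#' @param base_abundance Optional named vector of state-A genus abundances
#'   (MS-intensity scale); default drawn log-normally around 1e9.
#' @param fold_changes Optional named vector (genus -> positive ratio);
#'   default 1 for every genus.
#' @param samples_per_state Samples simulated per state.
#' @param detection_prob Probability a pool peptide is observed in a sample.
#' @param intensity_noise_sd Log-normal noise sd (log scale); 0 = noiseless.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(seed = 1L,
                              n_phyla = 3L,
                              genera_per_phylum = 3L,
                              species_per_genus = 2L,
                              proteins_per_species = 12L,
                              protein_length_mean = 300,
                              protein_length_sd = 60,
                              cross_species_copy_prob = 0.3,
                              point_mutation_rate = 0.02,
                              include_human_like_outgroup = TRUE,
                              base_abundance = NULL,
                              fold_changes = NULL,
                              samples_per_state = 4L,
                              detection_prob = 0.9,
                              intensity_noise_sd = 0.2) {
  counts <- c(n_phyla, genera_per_phylum, species_per_genus,
              proteins_per_species, samples_per_state)
  if (any(counts < 1L)) stop("all counts must be >= 1")
  probs <- c(cross_species_copy_prob, point_mutation_rate, detection_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (!is.null(fold_changes) && any(fold_changes <= 0)) {
    stop("fold_changes must be positive")
  }
  if (intensity_noise_sd < 0) stop("intensity_noise_sd must be >= 0")
  seed <- as.integer(seed)
  if (is.na(seed) || abs(seed) > 2^31 - 10) stop("seed out of integer range")
  structure(
    list(seed = seed, n_phyla = as.integer(n_phyla),
         genera_per_phylum = as.integer(genera_per_phylum),
         species_per_genus = as.integer(species_per_genus),
         proteins_per_species = as.integer(proteins_per_species),
         protein_length_mean = protein_length_mean,
         protein_length_sd = protein_length_sd,
         cross_species_copy_prob = cross_species_copy_prob,
         point_mutation_rate = point_mutation_rate,
         include_human_like_outgroup = isTRUE(include_human_like_outgroup),
         base_abundance = base_abundance,
         fold_changes = fold_changes,
         samples_per_state = as.integer(samples_per_state),
         detection_prob = detection_prob,
         intensity_noise_sd = intensity_noise_sd),
    class = "simulation_config")
}

sim_genus_ids <- function(config) {
  as.vector(t(outer(seq_len(config$n_phyla),
                    seq_len(config$genera_per_phylum),
                    function(p, g) sprintf("phy%02d_gen%02d", p, g))))
}

#' Simulate a balanced ranked taxonomy
#'
#' Bacterial phyla sit directly under the root (rank skipping, as real
#' taxonomies do); each phylum carries `genera_per_phylum` genera with
#' `species_per_genus` species. With the host outgroup enabled, a
#' superkingdom -> phylum -> genus -> species chain is added under the root,
#' so a host/bacteria peptide LCA is the root.
#'
#' @param config A [simulation_config()].
#' @return A `taxonomy_tree`.
#' @export
simulate_taxonomy <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rows <- list(data.frame(taxon_id = "root", parent_id = "", rank = "root",
                          name = "root", stringsAsFactors = FALSE))
  add <- function(id, parent, rank, name) {
    rows[[length(rows) + 1L]] <<- data.frame(
      taxon_id = id, parent_id = parent, rank = rank, name = name,
      stringsAsFactors = FALSE)
  }
  for (p in seq_len(config$n_phyla)) {
    pid <- sprintf("phy%02d", p)
    add(pid, "root", "phylum", sprintf("Phylum_%02d", p))
    for (g in seq_len(config$genera_per_phylum)) {
      gid <- sprintf("%s_gen%02d", pid, g)
      add(gid, pid, "genus", sprintf("Genus_%02d_%02d", p, g))
      for (s in seq_len(config$species_per_genus)) {
        sid <- sprintf("%s_sp%02d", gid, s)
        add(sid, gid, "species", sprintf("Species_%02d_%02d_%02d", p, g, s))
      }
    }
  }
  if (config$include_human_like_outgroup) {
    add("host_sk", "root", "superkingdom", "Eukaryota_like")
    add("host_phy", "host_sk", "phylum", "Chordata_like")
    add("host_gen", "host_phy", "genus", "Homo_like")
    add("host_sp", "host_gen", "species", "Host_sapiens_like")
  }
  load_taxonomy(do.call(rbind, rows))
}

# residue alphabet with K/R boosted so tryptic fragments average ~9 aa
sim_residue_freqs <- function() {
  aa <- setdiff(LETTERS, AMBIGUOUS_RESIDUES)
  p <- stats::setNames(rep((1 - 0.11) / (length(aa) - 2L), length(aa)), aa)
  p["K"] <- p["R"] <- 0.055
  p
}

random_protein <- function(len, freqs) {
  paste(sample(names(freqs), len, replace = TRUE, prob = freqs),
        collapse = "")
}

mutate_protein <- function(sequence, rate, freqs) {
  if (rate <= 0) return(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    alt <- setdiff(names(freqs), chars[i])
    chars[i] <- sample(alt, 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a multi-species protein database
#'
#' Each species receives `proteins_per_species` proteins. A protein is
#' either drawn i.i.d. from the tryptic-composition residue model, or (with
#' probability `cross_species_copy_prob`, when a same-genus neighbor species
#' already has proteins) a point-mutated copy of a random neighbor protein —
#' the mechanism that plants genus-shared peptides. The returned ground
#' truth records every copy event and the peptides shared by construction
#' (tryptic fragments surviving mutation unchanged).
#'
#' @param tree A `taxonomy_tree` from [simulate_taxonomy()].
#' @param config The same [simulation_config()].
#' @return List with `db` (a `sequence_db`) and `truth` (list:
#'   `copy_events` data.frame, `genus_shared_peptides`).
#' @export
simulate_database <- function(tree, config) {
  stopifnot(inherits(tree, "taxonomy_tree"),
            inherits(config, "simulation_config"))
  withr::with_seed(config$seed + 1L, {
    freqs <- sim_residue_freqs()
    species <- tree$nodes$taxon_id[tree$nodes$rank == "species"]
    host <- intersect(species, "host_sp")
    genus_of <- vapply(species, function(s) tree$parent[[s]], character(1))
    draw_len <- function() {
      max(50L, as.integer(round(stats::rnorm(
        1, config$protein_length_mean, config$protein_length_sd))))
    }
    recs <- list()
    proteins_of_species <- list()
    copy_events <- list()
    shared <- character(0)
    dparams <- digestion_params()
    for (sp in species) {
      sibs <- setdiff(species[genus_of == genus_of[[sp]]], c(sp, host))
      sibs <- sibs[vapply(sibs, function(x) {
        length(proteins_of_species[[x]]) > 0L
      }, logical(1))]
      seqs <- character(config$proteins_per_species)
      for (j in seq_len(config$proteins_per_species)) {
        acc <- sprintf("%s_PR%03d", toupper(sp), j)
        copied <- !(sp %in% host) && length(sibs) > 0L &&
          stats::runif(1) < config$cross_species_copy_prob
        if (copied) {
          src_sp <- if (length(sibs) == 1L) sibs else sample(sibs, 1L)
          src_i <- sample(length(proteins_of_species[[src_sp]]), 1L)
          src_seq <- proteins_of_species[[src_sp]][[src_i]]
          seqs[j] <- mutate_protein(src_seq, config$point_mutation_rate,
                                    freqs)
          shared <- c(shared, intersect(digest_protein(src_seq, dparams),
                                        digest_protein(seqs[j], dparams)))
          copy_events[[length(copy_events) + 1L]] <- data.frame(
            accession = acc,
            source_species = src_sp,
            genus = genus_of[[sp]],
            stringsAsFactors = FALSE)
        } else {
          seqs[j] <- random_protein(draw_len(), freqs)
        }
        recs[[length(recs) + 1L]] <- data.frame(
          accession = acc, sequence = seqs[j], taxon_id = sp,
          description = sprintf("simulated protein %d of %s", j,
                                tree$nodes[sp, "name"]),
          source_label = if (sp %in% host) "host" else "bacteria",
          stringsAsFactors = FALSE)
      }
      proteins_of_species[[sp]] <- seqs
    }
    db <- do.call(rbind, recs)
    rownames(db) <- NULL
    class(db) <- c("sequence_db", "data.frame")
    truth <- list(
      copy_events = if (length(copy_events)) {
        do.call(rbind, copy_events)
      } else {
        data.frame(accession = character(0), source_species = character(0),
                   genus = character(0))
      },
      genus_shared_peptides = sort(unique(shared)))
    list(db = db, truth = truth)
  })
}

#' Simulate a multi-sample, two-state evidence table
#'
#' Digests the database, assigns each distinct peptide to the genus of its
#' lexicographically first source protein, and generates per-sample
#' intensities: genus base abundance (state B scaled by the genus fold
#' change) x a fixed peptide-specific log-normal factor x multiplicative
#' log-normal noise, observed with probability `detection_prob` (zero
#' otherwise). Host peptides use a fixed host abundance with fold 1.
#'
#' @param db A `sequence_db` (typically from [simulate_database()]).
#' @param tree The `taxonomy_tree`.
#' @param config The [simulation_config()].
#' @return List with `evidence` (an `evidence_table`), `truth` (list:
#'   `sample_state`, `genus_abundance_a`, `fold_changes`, `peptide_genus`),
#'   and `index` (the `peptide_index` used).
#' @export
simulate_evidence <- function(db, tree, config) {
  stopifnot(inherits(db, "sequence_db"), inherits(tree, "taxonomy_tree"),
            inherits(config, "simulation_config"))
  index <- build_peptide_index(db, digestion_params())
  if (nrow(index$pairs) == 0L) stop("database digests to no peptides")
  withr::with_seed(config$seed + 2L, {
    genera <- sim_genus_ids(config)
    base <- config$base_abundance
    if (is.null(base)) {
      base <- stats::setNames(stats::rlnorm(length(genera), log(1e9), 1),
                              genera)
    } else if (is.null(names(base))) {
      base <- stats::setNames(rep_len(base, length(genera)), genera)
    }
    fold <- stats::setNames(rep(1, length(genera)), genera)
    if (!is.null(config$fold_changes)) {
      fc <- config$fold_changes
      if (is.null(names(fc))) {
        fold[] <- rep_len(fc, length(genera))
      } else {
        fold[names(fc)] <- fc
      }
    }
    if (config$include_human_like_outgroup) {
      base <- c(base, host_gen = 1e10)
      fold <- c(fold, host_gen = 1)
    }

    first_acc <- vapply(split(index$pairs$accession, index$pairs$peptide),
                        min, character(1))
    peptides <- names(first_acc)
    pep_genus <- vapply(unname(index$acc_taxon[first_acc]),
                        function(t) tree$parent[[t]], character(1))
    names(pep_genus) <- peptides
    pep_factor <- stats::setNames(stats::rlnorm(length(peptides), 0, 1),
                                  peptides)

    samples <- c(sprintf("A%d", seq_len(config$samples_per_state)),
                 sprintf("B%d", seq_len(config$samples_per_state)))
    state <- stats::setNames(rep(c("A", "B"),
                                 each = config$samples_per_state), samples)
    m <- matrix(0, length(peptides), length(samples),
                dimnames = list(peptides, samples))
    for (s in samples) {
      level <- base[pep_genus] * (if (state[[s]] == "B") fold[pep_genus]
                                  else 1)
      noise <- if (config$intensity_noise_sd > 0) {
        exp(stats::rnorm(length(peptides), 0, config$intensity_noise_sd))
      } else rep(1, length(peptides))
      det <- stats::runif(length(peptides)) < config$detection_prob
      m[, s] <- unname(level) * unname(pep_factor) * noise * det
    }
    acc_lists <- split(index$pairs$accession, index$pairs$peptide)[peptides]
    evidence <- evidence_table(peptides, m, acc_lists)
    truth <- list(sample_state = state,
                  genus_abundance_a = base,
                  fold_changes = fold,
                  peptide_genus = pep_genus)
    list(evidence = evidence, truth = truth, index = index)
  })
}

#' Simulate a complete dataset bundle
#'
#' Convenience wrapper chaining [simulate_taxonomy()], [simulate_database()]
#' and [simulate_evidence()].
#'
#' @param config A [simulation_config()].
#' @return List with `config`, `tree`, `db`, `index`, `evidence`, `truth`
#'   (database and evidence ground truths merged).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  tree <- simulate_taxonomy(config)
  dbres <- simulate_database(tree, config)
  evres <- simulate_evidence(dbres$db, tree, config)
  list(config = config, tree = tree, db = dbres$db, index = evres$index,
       evidence = evres$evidence,
       truth = c(dbres$truth, evres$truth))
}

#' Write a simulated dataset as a plain-text fixture bundle
#'
#' Emits `taxonomy.tsv`, `db.fasta`, `accession_map.tsv`, `evidence.tsv`,
#' `ground_truth.tsv` (per-genus planted state-A abundance and fold change)
#' and `config.json` into a directory.
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_taxonomy(sim$tree, file.path(dir, "taxonomy.tsv"))
  write_protein_database(sim$db, file.path(dir, "db.fasta"),
                         file.path(dir, "accession_map.tsv"))
  write_evidence(sim$evidence, file.path(dir, "evidence.tsv"))
  genera <- names(sim$truth$genus_abundance_a)
  utils::write.table(
    data.frame(genus = genera,
               base_abundance_state_a = unname(sim$truth$genus_abundance_a),
               fold_change = unname(sim$truth$fold_changes[genera])),
    file.path(dir, "ground_truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg <- unclass(cfg)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
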