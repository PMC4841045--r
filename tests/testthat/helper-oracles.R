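# Independent brute-force oracles and in-code fixture builders. The oracles
# deliberately re-derive results from first principles (substring
# enumeration, lineage materialization, full sorts) so they share no code
# path with the package implementations they check.

# ---- digestion oracle: enumerate every substring, keep cleavage-consistent
oracle_digest <- function(sequence, params) {
  if (!nzchar(sequence)) return(character(0))
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  site <- chars %in% params$cleavage_residues
  if (params$block_proline) site <- site & c(chars[-1] != "P", TRUE)
  res <- character(0)
  for (i in seq_len(n)) {
    if (i > 1 && !site[i - 1]) next
    for (j in i:n) {
      if (j < n && !site[j]) next
      internal <- if (j > i) sum(site[i:(j - 1)]) else 0L
      if (internal > params$max_missed_cleavages) next
      len <- j - i + 1L
      if (len < params$min_length) next
      if (!is.null(params$max_length) && len > params$max_length) next
      pep <- substr(sequence, i, j)
      if (grepl("[BJOUXZ]", pep)) next
      res <- c(res, pep)
    }
  }
  res
}

random_sequence <- function(max_len = 60) {
  alphabet <- c(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), "X", "U")
  w <- stats::setNames(rep(1, length(alphabet)), alphabet)
  w[c("K", "R")] <- 4    # frequent cleavage sites
  w[c("X", "U")] <- 0.3  # sprinkle ambiguous residues
  paste(sample(alphabet, sample.int(max_len, 1), replace = TRUE, prob = w),
        collapse = "")
}

# ---- taxonomy oracles: walk the raw parent table
oracle_lineage <- function(nodes, id) {
  parent <- stats::setNames(nodes$parent_id, nodes$taxon_id)
  ids <- id
  cur <- id
  while (nzchar(parent[[cur]])) {
    cur <- parent[[cur]]
    ids <- c(cur, ids)
  }
  ids
}

oracle_lca <- function(nodes, taxa) {
  lins <- lapply(taxa, oracle_lineage, nodes = nodes)
  common <- Reduce(intersect, lins)
  depth <- vapply(common, function(x) length(oracle_lineage(nodes, x)),
                  integer(1))
  common[which.max(depth)]
}

oracle_split_projection <- function(nodes, taxon, split_rank) {
  lin <- oracle_lineage(nodes, taxon)
  ords <- rank_order(nodes$rank[match(lin, nodes$taxon_id)])
  lin[max(which(ords <= rank_order(split_rank)))]
}

# random ranked tree with rank skipping: each new node hangs off any
# existing node of shallower rank
random_taxonomy <- function(n_nodes = 50) {
  nodes <- data.frame(taxon_id = "root", parent_id = "", rank = "root",
                      name = "root", stringsAsFactors = FALSE)
  ranks <- tax_ranks()
  for (i in seq_len(n_nodes - 1L)) {
    repeat {
      p <- sample.int(nrow(nodes), 1)
      po <- rank_order(nodes$rank[p])
      if (po < 7L) break
    }
    choices <- (po + 2L):8L # 1-based indexes of strictly deeper ranks
    r <- ranks[choices[sample.int(length(choices), 1)]]
    id <- sprintf("t%03d", i)
    nodes <- rbind(nodes, data.frame(taxon_id = id,
                                     parent_id = nodes$taxon_id[p],
                                     rank = r, name = id,
                                     stringsAsFactors = FALSE))
  }
  nodes
}

# ---- top-n oracle: rebuild pools from scratch and sort everything
oracle_genus_abundance <- function(evidence, index, tree, top_n,
                                   pool = "all-peptides") {
  nodes <- tree$nodes
  genera <- nodes$taxon_id[nodes$rank == "genus"]
  keys <- evidence$peptide
  res <- list(abundance = list(), pool_n = stats::setNames(
    integer(length(genera)), genera))
  for (g in genera) {
    in_pool <- character(0)
    for (p in keys) {
      acc <- index$pairs$accession[index$pairs$peptide == p]
      if (!length(acc)) next
      gg <- unique(vapply(unname(index$acc_taxon[acc]), function(t) {
        lin <- oracle_lineage(nodes, t)
        hit <- lin[nodes$rank[match(lin, nodes$taxon_id)] == "genus"]
        if (length(hit)) hit else NA_character_
      }, character(1)))
      gg <- gg[!is.na(gg)]
      ok <- if (pool == "all-peptides") g %in% gg else identical(sort(gg), g)
      if (ok) in_pool <- c(in_pool, p)
    }
    res$pool_n[g] <- length(in_pool)
    if (length(in_pool) >= top_n) {
      ab <- vapply(colnames(evidence$intensity), function(s) {
        v <- evidence$intensity[in_pool, s]
        v <- v[v > 0]
        v <- v[order(-v, names(v))]
        sum(utils::head(v, top_n))
      }, numeric(1))
      res$abundance[[g]] <- ab
    }
  }
  res
}

# ---- fixture builders -------------------------------------------------------
# distinct tryptic 7-mers: six letters from a K/R-free alphabet plus "K"
make_pep <- function(i, tail = "K") {
  s <- c("A", "C", "D", "E", "F", "G", "H", "M", "N", "Q", "S", "T", "V",
         "W", "Y")
  out <- character(6)
  for (k in 6:1) {
    out[k] <- s[(i %% length(s)) + 1L]
    i <- i %/% length(s)
  }
  paste0(paste(out, collapse = ""), tail)
}

toy_tree <- function() {
  load_taxonomy(data.frame(
    taxon_id = c("root", "hsk", "hphy", "hgen", "hsp",
                 "p1", "p2", "g1", "g2", "g3", "s1", "s2", "s3", "s4"),
    parent_id = c("", "root", "hsk", "hphy", "hgen",
                  "root", "root", "p1", "p1", "p2", "g1", "g1", "g2", "g3"),
    rank = c("root", "superkingdom", "phylum", "genus", "species",
             "phylum", "phylum", "genus", "genus", "genus",
             "species", "species", "species", "species"),
    name = c("root", "HostSK", "HostPhylum", "HostGenus", "HostSpecies",
             "Phylum1", "Phylum2", "Genus1", "Genus2", "Genus3",
             "Species1", "Species2", "Species3", "Species4"),
    stringsAsFactors = FALSE))
}

# proteins given as lists of peptides; sequences are their concatenation
toy_db <- function(acc, taxon, peps, source = "bacteria", tree = toy_tree()) {
  sequence_db(
    accession = acc,
    sequence = vapply(peps, paste, character(1), collapse = ""),
    taxon_id = taxon, source_label = source, tree = tree)
}

make_evidence <- function(peptides, intensity) {
  if (is.null(dim(intensity))) {
    intensity <- matrix(intensity, ncol = 1,
                        dimnames = list(NULL, "S1"))
  }
  evidence_table(peptides, intensity)
}
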