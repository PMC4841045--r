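# Split-by-taxonomy protein grouping and LCA placement of observed peptides.
#
# The central guarantee: a peptide whose source proteins project to two or
# more different taxa at the split rank (phylum by default) is discarded from
# identification, so no protein group ever spans split-rank taxa and no
# peptide is attributed to an organism it does not necessarily come from.

#' Grouping / assignment parameter set
#'
#' @param split_rank Rank at which taxa must not be bridged by identification
#'   evidence (default `"phylum"`). Must lie strictly between root and
#'   species.
#' @param min_peptides_per_group Minimum identifying peptides for a protein
#'   group to be reported.
#' @param quantify_unique_only Restrict quantification to peptides unique to
#'   a single protein group (razor peptides are never used).
#' @return A `grouping_params` object.
#' @export
grouping_params <- function(split_rank = "phylum",
                            min_peptides_per_group = 1L,
                            quantify_unique_only = TRUE) {
  ro <- rank_order(split_rank)
  if (ro <= rank_order("root") || ro >= rank_order("species")) {
    stop("split_rank must lie strictly between root and species")
  }
  stopifnot(min_peptides_per_group >= 1L)
  structure(
    list(split_rank = split_rank,
         min_peptides_per_group = as.integer(min_peptides_per_group),
         quantify_unique_only = isTRUE(quantify_unique_only)),
    class = "grouping_params")
}

# split-rank projection for a vector of taxa, memoised
split_projection <- function(tree, taxa, split_rank) {
  vapply(taxa, function(t) ancestor_at_or_above_rank(tree, t, split_rank),
         character(1))
}

#' Assign observed peptides to taxonomy nodes by lowest common ancestor
#'
#' Each observed peptide that matches the index is annotated with its source
#' species, the LCA of those species, its projection set at the split rank,
#' and a status: `unique-to-one-split-taxon` when all source proteins project
#' to a single split-rank taxon, `cross-split-shared` otherwise.
#' Cross-split-shared peptides are the ones excluded from identification.
#' Peptides matching no database protein are reported in `$unmatched`, never
#' silently dropped.
#'
#' @param observed Character vector of observed peptide sequences.
#' @param index A `peptide_index` built on a taxon-annotated database.
#' @param tree The companion `taxonomy_tree`.
#' @param params A [grouping_params()] object.
#' @return A `peptide_assignment`: list with `table` (peptide, lca, lca_rank,
#'   n_taxa, n_split_taxa, status), `source_taxa` and `split_taxa` (named
#'   lists), `unmatched`, and the parameters used.
#' @export
assign_peptide_lca <- function(observed, index, tree,
                               params = grouping_params()) {
  stopifnot(inherits(index, "peptide_index"),
            inherits(tree, "taxonomy_tree"))
  if (anyNA(index$acc_taxon)) {
    stop("index was built on a database without taxon annotation")
  }
  check_taxon(tree, unique(index$acc_taxon))
  observed <- unique(as.character(observed))
  keys <- il_key(observed, index$params)
  acc_by_pep <- index_accessions(index, keys)
  matched_keys <- names(acc_by_pep)
  unmatched <- observed[!(keys %in% matched_keys)]

  source_taxa <- lapply(acc_by_pep, function(acc) {
    sort(unique(unname(index$acc_taxon[acc])))
  })

  # memoise per distinct taxon, then per distinct taxa-set
  all_taxa <- unique(unlist(source_taxa, use.names = FALSE))
  proj <- stats::setNames(
    split_projection(tree, all_taxa, params$split_rank), all_taxa)
  lca_memo <- new.env(parent = emptyenv())
  lca_of <- function(taxa) {
    key <- paste(taxa, collapse = "\r")
    got <- lca_memo[[key]]
    if (is.null(got)) {
      got <- lowest_common_ancestor(tree, taxa)$taxon_id
      lca_memo[[key]] <- got
    }
    got
  }

  lca <- vapply(source_taxa, lca_of, character(1))
  split_taxa <- lapply(source_taxa, function(taxa) {
    sort(unique(unname(proj[taxa])))
  })
  n_split <- lengths(split_taxa)

  tab <- data.frame(
    peptide = matched_keys,
    lca = unname(lca),
    lca_rank = tree$nodes[unname(lca), "rank"],
    n_taxa = lengths(source_taxa),
    n_split_taxa = n_split,
    status = ifelse(n_split >= 2L, "cross-split-shared",
                    "unique-to-one-split-taxon"),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(
    list(table = tab, source_taxa = source_taxa, split_taxa = split_taxa,
         unmatched = unmatched, params = params),
    class = "peptide_assignment")
}

#' @export
print.peptide_assignment <- function(x, ...) {
  cat("peptide_assignment:", nrow(x$table), "matched peptides (",
      sum(x$table$status == "cross-split-shared"), "cross-split-shared ),",
      length(x$unmatched), "unmatched\n")
  invisible(x)
}

#' Attribute peptide counts to taxonomy nodes (taxonomy-tree report)
#'
#' Every matched peptide is counted once, at its LCA node; peptides shared
#' across superkingdoms land at the root and contribute nothing below it.
#' With pruning on, any genus (with its whole subtree) that has no peptide
#' attributed at the genus node or below is removed from the report; peptides
#' attributed inside a pruned subtree are listed in `pruned_peptides`, not
#' re-attributed upward.
#'
#' @param assignment A `peptide_assignment`.
#' @param tree The `taxonomy_tree` the assignment was computed on.
#' @param prune_genera_without_unique Remove genera lacking any
#'   genus-or-below attributed peptide (default `TRUE`).
#' @return A `taxon_peptide_tree`: list with `counts` (per-node data.frame
#'   with `attributed_count`), `genus_summary`, `pruned_genera`,
#'   `pruned_peptides`.
#' @export
build_taxon_peptide_tree <- function(assignment, tree,
                                     prune_genera_without_unique = TRUE) {
  stopifnot(inherits(assignment, "peptide_assignment"),
            inherits(tree, "taxonomy_tree"))
  lca <- assignment$table$lca
  counts <- table(factor(lca, levels = tree$nodes$taxon_id))
  nodes <- tree$nodes[c("taxon_id", "parent_id", "rank", "name")]
  nodes$attributed_count <- as.integer(counts[nodes$taxon_id])

  genera <- nodes$taxon_id[nodes$rank == "genus"]
  below <- lapply(stats::setNames(genera, genera),
                  function(g) descendant_ids(tree, g))
  genus_count <- vapply(below, function(ids) {
    sum(nodes$attributed_count[nodes$taxon_id %in% ids])
  }, integer(1))
  genus_summary <- data.frame(
    taxon_id = genera,
    name = nodes$name[match(genera, nodes$taxon_id)],
    n_attributed_at_or_below = unname(genus_count),
    has_unique = unname(genus_count > 0L),
    stringsAsFactors = FALSE)

  pruned_genera <- character(0)
  pruned_peptides <- character(0)
  if (isTRUE(prune_genera_without_unique)) {
    pruned_genera <- genera[genus_count == 0L]
    drop_ids <- unique(unlist(below[pruned_genera], use.names = FALSE))
    if (length(drop_ids)) {
      pruned_peptides <- assignment$table$peptide[lca %in% drop_ids]
      nodes <- nodes[!(nodes$taxon_id %in% drop_ids), , drop = FALSE]
    }
  }
  rownames(nodes) <- NULL
  structure(
    list(counts = nodes, genus_summary = genus_summary,
         pruned_genera = pruned_genera, pruned_peptides = pruned_peptides),
    class = "taxon_peptide_tree")
}

#' @export
print.taxon_peptide_tree <- function(x, ...) {
  cat("taxon_peptide_tree:", sum(x$counts$attributed_count),
      "peptides attributed over", nrow(x$counts), "nodes;",
      length(x$pruned_genera), "genera pruned\n")
  invisible(x)
}

#' Infer protein groups constrained to one split-rank taxon each
#'
#' Identification proceeds in five steps: (1) peptides shared across
#' split-rank taxa are discarded from the identifying set; (2) the remaining
#' peptide-to-protein map is partitioned by the proteins' split-rank taxon;
#' (3) within a partition, proteins with identical identifying-peptide sets
#' are merged, then any protein whose identifying set is a subset of a
#' larger group's set is subsumed into it (greedily, largest sets first,
#' ties broken lexicographically by leading accession); (4) groups with
#' fewer than `min_peptides_per_group` identifying peptides are dropped;
#' (5) unique peptides are those identifying exactly one surviving group.
#'
#' By construction no group spans split-rank taxa and no identifying peptide
#' projects to more than one split-rank taxon. The leading accession of a
#' group is its member with the most identifying peptides (lexicographic
#' tie-break).
#'
#' @param db The `sequence_db` the index was built on.
#' @param observed Character vector of observed peptides.
#' @param index A `peptide_index` over `db`.
#' @param tree The companion `taxonomy_tree`.
#' @param params A [grouping_params()] object.
#' @return A `protein_groups` object: `summary` data.frame (group_id,
#'   leading_accession, members, split_taxon, n_identifying, n_unique) plus
#'   `groups`, a list with per-group accession and peptide sets, and the
#'   underlying `assignment`.
#' @export
group_proteins_split_by_taxonomy <- function(db, observed, index, tree,
                                             params = grouping_params()) {
  assignment <- assign_peptide_lca(observed, index, tree, params)
  keep <- assignment$table$peptide[
    assignment$table$status == "unique-to-one-split-taxon"]
  pairs <- index$pairs[index$pairs$peptide %in% keep, , drop = FALSE]

  groups <- list()
  if (nrow(pairs)) {
    pepsets <- lapply(split(pairs$peptide, pairs$accession), sort)
    accs <- names(pepsets)
    acc_split <- split_projection(tree, unname(index$acc_taxon[accs]),
                                  params$split_rank)
    for (taxon in sort(unique(acc_split))) {
      part <- accs[acc_split == taxon]
      sets <- pepsets[part]
      # (3a) merge identical identifying-peptide sets
      key <- vapply(sets, paste, character(1), collapse = "\r")
      merged <- lapply(split(part, key), sort)
      uniq_keys <- names(merged)
      gsets <- lapply(strsplit(uniq_keys, "\r", fixed = TRUE), identity)
      sizes <- lengths(gsets)
      lead0 <- vapply(merged, `[`, character(1), 1L)
      ord <- order(-sizes, lead0)
      gsets <- gsets[ord]; members <- merged[ord]
      # (3b) greedy subset subsumption into the first covering larger group
      n <- length(gsets)
      alive <- rep(TRUE, n)
      if (n > 1L) {
        for (i in 2:n) {
          for (j in seq_len(i - 1L)) {
            if (alive[j] && length(gsets[[i]]) < length(gsets[[j]]) + 1L &&
                all(gsets[[i]] %in% gsets[[j]])) {
              members[[j]] <- sort(union(members[[j]], members[[i]]))
              alive[i] <- FALSE
              break
            }
          }
        }
      }
      for (i in which(alive)) {
        groups[[length(groups) + 1L]] <- list(
          split_taxon = taxon,
          members = members[[i]],
          identifying_peptides = gsets[[i]])
      }
    }
  }

  # (4) minimum identifying-peptide filter
  groups <- Filter(function(g) {
    length(g$identifying_peptides) >= params$min_peptides_per_group
  }, groups)

  # (5) unique peptides: identifying exactly one surviving group
  pep_tally <- table(unlist(lapply(groups, `[[`, "identifying_peptides"),
                            use.names = FALSE))
  n_ident_per_acc <- table(pairs$accession)
  groups <- lapply(groups, function(g) {
    g$unique_peptides <- g$identifying_peptides[
      pep_tally[g$identifying_peptides] == 1L]
    cnt <- as.integer(n_ident_per_acc[g$members])
    g$leading_accession <- g$members[order(-cnt, g$members)][1L]
    g
  })

  if (length(groups)) {
    ord <- order(vapply(groups, `[[`, character(1), "split_taxon"),
                 -vapply(groups, function(g) length(g$identifying_peptides),
                         integer(1)),
                 vapply(groups, `[[`, character(1), "leading_accession"))
    groups <- groups[ord]
  }
  ids <- sprintf("G%04d", seq_along(groups))
  for (i in seq_along(groups)) groups[[i]]$group_id <- ids[i]

  summary <- data.frame(
    group_id = ids,
    leading_accession = vapply(groups, `[[`, character(1),
                               "leading_accession"),
    members = vapply(groups, function(g) paste(g$members, collapse = ";"),
                     character(1)),
    split_taxon = vapply(groups, `[[`, character(1), "split_taxon"),
    n_identifying = vapply(groups, function(g) length(g$identifying_peptides),
                           integer(1)),
    n_unique = vapply(groups, function(g) length(g$unique_peptides),
                      integer(1)),
    stringsAsFactors = FALSE)
  structure(
    list(summary = summary, groups = groups, assignment = assignment,
         params = params),
    class = "protein_groups")
}

#' @export
print.protein_groups <- function(x, ...) {
  cat("protein_groups:", nrow(x$summary), "groups across",
      length(unique(x$summary$split_taxon)), "split-rank taxa\n")
  invisible(x)
}
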