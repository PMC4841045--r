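# Ranked taxonomy model: flat node table in, lineage / rank-projection / LCA
# queries out. Ranks form a fixed total order; rank skipping along an edge is
# legal (phylum -> genus), rank inversion is not.

#' Recognized taxonomic ranks, shallowest to deepest
#'
#' The fixed rank order used throughout the package:
#' root, superkingdom, phylum, class, order, family, genus, species.
#'
#' @return Character vector of rank names in depth order.
#' @export
#' @examples
#' tax_ranks()
tax_ranks <- function() {
  c("root", "superkingdom", "phylum", "class", "order", "family",
    "genus", "species")
}

#' Position of a rank in the rank order
#'
#' @param rank Character vector of rank names.
#' @return Integer vector: 0 for root up to 7 for species.
#' @export
rank_order <- function(rank) {
  idx <- match(rank, tax_ranks())
  if (anyNA(idx)) {
    stop("unknown rank(s): ", paste(unique(rank[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

#' Load a taxonomy tree from a flat node table
#'
#' Reads a tab-separated table with columns `taxon_id`, `parent_id`, `rank`
#' and `name` (header required, UTF-8). Exactly one row must have an empty
#' `parent_id`: the root. The tree is validated: taxon ids unique, every
#' parent present, no cycles, and every child's rank strictly deeper than its
#' parent's (skipping ranks is allowed).
#'
#' @param path Path to the node TSV, or a `data.frame` with the same columns.
#' @return A `taxonomy_tree` object.
#' @export
#' @examples
#' nodes <- data.frame(
#'   taxon_id = c("r", "p1", "g1", "s1"),
#'   parent_id = c("", "r", "p1", "g1"),
#'   rank = c("root", "phylum", "genus", "species"),
#'   name = c("root", "Firmicutes-like", "GenusA", "Species a1"))
#' tree <- load_taxonomy(nodes)
#' lineage(tree, "s1")$name
load_taxonomy <- function(path) {
  nodes <- if (is.data.frame(path)) {
    path
  } else {
    utils::read.delim(path, colClasses = "character", check.names = FALSE,
                      encoding = "UTF-8")
  }
  required <- c("taxon_id", "parent_id", "rank", "name")
  missing <- setdiff(required, names(nodes))
  if (length(missing)) {
    stop("taxonomy table lacks column(s): ", paste(missing, collapse = ", "))
  }
  nodes <- nodes[required]
  nodes[] <- lapply(nodes, as.character)
  nodes$parent_id[is.na(nodes$parent_id)] <- ""
  new_taxonomy_tree(nodes)
}

new_taxonomy_tree <- function(nodes) {
  if (anyDuplicated(nodes$taxon_id)) {
    dup <- unique(nodes$taxon_id[duplicated(nodes$taxon_id)])
    stop("duplicate taxon_id: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(nodes$taxon_id))) stop("empty taxon_id")
  is_root <- !nzchar(nodes$parent_id)
  if (sum(is_root) == 0L) stop("no root row (empty parent_id) found")
  if (sum(is_root) > 1L) {
    stop("multiple roots: ", paste(nodes$taxon_id[is_root], collapse = ", "))
  }
  root <- nodes$taxon_id[is_root]
  ord <- rank_order(nodes$rank)
  parent <- stats::setNames(nodes$parent_id, nodes$taxon_id)
  known <- nodes$taxon_id
  bad_parent <- !is_root & !(nodes$parent_id %in% known)
  if (any(bad_parent)) {
    stop("unknown parent_id for taxon: ",
         paste(nodes$taxon_id[bad_parent], collapse = ", "))
  }
  pord <- stats::setNames(ord, nodes$taxon_id)
  viol <- !is_root & ord <= pord[nodes$parent_id]
  if (any(viol)) {
    stop("rank must be strictly deeper than the parent's for taxon: ",
         paste(nodes$taxon_id[viol], collapse = ", "))
  }
  # ranks strictly increase root -> leaf, so any parent chain must terminate;
  # still guard explicitly so malformed input fails with a clear message
  n <- nrow(nodes)
  for (id in nodes$taxon_id) {
    steps <- 0L
    cur <- id
    while (nzchar(parent[[cur]])) {
      cur <- parent[[cur]]
      steps <- steps + 1L
      if (steps > n) stop("cycle detected involving taxon ", id)
    }
    if (cur != root) stop("taxon ", id, " is not connected to the root")
  }
  nodes$rank_order <- ord
  rownames(nodes) <- nodes$taxon_id
  structure(
    list(nodes = nodes, root = root, parent = parent,
         lineage_cache = new.env(parent = emptyenv())),
    class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  tab <- table(factor(x$nodes$rank, levels = tax_ranks()))
  cat("taxonomy_tree:", nrow(x$nodes), "nodes, root =", x$root, "\n")
  tab <- tab[tab > 0]
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

check_taxon <- function(tree, taxon) {
  unknown <- setdiff(taxon, tree$nodes$taxon_id)
  if (length(unknown)) {
    stop("unknown taxon id(s): ", paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

lineage_ids <- function(tree, taxon) {
  cached <- tree$lineage_cache[[taxon]]
  if (!is.null(cached)) return(cached)
  ids <- taxon
  cur <- taxon
  while (nzchar(tree$parent[[cur]])) {
    cur <- tree$parent[[cur]]
    ids <- c(cur, ids)
  }
  tree$lineage_cache[[taxon]] <- ids
  ids
}

#' Lineage of a taxon, root first
#'
#' @param tree A `taxonomy_tree`.
#' @param taxon A single taxon id present in the tree.
#' @return A `data.frame` of nodes (`taxon_id`, `parent_id`, `rank`, `name`,
#'   `rank_order`), ordered root first, ending at the queried taxon.
#' @export
lineage <- function(tree, taxon) {
  stopifnot(inherits(tree, "taxonomy_tree"), length(taxon) == 1L)
  check_taxon(tree, taxon)
  ids <- lineage_ids(tree, taxon)
  out <- tree$nodes[ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node lying on every queried taxon's root-to-node lineage.
#' `lowest_common_ancestor(tree, t)` is `t` itself; taxa whose lineages only
#' meet at the root (e.g. a host and a bacterial species placed under
#' different superkingdoms) yield the root.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxa Nonempty character vector of taxon ids.
#' @return A one-row `data.frame` describing the LCA node.
#' @export
lowest_common_ancestor <- function(tree, taxa) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("taxa must be a nonempty set of taxon ids")
  check_taxon(tree, taxa)
  common <- lineage_ids(tree, taxa[[1L]])
  for (t in taxa[-1L]) {
    lin <- lineage_ids(tree, t)
    # lineages in a tree share a root-anchored prefix
    k <- min(length(common), length(lin))
    same <- common[seq_len(k)] == lin[seq_len(k)]
    prefix <- if (all(same)) k else which(!same)[1L] - 1L
    common <- common[seq_len(prefix)]
  }
  node <- tree$nodes[common[length(common)], , drop = FALSE]
  rownames(node) <- NULL
  node
}

#' Project a taxon onto an ancestor of a given rank
#'
#' Returns the unique lineage node carrying `rank`, or `NULL` when the
#' lineage skips that rank or the taxon itself sits above it.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxon A single taxon id.
#' @param rank A rank name (see [tax_ranks()]).
#' @return A one-row `data.frame`, or `NULL`.
#' @export
ancestor_at_rank <- function(tree, taxon, rank) {
  stopifnot(length(rank) == 1L)
  rank_order(rank) # validates
  lin <- lineage(tree, taxon)
  hit <- lin[lin$rank == rank, , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  hit
}

# Deepest lineage node at or above `rank` (used for split-rank projection:
# lineages that skip the split rank project to the boundary node instead).
ancestor_at_or_above_rank <- function(tree, taxon, rank) {
  ro <- rank_order(rank)
  ids <- lineage_ids(tree, taxon)
  ords <- tree$nodes[ids, "rank_order"]
  ids[max(which(ords <= ro))]
}

descendant_ids <- function(tree, taxon) {
  kids <- split(tree$nodes$taxon_id, tree$nodes$parent_id)
  out <- character(0)
  frontier <- taxon
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  out
}

# ---- Newick serialization ---------------------------------------------------
# Ranked taxonomies contain unary internal nodes (root -> superkingdom ->
# phylum chains), which the common phylo representation cannot hold, so the
# (tiny) Newick writer/reader lives here. Node names become labels; ranks are
# not part of Newick and must be re-supplied on read.

newick_quote <- function(label) {
  needs <- grepl("[\\s()\\[\\]',;:]", label, perl = TRUE)
  label[needs] <- paste0("'", gsub("'", "''", label[needs]), "'")
  label
}

#' Serialize a taxonomy tree to a Newick string
#'
#' Node display names become Newick labels (quoted where necessary); unary
#' internal nodes are preserved.
#'
#' @param tree A `taxonomy_tree`.
#' @param path Optional file path; when given the string is also written out.
#' @return The Newick string, invisibly when `path` is given.
#' @export
taxonomy_to_newick <- function(tree, path = NULL) {
  kids <- split(tree$nodes$taxon_id, tree$nodes$parent_id)
  kids <- lapply(kids, sort)
  name_of <- stats::setNames(tree$nodes$name, tree$nodes$taxon_id)
  recurse <- function(id) {
    lab <- newick_quote(name_of[[id]])
    ch <- kids[[id]]
    if (is.null(ch)) return(lab)
    paste0("(", paste(vapply(ch, recurse, character(1)), collapse = ","),
           ")", lab)
  }
  nwk <- paste0(recurse(tree$root), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Rebuild a taxonomy tree from a Newick string
#'
#' Inverse of [taxonomy_to_newick()] for round-tripping. Newick carries no
#' rank information, so ranks are re-supplied through `rank_map` (node name ->
#' rank). Taxon ids are taken equal to node names.
#'
#' @param newick A Newick string (or path to a file containing one).
#' @param rank_map Named character vector mapping node names to ranks.
#' @return A `taxonomy_tree`.
#' @export
taxonomy_from_newick <- function(newick, rank_map) {
  if (file.exists(newick)) newick <- paste(readLines(newick), collapse = "")
  s <- sub(";\\s*$", "", trimws(newick))
  pos <- 1L
  n <- nchar(s)
  peek <- function() substr(s, pos, pos)
  read_label <- function() {
    if (peek() == "'") {
      out <- ""
      pos <<- pos + 1L
      repeat {
        ch <- peek()
        if (ch == "'") {
          if (substr(s, pos + 1L, pos + 1L) == "'") {
            out <- paste0(out, "'"); pos <<- pos + 2L
          } else {
            pos <<- pos + 1L; break
          }
        } else {
          out <- paste0(out, ch); pos <<- pos + 1L
        }
      }
      out
    } else {
      start <- pos
      while (pos <= n && !(peek() %in% c("(", ")", ",", ";"))) pos <<- pos + 1L
      substr(s, start, pos - 1L)
    }
  }
  parent_of <- character(0) # child name -> parent name
  parse_node <- function() {
    children <- character(0)
    if (peek() == "(") {
      pos <<- pos + 1L
      repeat {
        children <- c(children, parse_node())
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        stop("malformed Newick at position ", pos)
      }
    }
    name <- read_label()
    if (!nzchar(name)) stop("unlabeled Newick node is not supported")
    parent_of[children] <<- name
    name
  }
  root_name <- parse_node()
  all_names <- c(names(parent_of), root_name)
  nodes <- data.frame(
    taxon_id = all_names,
    parent_id = ifelse(all_names == root_name, "", parent_of[all_names]),
    stringsAsFactors = FALSE)
  missing <- setdiff(nodes$taxon_id, names(rank_map))
  if (length(missing)) {
    stop("rank_map lacks rank for node(s): ", paste(missing, collapse = ", "))
  }
  nodes$rank <- unname(rank_map[nodes$taxon_id])
  nodes$name <- nodes$taxon_id
  load_taxonomy(nodes[c("taxon_id", "parent_id", "rank", "name")])
}

#' Write a taxonomy tree back to a flat node TSV
#'
#' @param tree A `taxonomy_tree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(tree, path) {
  utils::write.table(
    tree$nodes[c("taxon_id", "parent_id", "rank", "name")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
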