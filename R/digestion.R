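# In-silico proteolytic digestion, nonredundant peptide indexing and
# cross-database shared-peptide overlap.

AMBIGUOUS_RESIDUES <- c("B", "J", "O", "U", "X", "Z")

#' Digestion parameter set
#'
#' Defaults follow common shotgun metaproteomics practice: cleavage
#' C-terminal to K/R (trypsin + LysC), cleavage before proline allowed, up to
#' two missed cleavages, minimum peptide length seven residues.
#' `block_proline = TRUE` restores classical trypsin specificity (no cleavage
#' when the next residue is P). `equate_il` collapses isoleucine to leucine
#' when peptides are keyed in an index, since MS cannot distinguish them.
#'
#' @param cleavage_residues Residues after which the protease cuts.
#' @param block_proline Suppress cleavage when the following residue is P.
#' @param max_missed_cleavages Maximum internal uncleaved sites per peptide.
#' @param min_length Minimum peptide length in residues.
#' @param max_length Optional maximum peptide length.
#' @param equate_il Treat I and L as the same residue when indexing.
#' @return A `digestion_params` object.
#' @export
digestion_params <- function(cleavage_residues = c("K", "R"),
                             block_proline = FALSE,
                             max_missed_cleavages = 2L,
                             min_length = 7L,
                             max_length = NULL,
                             equate_il = FALSE) {
  stopifnot(length(cleavage_residues) >= 1L,
            max_missed_cleavages >= 0L, min_length >= 1L)
  if (!is.null(max_length) && max_length < min_length) {
    stop("max_length must be >= min_length")
  }
  structure(
    list(cleavage_residues = toupper(cleavage_residues),
         block_proline = isTRUE(block_proline),
         max_missed_cleavages = as.integer(max_missed_cleavages),
         min_length = as.integer(min_length),
         max_length = if (is.null(max_length)) NULL else as.integer(max_length),
         equate_il = isTRUE(equate_il)),
    class = "digestion_params")
}

same_digestion_params <- function(a, b) {
  identical(unclass(a), unclass(b))
}

il_key <- function(peptide, params) {
  if (isTRUE(params$equate_il)) chartr("I", "L", peptide) else peptide
}

#' Digest one protein sequence in silico
#'
#' Enumerates all cleavage-consistent fragments with 0 to
#' `max_missed_cleavages` internal cleavage sites, N- to C-terminal, then
#' applies the length filter and removes peptides containing ambiguous
#' residues (B, J, O, U, X, Z). Fragments arising at distinct positions are
#' all returned; they collapse to one entry when indexed.
#'
#' @param sequence Uppercase amino-acid string; the empty string digests to
#'   an empty set.
#' @param params A [digestion_params()] object.
#' @return Character vector of peptides.
#' @export
#' @examples
#' digest_protein("AAAAAAKGGGGGGRLLLLLLL")
digest_protein <- function(sequence, params = digestion_params()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (is.na(sequence) || !nzchar(sequence)) return(character(0))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  site <- chars %in% params$cleavage_residues
  if (params$block_proline && n > 1L) {
    site <- site & c(chars[-1L] != "P", TRUE)
  }
  cut_after <- which(site[-n]) # a terminal K/R is not an internal boundary
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  k <- length(starts)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    j <- i:min(k, i + params$max_missed_cleavages)
    len <- ends[j] - starts[i] + 1L
    keep <- len >= params$min_length
    if (!is.null(params$max_length)) keep <- keep & len <= params$max_length
    stop_at <- ends[j][keep]
    out[[i]] <- if (length(stop_at)) {
      substring(sequence, rep.int(starts[i], length(stop_at)), stop_at)
    } else character(0)
  }
  peps <- unlist(out, use.names = FALSE)
  peps[!grepl(paste0("[", paste(AMBIGUOUS_RESIDUES, collapse = ""), "]"),
              peps)]
}

#' Build a nonredundant peptide index over a database
#'
#' Digests every protein and maps each distinct peptide sequence to the set
#' of accessions whose digestion yields it. With `equate_il` set in `params`,
#' I is collapsed to L before keying.
#'
#' @param db A `sequence_db`.
#' @param params A [digestion_params()] object.
#' @return A `peptide_index` holding peptide/accession pairs plus taxon and
#'   source-label lookups.
#' @export
build_peptide_index <- function(db, params = digestion_params()) {
  stopifnot(inherits(db, "sequence_db"))
  per_prot <- lapply(db$sequence, digest_protein, params = params)
  counts <- lengths(per_prot)
  pairs <- data.frame(
    peptide = il_key(as.character(unlist(per_prot, use.names = FALSE)),
                     params),
    accession = rep(db$accession, counts),
    stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  pairs <- pairs[order(pairs$peptide, pairs$accession), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(pairs = pairs,
         params = params,
         acc_taxon = stats::setNames(db$taxon_id, db$accession),
         acc_source = stats::setNames(db$source_label, db$accession)),
    class = "peptide_index")
}

#' Distinct peptide keys of an index
#' @param index A `peptide_index`.
#' @return Character vector of nonredundant peptides.
#' @export
index_peptides <- function(index) {
  unique(index$pairs$peptide)
}

# accessions matching a set of (already IL-keyed) peptides, as a named list
index_accessions <- function(index, peptides) {
  sub <- index$pairs[index$pairs$peptide %in% peptides, , drop = FALSE]
  split(sub$accession, sub$peptide)
}

#' @export
print.peptide_index <- function(x, ...) {
  cat("peptide_index:", length(index_peptides(x)), "nonredundant peptides,",
      length(unique(x$pairs$accession)), "proteins",
      if (x$params$equate_il) "(I/L equated)" else "", "\n")
  invisible(x)
}

#' Shared-peptide overlap between two peptide indexes
#'
#' Exact set arithmetic on peptide keys. The shared percentage uses the union
#' of both nonredundant peptide sets as denominator, i.e.
#' `100 * n_shared / (n_a + n_b - n_shared)`.
#'
#' @param index_a,index_b `peptide_index` objects built with identical
#'   parameters.
#' @return An `overlap_summary`: list with `n_a`, `n_b`, `n_shared`, `union`,
#'   `pct_shared`.
#' @export
shared_peptide_fraction <- function(index_a, index_b) {
  if (!same_digestion_params(index_a$params, index_b$params)) {
    stop("indexes were built with different digestion parameters")
  }
  a <- index_peptides(index_a)
  b <- index_peptides(index_b)
  n_shared <- length(intersect(a, b))
  un <- length(a) + length(b) - n_shared
  structure(
    list(n_a = length(a), n_b = length(b), n_shared = n_shared,
         union = un,
         pct_shared = if (un == 0L) 0 else 100 * n_shared / un),
    class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(sprintf("overlap: %d vs %d peptides, %d shared (%.3f%% of union %d)\n",
              x$n_a, x$n_b, x$n_shared, x$pct_shared, x$union))
  invisible(x)
}

#' Pairwise shared-peptide matrix over several databases
#'
#' @param dbs Named list of `sequence_db` objects (at least two).
#' @param params A [digestion_params()] object applied to all databases.
#' @return Symmetric numeric matrix of `pct_shared` values (diagonal 100);
#'   the full `overlap_summary` objects are attached as attribute
#'   `"summaries"` (a list keyed `"a|b"`).
#' @export
pairwise_overlap_matrix <- function(dbs, params = digestion_params()) {
  if (length(dbs) < 2L) stop("need at least two databases")
  if (is.null(names(dbs)) || any(!nzchar(names(dbs)))) {
    names(dbs) <- paste0("db", seq_along(dbs))
  }
  idx <- lapply(dbs, build_peptide_index, params = params)
  nms <- names(dbs)
  m <- matrix(100, length(dbs), length(dbs), dimnames = list(nms, nms))
  summaries <- list()
  for (i in seq_along(dbs)) {
    for (j in seq_along(dbs)) {
      if (j <= i) next
      ov <- shared_peptide_fraction(idx[[i]], idx[[j]])
      m[i, j] <- m[j, i] <- ov$pct_shared
      summaries[[paste(nms[i], nms[j], sep = "|")]] <- ov
    }
  }
  attr(m, "summaries") <- summaries
  m
}
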