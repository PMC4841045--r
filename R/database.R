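# Multi-organism protein sequence databases: FASTA + accession->taxon map in,
# validated record table out. FASTA I/O goes through Biostrings.

#' Read a multi-organism protein database
#'
#' Reads one or more FASTA files, attaches a source label per file, resolves
#' each record to a species-level taxon and validates the result. Accessions
#' are the first header token; the UniProt `db|ACC|NAME` dialect is
#' recognized, and a `OX=<taxon>` header field is used as taxon fallback
#' when an accession is absent from `taxon_map` (the map takes precedence).
#'
#' @param fasta_paths Character vector of FASTA paths. Names, when present,
#'   become the per-file source labels (default: file base name).
#' @param taxon_map Path to a TSV with columns `accession`, `taxon_id`, or a
#'   `data.frame` with those columns, or `NULL` to rely on `OX=` fields only.
#' @param tree A `taxonomy_tree` used to validate taxon ids, or `NULL` to
#'   skip taxon resolution entirely (sequence-only workflows such as
#'   cross-database overlap analysis).
#' @return A `sequence_db`: data.frame with columns `accession`, `sequence`,
#'   `taxon_id`, `description`, `source_label`.
#' @export
read_protein_database <- function(fasta_paths, taxon_map = NULL, tree = NULL) {
  stopifnot(length(fasta_paths) >= 1L)
  labels <- names(fasta_paths)
  if (is.null(labels)) labels <- rep("", length(fasta_paths))
  blank <- !nzchar(labels)
  labels[blank] <- sub("\\.[^.]*$", "", basename(fasta_paths[blank]))

  recs <- lapply(seq_along(fasta_paths), function(i) {
    aa <- Biostrings::readAAStringSet(fasta_paths[[i]])
    header <- names(aa)
    first <- sub("\\s.*$", "", header)
    acc <- ifelse(grepl("^[^|]+\\|[^|]+\\|", first),
                  sub("^[^|]+\\|([^|]+)\\|.*$", "\\1", first), first)
    desc <- trimws(sub("^\\S+\\s*", "", header))
    ox <- ifelse(grepl("\\bOX=(\\S+)", header),
                 sub(".*\\bOX=(\\S+).*", "\\1", header), NA_character_)
    data.frame(accession = acc, sequence = toupper(as.character(aa)),
               description = desc, ox = ox, source_label = labels[[i]],
               stringsAsFactors = FALSE)
  })
  db <- do.call(rbind, recs)

  if (anyDuplicated(db$accession)) {
    dup <- unique(db$accession[duplicated(db$accession)])
    stop("duplicate accession(s) across input FASTA files: ",
         paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(!nzchar(db$sequence))) {
    stop("empty sequence for accession(s): ",
         paste(db$accession[!nzchar(db$sequence)], collapse = ", "))
  }

  if (!is.null(tree)) {
    map <- NULL
    if (!is.null(taxon_map)) {
      map <- if (is.data.frame(taxon_map)) taxon_map else {
        utils::read.delim(taxon_map, colClasses = "character",
                          check.names = FALSE)
      }
      if (!all(c("accession", "taxon_id") %in% names(map))) {
        stop("taxon_map needs columns accession, taxon_id")
      }
      if (anyDuplicated(map$accession)) stop("duplicate accession in taxon_map")
    }
    taxon <- if (is.null(map)) rep(NA_character_, nrow(db)) else {
      map$taxon_id[match(db$accession, map$accession)]
    }
    taxon[is.na(taxon)] <- db$ox[is.na(taxon)]
    if (anyNA(taxon)) {
      stop("no taxon for accession(s) (absent from map, no OX= field): ",
           paste(utils::head(db$accession[is.na(taxon)], 5), collapse = ", "))
    }
    check_taxon(tree, unique(taxon))
    db$taxon_id <- taxon
  } else {
    db$taxon_id <- NA_character_
  }

  db <- db[c("accession", "sequence", "taxon_id", "description",
             "source_label")]
  rownames(db) <- NULL
  class(db) <- c("sequence_db", "data.frame")
  db
}

#' Construct a sequence database from vectors
#'
#' Programmatic counterpart of [read_protein_database()] with the same
#' validation; handy for building databases in code.
#'
#' @param accession Unique accession strings.
#' @param sequence Amino-acid sequences (uppercased on construction).
#' @param taxon_id Species-level taxon ids (may be `NA` when no `tree`).
#' @param description Free-text descriptions.
#' @param source_label Source-database tag per record.
#' @param tree Optional `taxonomy_tree` used to validate `taxon_id`.
#' @return A `sequence_db`.
#' @export
sequence_db <- function(accession, sequence, taxon_id = NA_character_,
                        description = "", source_label = "db",
                        tree = NULL) {
  n <- length(accession)
  db <- data.frame(accession = as.character(accession),
                   sequence = toupper(as.character(sequence)),
                   taxon_id = rep_len(as.character(taxon_id), n),
                   description = rep_len(as.character(description), n),
                   source_label = rep_len(as.character(source_label), n),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(db$accession)) stop("duplicate accession")
  if (any(!nzchar(db$sequence))) stop("empty sequence")
  if (!is.null(tree)) check_taxon(tree, unique(db$taxon_id))
  class(db) <- c("sequence_db", "data.frame")
  db
}

#' Write a sequence database to FASTA (plus optional accession map)
#'
#' Headers take the form `>ACC description OX=taxon`; reading the file back
#' with [read_protein_database()] reproduces accessions, sequences and taxa.
#'
#' @param db A `sequence_db`.
#' @param fasta_path Output FASTA path.
#' @param map_path Optional path for an accession -> taxon TSV.
#' @return `fasta_path`, invisibly.
#' @export
write_protein_database <- function(db, fasta_path, map_path = NULL) {
  aa <- Biostrings::AAStringSet(db$sequence)
  ox <- ifelse(is.na(db$taxon_id), "", paste0(" OX=", db$taxon_id))
  desc <- ifelse(nzchar(db$description), paste0(" ", db$description), "")
  names(aa) <- paste0(db$accession, desc, ox)
  Biostrings::writeXStringSet(aa, fasta_path, width = 60)
  if (!is.null(map_path)) {
    utils::write.table(
      data.frame(accession = db$accession, taxon_id = db$taxon_id),
      map_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}

#' @export
print.sequence_db <- function(x, ...) {
  cat("sequence_db:", nrow(x), "proteins,",
      length(unique(x$taxon_id[!is.na(x$taxon_id)])), "taxa,",
      "sources:", paste(unique(x$source_label), collapse = ", "), "\n")
  invisible(x)
}

keratin_pattern <- function() {
  # keratin type I and II entries are treated as skin-derived contaminants
  "keratin[, ]*type[ _-]*(II|I|1|2)\\b"
}

#' Remove contaminant accessions (optionally all type I/II keratins)
#'
#' Works on a `sequence_db` or an `evidence_table`. Records whose accession
#' is listed, or whose description matches "Keratin, type I/II"
#' (case-insensitive) when `drop_keratins` is set, are removed. Evidence rows
#' are removed when any matched accession is a contaminant. An empty list
#' with the flag off is the identity.
#'
#' @param x A `sequence_db` or `evidence_table`.
#' @param contaminants Character vector of contaminant accessions.
#' @param drop_keratins Also remove keratin type I/II records by description
#'   match (databases only).
#' @return The filtered object; a removal report data.frame (columns
#'   `reason`, `n`) is attached as attribute `"removal_report"`.
#' @export
filter_contaminant_accessions <- function(x, contaminants = character(0),
                                          drop_keratins = FALSE) {
  UseMethod("filter_contaminant_accessions")
}

#' @export
filter_contaminant_accessions.sequence_db <- function(
    x, contaminants = character(0), drop_keratins = FALSE) {
  listed <- x$accession %in% contaminants
  keratin <- if (drop_keratins) {
    grepl(keratin_pattern(), x$description, ignore.case = TRUE) & !listed
  } else rep(FALSE, nrow(x))
  out <- x[!(listed | keratin), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(x)
  attr(out, "removal_report") <- data.frame(
    reason = c("contaminant", "keratin"),
    n = c(sum(listed), sum(keratin)))
  out
}

#' @export
filter_contaminant_accessions.evidence_table <- function(
    x, contaminants = character(0), drop_keratins = FALSE) {
  if (drop_keratins) {
    warning("evidence tables carry no descriptions; drop_keratins ignored ",
            "(supply keratin accessions in `contaminants` instead)")
  }
  hit <- vapply(x$proteins, function(acc) any(acc %in% contaminants),
                logical(1))
  out <- x
  out$peptide <- x$peptide[!hit]
  out$proteins <- x$proteins[!hit]
  out$intensity <- x$intensity[!hit, , drop = FALSE]
  attr(out, "removal_report") <- data.frame(
    reason = "contaminant", n = sum(hit))
  out
}
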