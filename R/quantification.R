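# Evidence-table handling, top-N peptide-intensity genus abundance, state
# comparisons, and descriptive proteome summaries.

#' Construct an evidence table
#'
#' Rows with the same peptide sequence (e.g. charge states) are aggregated by
#' summing per-sample intensities. Zero intensity means "not observed in that
#' sample" and never occupies a top-N slot downstream.
#'
#' @param peptide Character vector of peptide sequences.
#' @param intensity Numeric matrix (rows parallel to `peptide`) with one
#'   column per sample; finite, nonnegative.
#' @param proteins Optional list (parallel to `peptide`) of matched
#'   accessions per row.
#' @return An `evidence_table`: list with `peptide`, `proteins`, `intensity`
#'   (matrix with peptide rownames), `samples`.
#' @export
evidence_table <- function(peptide, intensity, proteins = NULL) {
  intensity <- as.matrix(intensity)
  stopifnot(length(peptide) == nrow(intensity))
  if (is.null(colnames(intensity)) || any(!nzchar(colnames(intensity)))) {
    stop("intensity columns must carry sample names")
  }
  if (anyDuplicated(colnames(intensity))) stop("duplicate sample names")
  if (!is.numeric(intensity) || any(!is.finite(intensity)) ||
      any(intensity < 0)) {
    stop("intensities must be finite and nonnegative")
  }
  if (is.null(proteins)) proteins <- vector("list", length(peptide))
  if (anyDuplicated(peptide)) {
    f <- factor(peptide, levels = unique(peptide))
    intensity <- rowsum(intensity, f, reorder = FALSE)
    proteins <- lapply(split(proteins, f), function(p) {
      sort(unique(unlist(p, use.names = FALSE)))
    })
    peptide <- levels(f)
  }
  rownames(intensity) <- peptide
  structure(
    list(peptide = peptide, proteins = proteins, intensity = intensity,
         samples = colnames(intensity)),
    class = "evidence_table")
}

#' Read a MaxQuant-style evidence/peptides export
#'
#' Expects a tab-separated file with a `Sequence` column and one
#' `Intensity <sample>` column per sample; optional `Proteins` (";"-joined
#' accessions), `Reverse` and `Potential contaminant` columns where `"+"`
#' flags a row. Flagged rows are removed when the corresponding filter is on;
#' when a filter is requested but the column is absent, a warning is issued
#' and the table is left unchanged.
#'
#' @param path Path to the TSV.
#' @param filter_reverse Drop rows flagged in `Reverse` (default `TRUE`).
#' @param filter_contaminants Drop rows flagged in `Potential contaminant`
#'   (default `TRUE`).
#' @return An `evidence_table`; removal counts are attached as attribute
#'   `"removal_report"`.
#' @export
read_evidence <- function(path, filter_reverse = TRUE,
                          filter_contaminants = TRUE) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"Sequence" %in% names(df)) {
    stop("evidence file lacks a 'Sequence' column")
  }
  int_cols <- grep("^Intensity .+", names(df), value = TRUE)
  if (!length(int_cols)) {
    stop("evidence file lacks 'Intensity <sample>' columns")
  }
  for (cc in int_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v) && !all(is.na(df[[cc]]) == is.na(v))) {
      stop("non-numeric intensity in column '", cc, "'")
    }
    v[is.na(v)] <- 0
    if (any(v < 0)) stop("negative intensity in column '", cc, "'")
    df[[cc]] <- v
  }
  removed <- c(reverse = 0L, contaminant = 0L)
  flagged <- function(col) !is.na(df[[col]]) & trimws(df[[col]]) == "+"
  drop <- rep(FALSE, nrow(df))
  if (filter_reverse) {
    if ("Reverse" %in% names(df)) {
      removed["reverse"] <- sum(flagged("Reverse") & !drop)
      drop <- drop | flagged("Reverse")
    } else {
      warning("no 'Reverse' column; reverse filter skipped")
    }
  }
  if (filter_contaminants) {
    if ("Potential contaminant" %in% names(df)) {
      removed["contaminant"] <- sum(flagged("Potential contaminant") & !drop)
      drop <- drop | flagged("Potential contaminant")
    } else {
      warning("no 'Potential contaminant' column; contaminant filter skipped")
    }
  }
  df <- df[!drop, , drop = FALSE]
  proteins <- if ("Proteins" %in% names(df)) {
    lapply(strsplit(as.character(df$Proteins), ";", fixed = TRUE),
           function(p) p[nzchar(p)])
  } else NULL
  m <- as.matrix(df[int_cols])
  colnames(m) <- sub("^Intensity ", "", int_cols)
  ev <- evidence_table(df$Sequence, m, proteins)
  attr(ev, "removal_report") <- data.frame(
    reason = names(removed), n = unname(removed))
  ev
}

#' Write an evidence table in the same TSV dialect
#' @param ev An `evidence_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(ev, path) {
  df <- data.frame(Sequence = ev$peptide, stringsAsFactors = FALSE)
  df$Proteins <- vapply(ev$proteins, paste, character(1), collapse = ";")
  m <- ev$intensity
  colnames(m) <- paste("Intensity", colnames(m))
  utils::write.table(cbind(df, as.data.frame(m)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.evidence_table <- function(x, ...) {
  cat("evidence_table:", length(x$peptide), "peptides x",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Genus quantification parameter set
#'
#' @param top_n How many highest-intensity peptides are summed per genus
#'   (default 10); genera whose peptide pool is smaller than `top_n` are
#'   excluded from quantification rather than summed over a short pool.
#' @param mode `"per-sample"` (default): the top `top_n` nonzero intensities
#'   are selected independently in every sample. `"global-median"`: the
#'   `top_n` pool peptides with the highest median intensity across samples
#'   are selected once, then summed per sample.
#' @param pool `"all-peptides"` (default): a genus pool holds every observed
#'   peptide with at least one source protein in that genus, shared or not.
#'   `"unique-only"`: only peptides whose every source protein lies in the
#'   genus.
#' @return A `genus_quant_params` object.
#' @export
genus_quant_params <- function(top_n = 10L,
                               mode = c("per-sample", "global-median"),
                               pool = c("all-peptides", "unique-only")) {
  stopifnot(top_n >= 1L)
  structure(
    list(top_n = as.integer(top_n), mode = match.arg(mode),
         pool = match.arg(pool)),
    class = "genus_quant_params")
}

#' Top-N peptide-intensity genus abundance
#'
#' For every genus in the tree, collects its peptide pool from the evidence
#' (membership through any source protein whose lineage contains the genus),
#' excludes genera with fewer than `top_n` pool peptides, and sums the
#' `top_n` highest peptide intensities per sample (zeros, i.e.
#' non-detections, never occupy a slot; intensity ties break by peptide
#' lexicographic order).
#'
#' @param evidence An `evidence_table`.
#' @param index A `peptide_index` on a taxon-annotated database.
#' @param tree The companion `taxonomy_tree`.
#' @param params A [genus_quant_params()] object.
#' @return A `genus_abundance` object: `abundance` (genus x sample matrix),
#'   `n_peptides` (pool sizes, all genera), `excluded` (data.frame with
#'   reasons), `unmatched_peptides`, `params`.
#' @export
genus_abundance_topn <- function(evidence, index, tree,
                                 params = genus_quant_params()) {
  stopifnot(inherits(evidence, "evidence_table"),
            inherits(index, "peptide_index"),
            inherits(tree, "taxonomy_tree"))
  if (anyNA(index$acc_taxon)) {
    stop("index was built on a database without taxon annotation")
  }
  keys <- il_key(evidence$peptide, index$params)
  if (anyDuplicated(keys)) {
    stop("evidence peptides collapse under the index's I/L setting; ",
         "aggregate the evidence first")
  }
  intens <- evidence$intensity
  rownames(intens) <- keys
  acc_by_pep <- index_accessions(index, keys)
  unmatched <- evidence$peptide[!(keys %in% names(acc_by_pep))]

  taxa <- unique(unname(index$acc_taxon))
  genus_of_taxon <- vapply(taxa, function(t) {
    g <- ancestor_at_rank(tree, t, "genus")
    if (is.null(g)) NA_character_ else g$taxon_id
  }, character(1))
  names(genus_of_taxon) <- taxa

  pep_genera <- lapply(acc_by_pep, function(acc) {
    g <- genus_of_taxon[unname(index$acc_taxon[acc])]
    sort(unique(g[!is.na(g)]))
  })
  genera <- tree$nodes$taxon_id[tree$nodes$rank == "genus"]

  pools <- lapply(stats::setNames(genera, genera), function(g) {
    if (params$pool == "all-peptides") {
      names(pep_genera)[vapply(pep_genera, function(x) g %in% x, logical(1))]
    } else {
      names(pep_genera)[vapply(pep_genera, function(x) identical(x, g),
                               logical(1))]
    }
  })
  pool_n <- lengths(pools)
  quantified <- genera[pool_n >= params$top_n]
  excluded <- data.frame(
    genus = genera[pool_n < params$top_n],
    n_peptides = unname(pool_n[pool_n < params$top_n]),
    reason = sprintf("pool smaller than top_n (%d < %d)",
                     pool_n[pool_n < params$top_n], params$top_n),
    stringsAsFactors = FALSE)

  ab <- matrix(0, length(quantified), ncol(intens),
               dimnames = list(quantified, colnames(intens)))
  for (g in quantified) {
    sub <- intens[pools[[g]], , drop = FALSE]
    if (params$mode == "per-sample") {
      for (s in colnames(sub)) {
        v <- stats::setNames(sub[, s], rownames(sub))
        v <- v[v > 0]
        if (length(v)) {
          ord <- order(-v, names(v))
          ab[g, s] <- sum(v[ord][seq_len(min(params$top_n, length(v)))])
        }
      }
    } else {
      med <- apply(sub, 1L, stats::median)
      ord <- order(-med, rownames(sub))
      sel <- rownames(sub)[ord][seq_len(params$top_n)]
      ab[g, ] <- colSums(sub[sel, , drop = FALSE])
    }
  }
  structure(
    list(abundance = ab, n_peptides = pool_n, excluded = excluded,
         unmatched_peptides = unmatched, params = params),
    class = "genus_abundance")
}

#' @export
print.genus_abundance <- function(x, ...) {
  cat("genus_abundance:", nrow(x$abundance), "genera quantified (",
      nrow(x$excluded), "excluded ) across", ncol(x$abundance),
      "samples; mode =", x$params$mode, "\n")
  invisible(x)
}

#' Write a genus-abundance table to TSV
#' @param quant A `genus_abundance`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genus_abundance <- function(quant, path) {
  df <- data.frame(genus = rownames(quant$abundance),
                   n_peptides_in_pool =
                     unname(quant$n_peptides[rownames(quant$abundance)]),
                   quant$abundance, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-genus abundance ratio between two sample states
#'
#' Computes, for every quantified genus, the ratio of its mean abundance in
#' state A to its mean abundance in state B (arithmetic means over the
#' samples of each state). Genera whose state-B mean is zero are flagged
#' not-evaluable rather than producing infinities.
#'
#' @param quant A `genus_abundance` covering samples of both states.
#' @param grouping Named character vector mapping sample name to state.
#' @param state_a,state_b State labels; default: first and second state in
#'   order of appearance in `grouping`.
#' @return A data.frame (genus, mean_a, mean_b, ratio, evaluable) with a
#'   `summary` attribute (mean and median ratio over evaluable genera).
#' @export
fold_change_between_states <- function(quant, grouping,
                                       state_a = NULL, state_b = NULL) {
  stopifnot(inherits(quant, "genus_abundance"))
  states <- unique(unname(grouping))
  if (is.null(state_a)) state_a <- states[1L]
  if (is.null(state_b)) state_b <- states[2L]
  if (is.na(state_a) || is.na(state_b)) {
    stop("grouping must cover two states with at least one sample each")
  }
  sa <- names(grouping)[grouping == state_a]
  sb <- names(grouping)[grouping == state_b]
  if (!length(sa) || !length(sb)) stop("each state needs at least one sample")
  missing <- setdiff(c(sa, sb), colnames(quant$abundance))
  if (length(missing)) {
    stop("samples absent from abundance table: ",
         paste(missing, collapse = ", "))
  }
  mean_a <- rowMeans(quant$abundance[, sa, drop = FALSE])
  mean_b <- rowMeans(quant$abundance[, sb, drop = FALSE])
  evaluable <- mean_b > 0 & mean_a > 0
  out <- data.frame(
    genus = rownames(quant$abundance),
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    ratio = ifelse(evaluable, mean_a / mean_b, NA_real_),
    evaluable = unname(evaluable),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    state_a = state_a, state_b = state_b,
    mean_ratio = mean(out$ratio[out$evaluable]),
    median_ratio = stats::median(out$ratio[out$evaluable]),
    n_not_evaluable = sum(!out$evaluable))
  out
}

#' Histogram of protein sharing across donors, and the core set
#'
#' @param presence Logical matrix, donors in rows, proteins in columns;
#'   `TRUE` marks detection of a protein in a donor.
#' @return List with `histogram` (named counts over 1..n_donors donors),
#'   `core` (proteins present in every donor), `n_detected`, and
#'   `percent` (histogram as percentages of detected proteins).
#' @export
core_membership_histogram <- function(presence) {
  presence <- as.matrix(presence)
  if (!is.logical(presence)) storage.mode(presence) <- "logical"
  if (nrow(presence) == 0L || ncol(presence) == 0L) {
    stop("presence matrix must have at least one donor and one protein")
  }
  n_donors <- nrow(presence)
  counts <- colSums(presence)
  detected <- counts > 0
  hist <- table(factor(counts[detected], levels = seq_len(n_donors)))
  hist <- stats::setNames(as.integer(hist), names(hist))
  core <- colnames(presence)[counts == n_donors]
  n_det <- sum(detected)
  list(histogram = hist,
       core = core,
       n_detected = n_det,
       percent = if (n_det) 100 * hist / n_det else hist * NA_real_)
}

#' Fraction of total abundance captured by the top k entities
#'
#' Sorts abundances in decreasing order (ties broken lexicographically by
#' name) and returns the mass fraction of the first `k`; `k >= n` gives 1.
#'
#' @param abundances Named nonnegative numeric vector; at least one positive.
#' @param k Positive integer.
#' @return A number in (0, 1].
#' @export
cumulative_abundance_fraction <- function(abundances, k) {
  stopifnot(k >= 1L)
  if (all(abundances <= 0)) stop("all abundances are zero")
  nm <- names(abundances)
  if (is.null(nm)) nm <- as.character(seq_along(abundances))
  ord <- order(-abundances, nm)
  sum(abundances[ord][seq_len(min(k, length(abundances)))]) / sum(abundances)
}

#' Cumulative percentage of one origin class along an abundance ranking
#'
#' Given proteins sorted by descending abundance with an origin label each
#' (`"human"` or `"bacterial"`), returns the running percentage of bacterial
#' proteins among the first r, for every rank r, plus a windowed series
#' (percentage bacterial within consecutive blocks of `window` proteins).
#'
#' @param origin Character vector of origin labels in descending-abundance
#'   order.
#' @param window Block size of the windowed series (default 100).
#' @return List with `cumulative_pct` (length = length(origin)) and
#'   `windowed` (data.frame: window start/end, pct bacterial).
#' @export
bacterial_fraction_by_rank <- function(origin, window = 100L) {
  origin <- as.character(origin)
  bad <- setdiff(unique(origin), c("human", "bacterial"))
  if (length(bad)) {
    stop("unknown origin label(s): ", paste(bad, collapse = ", "))
  }
  is_bact <- origin == "bacterial"
  cum <- 100 * cumsum(is_bact) / seq_along(origin)
  starts <- seq(1L, length(origin), by = window)
  ends <- pmin(starts + window - 1L, length(origin))
  win <- vapply(seq_along(starts), function(i) {
    100 * mean(is_bact[starts[i]:ends[i]])
  }, numeric(1))
  list(cumulative_pct = cum,
       windowed = data.frame(from = starts, to = ends, pct_bacterial = win))
}

#' Z-score standardization within each sample column
#'
#' Centers and scales every column to mean 0, standard deviation 1, using the
#' population convention (denominator n). Constant columns are an error that
#' names the offending sample.
#'
#' @param m Numeric matrix, entities in rows, samples in columns.
#' @return Matrix of the same shape.
#' @export
zscore_within_sample <- function(m) {
  m <- as.matrix(m)
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    mu <- mean(v)
    sdev <- sqrt(mean((v - mu)^2))
    if (sdev == 0) {
      stop("constant column: sample '",
           if (is.null(colnames(m))) j else colnames(m)[j],
           "' cannot be Z-scored")
    }
    out[, j] <- (v - mu) / sdev
  }
  out
}

#' Coefficient of determination between two samples on the log scale
#'
#' Restricts to entries positive in both vectors, log10-transforms, and
#' returns the squared Pearson correlation (the R-squared of the
#' least-squares line). Entries nonpositive in either vector are dropped and
#' counted.
#'
#' @param a,b Numeric vectors of equal length (paired abundances).
#' @return List with `r2`, `n_used`, `n_dropped`.
#' @export
pairwise_log_r2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- a > 0 & b > 0
  if (sum(ok) < 3L) {
    stop("need at least 3 entries positive in both vectors; have ", sum(ok))
  }
  r2 <- stats::cor(log10(a[ok]), log10(b[ok]))^2
  list(r2 = r2, n_used = sum(ok), n_dropped = sum(!ok))
}
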