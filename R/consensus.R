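#' Read a PSM table exported by a search engine
#'
#' Expects a CSV mirroring a "protein-peptides" export: columns
#' `protein_id`, `peptide`, `start`, `score` (e.g. -10lgP),
#' `spectral_count`, and optionally `is_decoy`. Modification annotations
#' in the peptide string — bracketed deltas like `GVQ(+.98)GPP` or
#' lowercase ptm letters — are stripped into a parallel `modifications`
#' column.
#'
#' @param path CSV path.
#' @return Data frame of PSM records.
#' @export
read_psm_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "peptide", "start", "score", "spectral_count")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("PSM table lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$is_decoy)) df$is_decoy <- FALSE
  df$modifications <- vapply(regmatches(df$peptide,
                                        gregexpr("\\([^)]*\\)", df$peptide)),
                             paste, "", collapse = ";")
  df$peptide <- toupper(gsub("\\([^)]*\\)", "", df$peptide))
  stopifnot(all(df$start >= 1), all(nchar(df$peptide) > 0))
  df
}

#' Target-decoy FDR filtering of PSMs
#'
#' PSMs are ranked by decreasing score; at each threshold the false
#' discovery proportion is estimated as decoys/targets at-or-above the
#' threshold, monotonized into q-values; target PSMs with q-value at or
#' below `fdr` are returned.
#'
#' @param psms data frame with at least `score` and `is_decoy` columns.
#' @param fdr false discovery rate threshold (e.g. 0.005 for the 0.5%
#'   convention used for skeletal palaeoproteomes).
#' @param pass_through set `TRUE` for pre-filtered input without decoys.
#' @return The retained target rows, with a `q_value` column.
#' @export
filter_fdr <- function(psms, fdr = 0.005, pass_through = FALSE) {
  if (!any(psms$is_decoy)) {
    if (pass_through) {
      psms$q_value <- NA_real_
      return(psms)
    }
    stop("no decoy PSMs: supply decoys or set pass_through = TRUE",
         call. = FALSE)
  }
  if (!any(!psms$is_decoy)) return(psms[0, , drop = FALSE])
  o <- order(psms$score, decreasing = TRUE)
  sorted <- psms[o, , drop = FALSE]
  n_decoy <- cumsum(sorted$is_decoy)
  n_target <- cumsum(!sorted$is_decoy)
  fdp <- n_decoy / pmax(n_target, 1L)
  # ties share the worst (last) estimate within the tied score block
  fdp <- stats::ave(fdp, sorted$score, FUN = max)
  q <- rev(cummin(rev(fdp)))
  sorted$q_value <- q
  out <- sorted[!sorted$is_decoy & q <= fdr, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Majority-consensus protein reconstruction from peptides
#'
#' Proteins covered by fewer than `min_peptides` distinct peptide
#' sequences are rejected (returns `NULL` with a message), mirroring the
#' >= 5 peptides rule used for ancient skeletal proteomes. For each
#' reference position the residue with the largest summed peptide count
#' wins; ties give `X`; positions without coverage give a gap (`-`).
#'
#' @param psms data frame of PSMs for one protein (`protein_id`,
#'   `peptide`, `start`, `spectral_count`).
#' @param reference_length length of the reference protein.
#' @param min_peptides minimal distinct peptide count (default 5).
#' @param weighting `"spectral"` (default: each distinct peptide weighted
#'   by its summed spectral count) or `"distinct"` (each distinct peptide
#'   counts once).
#' @return List of class `consensus_protein`: `protein_id`, `sequence`
#'   (character scalar with `-`/`X`), `support` and `runner_up_support`
#'   (integer vectors per position), `n_peptides`; or `NULL` when
#'   rejected.
#' @export
build_consensus <- function(psms, reference_length,
                            min_peptides = 5L,
                            weighting = c("spectral", "distinct")) {
  weighting <- match.arg(weighting)
  pid <- unique(psms$protein_id)
  if (length(pid) != 1L) stop("psms must share one protein_id",
                              call. = FALSE)
  if (any(psms$start + nchar(psms$peptide) - 1L > reference_length)) {
    stop("peptide overruns reference length for ", pid, call. = FALSE)
  }
  # collapse to distinct (peptide, start) with summed spectral counts
  key <- paste(psms$peptide, psms$start)
  agg <- psms[!duplicated(key), c("peptide", "start"), drop = FALSE]
  agg$weight <- if (weighting == "spectral") {
    vapply(split(psms$spectral_count, key), sum, 0)[
      paste(agg$peptide, agg$start)]
  } else rep(1, nrow(agg))
  n_pep <- length(unique(psms$peptide))
  if (n_pep < min_peptides) {
    message(sprintf("protein %s rejected: %d < %d distinct peptides",
                    pid, n_pep, min_peptides))
    return(NULL)
  }
  votes <- matrix(0, nrow = 21L, ncol = reference_length,
                  dimnames = list(c(AMINO_ACIDS, "X"), NULL))
  for (i in seq_len(nrow(agg))) {
    res <- split_residues(agg$peptide[i], allow_x = TRUE)
    pos <- agg$start[i] + seq_along(res) - 1L
    for (j in seq_along(res)) {
      votes[res[j], pos[j]] <- votes[res[j], pos[j]] + agg$weight[i]
    }
  }
  votes <- votes[AMINO_ACIDS, , drop = FALSE]  # X votes carry no residue
  support <- apply(votes, 2, max)
  runner_up <- apply(votes, 2, function(v) sort(v, decreasing = TRUE)[2])
  call_at <- function(j) {
    v <- votes[, j]
    if (max(v) == 0) return("-")
    top <- names(v)[v == max(v)]
    if (length(top) > 1L) "X" else top
  }
  seq_chars <- vapply(seq_len(reference_length), call_at, "")
  structure(list(protein_id = pid,
                 sequence = paste(seq_chars, collapse = ""),
                 support = support, runner_up_support = runner_up,
                 n_peptides = n_pep),
            class = "consensus_protein")
}

#' @export
print.consensus_protein <- function(x, ...) {
  covered <- sum(strsplit(x$sequence, "")[[1]] != "-")
  cat(sprintf("<consensus_protein %s: %d/%d positions, %d peptides>\n",
              x$protein_id, covered, nchar(x$sequence), x$n_peptides))
  invisible(x)
}

apply_edit <- function(seq_chars, edit) {
  from <- edit$from; to <- edit$to
  stopifnot(from >= 1, to >= from)
  switch(edit$action,
    delete = {
      kept <- seq_chars[-(from:min(to, length(seq_chars)))]
      c(kept, rep("-", length(seq_chars) - length(kept)))
    },
    mask = {
      seq_chars[from:min(to, length(seq_chars))] <- "X"
      seq_chars
    },
    insert_unknowns = {
      append(seq_chars, rep("X", to - from + 1L), after = from - 1L)
    },
    stop("unknown edit action: ", edit$action, call. = FALSE))
}

#' Concatenate per-protein sequences into one partitioned alignment
#'
#' Every taxon must provide every protein (an all-gap placeholder is
#' allowed); isoform edits (delete / mask / insert_unknowns on 1-based
#' inclusive intervals of a given taxon and protein) are applied before
#' concatenation, with deletions padded by trailing gaps so the matrix
#' stays rectangular.
#'
#' @param proteins named list: `protein_id -> named character vector of
#'   sequences by taxon`.
#' @param protein_order order of proteins in the concatenation (default:
#'   list order).
#' @param edits list of edits, each a list with `taxon`, `protein`,
#'   `from`, `to`, `action`; or a path to a JSON file holding that list.
#' @return List of class `concat_alignment`: `taxa`, `matrix` (taxa x
#'   columns character matrix), `partitions` (data frame `protein, from,
#'   to`).
#' @export
concatenate_proteins <- function(proteins, protein_order = names(proteins),
                                 edits = list()) {
  if (is.character(edits) && length(edits) == 1L) {
    edits <- jsonlite::read_json(edits, simplifyVector = FALSE)
  }
  taxa <- sort(unique(unlist(lapply(proteins, names))))
  # overlapping edits on one (taxon, protein) are a configuration error
  if (length(edits) > 1L) {
    keys <- vapply(edits, function(e) paste(e$taxon, e$protein), "")
    for (k in unique(keys[duplicated(keys)])) {
      es <- edits[keys == k]
      iv <- do.call(rbind, lapply(es, function(e) c(e$from, e$to)))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (any(iv[-1, 1] <= iv[-nrow(iv), 2])) {
        stop("overlapping edits on ", k, call. = FALSE)
      }
    }
  }
  blocks <- list(); parts <- list(); col0 <- 0L
  for (p in protein_order) {
    seqs <- proteins[[p]]
    missing <- setdiff(taxa, names(seqs))
    chars <- lapply(taxa, function(t) {
      if (t %in% missing) return(NULL)
      s <- strsplit(seqs[[t]], "")[[1]]
      for (e in edits) {
        if (identical(e$taxon, t) && identical(e$protein, p)) {
          s <- apply_edit(s, e)
        }
      }
      s
    })
    names(chars) <- taxa
    lens <- unique(lengths(chars[!vapply(chars, is.null, TRUE)]))
    if (length(lens) != 1L) {
      stop("protein ", p, " has unequal post-edit lengths: ",
           paste(lens, collapse = ", "), call. = FALSE)
    }
    chars[vapply(chars, is.null, TRUE)] <-
      list(rep("-", lens))
    blocks[[p]] <- do.call(rbind, chars)
    parts[[p]] <- data.frame(protein = p, from = col0 + 1L,
                             to = col0 + lens)
    col0 <- col0 + lens
  }
  mat <- do.call(cbind, blocks)
  rownames(mat) <- taxa
  structure(list(taxa = taxa, matrix = mat,
                 partitions = do.call(rbind, parts)),
            class = "concat_alignment")
}

#' @export
print.concat_alignment <- function(x, ...) {
  cat(sprintf("<concat_alignment: %d taxa x %d columns, %d partitions>\n",
              nrow(x$matrix), ncol(x$matrix), nrow(x$partitions)))
  invisible(x)
}

#' Reconstructed-position coverage of a taxon in an alignment
#'
#' Counts non-gap, non-X residues and reports the fraction of total
#' columns as a percentage rounded to one decimal.
#'
#' @param alignment a `concat_alignment` (or a taxa x columns character
#'   matrix).
#' @param taxon row name to summarize.
#' @return List `positions_reconstructed`, `fraction_percent`.
#' @examples
#' # 4,597 positions over 31,781 columns -> 14.5%
#' coverage_percent(4597, 31781)
#' @export
coverage_stats <- function(alignment, taxon) {
  mat <- if (inherits(alignment, "concat_alignment")) alignment$matrix
         else alignment
  if (!taxon %in% rownames(mat)) stop("taxon not in alignment",
                                      call. = FALSE)
  row <- mat[taxon, ]
  n <- sum(!row %in% c("-", "X", "?"))
  list(positions_reconstructed = n,
       fraction_percent = coverage_percent(n, ncol(mat)))
}

#' @rdname coverage_stats
#' @param n_positions,n_columns integer counts.
#' @export
coverage_percent <- function(n_positions, n_columns) {
  round_half_up(100 * n_positions / n_columns, 1L)
}

#' Write an alignment as FASTA plus a partitions file
#'
#' @param alignment a `concat_alignment`.
#' @param fasta_path,partitions_path output paths; partition lines have
#'   the form `protein = start-end`.
#' @export
write_alignment <- function(alignment, fasta_path, partitions_path = NULL) {
  seqs <- apply(alignment$matrix, 1, paste, collapse = "")
  write_fasta(seqs, fasta_path)
  if (!is.null(partitions_path)) {
    writeLines(sprintf("%s = %d-%d", alignment$partitions$protein,
                       alignment$partitions$from, alignment$partitions$to),
               partitions_path)
  }
  invisible(fasta_path)
}
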