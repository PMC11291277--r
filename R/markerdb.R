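#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the following residue is P (the
#' classical trypsin rule), optionally keeping peptides with internal
#' missed cleavage sites.
#'
#' @param sequence amino-acid string (20 canonical residues plus X).
#' @param min_length minimum peptide length to keep (default 6, typical
#'   ZooMS practice).
#' @param max_missed_cleavages maximum number of internal K/R cleavage
#'   sites allowed per peptide (default 1).
#' @return Character vector of unique peptides.
#' @examples
#' digest_sequence("AAKPGGKRAA", min_length = 1, max_missed_cleavages = 0)
#' @export
digest_sequence <- function(sequence, min_length = 6L,
                            max_missed_cleavages = 1L) {
  res <- split_residues(sequence, allow_x = TRUE)
  n <- length(res)
  if (n == 0L) return(character())
  # cleavage after position i: res[i] in K/R and res[i+1] != P
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!n %in% cut_after) n)
  bounds <- unique(bounds)
  nfrag <- length(bounds) - 1L
  peps <- character()
  for (i in seq_len(nfrag)) {
    for (j in i:min(nfrag, i + max_missed_cleavages)) {
      peps <- c(peps, paste(res[(bounds[i] + 1L):bounds[j + 1L]],
                            collapse = ""))
    }
  }
  unique(peps[nchar(peps) >= min_length])
}

#' Monoisotopic peptide m/z
#'
#' Residue-mass sum plus water, protonated, with optional proline
#' hydroxylations (+15.994915 Da each) and deamidations (+0.984016 Da
#' each), divided by charge.
#'
#' @param sequence amino-acid string (canonical residues only).
#' @param n_hydroxylations number of hydroxyprolines (must not exceed the
#'   P count of the sequence).
#' @param n_deamidations number of deamidated N/Q (must not exceed the
#'   N+Q count).
#' @param charge positive integer charge state; 1 gives \[M+H\]+.
#' @return m/z in Da.
#' @examples
#' peptide_mz("GVQGPPGPAGPR", n_hydroxylations = 1)  # ZooMS marker P1105
#' @export
peptide_mz <- function(sequence, n_hydroxylations = 0L,
                       n_deamidations = 0L, charge = 1L) {
  stopifnot(charge >= 1L, n_hydroxylations >= 0L, n_deamidations >= 0L)
  res <- split_residues(sequence)
  if (n_hydroxylations > sum(res == "P")) {
    stop("n_hydroxylations exceeds proline count", call. = FALSE)
  }
  if (n_deamidations > sum(res %in% c("N", "Q"))) {
    stop("n_deamidations exceeds N+Q count", call. = FALSE)
  }
  m <- sum(RESIDUE_MASS[res]) + WATER_MASS +
    n_hydroxylations * HYDROXYLATION_SHIFT +
    n_deamidations * DEAMIDATION_SHIFT
  (m + charge * PROTON_MASS) / charge
}

#' Marker records and marker databases
#'
#' A `marker_record` describes one collagen peptide marker: its label, the
#' peptide sequence when known (mass-only markers from measured reference
#' spectra are allowed), modification counts, the monoisotopic \[M+H\]+
#' mass, the taxon at which the marker is diagnostic, and whether the mass
#' was measured or predicted. A `marker_database` bundles a set of marker
#' records with the taxonomy their diagnostic taxa live in.
#'
#' @param label marker label, e.g. `"COL1a1 508-519"` or `"P1105"`.
#' @param mz_MH monoisotopic \[M+H\]+ mass in Da; if `sequence` is given it
#'   must agree with the computed mass within 0.05 Da (and is taken from
#'   the sequence when omitted).
#' @param sequence peptide string or `NA` for mass-only markers.
#' @param n_hydroxylations,n_deamidations modification counts.
#' @param diagnostic_taxon taxon name the marker is diagnostic for.
#' @param source `"measured"` or `"predicted"`.
#' @return `marker_record()`: a one-row data frame; `marker_database()`:
#'   an object of class `marker_database` with elements `taxonomy` and
#'   `markers`.
#' @export
marker_record <- function(label, mz_MH = NULL, sequence = NA_character_,
                          n_hydroxylations = 0L, n_deamidations = 0L,
                          diagnostic_taxon, source = "predicted") {
  stopifnot(source %in% c("measured", "predicted"))
  if (!is.na(sequence)) {
    computed <- peptide_mz(sequence, n_hydroxylations, n_deamidations)
    if (is.null(mz_MH)) mz_MH <- computed
    if (abs(mz_MH - computed) > 0.05) {
      stop(sprintf("mz_MH %.4f disagrees with computed %.4f for %s",
                   mz_MH, computed, label), call. = FALSE)
    }
  }
  if (is.null(mz_MH) || mz_MH <= 0) {
    stop("mz_MH must be positive (or derivable from a sequence)",
         call. = FALSE)
  }
  data.frame(label = label, sequence = sequence,
             n_hyd = as.integer(n_hydroxylations),
             n_deam = as.integer(n_deamidations),
             mz_MH = mz_MH, taxon = diagnostic_taxon,
             source = source, stringsAsFactors = FALSE)
}

#' @rdname marker_record
#' @param taxonomy a [taxonomy()].
#' @param markers data frame of marker records (rows from
#'   [marker_record()]).
#' @export
marker_database <- function(taxonomy, markers) {
  stopifnot(inherits(taxonomy, "taxonomy"))
  tax_check_node(taxonomy, unique(markers$taxon))
  key <- paste(markers$label, markers$taxon, markers$n_hyd, markers$n_deam)
  if (anyDuplicated(key)) {
    stop("duplicate (label, taxon, n_hyd, n_deam) marker", call. = FALSE)
  }
  markers$rank <- taxonomy$rank[match(markers$taxon, taxonomy$name)]
  structure(list(taxonomy = taxonomy,
                 markers = markers[order(markers$mz_MH), , drop = FALSE]),
            class = "marker_database")
}

#' @export
print.marker_database <- function(x, ...) {
  cat(sprintf("<marker_database: %d markers, %d taxa, m/z %.1f-%.1f>\n",
              nrow(x$markers), length(unique(x$markers$taxon)),
              min(x$markers$mz_MH), max(x$markers$mz_MH)))
  invisible(x)
}

#' Predict ZooMS markers from COL1 sequences
#'
#' Digests each taxon's collagen sequence(s), computes marker masses for a
#' range of hydroxylation states, and assigns each distinct mass a
#' diagnostic taxon: masses observed in several taxa become diagnostic at
#' the lowest common ancestor of those taxa; taxon-unique masses are
#' diagnostic at that taxon.
#'
#' @param col1_sequences named character vector (or list) of amino-acid
#'   sequences; names are taxa present in `taxonomy`. Several records per
#'   taxon are allowed (e.g. COL1a1 and COL1a2 chains).
#' @param taxonomy a [taxonomy()] containing every sequence taxon.
#' @param hydroxylation_range integer vector of hydroxylation counts to
#'   emit per peptide (capped at the peptide's proline count).
#' @param min_length,max_missed_cleavages passed to [digest_sequence()].
#' @param group_tol masses closer than this (Da) are considered the same
#'   marker across taxa (default 0.05).
#' @return A [marker_database()].
#' @export
predict_markers <- function(col1_sequences, taxonomy,
                            hydroxylation_range = 0:1,
                            min_length = 6L, max_missed_cleavages = 1L,
                            group_tol = 0.05) {
  seqs <- unlist(col1_sequences)
  taxa <- names(seqs)
  if (is.null(taxa) || any(taxa == "")) {
    stop("col1_sequences must be named by taxon", call. = FALSE)
  }
  tax_check_node(taxonomy, unique(taxa))
  rows <- list()
  for (i in seq_along(seqs)) {
    peps <- digest_sequence(seqs[[i]], min_length, max_missed_cleavages)
    peps <- peps[!grepl("X", peps, fixed = TRUE)]
    for (p in peps) {
      hmax <- sum(strsplit(p, "")[[1]] == "P")
      for (h in intersect(hydroxylation_range, 0:hmax)) {
        rows[[length(rows) + 1L]] <- data.frame(
          taxon = taxa[i], sequence = p, n_hyd = h,
          mz = peptide_mz(p, h), stringsAsFactors = FALSE)
      }
    }
  }
  all <- unique(do.call(rbind, rows))
  # single-linkage 1-D clustering of masses across taxa
  all <- all[order(all$mz), , drop = FALSE]
  grp <- cumsum(c(1, diff(all$mz) > group_tol))
  records <- lapply(split(all, grp), function(g) {
    taxa_g <- unique(g$taxon)
    diag_taxon <- if (length(taxa_g) == 1L) taxa_g else
      tax_lca(taxonomy, taxa_g)
    marker_record(
      label = sprintf("P%d", round(g$mz[1])),
      sequence = g$sequence[1], n_hydroxylations = g$n_hyd[1],
      mz_MH = mean(g$mz), diagnostic_taxon = diag_taxon,
      source = "predicted")
  })
  markers <- do.call(rbind, records)
  # disambiguate duplicate (label, taxon, h, d) from distinct peptides
  key <- paste(markers$label, markers$taxon, markers$n_hyd, markers$n_deam)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    markers$label[dup] <- sprintf("%s.%04.0f", markers$label[dup],
                                  (markers$mz_MH[dup] %% 1) * 1e4)
  }
  marker_database(taxonomy, markers)
}

#' Read / write a marker database as TSV
#'
#' Markers are stored in a TSV with header
#' `label sequence n_hyd n_deam mz_MH taxon rank source` (m/z written with
#' 4 decimals); the taxonomy is stored alongside with [write_taxonomy()]
#' under the same path with extension `.taxonomy.tsv`.
#'
#' @param db a [marker_database()].
#' @param path path of the marker TSV.
#' @export
write_marker_db <- function(db, path) {
  out <- db$markers
  out$mz_MH <- sprintf("%.4f", out$mz_MH)
  out$sequence[is.na(out$sequence)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_taxonomy(db$taxonomy, paste0(path, ".taxonomy.tsv"))
  invisible(path)
}

#' @rdname write_marker_db
#' @param taxonomy optional [taxonomy()]; when `NULL` it is read from
#'   `<path>.taxonomy.tsv`.
#' @export
read_marker_db <- function(path, taxonomy = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$sequence[df$sequence == "" | is.na(df$sequence)] <- NA_character_
  df$mz_MH <- as.numeric(df$mz_MH)
  df$n_hyd <- as.integer(df$n_hyd)
  df$n_deam <- as.integer(df$n_deam)
  if (is.null(taxonomy)) taxonomy <- read_taxonomy(paste0(path, ".taxonomy.tsv"))
  marker_database(taxonomy, df[c("label", "sequence", "n_hyd", "n_deam",
                                 "mz_MH", "taxon", "source")])
}
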