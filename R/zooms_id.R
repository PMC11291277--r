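#' Match consensus peaks against a marker database
#'
#' Every (peak, marker) pair whose m/z difference is within `tol` is
#' emitted; a peak may match several markers, preserving taxonomic
#' ambiguity for downstream assignment. Matches are ordered by m/z then
#' diagnostic taxon name.
#'
#' @param peaks a `consensus_peaks` object (see [merge_replicates()]).
#' @param db a [marker_database()].
#' @param tol matching tolerance in Da (default 0.2, MALDI-TOF external
#'   calibration regime).
#' @return Data frame with columns `label`, `taxon`, `rank`, `sequence`,
#'   `n_hyd`, `n_deam`, `predicted_mz`, `observed_mz`, `delta`,
#'   `intensity`.
#' @export
match_markers <- function(peaks, db, tol = 0.2) {
  stopifnot(inherits(db, "marker_database"), tol > 0)
  if (!nrow(db$markers)) stop("empty marker database", call. = FALSE)
  pk <- if (inherits(peaks, "consensus_peaks")) peaks$peaks else peaks
  m <- db$markers
  out <- list()
  for (i in seq_len(nrow(pk))) {
    hit <- which(abs(m$mz_MH - pk$mz[i]) <= tol)
    if (length(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        label = m$label[hit], taxon = m$taxon[hit], rank = m$rank[hit],
        sequence = m$sequence[hit], n_hyd = m$n_hyd[hit],
        n_deam = m$n_deam[hit], predicted_mz = m$mz_MH[hit],
        observed_mz = pk$mz[i], delta = pk$mz[i] - m$mz_MH[hit],
        intensity = pk$intensity[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(label = character(), taxon = character(),
                      rank = character(), sequence = character(),
                      n_hyd = integer(), n_deam = integer(),
                      predicted_mz = numeric(), observed_mz = numeric(),
                      delta = numeric(), intensity = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$observed_mz, res$taxon, res$label), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Taxonomic assignment from marker matches
#'
#' Matched markers vote for their diagnostic taxa. Deamidated satellite
#' peaks of a marker (same label/taxon/hydroxylation, different
#' deamidation count) are collapsed to one piece of evidence, since they
#' are chemically the same peptide. The assignment is the most specific
#' taxon consistent with the best-supported evidence path: markers whose
#' taxa lie on one root-to-leaf path reinforce each other (e.g. 14
#' Homininae markers plus one Hominoidea marker assign to Homininae);
#' equal support for conflicting lineages coarsens the call to their
#' lowest common ancestor, flagged tentative, with the tied taxa listed
#' in the ambiguity set.
#'
#' @param matches data frame from [match_markers()].
#' @param db the [marker_database()] used for matching.
#' @param min_markers minimal distinct-marker count for a `secure` call
#'   (default 3).
#' @param specimen_id carried through to the result.
#' @return A list of class `taxon_assignment`: `specimen_id`,
#'   `assigned_taxon`, `rank`, `n_markers_at_assigned_rank`, `quality`
#'   (`secure`/`tentative`/`unidentifiable`), `ambiguity_set`, `matches`.
#' @export
assign_taxon <- function(matches, db, min_markers = 3L,
                         specimen_id = "unknown") {
  tax <- db$taxonomy
  finish <- function(taxon, n, quality, amb = character()) {
    structure(list(specimen_id = specimen_id, assigned_taxon = taxon,
                   rank = if (is.na(taxon)) NA_character_ else
                     tax$rank[match(taxon, tax$name)],
                   n_markers_at_assigned_rank = n, quality = quality,
                   ambiguity_set = amb, matches = matches),
              class = "taxon_assignment")
  }
  if (is.null(matches) || !nrow(matches)) {
    return(finish(NA_character_, 0L, "unidentifiable"))
  }
  # one evidence unit per marker peptide, deamidation satellites collapsed
  ev <- unique(matches[c("label", "taxon", "n_hyd")])
  ev$key <- paste(ev$label, ev$taxon)
  ev <- ev[!duplicated(ev$key), , drop = FALSE]
  counts <- table(ev$taxon)
  taxa <- names(counts)
  # support along each matched taxon's root path
  path_support <- vapply(taxa, function(t) {
    anc <- tax_ancestors(tax, t)
    sum(counts[intersect(taxa, anc)])
  }, 0)
  depth <- vapply(taxa, function(t) length(tax_ancestors(tax, t)), 0L)
  best <- max(path_support)
  cand <- taxa[path_support == best]
  # among equally supported candidates keep the deepest ones
  cand <- cand[depth[cand] == max(depth[cand])]
  if (length(cand) == 1L) {
    assigned <- cand
    amb <- character()
  } else {
    assigned <- lowest_consistent_taxon(tax, cand)
    amb <- cand
  }
  # evidence at-or-below the assigned node
  n_assigned <- sum(vapply(ev$taxon, function(t)
    tax_is_ancestor(tax, assigned, t), TRUE))
  # conflicting lineages: matched taxa neither ancestor nor descendant
  conflict <- counts[vapply(taxa, function(t)
    !(tax_is_ancestor(tax, assigned, t) ||
        tax_is_ancestor(tax, t, assigned)), TRUE)]
  if (length(conflict) && max(conflict) >= best / 2) {
    assigned <- lowest_consistent_taxon(tax, taxa)
    amb <- unique(c(amb, names(conflict)[conflict >= best / 2]))
    n_assigned <- sum(counts)
    return(finish(assigned, as.integer(n_assigned), "tentative", amb))
  }
  quality <- if (length(amb)) "tentative"
  else if (n_assigned >= min_markers) "secure" else "tentative"
  finish(assigned, as.integer(n_assigned), quality, amb)
}

#' @export
print.taxon_assignment <- function(x, ...) {
  cat(sprintf("<assignment %s: %s (%s), %d markers, %s>\n",
              x$specimen_id,
              ifelse(is.na(x$assigned_taxon), "-", x$assigned_taxon),
              ifelse(is.na(x$rank), "-", x$rank),
              x$n_markers_at_assigned_rank, x$quality))
  invisible(x)
}

#' Identify a batch of specimens
#'
#' Convenience wrapper: match and assign each consensus peak list, and
#' return the one-row-per-specimen summary table described by the
#' module's output contract.
#'
#' @param consensus_list list of `consensus_peaks`.
#' @param db a [marker_database()].
#' @param tol,min_markers see [match_markers()] and [assign_taxon()].
#' @return Data frame `specimen_id, taxon, rank, n_markers, quality,
#'   markers_matched`; the per-match evidence is attached as attribute
#'   `"evidence"` (long format).
#' @export
identify_specimens <- function(consensus_list, db, tol = 0.2,
                               min_markers = 3L) {
  rows <- list(); evid <- list()
  for (cp in consensus_list) {
    m <- match_markers(cp, db, tol)
    a <- assign_taxon(m, db, min_markers, specimen_id = cp$specimen_id)
    rows[[length(rows) + 1L]] <- data.frame(
      specimen_id = cp$specimen_id,
      taxon = a$assigned_taxon, rank = a$rank,
      n_markers = a$n_markers_at_assigned_rank, quality = a$quality,
      markers_matched = paste(unique(m$label), collapse = ";"),
      stringsAsFactors = FALSE)
    if (nrow(m)) evid[[length(evid) + 1L]] <-
        cbind(specimen_id = cp$specimen_id, m)
  }
  out <- do.call(rbind, rows)
  attr(out, "evidence") <- if (length(evid)) do.call(rbind, evid)
  out
}
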