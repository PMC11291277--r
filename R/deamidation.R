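# Glutamine deamidation from MALDI isotope envelopes.
#
# The two collagen peptides tracked here are conserved across most
# terrestrial mammals and carry a single glutamine each:
#   COL1a1 508-519  GVQGPPGPAGPR        (marker P1105, 1 hydroxylation)
#   COL1a1 435-453  DGEAGAQGPPGPAGPAGER (marker P1706, 1 hydroxylation)
# Deamidation (Q -> E, +0.984016 Da) shifts the envelope by just under
# one isotope spacing, so the observed envelope is a mixture of two
# overlapping combs; the deamidation value is the non-deamidated fraction
# (1 = no deamidation, 0 = complete deamidation).

DEAMIDATION_PEPTIDES <- list(
  "COL1a1 508-519" = list(sequence = "GVQGPPGPAGPR", n_hyd = 1L),
  "COL1a1 435-453" = list(sequence = "DGEAGAQGPPGPAGPAGER", n_hyd = 1L)
)

peptide_composition <- function(sequence, n_hydroxylations = 0L,
                                n_deamidations = 0L) {
  res <- split_residues(sequence)
  counts <- rowSums(RESIDUE_FORMULA[, res, drop = FALSE])
  counts["H"] <- counts["H"] + 2          # water
  counts["O"] <- counts["O"] + 1 + n_hydroxylations + n_deamidations
  counts["N"] <- counts["N"] - n_deamidations
  counts["H"] <- counts["H"] - n_deamidations
  counts
}

#' Theoretical isotope envelope of a peptide
#'
#' Aggregated (nominal-mass) isotopic distribution computed by polynomial
#' convolution of the per-element distributions, truncated to
#' `n_isotopes` positions and renormalized.
#'
#' @param sequence amino-acid string.
#' @param n_hydroxylations,n_deamidations modification counts.
#' @param n_isotopes number of isotope positions to keep (>= 4).
#' @param charge charge state for `base_mz` (default 1).
#' @return List of class `isotope_envelope` with `base_mz` (monoisotopic
#'   m/z) and `relative_abundances` (sums to 1).
#' @export
theoretical_envelope <- function(sequence, n_hydroxylations = 0L,
                                 n_deamidations = 0L, n_isotopes = 6L,
                                 charge = 1L) {
  stopifnot(n_isotopes >= 4L)
  comp <- peptide_composition(sequence, n_hydroxylations, n_deamidations)
  dist <- 1
  for (el in names(comp)) {
    p <- ELEMENT_ISOTOPES[[el]]
    for (k in seq_len(comp[[el]])) {
      new <- numeric(length(dist) + length(p) - 1L)
      for (i in seq_along(p)) {
        if (p[i] > 0) {
          new[seq_along(dist) + i - 1L] <-
            new[seq_along(dist) + i - 1L] + dist * p[i]
        }
      }
      dist <- new[seq_len(min(length(new), n_isotopes + 2L))]
    }
  }
  ab <- dist[seq_len(min(n_isotopes, length(dist)))]
  structure(list(
    base_mz = peptide_mz(sequence, n_hydroxylations, n_deamidations,
                         charge),
    relative_abundances = ab / sum(ab)),
    class = "isotope_envelope")
}

# Two-column non-negative least squares, closed form.
nnls2 <- function(X, y) {
  fit <- function(active) {
    b <- numeric(2)
    if (length(active)) {
      Xa <- X[, active, drop = FALSE]
      b[active] <- solve(crossprod(Xa), crossprod(Xa, y))
    }
    b
  }
  b <- fit(1:2)
  if (all(b >= 0)) return(b)
  cand <- list(fit(1L), fit(2L), numeric(2))
  cand <- Filter(function(b) all(b >= -1e-12), cand)
  rss <- vapply(cand, function(b) sum((y - X %*% pmax(b, 0))^2), 0)
  pmax(cand[[which.min(rss)]], 0)
}

#' Estimate glutamine deamidation from a consensus peak list
#'
#' Fits the observed intensities over the combined isotope grid of the
#' glutamine (Q) form and the deamidated form (+0.984016 Da) as a
#' non-negative linear combination `alpha * envelope(Q) + beta *
#' envelope(deamidated)` and reports `alpha / (alpha + beta)`: 1 means no
#' deamidation, 0 complete deamidation.
#'
#' @param peaks a `consensus_peaks` (or [peak_list()]) object.
#' @param peptide `"COL1a1 508-519"` or `"COL1a1 435-453"`.
#' @param tol peak-to-grid matching tolerance in Da (default 0.1).
#' @param n_isotopes isotope positions used per form (default 5).
#' @return List of class `deamidation_estimate`: `specimen_id`,
#'   `peptide`, `protocol`, `value`, `fit_residual`; or `NULL` (with a
#'   message attribute "peptide not detected") when no peak falls in the
#'   envelope window.
#' @export
estimate_deamidation <- function(peaks, peptide = "COL1a1 508-519",
                                 tol = 0.1, n_isotopes = 5L) {
  info <- DEAMIDATION_PEPTIDES[[peptide]]
  if (is.null(info)) stop("unknown peptide: ", peptide, call. = FALSE)
  pk <- if (is.data.frame(peaks)) peaks else peaks$peaks
  envQ <- theoretical_envelope(info$sequence, info$n_hyd, 0L,
                               n_isotopes = n_isotopes)
  envD <- theoretical_envelope(info$sequence, info$n_hyd, 1L,
                               n_isotopes = n_isotopes)
  # shared nominal grid anchored on the Q-form monoisotopic mass; the
  # deamidated comb sits 0.984 Da up, i.e. slot k of the grid collects
  # Q-form isotope k and deamidated isotope k-1
  ngrid <- n_isotopes + 1L
  grid_mz <- envQ$base_mz + (seq_len(ngrid) - 1L) * ISOTOPE_SPACING
  y <- vapply(grid_mz, function(m) {
    hit <- which(abs(pk$mz - m) <= tol + 0.02)
    if (length(hit)) max(pk$intensity[hit]) else 0
  }, 0)
  if (all(y == 0)) {
    message("peptide not detected: ", peptide)
    return(NULL)
  }
  X <- cbind(Q = c(envQ$relative_abundances, 0),
             deamidated = c(0, envD$relative_abundances))
  b <- nnls2(X, y)
  if (sum(b) == 0) {
    message("degenerate envelope fit: ", peptide)
    return(NULL)
  }
  value <- b[1] / sum(b)
  structure(list(
    specimen_id = if (is.data.frame(peaks)) "unknown" else peaks$specimen_id,
    peptide = peptide,
    protocol = if (is.data.frame(peaks)) NA_character_ else peaks$protocol,
    value = value,
    fit_residual = sum((y - X %*% b)^2) / sum(y^2)),
    class = "deamidation_estimate")
}

#' Per-layer deamidation summaries with bootstrap intervals
#'
#' Arithmetic mean per layer and peptide, with a 68.2% interval taken as
#' the 15.9th-84.1st percentiles of bootstrap means (specimens resampled
#' with replacement).
#'
#' @param estimates list of `deamidation_estimate` objects (NULLs are
#'   dropped), or a data frame with columns `specimen_id`, `peptide`,
#'   `value`.
#' @param layer_map named character vector mapping specimen_id to layer.
#' @param n_boot bootstrap replicates (>= 100, default 1000).
#' @param seed RNG seed (default 42, recorded in the output).
#' @return Data frame `layer, peptide, n, mean, lo_68, hi_68` with
#'   attribute `seed`.
#' @export
summarize_by_layer <- function(estimates, layer_map, n_boot = 1000L,
                               seed = 42L) {
  stopifnot(n_boot >= 100L)
  if (!is.data.frame(estimates)) {
    estimates <- Filter(Negate(is.null), estimates)
    estimates <- do.call(rbind, lapply(estimates, function(e)
      data.frame(specimen_id = e$specimen_id, peptide = e$peptide,
                 value = e$value, stringsAsFactors = FALSE)))
  }
  estimates$layer <- unname(layer_map[estimates$specimen_id])
  dropped <- is.na(estimates$layer)
  if (any(dropped)) {
    warning(sum(dropped), " estimate(s) without layer dropped")
    estimates <- estimates[!dropped, , drop = FALSE]
  }
  set.seed(seed)
  out <- do.call(rbind, lapply(
    split(estimates, estimates[c("layer", "peptide")], drop = TRUE),
    function(g) {
      v <- g$value
      boots <- vapply(seq_len(n_boot), function(i)
        mean(sample(v, length(v), replace = TRUE)), 0)
      ci <- stats::quantile(boots, c(0.159, 0.841), names = FALSE)
      data.frame(layer = g$layer[1], peptide = g$peptide[1],
                 n = length(v), mean = mean(v),
                 lo_68 = ci[1], hi_68 = ci[2])
    }))
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}
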