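#' MALDI-TOF peak lists
#'
#' A `peak_list` holds centroided (or profile) peaks for one spotting
#' replicate of one specimen under one extraction protocol (AmBic or
#' acid). Peaks are kept sorted by m/z with non-negative intensities;
#' duplicate m/z values (within 1e-6 Da) are collapsed with a warning.
#'
#' @param mz,intensity numeric vectors of equal length.
#' @param specimen_id,protocol,replicate_id metadata; `protocol` is one of
#'   `"AmBic"` or `"acid"`.
#' @param snr optional per-peak signal-to-noise values.
#' @return An object of class `peak_list`.
#' @export
peak_list <- function(mz, intensity, specimen_id = "unknown",
                      protocol = c("AmBic", "acid"), replicate_id = 1L,
                      snr = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("negative intensity", call. = FALSE)
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (!is.null(snr)) snr <- snr[o]
  dup <- c(FALSE, diff(mz) < 1e-6)
  if (any(dup)) {
    warning("collapsing ", sum(dup), " duplicate m/z value(s)")
    keep <- !dup
    intensity <- vapply(split(intensity, cumsum(keep)), max, 0)
    if (!is.null(snr)) snr <- snr[keep]
    mz <- mz[keep]
  }
  structure(list(specimen_id = specimen_id, replicate_id = replicate_id,
                 protocol = protocol,
                 peaks = data.frame(mz = mz, intensity = intensity),
                 snr = snr),
            class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list %s rep%d [%s]: %d peaks>\n", x$specimen_id,
              x$replicate_id, x$protocol, nrow(x$peaks)))
  invisible(x)
}

parse_peaklist_name <- function(path) {
  base <- sub("\\.[^.]+$", "", basename(path))
  m <- regmatches(base,
                  regexec("^(.*)_(AmBic|acid)_rep([0-9]+)$", base))[[1]]
  if (length(m) == 4L) {
    list(specimen_id = m[2], protocol = m[3],
         replicate_id = as.integer(m[4]))
  } else {
    list(specimen_id = base, protocol = "AmBic", replicate_id = 1L)
  }
}

#' Read a peak list from TSV or mzML
#'
#' TSV dialect: two tab-separated columns `mz` and `intensity` (optional
#' third column `snr`), with or without a header line. Specimen metadata
#' is parsed from a filename of the form `<specimen>_<protocol>_rep<k>`.
#' mzML dialect: minimal uncompressed 64-bit little-endian arrays, as
#' written by [write_mzml()].
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"mzml"`.
#' @return A [peak_list()].
#' @export
read_peaklist <- function(path, dialect = c("tsv", "mzml")) {
  dialect <- match.arg(dialect)
  meta <- parse_peaklist_name(path)
  if (dialect == "mzml") {
    arr <- read_mzml(path)
    return(peak_list(arr$mz, arr$intensity, meta$specimen_id,
                     meta$protocol, meta$replicate_id))
  }
  first <- readLines(path, n = 1L)
  if (!length(first)) {
    warning("empty peak list: ", path)
    return(peak_list(numeric(), numeric(), meta$specimen_id,
                     meta$protocol, meta$replicate_id))
  }
  header <- grepl("[A-Za-z]", strsplit(first, "\t")[[1]][1])
  df <- utils::read.delim(path, header = header)
  peak_list(as.numeric(df[[1]]), as.numeric(df[[2]]),
            meta$specimen_id, meta$protocol, meta$replicate_id,
            snr = if (ncol(df) >= 3) as.numeric(df[[3]]))
}

#' Write a peak list as two/three-column TSV
#' @param x a [peak_list()].
#' @param path output path; conventionally
#'   `<specimen>_<protocol>_rep<k>.tsv` so metadata round-trips.
#' @export
write_peaklist <- function(x, path) {
  df <- x$peaks
  if (!is.null(x$snr)) df$snr <- x$snr
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Peak picking on profile spectra
#'
#' Standard MALDI processing chain: square-root intensity transform,
#' moving-average smoothing, moving-median baseline subtraction, then
#' local-maximum detection gated on signal-to-noise, with noise estimated
#' as the median absolute deviation of the baseline-subtracted signal.
#' Already-centroided input (a peak list carrying per-peak SNR, i.e. the
#' output of this function) is passed through with only the SNR gate
#' applied, making the operation idempotent.
#'
#' @param profile a [peak_list()] in profile mode (>= 5 points).
#' @param snr_threshold minimal signal-to-noise ratio (default 3).
#' @param baseline_window moving-median window in points (default 200).
#' @param smooth_window moving-average half-window in points (default 2).
#' @param peak_half_window a peak must be the maximum of the
#'   baseline-subtracted signal within this many points on each side
#'   (default 10).
#' @return A centroided [peak_list()] with per-peak `snr`.
#' @export
pick_peaks <- function(profile, snr_threshold = 3,
                       baseline_window = 200L, smooth_window = 2L,
                       peak_half_window = 10L) {
  stopifnot(inherits(profile, "peak_list"), snr_threshold > 0)
  if (!is.null(profile$snr)) {  # centroided already: gate only
    keep <- profile$snr >= snr_threshold
    return(peak_list(profile$peaks$mz[keep], profile$peaks$intensity[keep],
                     profile$specimen_id, profile$protocol,
                     profile$replicate_id, snr = profile$snr[keep]))
  }
  y <- profile$peaks$intensity
  mz <- profile$peaks$mz
  n <- length(y)
  if (n < 5L) stop("need at least 5 raw points for peak picking",
                   call. = FALSE)
  y <- sqrt(y)
  y <- stats::filter(y, rep(1, 2L * smooth_window + 1L) /
                       (2L * smooth_window + 1L), sides = 2)
  y[is.na(y)] <- 0
  base <- stats::runmed(y, k = min(2L * (baseline_window %/% 2L) + 1L,
                                   2L * (n %/% 2L) - 1L))
  s <- pmax(as.numeric(y - base), 0)
  noise <- stats::mad(as.numeric(y - base))
  if (noise <= 0) noise <- max(s) * 1e-6 + .Machine$double.eps
  hw <- max(1L, peak_half_window)
  is_max <- vapply(seq_len(n), function(i)
    s[i] > 0 && s[i] >= max(s[max(1L, i - hw):min(n, i + hw)]), TRUE)
  snr <- s / noise
  keep <- which(is_max & snr >= snr_threshold)
  if (length(keep) > 1L) keep <- keep[c(TRUE, diff(keep) > hw)]
  peak_list(mz[keep], profile$peaks$intensity[keep], profile$specimen_id,
            profile$protocol, profile$replicate_id, snr = snr[keep])
}

#' Merge triplicate peak lists into a consensus peak list
#'
#' Peaks from all replicates of one specimen/protocol are clustered by
#' single-linkage in m/z (adjacent peaks closer than `tol` join one
#' cluster); clusters supported by at least `min_support` distinct
#' replicates are emitted with intensity-weighted mean m/z and the mean of
#' member intensities.
#'
#' @param replicates list of >= 2 [peak_list()] objects for the same
#'   specimen and protocol.
#' @param tol clustering tolerance in Da (default 0.2).
#' @param min_support minimal number of distinct replicates per kept peak
#'   (default 2).
#' @return An object of class `consensus_peaks` with elements
#'   `specimen_id`, `protocol`, `n_replicates` and a `peaks` data frame
#'   (`mz`, `intensity`, `support`).
#' @export
merge_replicates <- function(replicates, tol = 0.2, min_support = 2L) {
  stopifnot(length(replicates) >= 2L,
            all(vapply(replicates, inherits, TRUE, "peak_list")))
  sid <- unique(vapply(replicates, `[[`, "", "specimen_id"))
  prot <- unique(vapply(replicates, `[[`, "", "protocol"))
  if (length(sid) != 1L || length(prot) != 1L) {
    stop("replicates mix specimen_ids or protocols", call. = FALSE)
  }
  pooled <- do.call(rbind, lapply(replicates, function(r) {
    if (!nrow(r$peaks)) return(NULL)
    cbind(r$peaks, rep = r$replicate_id)
  }))
  if (is.null(pooled) || !nrow(pooled)) {
    return(structure(list(specimen_id = sid, protocol = prot,
                          n_replicates = length(replicates),
                          peaks = data.frame(mz = numeric(),
                                             intensity = numeric(),
                                             support = integer())),
                     class = "consensus_peaks"))
  }
  pooled <- pooled[order(pooled$mz), , drop = FALSE]
  grp <- cumsum(c(1, diff(pooled$mz) > tol))
  out <- do.call(rbind, lapply(split(pooled, grp), function(g) {
    data.frame(mz = sum(g$mz * g$intensity) / max(sum(g$intensity),
                                                  .Machine$double.eps),
               intensity = mean(g$intensity),
               support = length(unique(g$rep)))
  }))
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  structure(list(specimen_id = sid, protocol = prot,
                 n_replicates = length(replicates), peaks = out),
            class = "consensus_peaks")
}

#' @export
print.consensus_peaks <- function(x, ...) {
  cat(sprintf("<consensus_peaks %s [%s]: %d peaks from %d replicates>\n",
              x$specimen_id, x$protocol, nrow(x$peaks), x$n_replicates))
  invisible(x)
}
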