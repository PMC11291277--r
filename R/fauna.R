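#' Combine morphological and ZooMS identifications
#'
#' Each specimen may carry a morphological taxon, a ZooMS taxon, both, or
#' neither. Identifications are united at ZooMS-compatible group levels:
#' when both are present and one is an ancestor of the other the more
#' specific one is coarsened to its ZooMS group; a lone identification is
#' likewise coarsened; genuinely conflicting pairs (neither ancestor of
#' the other) resolve to their lowest common ancestor and are flagged.
#' Specimens falling in excluded clades (birds, rodents by default) or
#' whose resolved taxon reaches no ZooMS group are marked excluded.
#'
#' @param records data frame with columns `specimen_id`, `layer`,
#'   `morpho_taxon`, `zooms_taxon` (NA for absent).
#' @param taxonomy a [taxonomy()] resolving every non-NA taxon.
#' @param groups character vector of node names that constitute the ZooMS
#'   group levels of the analysis (e.g. `"Caprinae"`, `"Bos"`).
#' @param exclude node names whose descendants are excluded from
#'   community analysis (default none; pass e.g. `c("Aves",
#'   "Rodentia")`).
#' @return `records` with added columns `resolved_taxon` (NA when
#'   unidentified or excluded), `conflict` and `excluded` (logicals).
#' @export
combine_identifications <- function(records, taxonomy, groups,
                                    exclude = character()) {
  tax_check_node(taxonomy, stats::na.omit(unique(c(records$morpho_taxon,
                                                   records$zooms_taxon))))
  tax_check_node(taxonomy, c(groups, exclude))
  coarsen <- function(taxon) {
    anc <- tax_ancestors(taxonomy, taxon)
    hit <- anc[anc %in% groups]
    if (length(hit)) hit[1] else NA_character_
  }
  n <- nrow(records)
  resolved <- rep(NA_character_, n)
  conflict <- logical(n)
  excluded <- logical(n)
  for (i in seq_len(n)) {
    m <- records$morpho_taxon[i]; z <- records$zooms_taxon[i]
    base <- if (!is.na(m) && !is.na(z)) {
      if (tax_is_ancestor(taxonomy, m, z) ||
          tax_is_ancestor(taxonomy, z, m)) {
        # agreeing pair: keep the more specific, then coarsen
        if (tax_is_ancestor(taxonomy, m, z)) z else m
      } else {
        conflict[i] <- TRUE
        tax_lca(taxonomy, c(m, z))
      }
    } else if (!is.na(m)) m else if (!is.na(z)) z else NA_character_
    if (is.na(base)) next
    anc <- tax_ancestors(taxonomy, base)
    if (any(exclude %in% anc)) {
      excluded[i] <- TRUE
      next
    }
    g <- coarsen(base)
    if (is.na(g)) excluded[i] <- TRUE else resolved[i] <- g
  }
  records$resolved_taxon <- resolved
  records$conflict <- conflict
  records$excluded <- excluded
  records
}

#' Layer-by-taxon NISP table
#'
#' NISP (number of identified specimens) counts per stratigraphic layer
#' and resolved taxon; unresolved or excluded specimens are dropped.
#'
#' @param records output of [combine_identifications()].
#' @return Integer matrix, layers x taxa, of class `assemblage_table`.
#' @export
nisp_table <- function(records) {
  keep <- !is.na(records$resolved_taxon) & !records$excluded
  tab <- table(layer = records$layer[keep],
               taxon = records$resolved_taxon[keep])
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  class(m) <- c("assemblage_table", class(m))
  m
}

#' Percentage with zooarchaeological rounding
#'
#' `100 * n / denominator`, rounded half away from zero to one decimal —
#' the convention that reproduces printed assemblage ratios such as
#' 386/2005 -> 19.3.
#'
#' @param n,denominator counts.
#' @export
percentage <- function(n, denominator) {
  stopifnot(denominator > 0)
  round_half_up(100 * n / denominator, 1L)
}

#' Bone-surface-modification percentages
#'
#' @param records data frame with logical or 0/1 columns named by
#'   modification category (e.g. `cut_mark`, `percussion`, `burning`,
#'   `rodent_gnaw`, `carnivore_gnaw`), or a `modifications` column of
#'   `;`-separated codes.
#' @param categories character vector of categories to tabulate.
#' @param denominator either `"identified"` (rows with a non-NA
#'   `resolved_taxon`) or `"all_observed"` (all rows), or an explicit
#'   count.
#' @return Data frame `category, n, percent`.
#' @export
modification_percentages <- function(records, categories,
                                     denominator = "identified") {
  denom <- if (is.numeric(denominator)) denominator
  else if (denominator == "identified") {
    if (is.null(records$resolved_taxon))
      stop("no resolved_taxon column; run combine_identifications first",
           call. = FALSE)
    sum(!is.na(records$resolved_taxon))
  } else nrow(records)
  if (denom == 0) stop("empty denominator population", call. = FALSE)
  has <- function(cat) {
    if (!is.null(records[[cat]])) return(as.logical(records[[cat]]))
    if (!is.null(records$modifications)) {
      return(vapply(strsplit(records$modifications, ";"),
                    function(x) cat %in% x, TRUE))
    }
    stop("no column or code for category ", cat, call. = FALSE)
  }
  do.call(rbind, lapply(categories, function(cat) {
    n <- sum(has(cat), na.rm = TRUE)
    data.frame(category = cat, n = n, percent = percentage(n, denom))
  }))
}

#' Shannon and Simpson diversity with bootstrap confidence intervals
#'
#' Shannon H = -sum p_i ln p_i (natural log); Simpson D = 1 - sum p_i^2
#' (Gini-Simpson; set `simpson = "inverse"` for 1 / sum p_i^2).
#' Confidence intervals (2.5th-97.5th percentile) come from multinomial
#' resamples of each layer's specimens.
#'
#' @param table an [nisp_table()] (layers x taxa matrix).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param simpson `"gini"` (default) or `"inverse"`.
#' @return Data frame per layer: `layer, n, richness, shannon,
#'   shannon_lo, shannon_hi, simpson, simpson_lo, simpson_hi`.
#' @export
diversity_indices <- function(table, n_boot = 1000L, seed = 42L,
                              simpson = c("gini", "inverse")) {
  simpson <- match.arg(simpson)
  shannon_f <- function(x) {
    p <- x[x > 0] / sum(x)
    -sum(p * log(p))
  }
  simpson_f <- function(x) {
    p <- x[x > 0] / sum(x)
    if (simpson == "gini") 1 - sum(p^2) else 1 / sum(p^2)
  }
  set.seed(seed)
  out <- lapply(rownames(table), function(layer) {
    x <- table[layer, ]
    total <- sum(x)
    if (total < 1) stop("layer with zero NISP: ", layer, call. = FALSE)
    if (total == 1L) {
      warning("single-specimen layer ", layer, ": degenerate indices")
      return(data.frame(layer = layer, n = 1L, richness = 1L,
                        shannon = 0, shannon_lo = 0, shannon_hi = 0,
                        simpson = 0, simpson_lo = 0, simpson_hi = 0))
    }
    boots <- stats::rmultinom(n_boot, total, x / total)
    hb <- apply(boots, 2, shannon_f)
    db <- apply(boots, 2, simpson_f)
    data.frame(layer = layer, n = total, richness = sum(x > 0),
               shannon = shannon_f(x),
               shannon_lo = stats::quantile(hb, 0.025, names = FALSE),
               shannon_hi = stats::quantile(hb, 0.975, names = FALSE),
               simpson = simpson_f(x),
               simpson_lo = stats::quantile(db, 0.025, names = FALSE),
               simpson_hi = stats::quantile(db, 0.975, names = FALSE))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
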