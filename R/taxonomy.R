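#' Taxonomy trees for ZooMS assignment
#'
#' A taxonomy is a rooted tree of named nodes, each carrying one of the
#' ranks used in ZooMS practice (species up to class). Ranks must strictly
#' coarsen from any node towards the root, and names are unique, so a node
#' name identifies a node.
#'
#' @param name character vector of node names.
#' @param rank character vector of ranks, one of `species`, `genus`,
#'   `subfamily`, `family`, `superfamily`, `order`, `class`.
#' @param parent character vector of parent names; `NA` for the root.
#' @return An object of class `taxonomy`: a data frame with columns
#'   `name`, `rank`, `parent`.
#' @examples
#' tax <- taxonomy(
#'   name   = c("Mammalia", "Bovidae", "Bos", "Capra"),
#'   rank   = c("class", "family", "genus", "genus"),
#'   parent = c(NA, "Mammalia", "Bovidae", "Bovidae")
#' )
#' tax_lca(tax, c("Bos", "Capra"))
#' @export
taxonomy <- function(name, rank, parent) {
  rank_levels <- c("species", "genus", "subfamily", "family",
                   "superfamily", "order", "class")
  stopifnot(length(name) == length(rank), length(name) == length(parent))
  if (anyDuplicated(name)) {
    stop("taxon names must be unique", call. = FALSE)
  }
  if (!all(rank %in% rank_levels)) {
    stop("unknown rank: ", paste(setdiff(rank, rank_levels), collapse = ", "),
         call. = FALSE)
  }
  if (sum(is.na(parent)) != 1L) {
    stop("taxonomy must have exactly one root (parent = NA)", call. = FALSE)
  }
  known <- parent %in% name | is.na(parent)
  if (!all(known)) {
    stop("unknown parent: ", paste(parent[!known], collapse = ", "),
         call. = FALSE)
  }
  tax <- data.frame(name = as.character(name), rank = as.character(rank),
                    parent = as.character(parent), stringsAsFactors = FALSE)
  class(tax) <- c("taxonomy", "data.frame")
  # strict coarsening check
  ord <- match(tax$rank, rank_levels)
  pord <- ord[match(tax$parent, tax$name)]
  bad <- which(!is.na(tax$parent) & pord <= ord)
  if (length(bad)) {
    stop("rank does not coarsen from ", tax$name[bad[1]], " to its parent",
         call. = FALSE)
  }
  tax
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy: %d nodes, root '%s'>\n",
              nrow(x), x$name[is.na(x$parent)]))
  NextMethod()
}

tax_check_node <- function(tax, name) {
  missing <- setdiff(name, tax$name)
  if (length(missing)) {
    stop("taxon not in taxonomy: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(name)
}

#' Path from a node to the root
#'
#' @param tax a [taxonomy()].
#' @param name a single node name.
#' @return Character vector of node names from `name` (inclusive) up to the
#'   root.
#' @export
tax_ancestors <- function(tax, name) {
  tax_check_node(tax, name)
  path <- character()
  cur <- name
  while (!is.na(cur)) {
    path <- c(path, cur)
    cur <- tax$parent[match(cur, tax$name)]
  }
  path
}

#' Is `a` an ancestor of (or equal to) `b`?
#' @inheritParams tax_ancestors
#' @param a,b node names.
#' @export
tax_is_ancestor <- function(tax, a, b) {
  a %in% tax_ancestors(tax, b)
}

#' Lowest common ancestor of a set of nodes
#' @inheritParams tax_ancestors
#' @param names character vector of node names (non-empty).
#' @return The name of the deepest node that is an ancestor-or-self of all
#'   `names`.
#' @export
tax_lca <- function(tax, names) {
  if (!length(names)) stop("empty taxon set", call. = FALSE)
  tax_check_node(tax, names)
  paths <- lapply(names, function(n) rev(tax_ancestors(tax, n)))
  k <- min(lengths(paths))
  common <- 0L
  for (i in seq_len(k)) {
    if (length(unique(vapply(paths, `[[`, "", i))) == 1L) common <- i
    else break
  }
  if (common == 0L) stop("nodes do not share a root", call. = FALSE)
  paths[[1]][common]
}

#' Most specific taxon consistent with a set of matched taxa
#'
#' Collagen peptide markers are diagnostic at different ranks; a specimen
#' matching markers for, say, both Homininae and Hominoidea is assigned to
#' the deepest matched node when all matched nodes lie on one root-to-leaf
#' path. When matched nodes conflict (none is ancestor of all others) the
#' assignment coarsens to their lowest common ancestor.
#'
#' @inheritParams tax_ancestors
#' @param matched non-empty character vector of matched node names.
#' @return A single node name.
#' @export
lowest_consistent_taxon <- function(tax, matched) {
  if (!length(matched)) stop("empty matched-taxon set", call. = FALSE)
  matched <- unique(matched)
  tax_check_node(tax, matched)
  depth <- vapply(matched, function(n) length(tax_ancestors(tax, n)), 0L)
  for (cand in matched[order(-depth)]) {
    anc <- tax_ancestors(tax, cand)
    if (all(matched %in% anc)) return(cand)
  }
  # genuine conflict: a matched node that is an ancestor of another
  # matched node carries no extra constraint, so the LCA is taken over
  # the maximal (deepest) conflicting nodes only
  redundant <- vapply(matched, function(n)
    any(vapply(setdiff(matched, n), function(m)
      tax_is_ancestor(tax, n, m), TRUE)), TRUE)
  tax_lca(tax, matched[!redundant])
}

#' Read / write a taxonomy as three-column TSV
#'
#' Format: header `child	parent	rank`; the root row has an empty parent.
#' @inheritParams tax_ancestors
#' @param path file path.
#' @export
write_taxonomy <- function(tax, path) {
  out <- data.frame(child = tax$name,
                    parent = ifelse(is.na(tax$parent), "", tax$parent),
                    rank = tax$rank)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  taxonomy(name = df$child, rank = df$rank,
           parent = ifelse(df$parent == "", NA, df$parent))
}
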