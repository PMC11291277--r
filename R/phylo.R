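#' The Dayhoff amino-acid substitution model
#'
#' Builds the reversible rate matrix `Q = S diag(pi)` from the canonical
#' Dayhoff (1978) exchangeabilities and equilibrium frequencies, rescaled
#' so the expected substitution rate at equilibrium is 1 (branch lengths
#' are then expected substitutions per site). The spectral decomposition
#' of the symmetrized generator is precomputed so transition matrices
#' `P(t) = exp(Qt)` are cheap.
#'
#' @return List of class `rate_model` with elements `name`, `S`, `pi`,
#'   `Q`, `eigenvalues`, `U`, `Uinv`.
#' @export
dayhoff_model <- function() {
  S <- matrix(0, 20, 20, dimnames = list(DAYHOFF_AA, DAYHOFF_AA))
  S[lower.tri(S)] <- DAYHOFF_EXCH_LT
  S <- S + t(S)
  pi <- DAYHOFF_FREQ / sum(DAYHOFF_FREQ)
  names(pi) <- DAYHOFF_AA
  Q <- S %*% diag(pi)
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(pi * -diag(Q))
  dimnames(Q) <- list(DAYHOFF_AA, DAYHOFF_AA)
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(name = "Dayhoff", S = S, pi = pi, Q = Q,
                 eigenvalues = e$values,
                 U = diag(1 / sp) %*% e$vectors,
                 Uinv = t(e$vectors) %*% diag(sp)),
            class = "rate_model")
}

#' Transition probability matrix P(t) = exp(Qt)
#' @param model a [dayhoff_model()].
#' @param t branch length (>= 0), expected substitutions per site.
#' @export
prob_matrix <- function(model, t) {
  P <- model$U %*% (exp(model$eigenvalues * t) * model$Uinv)
  P[P < 0] <- 0
  P
}

# Order edges so every child edge precedes its parent edge, regardless of
# how the edge matrix is arranged (ape's reorder assumes cladewise input,
# which NNI-swapped edge matrices need not satisfy).
po_tree <- function(tree) {
  edge <- tree$edge
  n <- nrow(edge)
  kids <- split(seq_len(n), edge[, 1])
  root <- edge[!(edge[, 1] %in% edge[, 2]), 1][1]
  out <- integer(n)
  pos <- 0L
  stack <- list(list(node = root, i = 1L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    es <- kids[[as.character(top$node)]]
    if (is.null(es) || top$i > length(es)) {
      stack[[length(stack)]] <- NULL
      if (length(stack)) {
        par <- stack[[length(stack)]]
        e <- kids[[as.character(par$node)]][par$i]
        pos <- pos + 1L
        out[pos] <- e
        par$i <- par$i + 1L
        stack[[length(stack)]] <- par
      }
    } else {
      stack[[length(stack) + 1L]] <- list(node = edge[es[top$i], 2], i = 1L)
    }
  }
  tree$edge <- edge[out, , drop = FALSE]
  tree$edge.length <- tree$edge.length[out]
  tree
}

# --- alignment preparation ------------------------------------------------

# Compress a taxa x columns character matrix to site patterns.
# states: ntaxa x npat integer matrix, 0 = missing (X, -, ?).
aln_patterns <- function(mat) {
  states <- matrix(match(mat, DAYHOFF_AA, nomatch = 0L), nrow = nrow(mat),
                   dimnames = dimnames(mat))
  key <- apply(states, 2, paste, collapse = ",")
  first <- !duplicated(key)
  list(states = states[, first, drop = FALSE],
       w = as.numeric(table(key)[key[first]]),
       taxa = rownames(mat))
}

as_aln_matrix <- function(alignment) {
  if (inherits(alignment, "concat_alignment")) alignment$matrix
  else alignment
}

tip_partial <- function(state_row) {
  npat <- length(state_row)
  L <- matrix(1, 20L, npat)
  obs <- which(state_row > 0L)
  if (length(obs)) {
    L[, obs] <- 0
    L[cbind(state_row[obs], obs)] <- 1
  }
  L
}

# Core pruning over a pattern structure; tree must be binary (trifurcating
# base allowed). Scaling by column sums prevents underflow.
loglik_patterns <- function(tree, pat, model) {
  tree <- po_tree(tree)
  edge <- tree$edge
  el <- tree$edge.length
  ntip <- length(tree$tip.label)
  tipidx <- match(tree$tip.label, pat$taxa)
  if (anyNA(tipidx)) stop("tree tips missing from alignment", call. = FALSE)
  npat <- length(pat$w)
  partial <- vector("list", ntip + tree$Nnode)
  logsc <- numeric(npat)
  for (e in seq_len(nrow(edge))) {
    parent <- edge[e, 1]; child <- edge[e, 2]
    Lc <- if (child <= ntip) tip_partial(pat$states[tipidx[child], ])
          else partial[[child]]
    contrib <- prob_matrix(model, el[e]) %*% Lc
    partial[[parent]] <- if (is.null(partial[[parent]])) contrib
                         else partial[[parent]] * contrib
    sc <- colSums(partial[[parent]])
    sc[sc == 0] <- .Machine$double.xmin
    partial[[parent]] <- partial[[parent]] / rep(sc, each = 20L)
    logsc <- logsc + log(sc)
  }
  root <- edge[nrow(edge), 1]
  site <- colSums(model$pi * partial[[root]])
  ll <- sum(pat$w * (log(site) + logsc))
  if (!is.finite(ll)) {
    stop("non-finite log-likelihood (first bad pattern: ",
         which(!is.finite(log(site) + logsc))[1], ")", call. = FALSE)
  }
  ll
}

#' Log-likelihood of an alignment on a tree (Felsenstein pruning)
#'
#' X, `-` and `?` are treated as missing data (partial likelihood 1 for
#' every state). The likelihood of an unrooted tree is independent of the
#' rooting used for the computation (pulley principle).
#'
#' @param alignment a `concat_alignment` or character matrix (taxa x
#'   columns).
#' @param tree an `ape::phylo` tree with branch lengths; tips must be a
#'   subset of the alignment's taxa.
#' @param model a [dayhoff_model()].
#' @return The total log-likelihood (<= 0).
#' @export
log_likelihood <- function(alignment, tree, model = dayhoff_model()) {
  mat <- as_aln_matrix(alignment)
  loglik_patterns(tree, aln_patterns(mat[tree$tip.label, , drop = FALSE]),
                  model)
}

# --- branch-length optimization -------------------------------------------

# Coordinate-ascent branch-length optimization. One sweep computes the
# downward partials ("down") and an outside message ("W", with the root
# frequencies folded in) per node, then optimizes each branch with the
# one-dimensional eigen form
#   L_site(t) = sum_k exp(lambda_k t) * (U^T R)_k (U^-1 down)_k,
# so a Brent iteration costs one 20 x npat product. Messages refreshed
# top-down within the sweep; a full pruning pass at the end of each sweep
# guards monotonicity (a worsened sweep is rolled back).
optimize_branch_lengths <- function(tree, pat, model, sweeps = 3L,
                                    tol = 1e-3, max_bl = 10) {
  tree <- po_tree(tree)
  edge <- tree$edge
  nedge <- nrow(edge)
  ntip <- length(tree$tip.label)
  npat <- length(pat$w)
  tipidx <- match(tree$tip.label, pat$taxa)
  root <- edge[nedge, 1]
  tips <- lapply(seq_len(ntip), function(i)
    tip_partial(pat$states[tipidx[i], ]))
  down_of <- function(v, down) if (v <= ntip) tips[[v]] else down[[v]]
  ll <- loglik_patterns(tree, pat, model)
  for (s in seq_len(sweeps)) {
    el_before <- tree$edge.length
    # down pass
    down <- vector("list", ntip + tree$Nnode)
    M <- vector("list", nedge)
    for (e in seq_len(nedge)) {
      M[[e]] <- prob_matrix(model, tree$edge.length[e]) %*%
        down_of(edge[e, 2], down)
      p <- edge[e, 1]
      down[[p]] <- if (is.null(down[[p]])) M[[e]] else down[[p]] * M[[e]]
    }
    # outside pass with per-branch optimization
    W <- vector("list", ntip + tree$Nnode)
    W[[root]] <- matrix(model$pi, 20L, npat)
    for (e in rev(seq_len(nedge))) {
      p <- edge[e, 1]; v <- edge[e, 2]
      R <- W[[p]]
      for (e2 in which(edge[, 1] == p)) {
        if (e2 != e) R <- R * M[[e2]]
      }
      dv <- down_of(v, down)
      cm <- crossprod(model$U, R) * (model$Uinv %*% dv)
      f <- function(t) {
        sum(pat$w * log(pmax(colSums(exp(model$eigenvalues * t) * cm),
                             1e-300)))
      }
      opt <- stats::optimize(f, c(1e-9, max_bl), maximum = TRUE, tol = tol)
      if (opt$objective > f(tree$edge.length[e])) {
        tree$edge.length[e] <- opt$maximum
      }
      P <- prob_matrix(model, tree$edge.length[e])
      M[[e]] <- P %*% dv
      if (v > ntip) W[[v]] <- crossprod(P, R)
    }
    new_ll <- loglik_patterns(tree, pat, model)
    if (new_ll < ll) {            # stale messages overshot: roll back
      tree$edge.length <- el_before
      break
    }
    gain <- new_ll - ll
    ll <- new_ll
    if (gain < 0.01) break
  }
  attr(tree, "loglik") <- ll
  tree
}

# --- topology enumeration and NNI -----------------------------------------

# All unrooted binary topologies over the given taxa, as newick strings,
# by recursive addition of each taxon to every edge.
enumerate_topologies <- function(taxa) {
  stopifnot(length(taxa) >= 3L)
  grow <- function(trees, tip) {
    out <- list()
    for (tr in trees) {
      slots <- attach_points(tr)
      for (k in seq_len(slots)) {
        out[[length(out) + 1L]] <- attach_at(tr, k, tip)
      }
    }
    out
  }
  # nested-list representation: root is list of 3 subtrees; internal
  # nodes are lists of 2; leaves are character scalars. Every non-root
  # subtree occurrence is one edge, counted in preorder.
  attach_points <- function(tr) count_edges(tr, is_root = TRUE)
  count_edges <- function(node, is_root = FALSE) {
    if (is.character(node)) return(1L)
    sum(vapply(node, count_edges, 0L)) + if (is_root) 0L else 1L
  }
  attach_at <- function(tr, k, tip) {
    cnt <- 0L
    rec <- function(node, at_root) {
      if (!at_root) {
        cnt <<- cnt + 1L
        if (cnt == k) return(list(node, tip))
        if (is.character(node)) return(node)
      }
      for (i in seq_along(node)) node[[i]] <- rec(node[[i]], FALSE)
      node
    }
    rec(tr, TRUE)
  }
  to_newick <- function(node) {
    if (is.character(node)) return(node)
    paste0("(", paste(vapply(node, to_newick, ""), collapse = ","), ")")
  }
  trees <- list(as.list(taxa[1:3]))
  for (tip in taxa[-(1:3)]) trees <- grow(trees, tip)
  vapply(trees, function(tr) paste0(to_newick(tr), ";"), "")
}

# The two NNI neighbors around each internal edge of an unrooted binary
# tree (ape phylo with trifurcating base).
nni_neighbors <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  internal <- which(edge[, 2] > ntip)
  out <- list()
  for (e in internal) {
    u <- edge[e, 1]; v <- edge[e, 2]
    a_edges <- which(edge[, 1] == u & edge[, 2] != v)
    if (!length(a_edges)) next
    ea <- a_edges[1]
    child_edges <- which(edge[, 1] == v)
    for (ec in child_edges) {
      t2 <- tree
      t2$edge[ea, 2] <- edge[ec, 2]
      t2$edge[ec, 2] <- edge[ea, 2]
      out[[length(out) + 1L]] <- t2
    }
  }
  out
}

#' Maximum-likelihood tree search
#'
#' Exhaustive enumeration of unrooted topologies with per-topology
#' branch-length optimization for small taxon sets (<= 8 taxa; 105
#' topologies at 6 taxa, 945 at 7), or NNI hill-climbing from a
#' neighbor-joining start tree. The automatic strategy is exhaustive up
#' to 7 taxa.
#'
#' @param alignment a `concat_alignment` or character matrix.
#' @param model a [dayhoff_model()].
#' @param strategy `"auto"`, `"exhaustive_le8"` or `"nni"`.
#' @param start optional starting tree for NNI.
#' @param sweeps branch-length optimization sweeps per topology.
#' @return The best tree (`ape::phylo`) with attribute `"loglik"`.
#' @export
ml_search <- function(alignment, model = dayhoff_model(),
                      strategy = c("auto", "exhaustive_le8", "nni"),
                      start = NULL, sweeps = 2L) {
  strategy <- match.arg(strategy)
  mat <- as_aln_matrix(alignment)
  taxa <- rownames(mat)
  if (length(taxa) < 4L) stop("need at least 4 taxa", call. = FALSE)
  pat <- aln_patterns(mat)
  if (strategy == "auto") {
    strategy <- if (length(taxa) <= 7L) "exhaustive_le8" else "nni"
  }
  if (strategy == "exhaustive_le8") {
    if (length(taxa) > 8L) {
      stop("exhaustive search supported for <= 8 taxa; use nni",
           call. = FALSE)
    }
    best <- NULL; best_ll <- -Inf
    for (nwk in enumerate_topologies(taxa)) {
      tr <- ape::read.tree(text = nwk)
      tr$edge.length <- rep(0.1, nrow(tr$edge))
      tr <- optimize_branch_lengths(tr, pat, model, sweeps = sweeps)
      if (attr(tr, "loglik") > best_ll) {
        best <- tr; best_ll <- attr(tr, "loglik")
      }
    }
    return(best)
  }
  # NNI hill climbing
  cur <- if (!is.null(start)) start else nj_start_tree(mat)
  cur$edge.length[cur$edge.length < 1e-6] <- 1e-6
  cur <- optimize_branch_lengths(cur, pat, model, sweeps = sweeps)
  repeat {
    improved <- FALSE
    for (cand in nni_neighbors(cur)) {
      cand <- optimize_branch_lengths(cand, pat, model, sweeps = 1L)
      if (attr(cand, "loglik") > attr(cur, "loglik") + 1e-6) {
        cur <- optimize_branch_lengths(cand, pat, model, sweeps = sweeps)
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  cur
}

# Neighbor-joining start tree from 20-state Jukes-Cantor-like distances.
nj_start_tree <- function(mat) {
  taxa <- rownames(mat)
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- mat[i, ] %in% DAYHOFF_AA & mat[j, ] %in% DAYHOFF_AA
      p <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 0.5
      p <- min(p, 0.93)
      D[i, j] <- D[j, i] <- -19 / 20 * log(1 - 20 / 19 * p)
    }
  }
  tr <- ape::nj(as.dist(D))
  tr <- ape::unroot(tr)
  tr$edge.length <- pmax(tr$edge.length, 1e-6)
  tr
}

# --- bootstrap -------------------------------------------------------------

# Canonical keys of the non-trivial bipartitions of an unrooted tree:
# the leaf set on the far side of each internal edge, normalized to the
# side not containing the reference taxon.
bipartitions <- function(tree, ref = NULL) {
  ntip <- length(tree$tip.label)
  if (is.null(ref)) ref <- sort(tree$tip.label)[1]
  tree <- po_tree(tree)
  edge <- tree$edge
  below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) below[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; c <- edge[e, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  keys <- character(); nodes <- integer()
  for (e in which(edge[, 2] > ntip)) {
    clade <- below[[edge[e, 2]]]
    if (length(clade) <= 1L || length(clade) >= ntip - 1L) next
    side <- if (ref %in% clade) setdiff(tree$tip.label, clade) else clade
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, edge[e, 2])
  }
  list(keys = keys, nodes = nodes)
}

#' Nonparametric bootstrap support for the ML tree
#'
#' Alignment columns are resampled with replacement; a tree search is run
#' per replicate (NNI from the full-data ML tree, which is also the
#' returned tree); each internal edge of the ML tree is annotated with
#' the fraction of replicate trees containing its bipartition.
#'
#' @param alignment a `concat_alignment` or character matrix.
#' @param model a [dayhoff_model()].
#' @param n_boot number of replicates (>= 10).
#' @param seed RNG seed.
#' @param tree optional precomputed ML tree (skips the initial search).
#' @param sweeps branch-length sweeps inside replicate searches.
#' @return The ML tree with `node.label` holding supports in \[0,1\]
#'   (empty at the base) and attribute `"support_table"`.
#' @export
bootstrap_support <- function(alignment, model = dayhoff_model(),
                              n_boot = 100L, seed = 42L, tree = NULL,
                              sweeps = 1L) {
  stopifnot(n_boot >= 10L)
  mat <- as_aln_matrix(alignment)
  if (is.null(tree)) tree <- ml_search(mat, model)
  set.seed(seed)
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    bt <- ml_search(mat[, cols, drop = FALSE], model, strategy = "nni",
                    start = tree, sweeps = sweeps)
    for (k in bipartitions(bt)$keys) {
      assign(k, (if (exists(k, counts)) get(k, counts) else 0) + 1,
             counts)
    }
  }
  bp <- bipartitions(tree)
  supp <- vapply(bp$keys, function(k)
    (if (exists(k, counts)) get(k, counts) else 0) / n_boot, 0)
  ntip <- length(tree$tip.label)
  labels <- rep("", tree$Nnode)
  labels[bp$nodes - ntip] <- formatC(supp, format = "f", digits = 2)
  tree$node.label <- labels
  attr(tree, "support_table") <- data.frame(bipartition = bp$keys,
                                            support = unname(supp))
  tree
}
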