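#' Configuration for the synthetic-data generators
#'
#' The defaults describe the stated world every generator emulates: an
#' eight-species assemblage over four families (the smallest taxonomy
#' exercising species-, genus- and family-level assignment), triplicate
#' MALDI spotting, layer-graded glutamine deamidation spanning the range
#' seen in deeply stratified cave sites, peptide error rates typical of
#' confidently filtered PSM tables, and a great-ape-like proteome tree
#' with one low-coverage "ancient" leaf.
#'
#' @param seed integer seed fixed before any draw.
#' @param n_taxa number of species (default 8, over `n_taxa/2` genera).
#' @param n_families number of families (default 4).
#' @param n_diagnostic species-level diagnostic substitutions per species
#'   (default 3).
#' @param layers ordered (shallow to deep) layer labels.
#' @param deamidation_by_layer named true non-deamidated fraction q per
#'   layer (1 = pristine, 0 = fully deamidated).
#' @param n_specimens_per_layer specimens simulated per layer.
#' @param mz_noise_sd Gaussian m/z error in Da (default 0.03, MALDI-TOF
#'   external calibration).
#' @param dropout per-replicate marker dropout probability (default 0.1).
#' @param noise_peaks_per_spectrum uniform background peaks per replicate.
#' @param peptide_error_rate per-residue PSM error rate epsilon.
#' @param coverage_depth target peptide coverage depth for PSM tables.
#' @param tree `ape::phylo` tree with branch lengths for proteome
#'   simulation; default an 8-leaf hominid-like tree with an `Ancient`
#'   leaf sister to `Denisovan`.
#' @param site_count alignment columns to simulate.
#' @param ancient_taxon leaf masked to low coverage.
#' @param ancient_coverage fraction of columns retained for the ancient
#'   leaf (default 0.145).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 42L, n_taxa = 8L, n_families = 4L,
                       n_diagnostic = 3L,
                       layers = c("L3", "L5", "L7", "L10"),
                       deamidation_by_layer = c(L3 = 0.7, L5 = 0.5,
                                                L7 = 0.3, L10 = 0.1),
                       n_specimens_per_layer = 10L,
                       mz_noise_sd = 0.03, dropout = 0.1,
                       noise_peaks_per_spectrum = 5L,
                       peptide_error_rate = 0.02, coverage_depth = 6L,
                       tree = NULL, site_count = 2000L,
                       ancient_taxon = "Ancient",
                       ancient_coverage = 0.145) {
  stopifnot(n_taxa >= 2L, all(deamidation_by_layer >= 0),
            all(deamidation_by_layer <= 1))
  if (is.null(tree)) {
    tree <- ape::read.tree(text = paste0(
      "(Outgroup:0.10,(Gorilla:0.08,((Chimp:0.06,((Modern1:0.02,",
      "Modern2:0.02):0.02,Neanderthal:0.03):0.03):0.03,",
      "(Denisovan:0.02,Ancient:0.02):0.05):0.03):0.04);"))
  }
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 n_families = as.integer(n_families),
                 n_diagnostic = as.integer(n_diagnostic),
                 layers = layers,
                 deamidation_by_layer = deamidation_by_layer,
                 n_specimens_per_layer = as.integer(n_specimens_per_layer),
                 mz_noise_sd = mz_noise_sd, dropout = dropout,
                 noise_peaks_per_spectrum =
                   as.integer(noise_peaks_per_spectrum),
                 peptide_error_rate = peptide_error_rate,
                 coverage_depth = as.integer(coverage_depth),
                 tree = tree, site_count = as.integer(site_count),
                 ancient_taxon = ancient_taxon,
                 ancient_coverage = ancient_coverage),
            class = "sim_config")
}

# Residues safe to substitute between species: mutually > 0.9 Da apart
# and never creating/destroying cleavage (K/R), proline or glycine.
SIM_SUB_POOL <- c("A", "S", "V", "T", "L", "F", "E", "Q")

# Deterministic collagen-like base chain: Gly-X-Y triplets organised into
# tryptic segments, with the two deamidation marker peptides embedded
# verbatim (they are conserved across terrestrial mammals).
sim_base_sequence <- function(n_segments = 40L) {
  xy <- c("P", "A", "S", "E", "L", "V", "T", "F", "Q", "D")
  set.seed(7041L)  # base chain is a fixture, independent of sim seed
  segs <- vapply(seq_len(n_segments), function(i) {
    ntrip <- sample(3:6, 1)
    body <- paste(vapply(seq_len(ntrip), function(j)
      paste0("G", sample(xy, 1), sample(xy, 1)), ""), collapse = "")
    paste0(body, sample(c("K", "R"), 1))
  }, "")
  # embed the deamidation peptides as segments 5 and 6
  segs[5] <- "GVQGPPGPAGPR"
  segs[6] <- "DGEAGAQGPPGPAGPAGER"
  paste(segs, collapse = "")
}

#' Simulate COL1-like sequences for a synthetic taxonomy
#'
#' Builds an `n_taxa`-species taxonomy over `n_families` families, then
#' mutates a shared collagen-like base chain hierarchically:
#' family-level substitutions shared within each family and
#' `n_diagnostic` species-private substitutions, all placed inside
#' distinct tryptic peptides so every species carries at least
#' `n_diagnostic` species-diagnostic markers.
#'
#' @param config a [sim_config()].
#' @return List: `sequences` (named by species), `taxonomy`, `truth`
#'   (data frame species/genus/family).
#' @export
simulate_col1_taxa <- function(config = sim_config()) {
  set.seed(config$seed)
  nf <- config$n_families
  nsp <- config$n_taxa
  fam <- sprintf("Family%d", seq_len(nf))
  gen <- sprintf("Genus%d", seq_len(nf))
  species <- sprintf("Species%d%s", rep(seq_len(nf), length.out = nsp),
                     letters[ceiling(seq_len(nsp) / nf)])
  sp_fam <- rep(seq_len(nf), length.out = nsp)
  tax <- taxonomy(
    name = c("Mammalia", fam, gen, species),
    rank = c("class", rep("family", nf), rep("genus", nf),
             rep("species", nsp)),
    parent = c(NA, rep("Mammalia", nf), fam, gen[sp_fam]))
  base <- sim_base_sequence()
  res <- strsplit(base, "")[[1]]
  # editable positions: substitutable residues outside the two reserved
  # deamidation peptides, one per tryptic peptide
  peps <- digest_sequence(base, min_length = 6, max_missed_cleavages = 0)
  reserved <- c("GVQGPPGPAGPR", "DGEAGAQGPPGPAGPAGER")
  sites <- integer()
  for (p in setdiff(peps, reserved)) {
    at <- regexpr(p, base, fixed = TRUE)
    cand <- which(strsplit(p, "")[[1]] %in% SIM_SUB_POOL)
    if (at > 0L && length(cand)) {
      sites <- c(sites, as.integer(at) + cand[ceiling(length(cand) / 2)] - 1L)
    }
  }
  sites <- unique(sites)
  need <- nf * 2L + nsp * config$n_diagnostic
  if (length(sites) < need) {
    stop("base chain too short for requested diagnostic structure",
         call. = FALSE)
  }
  sites <- sample(sites, need)
  fam_sites <- matrix(sites[seq_len(nf * 2L)], nrow = nf)
  sp_sites <- matrix(sites[-seq_len(nf * 2L)], nrow = nsp)
  mutate <- function(chars, pos) {
    cur <- chars[pos]
    chars[pos] <- vapply(cur, function(x)
      sample(setdiff(SIM_SUB_POOL, x), 1), "")
    chars
  }
  seqs <- character(nsp)
  fam_variants <- lapply(seq_len(nf), function(f) mutate(res, fam_sites[f, ]))
  for (i in seq_len(nsp)) {
    chars <- mutate(fam_variants[[sp_fam[i]]], sp_sites[i, ])
    seqs[i] <- paste(chars, collapse = "")
  }
  names(seqs) <- species
  list(sequences = seqs, taxonomy = tax,
       truth = data.frame(species = species, genus = gen[sp_fam],
                          family = fam[sp_fam],
                          stringsAsFactors = FALSE))
}

#' Simulate triplicate MALDI peak lists with ground truth
#'
#' Each specimen gets the marker peaks of its true taxon (markers
#' diagnostic at the species or any of its ancestors), log-normal
#' intensities, Gaussian m/z error, per-replicate dropout and uniform
#' background peaks. The two deamidation peptides are emitted as full
#' isotope envelopes with intensity split q : (1 - q) between the Q and
#' deamidated combs according to the specimen layer's true q.
#'
#' @param config a [sim_config()].
#' @param db a [marker_database()] (typically from [predict_markers()] on
#'   [simulate_col1_taxa()] output).
#' @param taxa optional character vector of species to draw specimens
#'   from (default: all species in the taxonomy).
#' @return List: `spectra` (list per specimen of 3 [peak_list()]s),
#'   `truth` (data frame specimen_id/taxon/layer/q).
#' @export
simulate_spectra <- function(config = sim_config(), db, taxa = NULL) {
  set.seed(config$seed + 1L)
  tax <- db$taxonomy
  if (is.null(taxa)) taxa <- tax$name[tax$rank == "species"]
  layers <- config$layers
  truth <- list(); spectra <- list()
  n_iso <- 5L
  env_cache <- lapply(DEAMIDATION_PEPTIDES, function(p) list(
    Q = theoretical_envelope(p$sequence, p$n_hyd, 0L, n_iso),
    D = theoretical_envelope(p$sequence, p$n_hyd, 1L, n_iso)))
  idx <- 0L
  for (layer in layers) {
    q <- config$deamidation_by_layer[[layer]]
    for (k in seq_len(config$n_specimens_per_layer)) {
      idx <- idx + 1L
      sid <- sprintf("SYN-%03d", idx)
      taxon <- taxa[1L + (idx - 1L) %% length(taxa)]
      anc <- tax_ancestors(tax, taxon)
      mk <- db$markers[db$markers$taxon %in% anc, , drop = FALSE]
      # reserved deamidation peptides handled separately as envelopes
      dea_mz <- vapply(env_cache, function(e) e$Q$base_mz, 0)
      mk <- mk[!vapply(mk$mz_MH, function(m)
        any(abs(m - dea_mz) < 0.01 | abs(m - dea_mz - DEAMIDATION_SHIFT)
            < 0.01), TRUE), , drop = FALSE]
      reps <- lapply(1:3, function(r) {
        keep <- stats::runif(nrow(mk)) > config$dropout
        mz <- mk$mz_MH[keep] +
          stats::rnorm(sum(keep), 0, config$mz_noise_sd)
        int <- stats::rlnorm(sum(keep), log(500), 0.4)
        for (pep in names(env_cache)) {
          if (stats::runif(1) < config$dropout) next
          e <- env_cache[[pep]]
          amp <- stats::rlnorm(1, log(800), 0.3)
          grid <- e$Q$base_mz + (0:n_iso) * ISOTOPE_SPACING
          yy <- q * c(e$Q$relative_abundances, 0) +
            (1 - q) * c(0, e$D$relative_abundances)
          on <- yy > 1e-4
          mz <- c(mz, grid[on] +
                    stats::rnorm(sum(on), 0, config$mz_noise_sd))
          int <- c(int, amp * yy[on])
        }
        nnoise <- config$noise_peaks_per_spectrum
        if (nnoise > 0) {
          mz <- c(mz, stats::runif(nnoise, 800, 3500))
          int <- c(int, stats::rlnorm(nnoise, log(80), 0.6))
        }
        peak_list(mz, int, specimen_id = sid, protocol = "acid",
                  replicate_id = r)
      })
      spectra[[sid]] <- reps
      truth[[sid]] <- data.frame(specimen_id = sid, taxon = taxon,
                                 layer = layer, q = q,
                                 stringsAsFactors = FALSE)
    }
  }
  list(spectra = spectra, truth = do.call(rbind, truth))
}

#' Simulate a PSM table with decoys and ground truth
#'
#' Tryptic-ish peptides are tiled over each protein to the target
#' coverage depth, per-residue errors applied at rate epsilon, decoys
#' generated by sequence reversal with scores from a clearly lower
#' distribution, and spectral counts drawn geometric.
#'
#' @param config a [sim_config()].
#' @param true_proteome named character vector protein_id -> sequence;
#'   default: three synthetic 120-residue proteins.
#' @param peptides_per_protein optional named integer vector forcing the
#'   number of distinct peptides for specific proteins.
#' @return List: `psms` (data frame with decoys appended), `proteome`.
#' @export
simulate_psm_table <- function(config = sim_config(),
                               true_proteome = NULL,
                               peptides_per_protein = NULL) {
  set.seed(config$seed + 2L)
  if (is.null(true_proteome)) {
    true_proteome <- vapply(1:3, function(i)
      paste(sample(AMINO_ACIDS, 120, replace = TRUE,
                   prob = DAYHOFF_FREQ[match(AMINO_ACIDS, DAYHOFF_AA)]),
            collapse = ""), "")
    names(true_proteome) <- sprintf("PROT%d", 1:3)
  }
  rows <- list()
  for (pid in names(true_proteome)) {
    s <- true_proteome[[pid]]
    len <- nchar(s)
    n_pep <- if (!is.null(peptides_per_protein) &&
                 pid %in% names(peptides_per_protein)) {
      peptides_per_protein[[pid]]
    } else {
      max(5L, ceiling(config$coverage_depth * len / 14))
    }
    pool <- seq_len(max(1L, len - 8L))
    starts <- sample(pool, n_pep, replace = n_pep > length(pool))
    for (st in starts) {
      plen <- min(sample(8:20, 1), len - st + 1L)
      pep <- strsplit(substr(s, st, st + plen - 1L), "")[[1]]
      err <- stats::runif(plen) < config$peptide_error_rate
      if (any(err)) {
        pep[err] <- vapply(pep[err], function(x)
          sample(setdiff(AMINO_ACIDS, x), 1), "")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, peptide = paste(pep, collapse = ""),
        start = st, score = stats::rnorm(1, 60, 8),
        spectral_count = stats::rgeom(1, 0.5) + 1L,
        is_decoy = FALSE, stringsAsFactors = FALSE)
    }
  }
  targets <- do.call(rbind, rows)
  decoys <- targets
  decoys$peptide <- vapply(strsplit(decoys$peptide, ""), function(x)
    paste(rev(x), collapse = ""), "")
  decoys$protein_id <- paste0("DECOY_", decoys$protein_id)
  decoys$score <- stats::rnorm(nrow(decoys), 25, 8)
  decoys$is_decoy <- TRUE
  list(psms = rbind(targets, decoys), proteome = true_proteome)
}

#' Simulate an amino-acid alignment on a tree under the Dayhoff model
#'
#' The root sequence is drawn from the equilibrium frequencies and
#' evolved along the tree with exact transition sampling (matrix
#' exponentials per branch). One designated "ancient" taxon is masked
#' with gaps down to a target coverage fraction, emulating a sparsely
#' reconstructed palaeoproteome.
#'
#' @param config a [sim_config()]; uses `tree`, `site_count`,
#'   `ancient_taxon`, `ancient_coverage`.
#' @param model a [dayhoff_model()].
#' @return List: `alignment` (character matrix taxa x sites), `tree`
#'   (the true tree), `kept_sites` (indices retained for the ancient
#'   taxon).
#' @export
simulate_alignment <- function(config = sim_config(),
                               model = dayhoff_model()) {
  set.seed(config$seed + 3L)
  tree <- po_tree(config$tree)
  if (length(tree$tip.label) < 4L) stop("tree needs >= 4 leaves",
                                        call. = FALSE)
  nsite <- config$site_count
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  edge <- tree$edge
  root <- edge[nrow(edge), 1]
  states <- matrix(NA_integer_, nnode, nsite)
  states[root, ] <- sample.int(20L, nsite, replace = TRUE,
                               prob = model$pi)
  for (e in rev(seq_len(nrow(edge)))) {  # preorder
    P <- prob_matrix(model, tree$edge.length[e])
    parent_states <- states[edge[e, 1], ]
    child <- integer(nsite)
    for (a in unique(parent_states)) {
      i <- which(parent_states == a)
      child[i] <- sample.int(20L, length(i), replace = TRUE,
                             prob = pmax(P[a, ], 0))
    }
    states[edge[e, 2], ] <- child
  }
  aln <- matrix(DAYHOFF_AA[states[seq_len(ntip), ]], ntip, nsite,
                dimnames = list(tree$tip.label, NULL))
  kept <- seq_len(nsite)
  at <- config$ancient_taxon
  if (!is.null(at) && at %in% rownames(aln) &&
      config$ancient_coverage < 1) {
    if (config$ancient_coverage <= 0) {
      aln[at, ] <- "-"
      kept <- integer()
      warning("ancient taxon fully masked: placement undefined")
    } else {
      kept <- sort(sample(nsite, round(config$ancient_coverage * nsite)))
      aln[at, setdiff(seq_len(nsite), kept)] <- "-"
    }
  }
  list(alignment = aln, tree = tree, kept_sites = kept)
}
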