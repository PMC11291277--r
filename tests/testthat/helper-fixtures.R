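# Shared fixtures, built in code.

# Hominoid taxonomy slice used for assignment tests.
hominoid_taxonomy <- function() {
  taxonomy(
    name = c("Hominoidea", "Hominidae", "Homininae", "Ponginae",
             "Homo", "Pan", "Pongo"),
    rank = c("superfamily", "family", "subfamily", "subfamily",
             "genus", "genus", "genus"),
    parent = c(NA, "Hominoidea", "Hominidae", "Hominidae",
               "Homininae", "Homininae", "Ponginae"))
}

# Bovid/cervid taxonomy for LCA and faunal tests.
ungulate_taxonomy <- function() {
  taxonomy(
    name = c("Mammalia", "Artiodactyla", "Bovidae", "Cervidae",
             "Caprinae", "Bos", "Capra", "Cervus",
             "Bos mutus", "Cervus elaphus", "Aves", "Rodentia"),
    rank = c("class", "order", "family", "family",
             "subfamily", "genus", "genus", "genus",
             "species", "species", "order", "order"),
    parent = c(NA, "Mammalia", "Artiodactyla", "Artiodactyla",
               "Bovidae", "Bovidae", "Caprinae", "Cervidae",
               "Bos", "Cervus", "Mammalia", "Mammalia"))
}

# A small mass-only marker database over the hominoid taxonomy.
hominoid_db <- function() {
  mk <- do.call(rbind, c(
    lapply(1:14, function(i) marker_record(
      label = sprintf("HOM%02d", i), mz_MH = 1000 + 37 * i,
      diagnostic_taxon = "Homininae", source = "measured")),
    list(marker_record(label = "HDA01", mz_MH = 2600.5,
                       diagnostic_taxon = "Hominoidea",
                       source = "measured"),
         marker_record(label = "PON01", mz_MH = 2710.7,
                       diagnostic_taxon = "Ponginae",
                       source = "measured"))))
  marker_database(hominoid_taxonomy(), mk)
}

# Consensus-peaks object from bare vectors.
consensus_from_peaks <- function(mz, intensity = rep(100, length(mz)),
                                 specimen_id = "T1") {
  structure(list(specimen_id = specimen_id, protocol = "acid",
                 n_replicates = 3L,
                 peaks = data.frame(mz = mz, intensity = intensity,
                                    support = 3L)),
            class = "consensus_peaks")
}

# Random rooted taxonomy with unique ranks per depth, for property tests.
random_taxonomy <- function(n_nodes, seed) {
  set.seed(seed)
  ranks <- c("class", "order", "family", "genus", "species")
  name <- sprintf("N%02d", seq_len(n_nodes))
  parent <- rep(NA_character_, n_nodes)
  depth <- integer(n_nodes); depth[1] <- 1L
  for (i in 2:n_nodes) {
    cand <- which(depth[seq_len(i - 1L)] < length(ranks))
    p <- if (length(cand) == 1L) cand else sample(cand, 1)
    parent[i] <- name[p]
    depth[i] <- depth[p] + 1L
  }
  taxonomy(name, ranks[depth], parent)
}

# Brute-force lowest-consistent-taxon oracle: enumerate every node; a
# node is consistent when it is comparable (ancestor/descendant) with
# every matched node and lies on some matched node's root path; return
# the deepest consistent node. Independent of the implementation's
# path-support shortcut.
lct_oracle <- function(tax, matched) {
  paths <- lapply(matched, function(m) tax_ancestors(tax, m))
  best <- NULL; best_depth <- -1L
  for (n in tax$name) {
    anc_n <- tax_ancestors(tax, n)
    comparable <- all(vapply(matched, function(m)
      n %in% tax_ancestors(tax, m) || m %in% anc_n, TRUE))
    on_path <- any(vapply(paths, function(p) n %in% p, TRUE))
    if (comparable && on_path && length(anc_n) > best_depth) {
      best <- n; best_depth <- length(anc_n)
    }
  }
  best
}
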