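test_that("tryptic digestion applies the K/R rule with the KP exception", {
  expect_setequal(digest_sequence("AAKPGGKRAA", 1, 0),
                  c("AAKPGGK", "R", "AA"))
  expect_identical(digest_sequence("GGG", 1, 0), "GGG")
  res <- digest_sequence("AKR", 1, 1)
  expect_true(all(c("AKR", "AK", "R") %in% res))
  # min_length drops short fragments
  expect_identical(digest_sequence("AAKPGGKRAA", 6, 0), "AAKPGGK")
  # enumeration oracle for missed cleavages on a 3-site chain
  res2 <- digest_sequence("AAKGGKCCKDD", 1, 2)
  expect_setequal(res2, c("AAK", "GGK", "CCK", "DD", "AAKGGK", "GGKCCK",
                          "CCKDD", "AAKGGKCCK", "GGKCCKDD"))
  expect_error(digest_sequence("AAZK", 1, 0), "position 3")
})

test_that("peptide m/z matches the residue-mass oracle for the ZooMS markers", {
  # frozen values cross-checked against an independent monoisotopic
  # mass calculator
  expect_equal(peptide_mz("GVQGPPGPAGPR", 1, 0, 1), 1105.5748,
               tolerance = 0.01)
  expect_equal(peptide_mz("GVQGPPGPAGPR", 1, 1, 1), 1106.5589,
               tolerance = 0.01)
  expect_equal(peptide_mz("DGEAGAQGPPGPAGPAGER", 1, 0, 1), 1706.7728,
               tolerance = 0.01)
  # charge-2 halves the protonated mass
  m1 <- peptide_mz("GVQGPPGPAGPR", 1, 0, 1)
  m2 <- peptide_mz("GVQGPPGPAGPR", 1, 0, 2)
  expect_equal(m2, (m1 + 1.007276) / 2, tolerance = 1e-9)
  expect_error(peptide_mz("GGG", 1, 0), "proline")
  expect_error(peptide_mz("GGG", 0, 1), "N\\+Q")
})

test_that("modification shifts are exactly additive", {
  seqs <- c("GVQGPPGPAGPR", "DGEAGAQGPPGPAGPAGER", "AQPNPK")
  for (s in seqs) {
    for (h in 0:1) {
      expect_equal(peptide_mz(s, h + 1, 0) - peptide_mz(s, h, 0),
                   15.994915, tolerance = 1e-10)
      expect_equal(peptide_mz(s, h, 1) - peptide_mz(s, h, 0),
                   0.984016, tolerance = 1e-10)
    }
  }
})

test_that("predict_markers assigns diagnostic ranks by mass sharing", {
  tax <- taxonomy(c("Root", "GenusA", "A1", "A2"),
                  c("family", "genus", "species", "species"),
                  c(NA, "Root", "GenusA", "GenusA"))
  base <- "GAPGALGPKGVEGAPGLRGGAPGDSGPR"
  variant <- sub("GVEGAPGLR", "GVEGSPGLR", base)  # A->S in one peptide
  db <- predict_markers(c(A1 = base, A2 = variant), tax,
                        hydroxylation_range = 0,
                        max_missed_cleavages = 0)
  m <- db$markers
  expect_true(all(m$taxon[m$sequence %in% c("GVEGAPGLR", "GVEGSPGLR")]
                  %in% c("A1", "A2")))
  expect_true(all(m$taxon[!m$sequence %in% c("GVEGAPGLR", "GVEGSPGLR")]
                  == "GenusA"))
  # single taxon: everything diagnostic at that taxon
  db1 <- predict_markers(c(A1 = base), tax, hydroxylation_range = 0,
                         max_missed_cleavages = 0)
  expect_true(all(db1$markers$taxon == "A1"))
  # identical sequences: only shared-ancestor diagnostics
  db2 <- predict_markers(c(A1 = base, A2 = base), tax,
                         hydroxylation_range = 0, max_missed_cleavages = 0)
  expect_true(all(db2$markers$taxon == "GenusA"))
})

test_that("three-taxon shared derived mass lands at the exclusive ancestor", {
  tax <- taxonomy(c("Root", "G1", "G2", "A1", "A2", "B1"),
                  c("family", "genus", "genus", "species", "species",
                    "species"),
                  c(NA, "Root", "Root", "G1", "G1", "G2"))
  base <- "GAPGALGPKGVEGAPGLRGGAPGDSGPR"
  derived <- sub("GVEGAPGLR", "GVEGSPGLR", base)
  db <- predict_markers(c(A1 = derived, A2 = derived, B1 = base), tax,
                        hydroxylation_range = 0,
                        max_missed_cleavages = 0)
  m <- db$markers
  expect_identical(unique(m$taxon[m$sequence == "GVEGSPGLR"]), "G1")
  expect_identical(unique(m$taxon[m$sequence == "GVEGAPGLR"]), "B1")
})

test_that("lowest_consistent_taxon matches the paper's Homininae case", {
  tax <- hominoid_taxonomy()
  expect_identical(lowest_consistent_taxon(tax, c("Homininae",
                                                  "Hominoidea")),
                   "Homininae")
  expect_identical(lowest_consistent_taxon(tax, "Homo"), "Homo")
  utax <- ungulate_taxonomy()
  expect_identical(
    lowest_consistent_taxon(utax, c("Caprinae", "Bovidae", "Cervidae")),
    tax_lca(utax, c("Bovidae", "Cervidae")))
  expect_error(lowest_consistent_taxon(tax, character()), "empty")
})

test_that("lowest_consistent_taxon agrees with the enumeration oracle", {
  for (seed in 1:8) {
    tax <- random_taxonomy(sample(10:50, 1), seed)
    for (rep in 1:5) {
      matched <- sample(tax$name, sample(1:4, 1))
      expect_identical(lowest_consistent_taxon(tax, matched),
                       lct_oracle(tax, matched),
                       info = sprintf("seed %d rep %d: {%s}", seed, rep,
                                      paste(matched, collapse = ",")))
    }
  }
})

test_that("marker database round-trips through TSV", {
  sim <- simulate_col1_taxa(sim_config(seed = 3))
  db <- predict_markers(sim$sequences, sim$taxonomy)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_db(db, path)
  db2 <- read_marker_db(path)
  expect_identical(db2$markers$label, db$markers$label)
  expect_identical(db2$markers$taxon, db$markers$taxon)
  expect_identical(db2$markers$sequence, db$markers$sequence)
  expect_equal(db2$markers$mz_MH, db$markers$mz_MH, tolerance = 5e-5)
  # idempotence at storage precision
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_marker_db(db2, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_identical(db$taxonomy, db2$taxonomy)
})

test_that("marker_record enforces its invariants", {
  expect_error(marker_record("X", mz_MH = 1100,
                             sequence = "GVQGPPGPAGPR",
                             n_hydroxylations = 1,
                             diagnostic_taxon = "Homo"),
               "disagrees")
  tax <- hominoid_taxonomy()
  mk <- rbind(marker_record("A", 1000, diagnostic_taxon = "Homo"),
              marker_record("A", 1000, diagnostic_taxon = "Homo"))
  expect_error(marker_database(tax, mk), "duplicate")
  expect_error(marker_database(tax, marker_record(
    "A", 1000, diagnostic_taxon = "Bos")), "not in taxonomy")
})
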