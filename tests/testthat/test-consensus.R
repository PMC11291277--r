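mk_psms <- function(scores_t, scores_d) {
  rbind(
    data.frame(protein_id = "P", peptide = "AAAAAA", start = 1,
               score = scores_t, spectral_count = 1, is_decoy = FALSE),
    data.frame(protein_id = "D", peptide = "AAAAAA", start = 1,
               score = scores_d, spectral_count = 1, is_decoy = TRUE))
}

test_that("target-decoy q-values behave at the toy limits", {
  # 99 targets above the single decoy: all pass at 0.5% FDR
  psms <- mk_psms(seq(100, 2, length.out = 99), 1)
  expect_equal(nrow(filter_fdr(psms, 0.005)), 99L)
  # fdr 0: only targets strictly above every decoy survive
  psms2 <- mk_psms(c(10, 9, 5, 4), 7)
  kept <- filter_fdr(psms2, 0)
  expect_equal(sort(kept$score), c(9, 10))
  # all decoys outscore all targets: nothing survives
  psms3 <- mk_psms(c(3, 2, 1), c(10, 9, 8))
  expect_equal(nrow(filter_fdr(psms3, 0.3)), 0L)
  expect_error(filter_fdr(data.frame(score = 1, is_decoy = FALSE), 0.01),
               "decoy")
  expect_equal(nrow(filter_fdr(data.frame(score = 1, is_decoy = FALSE),
                               0.01, pass_through = TRUE)), 1L)
})

test_that("filter_fdr is monotone in the threshold", {
  sim <- simulate_psm_table(sim_config(seed = 77))
  sizes <- vapply(c(0.2, 0.05, 0.01, 0.005, 0.001), function(f)
    nrow(filter_fdr(sim$psms, f)), 0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("majority consensus follows the peptide-count vote", {
  ref_len <- 12L
  psms <- data.frame(
    protein_id = "P",
    peptide = c("GGGGG", "GGGGG", "GGSGG", "GGAGG", "GGGGT"),
    start = c(1, 1, 1, 3, 6),
    score = 50, spectral_count = c(5, 2, 2, 2, 1),
    is_decoy = FALSE)
  cons <- build_consensus(psms, ref_len, min_peptides = 4,
                          weighting = "spectral")
  s <- strsplit(cons$sequence, "")[[1]]
  # position 3: G voted by GGGGG (5+2) and GGAGG@3 (2) vs S by GGSGG (2)
  expect_identical(s[3], "G")
  expect_equal(cons$support[3], 9)
  expect_equal(cons$runner_up_support[3], 2)
  # position 10 covered only by GGGGT@6
  expect_identical(s[10], "T")
  expect_equal(cons$support[10], 1)
  expect_identical(s[11], "-")   # uncovered
  expect_identical(s[12], "-")
  # tie -> X: construct 2 vs 2 at a position
  psms_tie <- data.frame(protein_id = "P",
                         peptide = c("AAAAA", "SAAAA"),
                         start = 1, score = 50, spectral_count = 2,
                         is_decoy = FALSE)
  cons_tie <- build_consensus(psms_tie, 5L, min_peptides = 2)
  expect_identical(substr(cons_tie$sequence, 1, 1), "X")
  # the >= 5 distinct peptide rule
  psms4 <- psms[1:4, ]
  psms4$peptide <- c("AAAAA", "CCCCC", "DDDDD", "EEEEE")
  expect_message(out <- build_consensus(psms4, ref_len, min_peptides = 5),
                 "rejected")
  expect_null(out)
  expect_error(build_consensus(
    data.frame(protein_id = "P", peptide = "AAAA", start = 9, score = 1,
               spectral_count = 1, is_decoy = FALSE), 10L, 1L),
    "overruns")
})

test_that("consensus recovers a simulated protein at >= 99% of covered sites", {
  accs <- vapply(1:5, function(rep) {
    cfg <- sim_config(seed = 100 + rep, peptide_error_rate = 0.02,
                      coverage_depth = 6)
    sim <- simulate_psm_table(cfg)
    flt <- filter_fdr(sim$psms, 0.005)
    acc <- vapply(names(sim$proteome), function(pid) {
      ps <- flt[flt$protein_id == pid, ]
      cons <- build_consensus(ps, nchar(sim$proteome[[pid]]))
      truth <- strsplit(sim$proteome[[pid]], "")[[1]]
      got <- strsplit(cons$sequence, "")[[1]]
      cov <- !(got %in% c("-", "X"))
      mean(got[cov] == truth[cov])
    }, 0)
    mean(acc)
  }, 0)
  expect_gte(mean(accs), 0.99)
})

test_that("concatenation tiles partitions and applies isoform edits", {
  prots <- list(COLA = c(t1 = "ABCDEFGHIJ", t2 = "ABCDEFGHIJ"),
                COLB = c(t1 = "KLMNO", t2 = "KLMNO"))
  al <- concatenate_proteins(prots)
  expect_equal(ncol(al$matrix), 15L)
  expect_equal(al$partitions$from, c(1L, 11L))
  expect_equal(al$partitions$to, c(10L, 15L))
  # delete pads with trailing gaps to stay rectangular
  ed <- list(list(taxon = "t2", protein = "COLA", from = 2, to = 8,
                  action = "delete"))
  al2 <- concatenate_proteins(prots, edits = ed)
  expect_equal(ncol(al2$matrix), 15L)
  expect_identical(paste(al2$matrix["t2", 1:10], collapse = ""),
                   "AIJ-------")
  # mask keeps length
  ed3 <- list(list(taxon = "t1", protein = "COLB", from = 2, to = 3,
                   action = "mask"))
  al3 <- concatenate_proteins(prots, edits = ed3)
  expect_identical(paste(al3$matrix["t1", 11:15], collapse = ""),
                   "KXXNO")
  # insert_unknowns reconciles a shorter reference
  prots4 <- list(COLA = c(t1 = "ABCDEFGHIJ", t2 = "ABCDE"))
  ed4 <- list(list(taxon = "t2", protein = "COLA", from = 6, to = 10,
                   action = "insert_unknowns"))
  al4 <- concatenate_proteins(prots4, edits = ed4)
  expect_identical(paste(al4$matrix["t2", ], collapse = ""),
                   "ABCDEXXXXX")
  # overlapping edits rejected
  bad <- list(list(taxon = "t1", protein = "COLA", from = 1, to = 4,
                   action = "mask"),
              list(taxon = "t1", protein = "COLA", from = 3, to = 6,
                   action = "mask"))
  expect_error(concatenate_proteins(prots, edits = bad), "overlapping")
  # taxon order invariance up to row permutation
  al5 <- concatenate_proteins(lapply(prots, rev))
  expect_identical(al5$matrix[rownames(al$matrix), ], al$matrix)
})

test_that("coverage statistics reproduce the printed percentage", {
  expect_equal(coverage_percent(4597, 31781), 14.5)
  mat <- rbind(a = c("A", "C", "-", "X"), b = rep("-", 4))
  al <- structure(list(taxa = c("a", "b"), matrix = mat,
                       partitions = data.frame(protein = "p", from = 1,
                                               to = 4)),
                  class = "concat_alignment")
  expect_equal(coverage_stats(al, "a")$positions_reconstructed, 2L)
  expect_equal(coverage_stats(al, "b")$fraction_percent, 0)
  full <- structure(list(taxa = "a",
                         matrix = matrix("A", 1, 5,
                                         dimnames = list("a", NULL)),
                         partitions = NULL),
                    class = "concat_alignment")
  expect_equal(coverage_stats(full, "a")$fraction_percent, 100)
})

test_that("PSM table IO strips modification annotations", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "psms.csv")
  df <- data.frame(protein_id = "P1", peptide = "GVQ(+.98)GPP(+15.99)GR",
                   start = 1, score = 55, spectral_count = 2)
  utils::write.csv(df, path, row.names = FALSE)
  back <- read_psm_table(path)
  expect_identical(back$peptide, "GVQGPPGR")
  expect_identical(back$modifications, "(+.98);(+15.99)")
  expect_false(back$is_decoy)
})
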