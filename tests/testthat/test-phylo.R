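# Exhaustive-sum likelihood oracle for the 4-taxon unrooted tree
# ((t1:a,t2:b):m,t3:c,t4:d); sums over both internal nodes' states.
ll_oracle_4taxa <- function(aln, bl, model) {
  P <- lapply(bl, function(t) prob_matrix(model, t))
  names(P) <- names(bl)
  AA <- rownames(model$Q)
  tipvec <- function(x) if (x %in% AA) as.numeric(AA == x) else rep(1, 20)
  total <- 0
  for (site in seq_len(ncol(aln))) {
    v <- lapply(rownames(aln), function(tx) tipvec(aln[tx, site]))
    names(v) <- rownames(aln)
    s <- 0
    for (r in 1:20) {
      inner <- 0
      for (i in 1:20) {
        inner <- inner + P$m[r, i] * sum(P$a[i, ] * v$t1) *
          sum(P$b[i, ] * v$t2)
      }
      s <- s + model$pi[r] * inner * sum(P$c[r, ] * v$t3) *
        sum(P$d[r, ] * v$t4)
    }
    total <- total + log(as.numeric(s))
  }
  total
}

test_that("the Dayhoff generator satisfies the rate-matrix invariants", {
  m <- dayhoff_model()
  expect_lt(max(abs(rowSums(m$Q))), 1e-12)
  expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  expect_equal(-sum(m$pi * diag(m$Q)), 1, tolerance = 1e-12)
  for (t in c(0, 0.01, 0.5, 2, 10)) {
    expect_lt(max(abs(rowSums(prob_matrix(m, t)) - 1)), 1e-10)
  }
})

test_that("pruning equals brute-force enumeration on 4 x 30 alignments", {
  m <- dayhoff_model()
  AA <- rownames(m$Q)
  for (seed in 1:3) {
    set.seed(seed)
    aln <- matrix(sample(AA, 120, replace = TRUE), 4, 30,
                  dimnames = list(c("t1", "t2", "t3", "t4"), NULL))
    aln[2, 1:4] <- "X"          # missing data handled as all-states
    aln[4, 5:6] <- "-"
    bl <- c(a = 0.11, b = 0.23, m = 0.08, c = 0.31, d = 0.05)
    tr <- ape::read.tree(
      text = sprintf("((t1:%f,t2:%f):%f,t3:%f,t4:%f);",
                     bl["a"], bl["b"], bl["m"], bl["c"], bl["d"]))
    expect_equal(log_likelihood(aln, tr, m),
                 ll_oracle_4taxa(aln, bl, m), tolerance = 1e-8)
  }
})

test_that("likelihood obeys the zero-branch limit and re-rooting invariance", {
  m <- dayhoff_model()
  AA <- rownames(m$Q)
  # two identical single-residue sequences at branch length 0: log(pi_aa)
  for (aa in c("A", "W", "G")) {
    aln <- matrix(c(aa, aa), 2, 1, dimnames = list(c("t1", "t2"), NULL))
    tr <- ape::read.tree(text = "(t1:0,t2:0);")
    expect_equal(log_likelihood(aln, tr, m), log(m$pi[[aa]]),
                 tolerance = 1e-10)
  }
  set.seed(42)
  aln <- matrix(sample(AA, 4 * 40, replace = TRUE), 4, 40,
                dimnames = list(c("t1", "t2", "t3", "t4"), NULL))
  t1 <- ape::read.tree(text = "((t1:0.1,t2:0.2):0.15,t3:0.3,t4:0.12);")
  t2 <- ape::read.tree(
    text = "((t3:0.3,(t1:0.1,t2:0.2):0.15):0.07,t4:0.05);")
  expect_equal(log_likelihood(aln, t1, m), log_likelihood(aln, t2, m),
               tolerance = 1e-8)
})

test_that("branch-length optimum is a local maximum of the likelihood", {
  m <- dayhoff_model()
  cfg <- sim_config(seed = 31, site_count = 500,
                    tree = ape::read.tree(
                      text = "((A:0.1,B:0.1):0.06,C:0.15,(D:0.1,E:0.1):0.06);"),
                    ancient_taxon = NULL)
  sim <- simulate_alignment(cfg, m)
  tr <- sim$tree
  pat <- paleozooms:::aln_patterns(sim$alignment)
  opt <- paleozooms:::optimize_branch_lengths(tr, pat, m, sweeps = 5)
  ll0 <- log_likelihood(sim$alignment, opt, m)
  for (e in c(1L, 4L)) {
    for (f in c(0.5, 2)) {
      pert <- opt
      pert$edge.length[e] <- pert$edge.length[e] * f
      expect_lt(log_likelihood(sim$alignment, pert, m), ll0 + 1e-6)
    }
  }
})

test_that("ml_search recovers a strong-signal 6-taxon topology", {
  m <- dayhoff_model()
  true_tree <- ape::read.tree(
    text = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05,(E:0.1,F:0.1):0.05);")
  cfg <- sim_config(seed = 5, site_count = 2000, tree = true_tree,
                    ancient_taxon = NULL)
  sim <- simulate_alignment(cfg, m)
  best <- ml_search(sim$alignment, m, strategy = "exhaustive_le8")
  expect_setequal(paleozooms:::bipartitions(best)$keys,
                  paleozooms:::bipartitions(true_tree)$keys)
  # NNI can never beat the exhaustive optimum
  nni <- ml_search(sim$alignment, m, strategy = "nni")
  expect_lte(attr(nni, "loglik"), attr(best, "loglik") + 1e-4)
  expect_error(ml_search(sim$alignment[1:3, ], m), "4 taxa")
})

test_that("identical taxa end up as siblings in the ML tree", {
  m <- dayhoff_model()
  set.seed(12)
  AA <- rownames(m$Q)
  base <- sample(AA, 400, replace = TRUE, prob = m$pi)
  mut <- function(x, k) {
    i <- sample(length(x), k)
    x[i] <- sample(AA, k, replace = TRUE)
    x
  }
  aln <- rbind(X1 = base, X2 = base, Y = mut(base, 60), Z = mut(base, 120),
               W = mut(base, 160))
  best <- ml_search(aln, m, strategy = "exhaustive_le8", sweeps = 1)
  expect_true("X1|X2" %in% paleozooms:::bipartitions(best)$keys)
})

test_that("topology enumeration counts 3, 15, 105 trees", {
  expect_length(paleozooms:::enumerate_topologies(letters[1:4]), 3L)
  expect_length(paleozooms:::enumerate_topologies(letters[1:5]), 15L)
  expect_length(paleozooms:::enumerate_topologies(letters[1:6]), 105L)
})

test_that("bootstrap supports are deterministic under a seed and in [0,1]", {
  m <- dayhoff_model()
  cfg <- sim_config(seed = 9, site_count = 400,
                    tree = ape::read.tree(
                      text = "((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05,E:0.15);"),
                    ancient_taxon = NULL)
  sim <- simulate_alignment(cfg, m)
  ml <- ml_search(sim$alignment, m, strategy = "nni")
  b1 <- bootstrap_support(sim$alignment, m, n_boot = 10, seed = 4,
                          tree = ml)
  b2 <- bootstrap_support(sim$alignment, m, n_boot = 10, seed = 4,
                          tree = ml)
  s1 <- attr(b1, "support_table")
  expect_identical(s1, attr(b2, "support_table"))
  expect_true(all(s1$support >= 0 & s1$support <= 1))
  expect_equal(length(b1$node.label), b1$Nnode)
})
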