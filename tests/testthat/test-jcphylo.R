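# jcphylo: pruning likelihood, branch-length optimization, topology
# search, bootstrap, canonical topologies.

test_that("two-taxon likelihoods match the closed-form JC pair formula", {
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")  # path length 0.1
  expect_equal(jcLogLikelihood(aln_of(a = "A", b = "A"), tr),
               log(0.25 * (0.25 + 0.75 * exp(-0.4 / 3))), tolerance = 1e-6)
  expect_equal(jcLogLikelihood(aln_of(a = "A", b = "A"), tr), -1.48459,
               tolerance = 1e-5)
  expect_equal(jcLogLikelihood(aln_of(a = "A", b = "C"), tr),
               log(0.25 * (0.25 - 0.25 * exp(-0.4 / 3))), tolerance = 1e-6)
  expect_equal(jcLogLikelihood(aln_of(a = "A", b = "C"), tr), -4.85343,
               tolerance = 1e-5)
})

test_that("pruning equals brute-force state enumeration on small trees", {
  set.seed(11)
  for (rep in 1:8) {
    ntip <- sample(3:5, 1)
    tr <- ape::rtree(ntip, tip.label = letters[1:ntip])
    tr$edge.length <- runif(nrow(tr$edge), 0.01, 0.6)
    nsites <- sample(2:6, 1)
    chars <- replicate(ntip, paste0(
      sample(c("A", "C", "G", "T", "-", "N"), nsites, replace = TRUE,
             prob = c(rep(0.22, 4), 0.06, 0.06)), collapse = ""))
    names(chars) <- letters[1:ntip]
    aln <- GenomeAlignment(chars)
    if (sum(rowSums(winnow:::.encode_alignment(aln) != 4L) > 0) < 2) next
    expect_equal(jcLogLikelihood(aln, tr), brute_jc_lnl(aln, tr),
                 tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to rooting and leaf order", {
  set.seed(4)
  tr <- ape::rtree(5, tip.label = letters[1:5])
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.4)
  aln <- random_alignment(5, 40, seed = 9)
  names(aln@seqs) <- letters[1:5]
  base <- jcLogLikelihood(aln, tr)
  un <- ape::unroot(tr)
  expect_equal(jcLogLikelihood(aln, un), base, tolerance = 1e-10)
  rr <- ape::root(un, outgroup = "d", resolve.root = TRUE)
  expect_equal(jcLogLikelihood(aln, rr), base, tolerance = 1e-10)
  perm <- aln
  perm@seqs <- perm@seqs[c(3, 1, 5, 2, 4)]
  expect_equal(jcLogLikelihood(perm, tr), base, tolerance = 1e-10)
})

test_that("an all-missing column contributes nothing", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05);")
  a1 <- aln_of(a = "AC", b = "AC", c = "AG", d = "AG")
  a2 <- aln_of(a = "AC-", b = "ACN", c = "AG-", d = "AGN")
  expect_equal(jcLogLikelihood(a2, tr), jcLogLikelihood(a1, tr))
})

test_that("branch-length optimization clamps, inverts JC distance, and is stable", {
  # identical sequences: both branches clamp to blmin
  same <- aln_of(a = strrep("ACGT", 25), b = strrep("ACGT", 25))
  tr <- ape::read.tree(text = "(a:0.3,b:0.3);")
  cfg <- searchConfig(blmin = 0.01)
  out <- optimizeBranchLengths(same, tr, cfg)
  expect_equal(max(out$edge.length), 0.01, tolerance = 1e-9)

  # p = 0.09362 difference proportion at 1e5 sites: path estimate ~ 0.1
  truth <- truth_of(0L, 100000L, "(a:0.05,b:0.05);")
  sim <- sim_from_truth(truth, seed = 2)
  fit <- optimizeBranchLengths(sim, ape::read.tree(text = "(a:0.3,b:0.3);"),
                               searchConfig(blmin = 1e-6))
  expect_equal(sum(fit$edge.length), 0.1, tolerance = 0.005)

  # re-optimizing an optimum is a fixed point up to the tolerance
  again <- optimizeBranchLengths(sim, fit, searchConfig(blmin = 1e-6))
  expect_lt(abs(attr(again, "lnl") - attr(fit, "lnl")), 1e-4 + 1e-8)
})

test_that("raising blmin never raises the optimized likelihood", {
  truth <- truth_of(0L, 2000L, quartet_newick())
  sim <- sim_from_truth(truth, seed = 5)
  lnls <- vapply(c(1e-4, 1e-3, 1e-2, 0.05, 0.2), function(bl) {
    f <- searchTopology(sim, searchConfig(blmin = bl))
    f$lnl
  }, numeric(1))
  expect_true(all(diff(lnls) <= 1e-6))
})

test_that("topology search recovers a strong 4-taxon split; k = 2t - 3", {
  truth <- truth_of(0L, 2000L, quartet_newick())
  sim <- sim_from_truth(truth, seed = 3)
  fit <- searchTopology(sim, searchConfig(blmin = 1 / 2000))
  expect_equal(fit$canonical,
               canonicalTopology(ape::read.tree(text = quartet_newick())))
  expect_equal(fit$k, 5L)

  truth7 <- segmentTruthMap(segmentLength = 2000, nSegments = 1)
  sim7 <- sim_from_truth(truth7, seed = 3)
  fit7 <- searchTopology(sim7, searchConfig(blmin = 1 / 2000))
  expect_equal(fit7$k, 11L)  # 2 * 7 - 3
  expect_equal(fit7$canonical, truth7@topology[1])
})

test_that("all-identical sequences fall back to the lexicographically first topology", {
  same <- GenomeAlignment(setNames(rep(strrep("ACGT", 10), 4),
                                   c("a", "b", "c", "d")))
  fit <- searchTopology(same, searchConfig(blmin = 0.001,
                                           strategy = "exhaustive"))
  ids <- sort(c("(a,((b,c),d));", "(a,((b,d),c));", "(a,((c,d),b));"))
  expect_equal(fit$canonical, ids[1])
})

test_that("4-taxon trees have exactly three distinct canonical IDs", {
  perms <- list(c("a","b","c","d"), c("b","a","d","c"), c("c","d","a","b"),
                c("a","c","b","d"), c("a","d","b","c"))
  ids <- vapply(perms, function(p)
    canonicalTopology(ape::read.tree(
      text = sprintf("((%s:1,%s:1):1,(%s:1,%s:1):1);",
                     p[1], p[2], p[3], p[4]))), character(1))
  expect_equal(length(unique(ids)), 3L)
  # unrooted equivalence: ((A,B),(C,D)) == ((C,D),(B,A))
  expect_equal(ids[1], ids[3])
  expect_equal(ids[1], ids[2])
  # different split -> different ID
  expect_false(ids[1] == ids[4])
})

test_that("exhaustive and NNI searches agree under strong signal", {
  agree <- 0
  trials <- 12
  for (i in seq_len(trials)) {
    truth <- truth_of(0L, 2000L, quartet_newick(tip = 0.1, internal = 0.06))
    sim <- sim_from_truth(truth, seed = 100 + i)
    fe <- searchTopology(sim, searchConfig(blmin = 1 / 2000,
                                           strategy = "exhaustive"))
    fn <- searchTopology(sim, searchConfig(blmin = 1 / 2000,
                                           strategy = "nni"))
    agree <- agree + (fe$canonical == fn$canonical)
    expect_lte(fn$lnl, fe$lnl + 1e-6)  # exhaustive is the global optimum
  }
  expect_equal(agree, trials)
})

test_that("fixed-tree likelihood matches phangorn's pml", {
  skip_if_not_installed("phangorn")
  truth7 <- segmentTruthMap(segmentLength = 500, nSegments = 1)
  sim <- sim_from_truth(truth7, seed = 8)
  tr <- ape::read.tree(text = truth7@newick[1])
  mat <- do.call(rbind, strsplit(as.character(alnSequences(sim)), ""))
  rownames(mat) <- alnTaxa(sim)
  dat <- phangorn::phyDat(mat)
  pm <- phangorn::pml(ape::unroot(tr), dat, model = "JC", bf = rep(0.25, 4))
  expect_equal(jcLogLikelihood(sim, tr), as.numeric(pm$logLik),
               tolerance = 1e-6)
})

test_that("bootstrap support follows the unique-sequence rule and bounds", {
  # < 4 unique sequences: support undefined, not zero
  s <- strrep("ACGTTGCA", 40)
  dup <- GenomeAlignment(c(a = s, b = s, c = s,
                           d = paste0(substr(s, 1, 319), "T")))
  set.seed(1)
  fit <- searchTopology(dup, searchConfig(blmin = 1 / 320),
                        bootstrapReps = 50)
  expect_lt(fit$nUnique, 4)
  expect_true(is.na(fit$meanSupport))

  # clean strong alignment: support near 100, inside [0, 100]
  truth <- truth_of(0L, 4000L, quartet_newick())
  sim <- sim_from_truth(truth, seed = 6)
  set.seed(1)
  fit2 <- searchTopology(sim, searchConfig(blmin = 1 / 4000),
                         bootstrapReps = 100)
  expect_gte(fit2$meanSupport, 95)
  expect_lte(fit2$meanSupport, 100)
  expect_identical(bootstrapSupport(sim, searchConfig(bootstrapReps = 0L)),
                   NA_real_)
})

test_that("search errors on unanalyzable windows and too few taxa", {
  gappy <- aln_of(a = "ACGT", b = "ACGT", c = "----", d = "NNNN")
  expect_error(searchTopology(gappy, dropMissingTaxa = FALSE), "filter")
  expect_error(searchTopology(gappy, dropMissingTaxa = TRUE), "fewer than 3")
  nogap <- aln_of(a = "----", b = "----")
  expect_error(jcLogLikelihood(nogap,
                               ape::read.tree(text = "(a:0.1,b:0.1);")),
               "fewer than 2")
})
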