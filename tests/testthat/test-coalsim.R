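# coalsim: unit conversion, gene-tree simulation contract, JC sequence
# evolution, truth-map bookkeeping.

test_that("Myr to coalescent-unit conversion is linear with a guarded origin", {
  expect_equal(myrToCoalescent(0.75, 0.75), 1.0)
  expect_equal(myrToCoalescent(1.5, 0.75), 2.0)
  expect_equal(myrToCoalescent(0, 0.75), 0.0)
  expect_error(myrToCoalescent(1, 0), "> 0")
})

test_that("infeasible introgression timing is rejected by name", {
  ig <- data.frame(donor = "erato", recipient = "himera",
                   timeMyr = 5, gamma = 0.1)  # after their merge at 2 Myr
  expect_error(
    SimulationModel(speciesTree = winnow:::.heliconius_tree,
                    introgression = ig, totalLength = 1000),
    "outside the lifetime")
  expect_error(
    SimulationModel(speciesTree = winnow:::.heliconius_tree,
                    introgression = data.frame(donor = "erato",
                                               recipient = "nosuch",
                                               timeMyr = 1, gamma = 0.1),
                    totalLength = 1000),
    "not in species tree")
})

test_that("no recombination yields a single locus; seeds are reproducible", {
  m <- heliconiusModel(rho = 0, totalLength = 10000, seed = 5)
  t1 <- simulateGeneTrees(m)
  expect_equal(nLoci(t1), 1L)
  expect_equal(truthLoci(t1)$start, 0)
  expect_equal(truthLoci(t1)$end, 10000)

  m2 <- heliconiusModel(rho = 8, totalLength = 100000, seed = 7)
  a <- simulateGeneTrees(m2)
  b <- simulateGeneTrees(m2)
  expect_identical(truthLoci(a), truthLoci(b))
  c_ <- simulateGeneTrees(m2, seed = 8)
  expect_false(identical(truthLoci(a), truthLoci(c_)))
})

test_that("truth loci tile the segment and weights sum to one", {
  m <- heliconiusModel(rho = 15, totalLength = 200000, seed = 3)
  truth <- simulateGeneTrees(m)
  df <- truthLoci(truth)
  expect_equal(df$start[1], 0)
  expect_equal(df$end[nrow(df)], 200000)
  if (nrow(df) > 1)
    expect_equal(df$start[-1], df$end[-nrow(df)])
  w <- truthTopologyWeights(truth)
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_true(all(w > 0))

  merged <- mergeSameTopology(truth)
  expect_lte(nLoci(merged), nLoci(truth))
  tp <- merged@topology
  if (length(tp) > 1) expect_true(all(tp[-1] != tp[-length(tp)]))
  expect_equal(truthTopologyWeights(merged), w)
})

test_that("python and R canonical topology IDs agree", {
  m <- heliconiusModel(rho = 10, totalLength = 100000, seed = 9)
  truth <- simulateGeneTrees(m)
  df <- truthLoci(truth)
  idx <- unique(round(seq(1, nrow(df), length.out = min(8, nrow(df)))))
  for (i in idx) {
    tr <- ape::read.tree(text = df$newick[i])
    expect_equal(canonicalTopology(tr), df$topology[i])
  }
})

test_that("mean locus count does not decrease with rho", {
  counts <- sapply(c(5, 50), function(rho)
    mean(sapply(1:10, function(s)
      nLoci(simulateGeneTrees(heliconiusModel(rho = rho,
                                              totalLength = 50000,
                                              seed = 20 + s))))))
  expect_true(counts[2] > counts[1])
})

test_that("sequence evolution matches JC expectations and is seeded", {
  # zero branch lengths: identical sequences
  star <- truth_of(0L, 500L, "((a:0,b:0):0,(c:0,d:0):0);")
  sim0 <- sim_from_truth(star, seed = 4)
  seqs <- as.character(alnSequences(sim0))
  expect_equal(length(unique(seqs)), 1L)

  # closed-form pairwise difference at t = 0.1
  truth <- truth_of(0L, 100000L, "(a:0.04,b:0.06);")
  sim <- sim_from_truth(truth, seed = 4)
  x <- strsplit(as.character(alnSequences(sim)), "")
  p <- mean(x[[1]] != x[[2]])
  expect_lt(abs(p - 0.75 * (1 - exp(-4 * 0.1 / 3))), 0.003)  # ~3 SE

  expect_identical(as.character(alnSequences(sim_from_truth(truth, seed = 4))),
                   as.character(alnSequences(sim)))
  expect_false(identical(
    as.character(alnSequences(sim_from_truth(truth, seed = 5))),
    as.character(alnSequences(sim))))
})

test_that("simulated site-pattern frequencies match pruning-engine probabilities", {
  # dual-oracle link: the simulator and the likelihood engine agree on the
  # JC distribution over site patterns of a fixed quartet tree
  nwk <- quartet_newick(tip = 0.15, internal = 0.1)
  truth <- truth_of(0L, 100000L, nwk)
  sim <- sim_from_truth(truth, seed = 12)
  tr <- ape::read.tree(text = nwk)
  chars <- do.call(rbind, strsplit(as.character(alnSequences(sim)), ""))
  pat <- apply(chars, 2, paste0, collapse = "")
  counts <- table(pat)
  states <- c("A", "C", "G", "T")
  all_pats <- apply(expand.grid(states, states, states, states), 1,
                    paste0, collapse = "")
  probs <- vapply(all_pats, function(p) {
    col <- strsplit(p, "")[[1]]
    names(col) <- rownames(chars)
    exp(jcLogLikelihood(GenomeAlignment(col), tr))
  }, numeric(1))
  expect_equal(sum(probs), 1, tolerance = 1e-9)
  obs <- setNames(rep(0, length(all_pats)), all_pats)
  obs[names(counts)] <- as.numeric(counts)
  keep <- probs * 1e5 >= 5  # chi-square validity
  chi <- sum((obs[keep] - 1e5 * probs[keep])^2 / (1e5 * probs[keep]))
  pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(pval, 1e-4)
})

test_that("per-locus ML topologies recover the truth for long strong loci", {
  truth <- segmentTruthMap(segmentLength = 5000, nSegments = 12)
  aln <- sim_from_truth(truth, seed = 21)
  enc <- winnow:::.encode_alignment(aln)
  part <- makeWindows(alnLength(aln), 5000)
  fit <- winnow:::.fit_windows(enc, part, searchConfig(blmin = 1 / 5000))
  hit <- mean(fit@stats$canonical == truth@topology)
  expect_gte(hit, 0.95)
})
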