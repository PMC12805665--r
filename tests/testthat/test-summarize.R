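# summarize: topology distributions, support/spacing filters, run
# lengths, per-topology statistics.

sfit <- function(ids, support = rep(NA_real_, length(ids)),
                 windowSize = 100L) {
  n <- length(ids)
  stats <- S4Vectors::DataFrame(
    lnl = rep(-1, n), k = rep(5L, n), n_taxa = rep(4L, n),
    n_unique = rep(4L, n), n_patterns = rep(1L, n), canonical = ids,
    newick = rep("((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05);", n),
    mean_support = support, analyzable = !is.na(ids))
  methods::new("NowFit", windowSize = windowSize,
               intervals = IRanges::IRanges(
                 start = (seq_len(n) - 1L) * windowSize + 1L,
                 width = windowSize),
               stats = stats, blmin = 0.01,
               nSites = windowSize * sum(!is.na(ids)))
}

test_that("topology distributions count and normalize", {
  d <- topologyDistribution(sfit(c("T1", "T1", "T2")))
  expect_equal(unname(d$proportions[c("T1", "T2")]), c(2 / 3, 1 / 3))
  expect_equal(sum(d$proportions), 1, tolerance = 1e-12)
})

test_that("support thresholds drop unsupported and undefined windows", {
  ids <- c("T1", "T1", "T2", "T3")
  sup <- c(99, 40, NA, 97)
  d <- topologyDistribution(sfit(ids, sup), supportMin = 95)
  expect_equal(d$nIncluded, 2L)
  expect_equal(sort(names(d$counts)), c("T1", "T3"))
  # monotone: a stricter threshold never includes more windows
  d2 <- topologyDistribution(sfit(ids, sup), supportMin = 98)
  expect_lte(d2$nIncluded, d$nIncluded)
  # without a threshold, undefined-support windows are included
  d0 <- topologyDistribution(sfit(ids, sup))
  expect_equal(d0$nIncluded, 4L)
})

test_that("spacing keeps at most one window per interval", {
  d <- topologyDistribution(sfit(rep("T1", 100)), spacing = 50)
  expect_lte(d$nIncluded, 2L)
  d2 <- topologyDistribution(sfit(rep("T1", 100)), spacing = 1)
  expect_equal(d2$nIncluded, 100L)
})

test_that("spacing-subsampled proportions approach unfiltered ones", {
  set.seed(2)
  ids <- sample(c("T1", "T2"), 600, replace = TRUE, prob = c(0.7, 0.3))
  full <- topologyDistribution(sfit(ids))
  spaced <- topologyDistribution(sfit(ids), spacing = 3)
  expect_lt(abs(full$proportions["T1"] - spaced$proportions["T1"]), 0.1)
})

test_that("run lengths split on topology changes and gaps", {
  expect_equal(runLengths(sfit(c("T1", "T1", "T2", "T1"))), c(2, 1, 1))
  expect_equal(runLengths(sfit(rep("T9", 7))), 7)
  expect_equal(runLengths(sfit(c("T1", "T2", "T1", "T2"))), rep(1, 4))
  expect_equal(runLengths(sfit(c("T1", "T1", NA, "T1"))), c(2, 1))
  r <- runLengths(sfit(c("T1", "T1", "T2", NA, "T2")))
  expect_equal(sum(r), 4)  # analyzable windows only
  expect_true(all(r >= 1))
})

test_that("parsimony-informative sites follow the two-by-two rule", {
  expect_equal(countInformativeSites(
    aln_of(a = "A", b = "A", c = "C", d = "C")), 1L)
  expect_equal(countInformativeSites(
    aln_of(a = "A", b = "A", c = "A", d = "C")), 0L)
  expect_equal(countInformativeSites(
    aln_of(a = "AAAA", b = "AAAA", c = "AAAA", d = "AAAA")), 0L)
  expect_equal(countInformativeSites(
    aln_of(a = "AG", b = "AG", c = "CG", d = "C-")), 1L)
})

test_that("internal-branch statistics isolate internal edges per topology", {
  truth <- truth_of(0L, 800L, quartet_newick(tip = 0.1, internal = 0.08))
  aln <- sim_from_truth(truth, seed = 17)
  enc <- winnow:::.encode_alignment(aln)
  part <- makeWindows(800, 400)
  fit <- winnow:::.fit_windows(enc, part, searchConfig(blmin = 1 / 400))
  st <- internalBranchStats(fit, aln)
  expect_equal(sum(st$n_windows), 2L)
  # a 4-taxon tree has exactly one internal branch; its fitted length is
  # bounded by the optimizer's clamp range
  expect_true(all(st$mean_internal_bl > 0 & st$mean_internal_bl <= 10))
  expect_true(all(st$mean_informative_sites >= 0))
})

test_that("support filtering enriches the major topology under ILS", {
  # great-ape-like quartet with ILS: short windows carry estimation error;
  # filtering to well-supported trees raises the major-topology share
  tree4 <- "(orang:12,(gorilla:7.2,(chimp:4.5,human:4.5):2.7):4.8);"
  m <- SimulationModel(speciesTree = tree4, rho = 30, totalLength = 60000,
                       myrPerCoalUnit = 3, mutationScale = 0.012, seed = 19)
  truth <- simulateGeneTrees(m)
  aln <- simulateSequences(truth, seed = 20)
  enc <- winnow:::.encode_alignment(aln)
  part <- makeWindows(60000, 200)
  set.seed(1)
  fit <- winnow:::.fit_windows(enc, part, searchConfig(blmin = 1 / 200),
                               bootstrapReps = 60L)
  major <- names(truthTopologyWeights(truth))[1]
  all_d <- topologyDistribution(fit)
  sup_d <- topologyDistribution(fit, supportMin = 95)
  expect_gt(sup_d$proportions[major], all_d$proportions[major])
})
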