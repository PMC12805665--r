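# stepwise: joint filtering and the pairwise-halving descent.

# alignment with a controllable missing-data block: taxon "gapper" is
# all-gap inside [gapFrom, gapTo)
gappy_alignment <- function(L, gapFrom, gapTo, seed = 1) {
  truth <- truth_of(0L, L, sprintf(
    "(melpomene:0.1,((erato:0.05,himera:0.05):0.03,(demeter:0.05,sara:0.05):0.03):0.05);"))
  aln <- sim_from_truth(truth, seed = seed)
  seqs <- as.character(alnSequences(aln))
  g <- seqs[["demeter"]]
  substr(g, gapFrom + 1, gapTo) <- strrep("-", gapTo - gapFrom)
  seqs[["demeter"]] <- g
  GenomeAlignment(seqs)
}

test_that("joint filtering keeps identical site sets at both sizes", {
  aln <- gappy_alignment(8000, 2000, 3000)
  jf <- jointFilter(aln, 2000, 1000)
  # the all-gap small window [2000,3000) kills large window 2 and both
  # its halves
  expect_equal(jf$retainedLarge, c(1L, 3L, 4L))
  largeSites <- unlist(Map(seq, windowStarts(jf$large)[jf$large@analyzable],
                           windowEnds(jf$large)[jf$large@analyzable] - 1L))
  smallSites <- unlist(Map(seq, windowStarts(jf$small)[jf$small@analyzable],
                           windowEnds(jf$small)[jf$small@analyzable] - 1L))
  expect_setequal(largeSites, smallSites)  # hard identity of retained sites
  expect_equal(jf$retainedSites, 3 * 2000)
  expect_error(jointFilter(aln, 2000, 800), "2 \\* sizeSmall")
})

test_that("fully analyzable alignments retain every window of a pair", {
  truth <- segmentTruthMap(segmentLength = 1000, nSegments = 8)
  aln <- sim_from_truth(truth, seed = 2)
  jf <- jointFilter(aln, 2000, 1000)
  expect_equal(sum(jf$large@analyzable), 4L)
  expect_equal(sum(jf$small@analyzable), 8L)
  expect_equal(jf$retainedSites, 8000)
})

test_that("a half-window failure removes the parent and the sibling half", {
  aln <- gappy_alignment(8000, 1000, 2000)  # second small window only
  jf <- jointFilter(aln, 2000, 1000)
  expect_false(1L %in% jf$retainedLarge)
  expect_false(jf$small@analyzable[1])  # sibling half dropped too
  expect_false(jf$small@analyzable[2])
})

test_that("stepwise equals the plain analysis on gapless data", {
  truth <- segmentTruthMap(segmentLength = 1000, nSegments = 16)
  aln <- sim_from_truth(truth, seed = 7)
  res <- stepwiseNow(aln, startSize = 8000, floorSize = 1000,
                     mode = "full-chain")
  steps <- stepwiseSteps(res)
  plain <- nowAnalysis(aln, sizes = c(1000, 2000, 4000, 8000))
  s <- nowSummaries(plain)
  for (i in seq_len(nrow(steps))) {
    expect_equal(steps$AIC_large[i], s$AIC[s$size == steps$size_large[i]])
    expect_equal(steps$AIC_small[i], s$AIC[s$size == steps$size_small[i]])
  }
  expect_equal(steps$retained_fraction, rep(1, nrow(steps)))
})

test_that("a single-history alignment stops the chain at the first comparison", {
  truth <- segmentTruthMap(segmentLength = 16000, nSegments = 1)
  aln <- sim_from_truth(truth, seed = 3)  # one topology throughout
  res <- stepwiseNow(aln, startSize = 16000, floorSize = 1000)
  expect_equal(stepwiseBestSize(res), 16000)
  expect_equal(nrow(stepwiseSteps(res)), 1L)
  expect_false(res@stillDeclining)
})

test_that("short true segments drive the chain downward", {
  truth <- random_truth(16000, mean_len = 400, seed = 55)
  aln <- sim_from_truth(truth, seed = 5)
  res <- stepwiseNow(aln, startSize = 16000, floorSize = 500)
  expect_lt(stepwiseBestSize(res), 4000)
})

test_that("reaching the floor with a declining AIC sets the flag", {
  truth <- random_truth(16000, mean_len = 200, seed = 77)
  aln <- sim_from_truth(truth, seed = 6)
  res <- stepwiseNow(aln, startSize = 4000, floorSize = 1000)
  if (res@stillDeclining) {
    expect_equal(stepwiseBestSize(res), 1000)
    last <- tail(stepwiseSteps(res), 1)
    expect_equal(last$winner, 1000)
  } else {
    succeed("chain stopped before the floor on this draw")
  }
})

test_that("stepwise results are deterministic and internally consistent", {
  aln <- gappy_alignment(16000, 3000, 9000, seed = 9)
  r1 <- stepwiseNow(aln, startSize = 4000, floorSize = 1000)
  r2 <- stepwiseNow(aln, startSize = 4000, floorSize = 1000)
  expect_identical(stepwiseSteps(r1), stepwiseSteps(r2))
  expect_identical(stepwiseBestSize(r1), stepwiseBestSize(r2))
  df <- reportChain(r1)
  expect_true(all(diff(df$retained_sites) <= 0))
  expect_equal(df$winner, ifelse(df$AIC_large <= df$AIC_small,
                                 df$size_large, df$size_small))
  # delta_AIC = AIC_small - AIC_large: nonnegative iff the larger size won
  expect_equal(df$delta_AIC >= 0, df$winner == df$size_large)
  expect_equal(attr(df, "best_size"), stepwiseBestSize(r1))
})

test_that("a non-power-of-two start/floor pair warns", {
  truth <- segmentTruthMap(segmentLength = 1000, nSegments = 6)
  aln <- sim_from_truth(truth, seed = 8)
  expect_warning(stepwiseNow(aln, startSize = 6000, floorSize = 1000),
                 "power-of-two")
})
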