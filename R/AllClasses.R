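#' @importClassesFrom Biostrings DNAStringSet
NULL

#' Whole-chromosome multiple sequence alignment
#'
#' Thin S4 wrapper around a \link[Biostrings]{DNAStringSet} holding one
#' equal-length sequence per taxon over the alphabet \code{A,C,G,T,-,N}.
#' Coordinates are 0-based half-open everywhere in this package; human
#' readable reports use 1-based window indices.
#'
#' @slot seqs A \code{DNAStringSet}, one entry per taxon, all equal width,
#'   unique names.
#' @seealso [readAlignmentFasta()], [alnTaxa()], [alnLength()]
#' @exportClass GenomeAlignment
setClass("GenomeAlignment", slots = c(seqs = "DNAStringSet"))

setValidity("GenomeAlignment", function(object) {
  w <- Biostrings::width(object@seqs)
  if (length(object@seqs) < 1L) return("alignment must contain >= 1 sequence")
  if (length(unique(w)) != 1L)
    return("all sequences must have the same length")
  if (w[1] < 1L) return("alignment length must be >= 1")
  nm <- names(object@seqs)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    return("taxa must have unique, non-empty names")
  TRUE
})

#' Non-overlapping window partition of an alignment
#'
#' Ordered, contiguous, non-overlapping windows of exactly `windowSize`
#' sites starting at position 0; a trailing remainder shorter than
#' `windowSize` is excluded.  The `analyzable` flag records the per-window
#' missing-data decision (see [windowAnalyzable()]).
#'
#' @slot windowSize Sites per window.
#' @slot intervals `IRanges` of the windows (1-based closed internally, as
#'   IRanges requires; accessors report 0-based half-open starts/ends).
#' @slot analyzable Logical, one entry per window.
#' @exportClass WindowPartition
setClass("WindowPartition",
         slots = c(windowSize = "integer", intervals = "IRanges",
                   analyzable = "logical"))

setValidity("WindowPartition", function(object) {
  iv <- object@intervals
  if (length(iv) != length(object@analyzable))
    return("analyzable must have one flag per window")
  if (length(iv) == 0L) return("partition must contain >= 1 window")
  if (any(IRanges::width(iv) != object@windowSize))
    return("every interval must span exactly windowSize sites")
  st <- IRanges::start(iv)
  if (st[1] != 1L || any(diff(st) != object@windowSize))
    return("intervals must be contiguous from 0 and sorted")
  TRUE
})

#' Per-site simulated truth for a chromosome
#'
#' The ordered sequence of distinct marginal genealogies from a coalescent
#' simulation: one row per locus with its half-open interval, the gene tree
#' (Newick, branch lengths in substitutions/site) and the canonical
#' unrooted topology ID.
#'
#' @slot intervals `IRanges` of the loci; they tile `[0, totalLength)`
#'   exactly.
#' @slot newick Per-locus gene trees.
#' @slot topology Canonical unrooted topology ID per locus (see
#'   [canonicalTopology()]).
#' @slot totalLength Simulated chromosome length in sites.
#' @slot seed RNG seed used for the gene-tree simulation.
#' @exportClass TruthMap
setClass("TruthMap",
         slots = c(intervals = "IRanges", newick = "character",
                   topology = "character", totalLength = "numeric",
                   seed = "integer"))

setValidity("TruthMap", function(object) {
  iv <- object@intervals
  n <- length(iv)
  if (n == 0L) return("truth map must contain >= 1 locus")
  if (length(object@newick) != n || length(object@topology) != n)
    return("newick and topology must parallel the intervals")
  if (any(IRanges::width(iv) < 1L)) return("each locus must span >= 1 site")
  st <- IRanges::start(iv); en <- IRanges::end(iv)
  if (st[1] != 1L || en[n] != object@totalLength ||
      (n > 1L && any(st[-1] != en[-n] + 1L)))
    return("loci must tile [0, totalLength) with no gaps or overlaps")
  TRUE
})

#' Coalescent simulation model
#'
#' The study conditions for the synthetic-data generator: an ultrametric
#' species tree with node times in Myr, the Myr-per-coalescent-unit
#' conversion (one coalescent unit = 4Ne generations), a global
#' ILS scaling multiplier on coalescent-unit times, instantaneous
#' introgression pulses, the ms-style total recombination parameter
#' \eqn{\rho = 4 N r L} over the segment, and the mutation scaling
#' (substitutions/site per coalescent unit, i.e. \eqn{4 N_e \mu}).
#'
#' @slot speciesTree Rooted ultrametric Newick, branch lengths in Myr.
#' @slot myrPerCoalUnit Myr equivalent to 4Ne generations (default 0.75).
#' @slot ilsScale Multiplier on all times in coalescent units; < 1 means
#'   more incomplete lineage sorting.
#' @slot introgression data.frame with columns donor, recipient, timeMyr,
#'   gamma; donor/recipient are taxa or `+`-joined clades, and a
#'   bidirectional event is two rows.
#' @slot rho Total ms-style recombination parameter over the segment.
#' @slot totalLength Segment length in sites.
#' @slot mutationScale Substitutions/site per coalescent unit.
#' @slot seed Default RNG seed.
#' @exportClass SimulationModel
setClass("SimulationModel",
         slots = c(speciesTree = "character", myrPerCoalUnit = "numeric",
                   ilsScale = "numeric", introgression = "data.frame",
                   rho = "numeric", totalLength = "numeric",
                   mutationScale = "numeric", seed = "integer"))

setValidity("SimulationModel", function(object) {
  if (object@myrPerCoalUnit <= 0) return("myrPerCoalUnit must be > 0")
  if (object@rho < 0) return("rho must be >= 0")
  if (object@totalLength < 1) return("totalLength must be >= 1")
  if (object@ilsScale <= 0) return("ilsScale must be > 0")
  if (object@mutationScale <= 0) return("mutationScale must be > 0")
  ig <- object@introgression
  if (nrow(ig) > 0) {
    need <- c("donor", "recipient", "timeMyr", "gamma")
    if (!all(need %in% names(ig)))
      return("introgression needs columns donor, recipient, timeMyr, gamma")
    if (any(ig$gamma < 0 | ig$gamma > 1))
      return("introgression gamma must lie in [0, 1]")
  }
  TRUE
})

#' Fitted non-overlapping window analysis at one window size
#'
#' One Jukes-Cantor ML fit per analyzable window: log-likelihood, free
#' parameter count (2t - 3 branch lengths for t taxa with data), the
#' canonical unrooted topology, the fitted tree, and optional mean
#' bootstrap support.  Unanalyzable windows carry `NA` rows.
#'
#' @slot windowSize Sites per window.
#' @slot intervals `IRanges` of all windows of the partition.
#' @slot stats `DataFrame` with columns `lnl`, `k`, `n_taxa`, `n_unique`,
#'   `n_patterns`, `canonical`, `newick`, `mean_support`, `analyzable`.
#' @slot blmin Minimum branch length used at fit time (1/windowSize).
#' @slot nSites Total sites analyzed (the BIC's n).
#' @exportClass NowFit
setClass("NowFit",
         slots = c(windowSize = "integer", intervals = "IRanges",
                   stats = "DataFrame", blmin = "numeric",
                   nSites = "numeric"))

#' Non-overlapping window analysis over a grid of sizes
#'
#' @slot summaries data.frame, one row per window size, with the AIC/BIC
#'   aggregation (see [aggregateScores()]).
#' @slot fits Named list of [NowFit-class] objects keyed by window size.
#' @exportClass NowResult
setClass("NowResult",
         slots = c(summaries = "data.frame", fits = "list"))

#' Result of the stepwise pairwise-halving window-size selection
#'
#' @slot steps data.frame, one row per pairwise comparison: sizes, number
#'   of retained large windows, retained sites and fraction, both AICs,
#'   delta-AIC and winner.
#' @slot bestSize Selected window size.
#' @slot retainedFractionAtBest Fraction of the original alignment analyzed
#'   at the best size.
#' @slot fitsAtBest [NowFit-class] at the best size (retained windows only).
#' @slot stillDeclining TRUE when the chain hit the floor size with the AIC
#'   still favouring the smaller member of the final pair.
#' @slot mode `"descend"` or `"full-chain"`.
#' @exportClass StepwiseResult
setClass("StepwiseResult",
         slots = c(steps = "data.frame", bestSize = "numeric",
                   retainedFractionAtBest = "numeric", fitsAtBest = "NowFit",
                   stillDeclining = "logical", mode = "character"))

# ------------------------------------------------------------------ show

setMethod("show", "GenomeAlignment", function(object) {
  cat(sprintf("GenomeAlignment: %d taxa x %d sites\n",
              length(object@seqs), Biostrings::width(object@seqs)[1]))
  cat("  taxa:", paste(head(names(object@seqs), 8), collapse = ", "),
      if (length(object@seqs) > 8) "..." else "", "\n")
})

setMethod("show", "WindowPartition", function(object) {
  cat(sprintf("WindowPartition: %d windows of %d sites (%d analyzable)\n",
              length(object@intervals), object@windowSize,
              sum(object@analyzable)))
})

setMethod("show", "TruthMap", function(object) {
  cat(sprintf(
    "TruthMap: %d loci over %g sites (mean length %.1f bp, %d topologies)\n",
    length(object@intervals), object@totalLength,
    mean(IRanges::width(object@intervals)),
    length(unique(object@topology))))
})

setMethod("show", "SimulationModel", function(object) {
  cat(sprintf(
    "SimulationModel: rho = %g over %g sites, ILS scale %g, %d introgression pulse(s)\n",
    object@rho, object@totalLength, object@ilsScale,
    nrow(object@introgression)))
  cat("  conversion: 4Ne generations =", object@myrPerCoalUnit, "Myr;",
      "mutation scale", object@mutationScale, "subs/site per coal unit\n")
})

setMethod("show", "NowFit", function(object) {
  ok <- object@stats$analyzable
  cat(sprintf(
    "NowFit: window size %d, %d/%d windows fitted (lnL total %.2f, K %d)\n",
    object@windowSize, sum(ok), length(ok),
    sum(object@stats$lnl[ok]), sum(object@stats$k[ok])))
})

setMethod("show", "NowResult", function(object) {
  cat("NowResult over", nrow(object@summaries), "window sizes\n")
  print(object@summaries, row.names = FALSE)
})

setMethod("show", "StepwiseResult", function(object) {
  cat(sprintf("StepwiseResult (%s): best window size %g%s\n", object@mode,
              object@bestSize,
              if (object@stillDeclining) " (AIC still declining at floor)"
              else ""))
  cat(sprintf("  retained fraction at best size: %.4f\n",
              object@retainedFractionAtBest))
  print(object@steps, row.names = FALSE)
})
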