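# Desk-scale reproduction of the simulation study that validates the AIC
# as a window-size criterion.  These drivers are what the acceptance
# machinery runs; the vignette documents the problem sizes.

# per-scenario window-size grids (sizes dividing the alignment length keep
# every AIC/BIC total on identical data)
.study_grid <- function(rho10, L) {
  sizes <- if (rho10 >= 2000)
    c(500, 1000, 2000, 4000, 8000, 20000, 40000, L)
  else
    c(1000, 2000, 5000, 10000, 20000, 40000, 1e5, L)
  sizes <- sizes[sizes <= L]
  sizes[L %% sizes == 0]
}

#' Scaled-down replicate study of AIC/BIC window-size selection
#'
#' Simulates replicate chromosome alignments under the Heliconius-like
#' medium-ILS model, runs the non-overlapping window analysis over a
#' per-scenario window-size grid, and scores both criteria against the
#' simulated truth.  Scenarios are labelled by their recombination
#' parameter on the 10 Mb convention (\eqn{\rho_{10}}); the simulated
#' segment uses `rho = rho10 * totalLength / 1e7` so the per-site
#' recombination rate matches that condition.
#'
#' @param seed Base RNG seed; replicate seeds are derived from it.
#' @param totalLength Simulated chromosome length (default 1 Mb).
#' @param replicates Replicates per scenario (default 4).
#' @param scenarios Recombination settings on the 10 Mb convention.
#' @param config A [searchConfig()] for the per-window fits.
#' @return data.frame, one row per replicate: scenario, sizes selected by
#'   AIC/BIC, the accuracy-optimal size, maximum site accuracy, site
#'   accuracy and RMSE at the criterion-selected sizes, both losses,
#'   concatenation (single-window) site accuracy, dominant truth topology
#'   weight, locus count.
#' @seealso [locusCountStudy()], [accuracyReport()], [criterionLoss()]
#' @export
simulationStudy <- function(seed = 1L, totalLength = 1e6, replicates = 4L,
                            scenarios = c(2000, 200),
                            config = searchConfig()) {
  base <- as.integer(seed) %% 100000L
  rows <- NULL
  for (si in seq_along(scenarios)) {
    rho10 <- scenarios[si]
    rho <- rho10 * totalLength / 1e7
    sizes <- .study_grid(rho10, totalLength)
    for (r in seq_len(replicates)) {
      s <- base * 10000L + si * 1000L + r
      model <- heliconiusModel(rho = rho, totalLength = totalLength,
                               seed = s)
      truth <- simulateGeneTrees(model)
      aln <- simulateSequences(truth, seed = s + 500L)
      res <- nowAnalysis(aln, sizes, config)
      rep_ <- accuracyReport(truth, res)
      la <- criterionLoss(rep_, res, "AIC")
      lb <- criterionLoss(rep_, res, "BIC")
      rows <- rbind(rows, data.frame(
        scenario = rho10, replicate = r, seed = s,
        n_loci = nLoci(truth),
        dominant_weight = unname(truthTopologyWeights(truth)[1]),
        aic_size = la$selected_size, bic_size = lb$selected_size,
        best_acc_size = rep_$size[which.max(rep_$site_accuracy)],
        max_site_accuracy = max(rep_$site_accuracy),
        aic_loss = la$site_accuracy_loss, bic_loss = lb$site_accuracy_loss,
        rmse_at_aic = rep_$rmse[rep_$size == la$selected_size],
        rmse_min = min(rep_$rmse),
        concat_accuracy = rep_$site_accuracy[rep_$size == totalLength]))
    }
  }
  rows
}

#' Locus count of the high-recombination study condition
#'
#' Simulates the gene trees (only) of the medium-ILS model with
#' rho = 2000 over 10 Mb and reports the number of loci and their mean
#' length.  Under this condition the segment shatters into on the order
#' of 126,000 loci of mean length about 80 bp.
#'
#' @param seed RNG seed.
#' @param totalLength Segment length (default 10 Mb).
#' @param rho Recombination parameter over the segment (default 2000).
#' @return List: `n_loci`, `mean_length_bp`.
#' @export
locusCountStudy <- function(seed = 1L, totalLength = 1e7, rho = 2000) {
  model <- heliconiusModel(rho = rho, totalLength = totalLength,
                           seed = as.integer(seed))
  truth <- simulateGeneTrees(model)
  list(n_loci = nLoci(truth),
       mean_length_bp = truthTotalLength(truth) / nLoci(truth))
}

#' Piecewise truth map with fixed-length same-topology segments
#'
#' Builds a synthetic [TruthMap-class] of `nSegments` segments of
#' `segmentLength` sites each, cycling through a set of distinct
#' seven-taxon gene trees with strong internal branches -- a controlled
#' ground truth for window-size recovery experiments where the
#' non-recombining block length is known exactly.
#'
#' @param segmentLength Sites per segment (default 5000).
#' @param nSegments Number of segments (default 40).
#' @param tipLength,internalLength Branch lengths (substitutions/site) of
#'   the segment gene trees.
#' @return A [TruthMap-class] of `segmentLength * nSegments` sites.
#' @export
segmentTruthMap <- function(segmentLength = 5000, nSegments = 40,
                            tipLength = 0.05, internalLength = 0.05) {
  base <- c(
    "(melpomene:%T,((((erato:%T,himera:%T):%I,hecalesia:%T):%I,telesiphe:%T):%I,(demeter:%T,sara:%T):%I):%I);",
    "(melpomene:%T,((((erato:%T,hecalesia:%T):%I,himera:%T):%I,telesiphe:%T):%I,(demeter:%T,sara:%T):%I):%I);",
    "(melpomene:%T,((((erato:%T,himera:%T):%I,telesiphe:%T):%I,hecalesia:%T):%I,(demeter:%T,sara:%T):%I):%I);",
    "(melpomene:%T,((erato:%T,himera:%T):%I,((hecalesia:%T,telesiphe:%T):%I,(demeter:%T,sara:%T):%I):%I):%I);")
  nwk <- vapply(base, function(b) {
    b <- gsub("%T", format(tipLength), b, fixed = TRUE)
    gsub("%I", format(internalLength), b, fixed = TRUE)
  }, character(1))
  idx <- rep_len(seq_along(nwk), nSegments)
  topo <- vapply(nwk, function(x)
    canonicalTopology(ape::read.tree(text = x)), character(1))
  methods::new(
    "TruthMap",
    intervals = IRanges::IRanges(
      start = (seq_len(nSegments) - 1L) * segmentLength + 1L,
      width = segmentLength),
    newick = unname(nwk[idx]), topology = unname(topo[idx]),
    totalLength = segmentLength * nSegments, seed = NA_integer_)
}
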