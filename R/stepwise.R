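# stepwise: the pairwise-halving non-overlapping window procedure for
# empirical alignments with missing data.  Each comparison (w, w/2) is
# made on the jointly analyzable subset of windows, so both AICs are
# computed on an identical alignment.

#' Jointly filter windows for a pairwise size comparison
#'
#' For `sizeLarge = 2 * sizeSmall`, a large window is retained if and only
#' if it and both of its halves are analyzable; dropped windows are
#' removed at both sizes, so the retained site sets are identical for both
#' members of the pair.
#'
#' @param x A [GenomeAlignment-class] or an encoded matrix from it.
#' @param sizeLarge,sizeSmall Window sizes; `sizeLarge` must equal
#'   `2 * sizeSmall`.
#' @param minTaxaWithData,strict Analyzability rule, see
#'   [windowAnalyzable()].
#' @return List: `large`/`small` ([WindowPartition-class]s whose
#'   `analyzable` flags mark the retained windows), `retainedLarge`
#'   (indices of retained large windows), `retainedSites`.
#' @export
jointFilter <- function(x, sizeLarge, sizeSmall, minTaxaWithData = 3L,
                        strict = TRUE) {
  if (sizeLarge != 2 * sizeSmall)
    stop("sizeLarge must equal 2 * sizeSmall")
  enc <- if (is.matrix(x)) x else .encode_alignment(x)
  L <- ncol(enc)
  if (sizeLarge > L) stop("sizeLarge exceeds alignment length")
  big <- windowAnalyzable(enc, makeWindows(L, sizeLarge), minTaxaWithData,
                          strict)
  small <- windowAnalyzable(enc, makeWindows(L, sizeSmall), minTaxaWithData,
                            strict)
  nb <- nWindows(big)
  # halves of large window i are small windows 2i-1, 2i (1-based)
  okA <- small@analyzable[seq(1L, 2L * nb, by = 2L)]
  okB <- small@analyzable[seq(2L, 2L * nb, by = 2L)]
  keep <- big@analyzable & okA & okB
  big@analyzable <- keep
  smallkeep <- rep(FALSE, nWindows(small))
  smallkeep[rep(which(keep), each = 2L) * 2L - c(1L, 0L)] <- TRUE
  small@analyzable <- smallkeep
  list(large = big, small = small, retainedLarge = which(keep),
       retainedSites = sum(keep) * sizeLarge)
}

#' Stepwise non-overlapping window size selection
#'
#' Starting from `startSize`, compares window sizes pairwise (w against
#' w/2) on the jointly filtered windows ([jointFilter()]), fitting JC ML
#' trees with `blmin = 1/w` and `1/(w/2)` respectively and aggregating AIC
#' on the identical retained alignment.  Under the default
#' `mode = "descend"`, the chain stops at the first comparison the larger
#' size wins; otherwise (`"full-chain"`) the whole trajectory down to
#' `floorSize` is computed and the same first-larger-win rule selects the
#' best size afterwards.  If the chain reaches `floorSize` with the AIC
#' still favouring the smaller member, the floor size is selected and the
#' `stillDeclining` flag set (the best size is then at most the floor).
#'
#' Cross-step AIC values are not comparable (each step retains a different
#' region), which is why selection only ever compares within a step.
#'
#' @param aln A [GenomeAlignment-class].
#' @param startSize Initial (largest) window size; default 64 kb.
#' @param floorSize Smallest size to descend to; default 125 bp.
#' @param config A [searchConfig()].
#' @param minTaxaWithData,strict Analyzability rule, see
#'   [windowAnalyzable()].
#' @param mode `"descend"` (stop at first larger-size win) or
#'   `"full-chain"`.
#' @param bootstrapRepsAtBest Bootstrap replicates for the fits at the
#'   selected size (support is computed only there, not during the
#'   descent); default 0.
#' @return A [StepwiseResult-class].
#' @export
stepwiseNow <- function(aln, startSize = 64000, floorSize = 125,
                        config = searchConfig(), minTaxaWithData = 3L,
                        strict = TRUE, mode = c("descend", "full-chain"),
                        bootstrapRepsAtBest = 0L) {
  mode <- match.arg(mode)
  L <- alnLength(aln)
  if (startSize > L) stop("startSize exceeds alignment length")
  if (floorSize < 1) stop("floorSize must be >= 1")
  r <- startSize / floorSize
  if (r != round(r) || bitwAnd(as.integer(round(r)),
                               as.integer(round(r)) - 1L) != 0L)
    warning("startSize is not a power-of-two multiple of floorSize; ",
            "the chain will stop once halving passes below floorSize")
  enc <- .encode_alignment(aln)
  steps <- NULL
  keptfits <- list()   # per step: fits of the larger and smaller member
  w <- startSize
  decided <- NA_real_
  declining <- FALSE
  repeat {
    if (w / 2 < floorSize) {  # cannot halve further
      if (is.na(decided)) decided <- w
      break
    }
    jf <- jointFilter(enc, w, w / 2, minTaxaWithData, strict)
    if (length(jf$retainedLarge) == 0L) {
      warning("no window retained for the (", w, ", ", w / 2,
              ") comparison; chain stopped")
      if (is.na(decided)) decided <- w
      break
    }
    fitL <- .fit_windows(enc, jf$large, config, 0L,
                         dropMissingTaxa = !strict, blmin = 1 / w)
    fitS <- .fit_windows(enc, jf$small, config, 0L,
                         dropMissingTaxa = !strict, blmin = 1 / (w / 2))
    aicL <- aggregateScores(fitL, nSites = jf$retainedSites)$AIC
    aicS <- aggregateScores(fitS, nSites = jf$retainedSites)$AIC
    winner <- if (aicL <= aicS) w else w / 2   # tie -> larger size
    steps <- rbind(steps, data.frame(
      size_large = w, size_small = w / 2,
      n_retained = length(jf$retainedLarge),
      retained_sites = jf$retainedSites,
      retained_fraction = jf$retainedSites / L,
      AIC_large = aicL, AIC_small = aicS,
      delta_AIC = aicS - aicL, winner = winner))
    keptfits[[length(keptfits) + 1L]] <- list(large = fitL, small = fitS)
    if (winner == w) {
      if (is.na(decided)) decided <- w
      if (mode == "descend") break
    }
    if (w / 2 < 2 * floorSize && winner == w / 2) {
      # floor reached with the AIC still declining
      if (is.na(decided)) {
        decided <- w / 2
        declining <- TRUE
      }
      break
    }
    w <- w / 2
  }
  # fits at the selected size come from the step that decided it, keeping
  # the AIC's retained-region semantics
  best <- decided
  fitsBest <- NULL
  retainedFrac <- NA_real_
  if (!is.null(steps)) {
    di <- which(steps$size_large == best | (declining &
                                            steps$size_small == best))
    di <- di[length(di)]
    if (length(di)) {
      fitsBest <- if (steps$size_large[di] == best && !declining)
        keptfits[[di]]$large else keptfits[[di]]$small
      retainedFrac <- steps$retained_fraction[di]
    }
  }
  if (is.null(fitsBest)) {  # single-window chain never entered a step
    part <- windowAnalyzable(enc, makeWindows(L, best), minTaxaWithData,
                             strict)
    fitsBest <- .fit_windows(enc, part, config, 0L,
                             dropMissingTaxa = !strict, blmin = 1 / best)
    retainedFrac <- sum(part@analyzable) * best / L
  }
  if (bootstrapRepsAtBest > 0L) {
    part <- methods::new("WindowPartition",
                         windowSize = fitsBest@windowSize,
                         intervals = fitsBest@intervals,
                         analyzable = fitsBest@stats$analyzable)
    fitsBest <- .fit_windows(enc, part, config, bootstrapRepsAtBest,
                             dropMissingTaxa = !strict,
                             blmin = fitsBest@blmin)
  }
  if (is.null(steps))
    steps <- data.frame(size_large = numeric(), size_small = numeric(),
                        n_retained = integer(), retained_sites = numeric(),
                        retained_fraction = numeric(),
                        AIC_large = numeric(), AIC_small = numeric(),
                        delta_AIC = numeric(), winner = numeric())
  methods::new("StepwiseResult", steps = steps, bestSize = best,
               retainedFractionAtBest = retainedFrac,
               fitsAtBest = fitsBest, stillDeclining = declining,
               mode = mode)
}

#' Report a stepwise chain as a table
#'
#' One row per pairwise comparison (sizes, retained fraction, both AICs,
#' delta-AIC, winner) plus the selected-size summary as attributes
#' `best_size`, `retained_fraction_at_best` and `still_declining`.
#'
#' @param result A [StepwiseResult-class].
#' @return data.frame of the chain.
#' @export
reportChain <- function(result) {
  df <- result@steps
  attr(df, "best_size") <- result@bestSize
  attr(df, "retained_fraction_at_best") <- result@retainedFractionAtBest
  attr(df, "still_declining") <- result@stillDeclining
  df
}

#' Accessors for StepwiseResult objects
#'
#' @param x A [StepwiseResult-class].
#' @return `stepwiseBestSize`: the selected window size;
#'   `stepwiseFits`: the [NowFit-class] at the best size;
#'   `stepwiseSteps`: the per-step table.
#' @export
stepwiseBestSize <- function(x) x@bestSize

#' @rdname stepwiseBestSize
#' @export
stepwiseFits <- function(x) x@fitsAtBest

#' @rdname stepwiseBestSize
#' @export
stepwiseSteps <- function(x) x@steps
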