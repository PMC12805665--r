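# accuracy: score a window analysis against simulated truth -- site
# accuracy, topology-weight RMSE, and the accuracy loss incurred by
# criterion-based window-size selection.

#' Site accuracy of a window analysis against the simulated truth
#'
#' A site is counted correct when the canonical unrooted topology of the
#' window covering it equals the canonical topology of the truth locus
#' covering it.  With `denominator = "total"` (the plain NOW convention)
#' the denominator is the full simulated alignment length, so sites in a
#' dropped trailing remainder or in unanalyzable windows count as
#' incorrect; with `"analyzed"` (the stepwise convention) only sites in
#' fitted windows enter numerator and denominator.
#'
#' @param truth A [TruthMap-class].
#' @param fit A [NowFit-class] over the same alignment.
#' @param denominator `"total"` or `"analyzed"`.
#' @return Site accuracy as a percentage in `[0, 100]`.
#' @export
siteAccuracy <- function(truth, fit, denominator = c("total", "analyzed")) {
  denominator <- match.arg(denominator)
  maxend <- max(IRanges::end(fit@intervals))
  if (maxend > truth@totalLength)
    stop("fit windows extend beyond the truth map (",
         maxend, " > ", truth@totalLength, " sites)")
  ok <- fit@stats$analyzable
  iv <- fit@intervals[ok]
  ids <- fit@stats$canonical[ok]
  hits <- IRanges::findOverlaps(iv, truth@intervals)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(iv[qh], truth@intervals[sh]))
  correct <- sum(ov[ids[qh] == truth@topology[sh]])
  denom <- if (denominator == "total") truth@totalLength
           else sum(IRanges::width(iv))
  if (denom <= 0) stop("no analyzed sites to score")
  100 * correct / denom
}

#' Observed topology weights of a window analysis
#'
#' The estimated distribution of unrooted topologies over the fitted
#' windows; `"site"` weighting (the default) weights each window by its
#' size so the weights are site proportions comparable to
#' [truthTopologyWeights()], `"window"` weighting counts windows.
#'
#' @param fit A [NowFit-class].
#' @param weighting `"site"` or `"window"`.
#' @return Named numeric vector of proportions summing to 1.
#' @export
observedTopologyWeights <- function(fit, weighting = c("site", "window")) {
  weighting <- match.arg(weighting)
  ok <- fit@stats$analyzable
  ids <- fit@stats$canonical[ok]
  if (length(ids) == 0L) stop("no fitted windows")
  unit <- if (weighting == "site") IRanges::width(fit@intervals)[ok]
          else rep(1, length(ids))  # identical for equal-size windows
  w <- tapply(unit, ids, sum)
  sort(w / sum(w), decreasing = TRUE)
}

#' Root mean squared error between two topology-weight distributions
#'
#' \eqn{RMSE = \sqrt{\sum_i (P_i - O_i)^2 / n}} over the union of the two
#' distributions' topologies (n = union size); a topology absent from one
#' side contributes weight 0 there.  For normalized weights the maximum, 1,
#' is attained by two disjoint point masses.
#'
#' @param P Predicted (truth) weights: named numeric vector.
#' @param O Observed weights: named numeric vector.
#' @return RMSE in `[0, 1]`.
#' @export
topologyRmse <- function(P, O) {
  topos <- union(names(P), names(O))
  if (length(topos) == 0L) stop("empty topology union")
  p <- setNames(rep(0, length(topos)), topos)
  o <- p
  p[names(P)] <- P
  o[names(O)] <- O
  sqrt(sum((p - o)^2) / length(topos))
}

#' Accuracy report across the window sizes of a NOW analysis
#'
#' @param truth A [TruthMap-class].
#' @param result A [NowResult-class] over the simulated alignment.
#' @param denominator Passed to [siteAccuracy()].
#' @return data.frame, one row per size: `size`, `site_accuracy`, `rmse`,
#'   `n_topologies` (size of the truth/observed topology union); the
#'   per-size weight tables are attached as attribute `weights`.
#' @export
accuracyReport <- function(truth, result,
                           denominator = c("total", "analyzed")) {
  denominator <- match.arg(denominator)
  P <- truthTopologyWeights(truth)
  rows <- NULL
  wtab <- list()
  for (key in names(result@fits)) {
    fit <- result@fits[[key]]
    O <- observedTopologyWeights(fit)
    rows <- rbind(rows, data.frame(
      size = fit@windowSize,
      site_accuracy = siteAccuracy(truth, fit, denominator),
      rmse = topologyRmse(P, O),
      n_topologies = length(union(names(P), names(O)))))
    wtab[[key]] <- list(predicted = P, observed = O)
  }
  attr(rows, "weights") <- wtab
  rows
}

#' Accuracy loss of criterion-based window-size selection
#'
#' Compares the accuracy of the most accurate window size on the grid with
#' the accuracy of the size the criterion selects:
#' `site_accuracy_loss = max(site_accuracy) - site_accuracy(selected)` and
#' `rmse_gain = rmse(selected) - min(rmse)`; both are >= 0 by
#' construction, and both are 0 when the criterion picks the most accurate
#' size.
#'
#' @param reports data.frame from [accuracyReport()].
#' @param summaries Score summaries over the same size grid (a
#'   [NowResult-class] or its `summaries`).
#' @param criterion `"AIC"` or `"BIC"`.
#' @return List: `selected_size`, `site_accuracy_loss`, `rmse_gain`.
#' @export
criterionLoss <- function(reports, summaries, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (is(summaries, "NowResult")) summaries <- summaries@summaries
  if (!setequal(reports$size, summaries$size))
    stop("reports and summaries cover different window-size grids")
  sel <- selectBestSize(summaries, criterion)
  at <- reports[reports$size == sel, ]
  list(selected_size = sel,
       site_accuracy_loss = max(reports$site_accuracy) - at$site_accuracy,
       rmse_gain = at$rmse - min(reports$rmse))
}
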