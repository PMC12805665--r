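# now_scoring: run the non-overlapping window analysis over a grid of
# window sizes, aggregate AIC/BIC across windows per size, select the
# best size.

#' Window-size grids
#'
#' `"halving"` (the default grid): powers-of-two halvings from `start`
#' down to `floor`, plus the full alignment length (a fully concatenated
#' analysis).  `"decade16"`: the 1-2-5 decade ladder from 100 bp to 10 Mb
#' (16 sizes), truncated to the alignment length.
#'
#' @param alignmentLength Total sites.
#' @param type Grid type.
#' @param start,floor Largest/smallest halving size.
#' @return Sorted numeric vector of window sizes.
#' @export
windowSizeGrid <- function(alignmentLength, type = c("halving", "decade16"),
                           start = 64000, floor = 125) {
  type <- match.arg(type)
  sizes <- if (type == "halving") {
    s <- start
    out <- c()
    while (s >= floor) {
      out <- c(out, s)
      s <- s / 2
    }
    c(out, alignmentLength)
  } else {
    c(1, 2, 5) %o% 10^(2:6) |> as.vector() |> c(1e7)
  }
  sizes <- sizes[sizes <= alignmentLength & sizes >= 1]
  sort(unique(sizes))
}

#' Aggregate per-window fits into AIC/BIC scores
#'
#' Sums the per-window log-likelihoods and free-parameter counts and
#' applies \eqn{AIC = -2 \ln L + 2k} and
#' \eqn{BIC = -2 \ln L + k \ln n}, where \eqn{\ln L} is the total
#' log-likelihood across all windows, \eqn{k} the total number of free
#' parameters (branch lengths) across all windows, and \eqn{n} the number
#' of sites across all windows.
#'
#' @param fits A [NowFit-class], or a data.frame with columns `lnl` and
#'   `k` (one row per window).
#' @param nSites Number of sites across all windows (the BIC's n);
#'   defaults to the fit's own site total.
#' @return One-row data.frame: `size`, `n_windows`, `total_lnl`, `K`,
#'   `n_sites`, `AIC`, `BIC`.
#' @export
aggregateScores <- function(fits, nSites = NULL) {
  if (is(fits, "NowFit")) {
    ok <- fits@stats$analyzable
    lnl <- fits@stats$lnl[ok]
    k <- fits@stats$k[ok]
    size <- fits@windowSize
    if (is.null(nSites)) nSites <- fits@nSites
  } else {
    lnl <- fits$lnl
    k <- fits$k
    size <- NA_real_
    if (is.null(nSites)) stop("nSites is required for data.frame input")
  }
  if (length(lnl) == 0L) stop("no fitted windows to aggregate")
  if (nSites <= 0) stop("nSites must be > 0")
  total_lnl <- sum(lnl)
  K <- sum(k)
  data.frame(size = size, n_windows = length(lnl), total_lnl = total_lnl,
             K = K, n_sites = nSites,
             AIC = -2 * total_lnl + 2 * K,
             BIC = -2 * total_lnl + K * log(nSites))
}

#' Non-overlapping window analysis over a grid of window sizes
#'
#' For each size: partition the alignment from position 0 into windows of
#' exactly that size (trailing remainder dropped), fit a JC ML tree per
#' window with `blmin = 1/size`, and aggregate AIC and BIC.  All sizes are
#' scored on the same alignment, which AIC comparability requires; if any
#' window is unanalyzable the analysis stops and directs you to
#' [stepwiseNow()], which handles missing data by joint filtering.
#'
#' @param aln A [GenomeAlignment-class].
#' @param sizes Window sizes (default [windowSizeGrid()] `"halving"`).
#' @param config A [searchConfig()].
#' @param minTaxaWithData,strict Analyzability rule, see
#'   [windowAnalyzable()].
#' @param bootstrapReps Bootstrap replicates per window (default 0).
#' @return A [NowResult-class]: `summaries` (one row per size, with
#'   `delta_AIC` relative to the best size) and per-size [NowFit-class]
#'   objects.
#' @export
nowAnalysis <- function(aln, sizes = NULL, config = searchConfig(),
                        minTaxaWithData = 3L, strict = TRUE,
                        bootstrapReps = 0L) {
  L <- alnLength(aln)
  if (is.null(sizes)) sizes <- windowSizeGrid(L)
  if (any(sizes > L)) stop("window sizes exceed alignment length")
  sizes <- sort(unique(sizes))
  if (any(L %% sizes != 0))
    warning("window size(s) ", paste(sizes[L %% sizes != 0], collapse = ", "),
            " do not divide the alignment length; their dropped trailing ",
            "remainder makes their AIC/BIC totals cover fewer sites than ",
            "the other sizes -- prefer sizes that divide the alignment")
  enc <- .encode_alignment(aln)
  fits <- list()
  summaries <- NULL
  for (s in sizes) {
    part <- makeWindows(L, s)
    part <- windowAnalyzable(enc, part, minTaxaWithData, strict)
    if (!all(part@analyzable))
      stop(sum(!part@analyzable), " window(s) of size ", s,
           " cannot be analyzed due to missing data; AIC comparability ",
           "across sizes requires the identical alignment -- use ",
           "stepwiseNow() for alignments with missing data")
    fit <- .fit_windows(enc, part, config, bootstrapReps,
                        dropMissingTaxa = !strict)
    fits[[as.character(s)]] <- fit
    summaries <- rbind(summaries, aggregateScores(fit))
  }
  summaries$delta_AIC <- summaries$AIC - min(summaries$AIC)
  methods::new("NowResult", summaries = summaries, fits = fits)
}

#' Select the window size with the best AIC
#'
#' Argmin over the summaries' criterion column; exact ties are broken
#' toward the larger window size.
#'
#' @param summaries data.frame from [nowAnalysis()]'s `summaries` (or
#'   [aggregateScores()] rows), or a [NowResult-class].
#' @param criterion `"AIC"` or `"BIC"`.
#' @return The selected window size.
#' @export
selectBestSize <- function(summaries, criterion = c("AIC", "BIC")) {
  criterion <- match.arg(criterion)
  if (is(summaries, "NowResult")) summaries <- summaries@summaries
  if (nrow(summaries) < 1L) stop("no summaries to select from")
  val <- summaries[[criterion]]
  best <- min(val)
  max(summaries$size[val == best])  # ties -> larger size
}

#' Accessors for NowResult objects
#'
#' `nowSummaries` returns the per-size score table; `nowFit` the
#' [NowFit-class] for one size.
#'
#' @param x A [NowResult-class].
#' @param size Window size (must be one of the analyzed sizes).
#' @return See description.
#' @export
nowSummaries <- function(x) x@summaries

#' @rdname nowSummaries
#' @export
nowFit <- function(x, size) {
  key <- as.character(size)
  if (!key %in% names(x@fits)) stop("size ", size, " was not analyzed")
  x@fits[[key]]
}

#' Write the per-size score table as TSV
#'
#' @param x A [NowResult-class] or its summaries data.frame.
#' @param path Output path.
#' @return Invisibly, the data.frame written.
#' @export
writeScoreTsv <- function(x, path) {
  df <- if (is(x, "NowResult")) x@summaries else x
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
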