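# summarize_cli: topology-distribution summaries and empirical
# post-processing (support filtering, window spacing, run lengths,
# per-topology branch/informative-site statistics).

#' Topology distribution over fitted windows
#'
#' Counts and proportions per canonical topology over the fitted windows,
#' optionally restricted to well-supported trees
#' (`mean_support >= supportMin`; windows whose support is undefined --
#' fewer than four unique sequences -- are excluded whenever a support
#' threshold is active) and/or greedily subsampled so that consecutive
#' kept windows are at least `spacing` windows apart (a guard against
#' counting one non-recombining block many times).
#'
#' @param fit A [NowFit-class] with windows ordered by genomic position.
#' @param supportMin Minimum mean bootstrap support in `[0, 100]`, or
#'   `NULL` for no filter.
#' @param spacing Minimum number of windows between kept windows, or
#'   `NULL` for no spacing.
#' @return List: `counts`, `proportions` (both named by topology, sorted
#'   decreasing), `nIncluded`, `filters`.
#' @export
topologyDistribution <- function(fit, supportMin = NULL, spacing = NULL) {
  df <- fitStats(fit)
  keep <- df$analyzable
  if (!is.null(supportMin))
    keep <- keep & !is.na(df$mean_support) & df$mean_support >= supportMin
  idx <- which(keep)
  if (!is.null(spacing) && length(idx) > 0L) {
    kept <- idx[1]
    last <- idx[1]
    for (i in idx[-1]) {
      if (i - last >= spacing) {
        kept <- c(kept, i)
        last <- i
      }
    }
    idx <- kept
  }
  ids <- df$canonical[idx]
  tab <- sort(table(ids), decreasing = TRUE)
  counts <- setNames(as.integer(tab), names(tab))
  list(counts = counts,
       proportions = if (length(ids)) counts / length(ids)
                     else setNames(numeric(), character()),
       nIncluded = length(ids),
       filters = list(supportMin = supportMin, spacing = spacing))
}

#' Run lengths of consecutive same-topology windows
#'
#' Maximal runs of identical canonical topology IDs along the window
#' sequence; windows without a fit (unanalyzable, or removed by an
#' upstream filter) break runs.
#'
#' @param fit A [NowFit-class] with windows ordered and contiguous.
#' @return Integer vector of run lengths (analyzable windows only).
#' @export
runLengths <- function(fit) {
  ids <- as.character(fit@stats$canonical)
  ids[!fit@stats$analyzable] <- NA_character_
  r <- rle(ids)
  r$lengths[!is.na(r$values)]
}

#' Per-topology internal-branch and informative-site statistics
#'
#' For each canonical topology: the mean (over its windows) of the sum of
#' internal branch lengths of the fitted tree, and the mean count of
#' parsimony-informative sites (columns with at least two states each
#' present in at least two sequences).
#'
#' @param fit A [NowFit-class].
#' @param aln The [GenomeAlignment-class] the fit was computed on.
#' @return data.frame: `topology`, `n_windows`, `mean_internal_bl`,
#'   `mean_informative_sites`, sorted by `n_windows` decreasing.
#' @export
internalBranchStats <- function(fit, aln) {
  ok <- which(fit@stats$analyzable)
  if (length(ok) == 0L) stop("no fitted windows")
  enc <- .encode_alignment(aln)
  st <- IRanges::start(fit@intervals) - 1L
  en <- IRanges::end(fit@intervals)
  ibl <- inf <- numeric(length(ok))
  for (j in seq_along(ok)) {
    i <- ok[j]
    tr <- ape::read.tree(text = fit@stats$newick[[i]])
    internal <- tr$edge[, 2] > length(tr$tip.label)
    ibl[j] <- sum(tr$edge.length[internal])
    inf[j] <- .cpp_count_informative(enc, st[i], en[i])
  }
  ids <- fit@stats$canonical[ok]
  out <- data.frame(
    topology = names(tapply(ibl, ids, mean)),
    n_windows = as.integer(table(ids)[names(tapply(ibl, ids, mean))]),
    mean_internal_bl = as.numeric(tapply(ibl, ids, mean)),
    mean_informative_sites = as.numeric(tapply(inf, ids, mean)))
  out[order(-out$n_windows), , drop = FALSE]
}

#' Count parsimony-informative sites of an alignment
#'
#' A column is parsimony-informative when at least two states are each
#' present in at least two sequences (gaps/N ignored).
#'
#' @param aln A [GenomeAlignment-class].
#' @return Integer count.
#' @export
countInformativeSites <- function(aln) {
  enc <- .encode_alignment(aln)
  .cpp_count_informative(enc, 0L, ncol(enc))
}
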