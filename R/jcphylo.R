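# jcphylo: per-window Jukes-Cantor phylogenetics.  The numerical engine
# (pattern compression, pruning likelihood, Brent branch-length
# optimization, exhaustive/NNI search, nonparametric bootstrap) lives in
# src/jcengine.cpp; these wrappers convert between ape 'phylo' objects and
# the engine's edge-list representation.

#' Search configuration for per-window tree estimation
#'
#' @param blmin Minimum branch length (substitutions/site).  `NULL` means
#'   "1/window size", recomputed per window size -- one expected
#'   substitution per branch, penalizing spurious resolution in
#'   uninformative windows.
#' @param blmax Maximum branch length (default 10).
#' @param strategy `"auto"` (exhaustive for <= 5 taxa, NNI otherwise),
#'   `"exhaustive"`, or `"nni"` (neighbour-joining start, best-improvement
#'   NNI hill climbing).
#' @param bootstrapReps Nonparametric bootstrap replicates (default 1000).
#' @param tol Log-likelihood convergence threshold for branch-length
#'   optimization.
#' @param seed RNG seed used for the bootstrap.
#' @return A list of class `searchConfig`.
#' @export
searchConfig <- function(blmin = NULL, blmax = 10,
                         strategy = c("auto", "exhaustive", "nni"),
                         bootstrapReps = 1000L, tol = 1e-4, seed = NULL) {
  strategy <- match.arg(strategy)
  if (!is.null(blmin) && (blmin <= 0 || blmin >= blmax))
    stop("blmin must satisfy 0 < blmin < blmax")
  if (bootstrapReps < 0) stop("bootstrapReps must be >= 0")
  structure(list(blmin = blmin, blmax = blmax, strategy = strategy,
                 bootstrapReps = as.integer(bootstrapReps), tol = tol,
                 seed = seed),
            class = "searchConfig")
}

.strategy_code <- function(strategy)
  switch(strategy, auto = 0L, exhaustive = 1L, nni = 2L)

# encode a window for the engine, rows ordered to match `taxa`
.enc_for <- function(aln, taxa) .encode_alignment(aln, taxa = taxa)

#' Jukes-Cantor log-likelihood of a tree for an alignment
#'
#' Felsenstein-pruning log-likelihood under JC (uniform stationary
#' frequencies 1/4; \eqn{P_{same}(t) = 1/4 + 3/4 e^{-4t/3}}).  Gap and N
#' characters are missing data (partial-likelihood vectors of ones);
#' columns with no observed base at all are skipped and contribute 0.
#' The result is invariant to the rooting position of `tree`.
#'
#' @param aln A [GenomeAlignment-class] (typically one window).
#' @param tree An `ape` `phylo` with branch lengths in substitutions/site;
#'   its tip labels must be a subset of `alnTaxa(aln)`.
#' @return Log-likelihood (numeric scalar).
#' @export
jcLogLikelihood <- function(aln, tree) {
  enc <- .enc_for(aln, tree$tip.label)
  if (sum(rowSums(enc != 4L) > 0L) < 2L)
    stop("likelihood undefined: fewer than 2 taxa with data")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  .cpp_jc_lnl(enc, tree$edge, tree$edge.length, length(tree$tip.label))
}

#' Optimize branch lengths of a fixed topology
#'
#' Coordinate ascent over branches (exact 1-D Brent optimization per
#' branch, clamped to `[blmin, blmax]`) until the total log-likelihood
#' improves by less than `tol`.
#'
#' @inheritParams jcLogLikelihood
#' @param config A [searchConfig()]; `blmin = NULL` uses 1/window size.
#' @return The tree with optimized `edge.length` and attributes `lnl`.
#' @export
optimizeBranchLengths <- function(aln, tree, config = searchConfig()) {
  enc <- .enc_for(aln, tree$tip.label)
  blmin <- if (is.null(config$blmin)) 1 / alnLength(aln) else config$blmin
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  res <- .cpp_optimize_bl(enc, tree$edge, tree$edge.length,
                          length(tree$tip.label), blmin, config$blmax,
                          config$tol, 20L)
  if (!is.finite(res$lnl))
    stop("non-finite likelihood during branch-length optimization")
  tree$edge.length <- res$lengths
  attr(tree, "lnl") <- res$lnl
  tree
}

#' Estimate the ML tree of one window
#'
#' Under `strategy = "exhaustive"` every unrooted topology is
#' branch-length-optimized and the best is returned (ties broken by
#' lexicographic canonical topology ID); under `"nni"` a JC-distance
#' neighbour-joining tree is refined by best-improvement NNI hill
#' climbing.  `"auto"` uses exhaustive search up to 5 taxa.
#'
#' @inheritParams optimizeBranchLengths
#' @param dropMissingTaxa Drop taxa without any observed base in this
#'   window before fitting (the lenient analyzability rule); with
#'   `FALSE`, such taxa cause an error.
#' @param bootstrapReps Override `config$bootstrapReps` (default 0: no
#'   support here; see [bootstrapSupport()]).
#' @return A list with elements `tree` (phylo), `lnl`, `k` (= 2t - 3 free
#'   branch lengths), `canonical` (topology ID), `nUnique` (distinct
#'   sequences), `meanSupport` (or `NA`), `nPatterns`.
#' @export
searchTopology <- function(aln, config = searchConfig(),
                           dropMissingTaxa = TRUE, bootstrapReps = 0L) {
  enc <- .encode_alignment(aln)
  has <- rowSums(enc != 4L) > 0L
  if (!all(has)) {
    if (!dropMissingTaxa)
      stop("window has taxa without data; filter windows first ",
           "(see windowAnalyzable) or set dropMissingTaxa = TRUE")
    enc <- enc[has, , drop = FALSE]
  }
  if (nrow(enc) < 3L)
    stop("window unanalyzable: fewer than 3 taxa with data; ",
         "filter windows first (see windowAnalyzable)")
  blmin <- if (is.null(config$blmin)) 1 / alnLength(aln) else config$blmin
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .cpp_search_topology(enc, rownames(enc),
                              .strategy_code(config$strategy), blmin,
                              config$blmax, config$tol,
                              as.integer(bootstrapReps), 4L)
  list(tree = ape::read.tree(text = res$newick), lnl = res$lnl, k = res$k,
       canonical = res$canonical, nUnique = res$n_unique,
       meanSupport = res$mean_support, nPatterns = res$n_patterns)
}

#' Mean nonparametric bootstrap support of a window's ML tree
#'
#' Standard nonparametric bootstrap: alignment columns are resampled with
#' replacement, the topology search is re-run, and each internal branch's
#' support is the percentage of replicates containing that bipartition;
#' the mean over internal branches is returned.  Windows with fewer than
#' four unique sequences get `NA` (support undefined, not zero), mirroring
#' the practice of skipping bootstrapping for such windows.
#'
#' @inheritParams searchTopology
#' @return Mean support in `[0, 100]`, or `NA`.
#' @export
bootstrapSupport <- function(aln, config = searchConfig(),
                             dropMissingTaxa = TRUE) {
  if (config$bootstrapReps == 0L) return(NA_real_)
  fit <- searchTopology(aln, config, dropMissingTaxa,
                        bootstrapReps = config$bootstrapReps)
  fit$meanSupport
}

#' Canonical ID of an unrooted leaf-labelled topology
#'
#' The tree is (re)rooted at its lexicographically smallest leaf and
#' serialized with children sorted recursively; branch lengths are
#' ignored.  Two trees get equal IDs exactly when their unrooted
#' topologies are equal.
#'
#' @param tree An `ape` `phylo` (rooted or unrooted) with >= 2 leaves.
#' @return Character scalar topology ID.
#' @export
canonicalTopology <- function(tree) {
  .cpp_canonical_id(tree$edge, length(tree$tip.label), tree$tip.label)
}

# Batch fit: one JC ML tree per analyzable window of a partition.
# Returns a NowFit.  blmin defaults to 1/windowSize (exact float division).
.fit_windows <- function(enc, partition, config = searchConfig(),
                         bootstrapReps = 0L, dropMissingTaxa = !is.null(config),
                         blmin = NULL) {
  ws <- partition@windowSize
  if (is.null(blmin))
    blmin <- if (is.null(config$blmin)) 1 / ws else config$blmin
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- .cpp_fit_windows(enc, rownames(enc), windowStarts(partition),
                          windowEnds(partition), partition@analyzable,
                          .strategy_code(config$strategy), blmin,
                          config$blmax, config$tol,
                          as.integer(bootstrapReps), 4L,
                          isTRUE(dropMissingTaxa))
  stats <- S4Vectors::DataFrame(
    lnl = res$lnl, k = res$k, n_taxa = res$n_taxa,
    n_unique = res$n_unique, n_patterns = res$n_patterns,
    canonical = res$canonical, newick = res$newick,
    mean_support = res$mean_support,
    analyzable = partition@analyzable & !is.na(res$lnl))
  methods::new("NowFit", windowSize = ws, intervals = partition@intervals,
               stats = stats, blmin = blmin,
               nSites = as.numeric(ws) * sum(stats$analyzable))
}

#' Accessors for NowFit objects
#'
#' `fitStats` returns the per-window table (as a data.frame with 0-based
#' `start` and half-open `end` columns prepended), `fitTrees` the fitted
#' trees as an `ape` `multiPhylo` (analyzable windows only), and
#' `fitWindowSize` the window size.
#'
#' @param fit A [NowFit-class].
#' @return See description.
#' @export
fitStats <- function(fit) {
  df <- as.data.frame(fit@stats)
  cbind(data.frame(window_index = seq_len(nrow(df)),
                   start = IRanges::start(fit@intervals) - 1L,
                   end = IRanges::end(fit@intervals)), df)
}

#' @rdname fitStats
#' @export
fitTrees <- function(fit) {
  ok <- fit@stats$analyzable
  trees <- ape::read.tree(text = unlist(fit@stats$newick[ok]))
  if (inherits(trees, "phylo")) trees <- c(trees)  # multiPhylo of length 1
  trees
}

#' @rdname fitStats
#' @export
fitWindowSize <- function(fit) fit@windowSize

#' Write a per-window fit table as TSV
#'
#' Columns: window_index (1-based), start, end (0-based half-open),
#' topology_id, lnl, k, mean_support, n_unique_sequences.
#'
#' @param fit A [NowFit-class].
#' @param path Output path.
#' @return Invisibly, the data.frame written.
#' @export
writeFitTsv <- function(fit, path) {
  df <- fitStats(fit)
  out <- df[, c("window_index", "start", "end", "canonical", "lnl", "k",
                "mean_support", "n_unique")]
  names(out)[c(4, 7, 8)] <- c("topology_id", "mean_support",
                              "n_unique_sequences")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
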