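# Shared fixtures and independent oracles.

# quick alignment from a named character vector
aln_of <- function(...) GenomeAlignment(c(...))

# random gapless alignment (uniform iid sites; no phylogenetic signal)
random_alignment <- function(ntax, L, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(ntax), function(i)
    paste0(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("t", seq_len(ntax))
  GenomeAlignment(seqs)
}

# Independent brute-force JC log-likelihood: enumerate all internal-node
# state assignments (feasible for <= 5 leaves).  aln: GenomeAlignment,
# tree: rooted or unrooted ape phylo with edge lengths.
brute_jc_lnl <- function(aln, tree) {
  chars <- strsplit(as.character(alnSequences(aln)), "")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  ninternal <- tree$Nnode
  pmat <- lapply(tree$edge.length, function(t) {
    e <- exp(-4 * t / 3)
    m <- matrix(0.25 - 0.25 * e, 4, 4)
    diag(m) <- 0.25 + 0.75 * e
    m
  })
  statemap <- c(A = 1, C = 2, G = 3, T = 4)
  L <- alnLength(aln)
  total <- 0
  for (site in seq_len(L)) {
    tipstate <- vapply(tree$tip.label, function(tx)
      statemap[chars[[tx]][site]], numeric(1))  # NA for gap/N
    if (all(is.na(tipstate))) next  # all-missing columns are skipped
    sitelik <- 0
    grid <- as.matrix(expand.grid(rep(list(1:4), ninternal)))
    for (g in seq_len(nrow(grid))) {
      assign_ <- grid[g, ]
      state_of <- function(node) {
        if (node <= ntip) tipstate[node] else assign_[node - ntip]
      }
      p <- 0.25  # uniform root frequency
      for (e in seq_len(nrow(tree$edge))) {
        par <- state_of(tree$edge[e, 1])
        ch <- state_of(tree$edge[e, 2])
        p <- p * if (is.na(ch)) 1 else pmat[[e]][par, ch]
        if (p == 0) break
      }
      sitelik <- sitelik + p
    }
    total <- total + log(sitelik)
  }
  total
}

# Naive per-site site-accuracy loop (independent of the interval sweep).
naive_site_accuracy <- function(truth, fit, denominator = "total") {
  tl <- truthLoci(truth)
  st <- fitStats(fit)
  truth_of_site <- rep(NA_character_, truthTotalLength(truth))
  for (i in seq_len(nrow(tl)))
    truth_of_site[(tl$start[i] + 1):tl$end[i]] <- tl$topology[i]
  fit_of_site <- rep(NA_character_, truthTotalLength(truth))
  for (i in which(st$analyzable))
    fit_of_site[(st$start[i] + 1):st$end[i]] <- st$canonical[i]
  correct <- sum(!is.na(fit_of_site) & fit_of_site == truth_of_site)
  denom <- if (denominator == "total") truthTotalLength(truth)
           else sum(!is.na(fit_of_site))
  100 * correct / denom
}

# TruthMap from explicit loci (0-based half-open starts/ends)
truth_of <- function(starts, ends, newicks, total = max(ends)) {
  topo <- vapply(newicks, function(x)
    canonicalTopology(ape::read.tree(text = x)), character(1))
  methods::new("TruthMap",
               intervals = IRanges::IRanges(start = starts + 1L, end = ends),
               newick = newicks, topology = unname(topo),
               totalLength = total, seed = 1L)
}

# simulate a gapless alignment from an explicit truth map
sim_from_truth <- function(truth, seed = 1) {
  taxa <- sort(ape::read.tree(text = truth@newick[1])$tip.label)
  simulateSequences(truth, taxa = taxa, seed = seed)
}

# truth map with random (geometric) segment lengths around mean_len,
# cycling random draws from the four segmentTruthMap gene trees
random_truth <- function(L, mean_len, seed = 1) {
  set.seed(seed)
  base <- segmentTruthMap(segmentLength = 100, nSegments = 4)
  lens <- pmax(50, stats::rgeom(ceiling(4 * L / mean_len), 1 / mean_len))
  lens <- lens[cumsum(lens) <= L]
  lens <- c(lens, L - sum(lens))
  lens <- lens[lens > 0]
  ids <- sample(1:4, length(lens), replace = TRUE)
  starts <- cumsum(c(0, head(lens, -1)))
  truth_of(starts, starts + lens, base@newick[ids], total = L)
}

# a strong-signal 4-taxon truth tree (AB|CD split)
quartet_newick <- function(tip = 0.1, internal = 0.08)
  sprintf("((a:%g,b:%g):%g,(c:%g,d:%g):%g);", tip, tip, internal / 2,
          tip, tip, internal / 2)
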