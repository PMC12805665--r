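# coalsim: synthetic-data generator.  Gene trees come from a multispecies
# coalescent with recombination and introgression (simulated by msprime via
# the bundled inst/python script); sequences are evolved under Jukes-Cantor
# by the package's own engine; the per-site truth map is retained.

#' Convert a time in Myr to coalescent units
#'
#' One coalescent unit is 4Ne generations; the default conversion of
#' 0.75 Myr per unit reflects Heliconius population-genetic estimates.
#'
#' @param timeMyr Time in Myr.
#' @param myrPerCoalUnit Myr equivalent to one coalescent unit (> 0).
#' @return Time in coalescent units (`timeMyr / myrPerCoalUnit`).
#' @examples
#' myrToCoalescent(0.75, 0.75)  # 1
#' @export
myrToCoalescent <- function(timeMyr, myrPerCoalUnit = 0.75) {
  if (myrPerCoalUnit <= 0) stop("myrPerCoalUnit must be > 0")
  timeMyr / myrPerCoalUnit
}

#' Construct a coalescent simulation model
#'
#' See [SimulationModel-class] for the slot semantics and
#' [heliconiusModel()] for the packaged seven-taxon study preset.
#'
#' @param speciesTree Rooted ultrametric Newick string, branch lengths in
#'   Myr.
#' @param rho Total ms-style recombination parameter 4NrL over the
#'   segment.
#' @param totalLength Segment length in sites.
#' @param introgression data.frame with columns donor, recipient, timeMyr,
#'   gamma (one row per unidirectional pulse; clades written as
#'   `"taxonA+taxonB"`).
#' @param myrPerCoalUnit Myr per coalescent unit.
#' @param ilsScale Multiplier on coalescent-unit times; < 1 increases ILS.
#' @param mutationScale Substitutions/site per coalescent unit.
#' @param seed Default RNG seed (positive integer).
#' @return A [SimulationModel-class].
#' @export
SimulationModel <- function(speciesTree, rho = 0, totalLength = 1e7,
                            introgression = data.frame(),
                            myrPerCoalUnit = 0.75, ilsScale = 1,
                            mutationScale = 0.011, seed = 1L) {
  obj <- methods::new(
    "SimulationModel", speciesTree = speciesTree,
    myrPerCoalUnit = myrPerCoalUnit, ilsScale = ilsScale,
    introgression = introgression, rho = rho, totalLength = totalLength,
    mutationScale = mutationScale, seed = as.integer(seed))
  methods::validObject(obj)
  .model_demography(obj)  # errors early on infeasible event timing
  obj
}

# Heliconius erato-sara clade (six ingroup species) plus H. melpomene
# outgroup.  Node times in Myr follow published fossil-calibrated estimates
# for the clade; see the methods vignette for the calibration of the
# remaining free knobs (introgression gammas, mutation scale).
.heliconius_tree <- paste0(
  "(melpomene:13.5,((((erato:2.0,himera:2.0):1.2,hecalesia:3.2):0.55,",
  "telesiphe:3.75):0.5,(demeter:3.4,sara:3.4):0.85):9.25);")

.heliconius_introgression <- data.frame(
  donor = c("himera", "erato", "telesiphe",
            "telesiphe", "demeter+sara"),
  recipient = c("erato", "himera", "hecalesia",
                "demeter+sara", "telesiphe"),
  timeMyr = c(1.0, 1.0, 2.0, 3.5, 3.5),
  gamma = c(0.3, 0.3, 0.05, 0.1, 0.1),
  stringsAsFactors = FALSE)

#' Heliconius-like seven-taxon simulation preset
#'
#' The packaged study conditions: six erato-sara clade species plus the
#' melpomene outgroup, three bidirectional introgression events
#' (himera–erato; telesiphe–hecalesia, one direction; telesiphe–the
#' demeter+sara ancestor), a 10 Mb segment, and recombination
#' \eqn{\rho \in \{0, 20, 200, 2000\}}.  ILS levels scale all
#' coalescent-unit times (low = 2, medium = 1, high = 0.5).
#'
#' @param rho Total recombination parameter over `totalLength`.  When you
#'   shorten `totalLength`, scale `rho` proportionally to keep the per-site
#'   recombination rate (e.g. 1 Mb at the 10 Mb rho = 2000 condition uses
#'   rho = 200).
#' @param totalLength Segment length in sites (default 10 Mb).
#' @param ils One of "medium", "low", "high".
#' @param introgression If `FALSE`, drop all introgression pulses.
#' @param seed Default RNG seed.
#' @return A [SimulationModel-class].
#' @export
heliconiusModel <- function(rho = 0, totalLength = 1e7,
                            ils = c("medium", "low", "high"),
                            introgression = TRUE, seed = 1L) {
  ils <- match.arg(ils)
  scale <- c(medium = 1, low = 2, high = 0.5)[[ils]]
  SimulationModel(
    speciesTree = .heliconius_tree, rho = rho, totalLength = totalLength,
    introgression = if (introgression) .heliconius_introgression
                    else data.frame(),
    myrPerCoalUnit = 0.75, ilsScale = scale, mutationScale = 0.011,
    seed = seed)
}

# Translate a SimulationModel into the population/split/pulse description
# the msprime backend consumes.  Internal populations are named by their
# sorted "+"-joined tip sets, which is also how introgression rows refer
# to ancestral branches.
.model_demography <- function(model) {
  tree <- ape::read.tree(text = model@speciesTree)
  if (is.null(tree)) stop("could not parse species tree")
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  times_myr <- max(depth) - depth       # node heights; tips ~ 0
  if (any(times_myr[seq_len(ntip)] > 1e-8))
    stop("species tree must be ultrametric (all tips at time 0)")
  tocoal <- function(t) myrToCoalescent(t, model@myrPerCoalUnit) *
    model@ilsScale
  cladename <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    tips <- ape::extract.clade(tree, node)$tip.label
    paste(sort(tips), collapse = "+")
  }
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  ord <- nodes[order(times_myr[nodes])]
  popbirth <- setNames(rep(0, ntip), tree$tip.label)
  popdeath <- setNames(rep(Inf, ntip), tree$tip.label)
  # msprime population names must be identifiers; clades get anc1, anc2, ...
  msname <- setNames(tree$tip.label, tree$tip.label)
  splits <- list()
  for (v in ord) {
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    dn <- vapply(kids, cladename, character(1))
    an <- cladename(v)
    t <- tocoal(times_myr[v])
    popbirth[an] <- t
    popdeath[an] <- Inf
    popdeath[dn] <- t
    msname[an] <- paste0("anc", length(splits) + 1L)
    splits[[length(splits) + 1L]] <-
      list(time = t, derived = as.list(unname(msname[dn])),
           ancestral = unname(msname[an]))
  }
  pulses <- list()
  ig <- model@introgression
  normname <- function(x) paste(sort(strsplit(x, "+", fixed = TRUE)[[1]]),
                                collapse = "+")
  if (nrow(ig) > 0) {
    for (i in seq_len(nrow(ig))) {
      dn <- normname(ig$donor[i]); rc <- normname(ig$recipient[i])
      t <- tocoal(ig$timeMyr[i])
      for (p in c(dn, rc)) {
        if (!p %in% names(popbirth))
          stop("introgression population not in species tree: ", p)
        if (t <= popbirth[[p]] || t >= popdeath[[p]])
          stop(sprintf(
            "introgression %s -> %s at %.3g Myr is outside the lifetime of branch %s",
            ig$donor[i], ig$recipient[i], ig$timeMyr[i], p))
      }
      pulses[[length(pulses) + 1L]] <-
        list(time = t, donor = unname(msname[dn]),
             recipient = unname(msname[rc]), gamma = ig$gamma[i])
    }
  }
  list(taxa = as.list(tree$tip.label),
       populations = as.list(unname(msname[names(popbirth)])),
       splits = splits, pulses = pulses,
       rho = model@rho, length = model@totalLength,
       mutation_scale = model@mutationScale)
}

.python_bin <- function() {
  for (cand in c("python", "python3")) {
    p <- Sys.which(cand)
    if (nzchar(p)) return(p)
  }
  stop("no python interpreter found on PATH (needed for gene-tree simulation)")
}

#' Simulate gene trees along the species tree
#'
#' Runs a coalescent-with-recombination simulation under the model (ILS,
#' introgression pulses, ms-style total recombination rho) and returns the
#' ordered sequence of distinct marginal genealogies with their spans: the
#' per-site truth map.  With `rho = 0` the map contains exactly one locus
#' spanning the whole segment.  Deterministic given `seed`.
#'
#' @param model A [SimulationModel-class].
#' @param seed Positive integer RNG seed; defaults to the model's.
#' @return A [TruthMap-class].
#' @export
simulateGeneTrees <- function(model, seed = NULL) {
  seed <- as.integer(if (is.null(seed)) model@seed else seed)
  if (is.na(seed) || seed < 1L) stop("seed must be a positive integer")
  cfg <- .model_demography(model)
  cfg$seed <- seed
  cfgfile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(cfgfile, outfile)), add = TRUE)
  jsonlite::write_json(cfg, cfgfile, auto_unbox = TRUE, digits = NA)
  script <- system.file("python", "sim_gene_trees.py", package = "winnow")
  status <- system2(.python_bin(), c(shQuote(script), shQuote(cfgfile),
                                     shQuote(outfile)),
                    stdout = FALSE, stderr = "")
  if (status != 0L) stop("gene-tree simulation backend failed (exit ",
                         status, ")")
  tab <- read.table(outfile, header = TRUE, sep = "\t", comment.char = "#",
                    colClasses = c("numeric", "numeric", "character",
                                   "character"))
  methods::new("TruthMap",
               intervals = IRanges::IRanges(start = tab$start + 1L,
                                            end = tab$end),
               newick = tab$newick, topology = tab$topology,
               totalLength = model@totalLength, seed = seed)
}

#' Truth-map accessors
#'
#' `truthLoci` returns a data.frame of the loci (0-based half-open
#' `start`/`end`, `topology`, `newick`); `truthTotalLength` the simulated
#' segment length; `nLoci` the locus count.
#'
#' @param truth A [TruthMap-class].
#' @return See description.
#' @export
truthLoci <- function(truth) {
  data.frame(start = IRanges::start(truth@intervals) - 1L,
             end = IRanges::end(truth@intervals),
             topology = truth@topology, newick = truth@newick,
             stringsAsFactors = FALSE)
}

#' @rdname truthLoci
#' @export
truthTotalLength <- function(truth) truth@totalLength

#' @rdname truthLoci
#' @export
nLoci <- function(truth) length(truth@intervals)

#' Merge adjacent same-topology loci of a truth map
#'
#' Secondary "topology-only" view of the truth: consecutive loci sharing a
#' canonical topology are merged into one (their first gene tree is kept as
#' the representative).
#'
#' @param truth A [TruthMap-class].
#' @return A [TruthMap-class] with merged loci.
#' @export
mergeSameTopology <- function(truth) {
  tp <- truth@topology
  grp <- cumsum(c(TRUE, tp[-1] != tp[-length(tp)]))
  st <- tapply(IRanges::start(truth@intervals), grp, min)
  en <- tapply(IRanges::end(truth@intervals), grp, max)
  first <- match(unique(grp), grp)
  methods::new("TruthMap",
               intervals = IRanges::IRanges(start = as.integer(st),
                                            end = as.integer(en)),
               newick = truth@newick[first], topology = tp[first],
               totalLength = truth@totalLength, seed = truth@seed)
}

#' Per-topology site proportions of the simulated truth
#'
#' For each canonical unrooted topology, the fraction of sites whose locus
#' carries it.  Proportions sum to 1.
#'
#' @param truth A [TruthMap-class].
#' @return Named numeric vector (sorted decreasing).
#' @export
truthTopologyWeights <- function(truth) {
  w <- tapply(IRanges::width(truth@intervals), truth@topology, sum)
  sort(w / truth@totalLength, decreasing = TRUE)
}

#' Evolve sequences under Jukes-Cantor along the truth map
#'
#' Each locus is evolved independently under the JC model (uniform base
#' frequencies, no rate heterogeneity, no indels) along its gene tree,
#' whose branch lengths are in substitutions/site; loci are concatenated
#' in order.  Deterministic given `seed`.
#'
#' @param truth A [TruthMap-class].
#' @param taxa Taxon order for the output alignment; defaults to the
#'   sorted leaf set of the first gene tree.
#' @param seed RNG seed.
#' @return A [GenomeAlignment-class] of `truthTotalLength(truth)` sites.
#' @export
simulateSequences <- function(truth, taxa = NULL, seed = 1L) {
  if (is.null(taxa)) {
    t1 <- ape::read.tree(text = truth@newick[1])
    taxa <- sort(t1$tip.label)
  }
  set.seed(seed)
  enc <- .cpp_simulate_alignment(truth@newick,
                                 IRanges::width(truth@intervals), taxa)
  rownames(enc) <- taxa
  .decode_alignment(enc)
}
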