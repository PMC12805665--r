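---
title: "Choosing a non-overlapping window size with the AIC"
author: "winnow package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing a non-overlapping window size with the AIC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(winnow)
```

## The problem

Closely related genomes can be aligned almost end to end, but different
parts of the alignment follow different genealogies: recombination,
incomplete lineage sorting (ILS) and introgression make the local tree
change along the chromosome.  A common way to study this variation is the
non-overlapping window (NOW) analysis: cut the alignment into equal,
contiguous windows and estimate one tree per window, implicitly assuming
each window contains no recombination breakpoint.  The window size is the
load-bearing choice, and it is usually picked by convention.  Too small,
and per-window trees drown in estimation error; too large, and windows
straddle breakpoints, biasing every window toward a single averaged
topology (the concatenation effect).

winnow treats the window size as a model-selection problem.  At window
size $s$, the model for the whole alignment is the collection of
per-window Jukes–Cantor (JC) trees; its total log-likelihood is the sum
of window log-likelihoods, and its parameter count is the sum of free
branch lengths, $k = 2t - 3$ per window of $t$ taxa.  Candidate sizes are
ranked by

$$\mathrm{AIC}(s) = -2\ln L + 2k, \qquad
  \mathrm{BIC}(s) = -2\ln L + k\,\ln n,$$

with $n$ the number of sites across all windows.  Lower is better; ties
go to the larger (more parsimonious) size.  Comparing information
criteria across sizes is only meaningful when every size scores the
*identical* alignment — this constraint shapes two design rules below
(divisor-friendly grids, and the stepwise procedure's joint filtering).

## Per-window trees

Each analyzable window is fitted by maximum likelihood under JC: uniform
base frequencies, equal exchangeabilities, no rate heterogeneity.  The
engine computes Felsenstein-pruning likelihoods on compressed site
patterns, optimizes branch lengths by per-branch Brent searches
(coordinate ascent until the log-likelihood gain drops below `tol`,
default $10^{-4}$), and searches topologies exhaustively for up to five
taxa or by neighbour-joining + best-improvement NNI hill climbing above
that.  Tie-breaking is everywhere lexicographic on canonical topology
IDs, which makes results deterministic.

Three conventions matter:

* **Minimum branch length.** Every fit clamps branch lengths to
  `blmin = 1/s` — at least one expected substitution per branch.  Short,
  uninformative windows would otherwise resolve arbitrary topologies
  with near-zero internal branches at no likelihood cost; the floor makes
  that resolution cost likelihood, penalizing gene-tree estimation error.
  `blmax` is 10 substitutions/site, a numerical guard for the optimizer.
* **Missing data.** Gaps and `N` are missing: a missing leaf contributes
  a partial-likelihood vector of ones, and a column with no observed base
  at all is skipped (contributes 0 to $\ln L$).  This is the standard ML
  convention.
* **Parameter counting.** JC has no free rate or frequency parameters,
  so $k$ counts branch lengths only: $2t-3$ for $t \ge 3$ taxa.

Support values come from a standard nonparametric bootstrap (resample
columns, re-search, per-branch support = % of replicates containing that
bipartition, averaged over internal branches).  This deliberately
substitutes the classical bootstrap for approximate-bootstrap schemes
used by fast ML software; the threshold semantics (e.g. "mean support
$\ge 95$") are preserved, and windows with fewer than four unique
sequences report support as undefined (`NA`), not zero.  Summaries that
apply a support threshold exclude such windows.

## Analyzability and the stepwise procedure

A window enters the analysis only if it is *analyzable*.  The default
rule is strict — every taxon must have at least one observed base —
matching the behaviour needed when all-gapped taxa are common (e.g.
Y-chromosome alignments).  The lenient alternative requires only
$\ge$ `minTaxaWithData` (default 3) taxa with data and drops the empty
taxa from that window's fit.  Both are exposed because published
missing-data filters are often stated only as "removed due to missing
data"; the strict default is documented rather than asserted as anyone
else's rule.

On empirical alignments the shortest size for which *every* window is
analyzable can be large, so a plain grid analysis over small sizes is
impossible without discarding data asymmetrically.  The stepwise NOW
procedure ([stepwiseNow()]) compares two sizes at a time, halving:
$64\,\mathrm{kb}$ vs $32\,\mathrm{kb}$, then $32$ vs $16$, … down to a
floor (default 125 bp, which is no longer halvable in integers).  Within
a pair, a large window is kept only if it *and both of its halves* are
analyzable, so the retained site sets at the two sizes are identical —
a hard invariant, asserted in the tests — and their AICs are comparable.

Because each step retains a different region, AIC values from different
steps are **not** comparable; only within-step comparisons are coherent.
The default descent therefore stops at the first comparison the larger
size wins ("descend while improving").  A `full-chain` mode computes the
whole trajectory for inspection and then applies the same first-win
rule.  If the chain reaches the floor with the smaller size still
winning, the floor size is reported with a `stillDeclining` flag: the
best size is then at most the floor.  The retained fraction reported for
the best size is the jointly filtered fraction of the step that decided
it, i.e. the data its AIC was computed on.  Bootstrap support, when
requested, is computed only at the selected size.

## Scoring against simulated truth

With simulated data the generator records which genealogy every site was
drawn from, so a window analysis can be scored exactly:

* **Site accuracy**: the percentage of sites whose covering window's
  fitted unrooted topology equals the truth topology at that site.  For
  plain NOW runs the denominator is the full alignment length (sites in
  a dropped remainder count as wrong); for stepwise runs, where regions
  are removed by construction, the `"analyzed"` denominator restricts
  both numerator and denominator to fitted windows.  Both totals are
  available.
* **Topology-weight RMSE**:
  $\sqrt{\sum_i (P_i - O_i)^2 / n}$ between the truth site-weight
  distribution $P$ and the observed distribution $O$ over windows, with
  $i$ ranging over the *union* of the two topology sets ($n$ = union
  size).  The union is the only index set that penalizes both a missing
  predicted topology and a spurious observed one; with normalized
  weights the maximum value 1 is attained exactly by two disjoint point
  masses.  Observed weights are site-weighted (window counts times
  window size); for equal-size windows this coincides with window
  counting, and both are exposed.
* **Criterion loss**: the site-accuracy difference between the best size
  on the grid and the size the criterion picks (and the analogous RMSE
  gain); zero when the criterion picks the optimum.

## The synthetic-data generator

`heliconiusModel()` packages the study conditions the criterion was
validated under: seven taxa (six species of a closely related butterfly
clade plus an outgroup), gene trees from a multispecies coalescent with
recombination, three bidirectional introgression pulses, JC sequences,
and a retained per-site truth map.

The ancestral-recombination simulation is delegated to msprime via a
bundled Python script; the R side owns the model description, unit
conversions, and the truth-map contract (seed determinism; exactly one
locus when $\rho = 0$).  Times are specified in Myr on an ultrametric
species tree and converted at 0.75 Myr per coalescent unit (one unit =
$4N_e$ generations).  Recombination follows the classic ms convention:
$\rho = 4NrL$ over the whole segment, so scaling a 10 Mb condition down
to 1 Mb divides $\rho$ by 10.  **Locus boundaries are all recombination
events in the sample's history** — the segment semantics of ms-style
simulators — so adjacent loci may carry identical genealogies; a merged,
topology-only view is available via `mergeSameTopology()`.  Internally
the backend records recombinant nodes in the tree sequence to obtain
exactly these boundaries.

Free knobs that the study conditions do not pin down were calibrated
once, before any acceptance checks were written, to the printed
characteristics of the target system, and then frozen:

* **Chronogram.** Node times follow published fossil-calibrated
  estimates for the clade (splits at 2.0, 3.2, 3.4, 3.75, 4.25 Myr; root
  13.5 Myr), chosen within the published ranges so that the $\rho = 2000$
  / 10 Mb condition shatters into roughly 126,000 loci of mean length
  about 80 bp.
* **ILS level.** The `ils` presets scale all coalescent-unit times
  (medium = 1, low = 2, high = 0.5).  Medium ILS was calibrated so the
  dominant unrooted topology accounts for about half of all sites
  (replicate mean 0.49, per-1 Mb-replicate SD about 0.08 — individual
  replicates legitimately range from ~0.35 to ~0.62).
* **Introgression.** Pulse probabilities $\gamma$ = 0.3 (the two sister
  species that hybridize extensively), 0.05 and 0.1 for the two deeper
  events, at 1.0, 2.0 and 3.5 Myr; a bidirectional event is two pulses
  of equal $\gamma$ at the same time.
* **Mutation scale.** Branch lengths convert to substitutions/site at
  $4N_e\mu = 0.011$ per coalescent unit, calibrated so simulated
  alignments carry ~7–8% parsimony-informative sites (about 14 in a
  ~180 bp window), the neighbourhood of the empirical alignments the
  conditions emulate.

What the generator does *not* emulate: indels and alignment error, rate
heterogeneity among sites or branches, non-JC substitution processes,
gene conversion, diploid phasing, and gene structure.  Passing tests on
these simulations therefore demonstrate the criterion's behaviour under
idealized sequence evolution with known truth; they do not certify
performance on real alignments, where alignment error and model
misspecification add error modes of their own.

## What the criterion study shows

`simulationStudy()` reruns the validation at desk scale: 1 Mb replicate
chromosomes (the per-site recombination rates of the 10 Mb conditions
with $\rho$ = 2000 and 200), three or more replicates per scenario, and
per-scenario window-size grids whose every size divides the alignment —
the scaled stand-in for the full-scale 16-size, 10-replicate design,
sized to run in minutes on one CPU.  The expected pattern, asserted in
`tests/testthat/test-acceptance.R` at ±1 grid step / ±5 percentage
points:

* the AIC-selected size matches the accuracy-optimal size (2 kb at
  $\rho=2000$; 5 kb at $\rho=200$) and loses almost no site accuracy;
* the BIC, whose $\ln n$ penalty grows with the alignment, consistently
  selects much larger windows and loses on the order of 18 percentage
  points of site accuracy at $\rho=2000$;
* single-window concatenation recovers the dominant topology and
  therefore converges to its site weight (~50% under medium ILS);
* at $\rho=2000$ even the best size plateaus near 75% site accuracy —
  with 80 bp loci, no single window size can track every breakpoint.

`locusCountStudy()` reproduces the locus-structure figures themselves,
and `segmentTruthMap()` provides a controlled fixture (fixed-length,
strong-signal segments) for exact recovery checks.  One caveat found
while testing: when same-topology segments all have *identical* length
and alternate regularly, every large window sees the same topology
mixture, the likelihood surface flattens, and the pairwise descent can
stall at the start size — a pathology of perfectly regular truth, absent
from coalescent-generated (geometric-length) loci, which is why the
descent tests use variable-length truth maps.

## Numerical choices and degenerate inputs

* Branch-length optimization: per-branch Brent on $[\mathrm{blmin},
  \mathrm{blmax}]$ with both interval endpoints checked (the MLE
  frequently clamps at `blmin`), sweeps until the gain is below `tol`.
* All-identical windows: every topology ties; the lexicographically
  first canonical ID is returned.
* Distances for the NJ start: JC-inverted $p$-distances with pairwise
  deletion, capped at `blmax`; taxon pairs with no shared sites get a
  neutral moderate distance (1.0) rather than infinity.
* Non-divisor window sizes in a grid analysis trigger a warning, since
  their dropped remainder breaks the identical-alignment requirement.
* `?` and `.` normalize to `-`; `U` to `T`; any other IUPAC code to `N`.
* Coordinates are 0-based half-open internally; printed window indices
  are 1-based.

## Known limitations

A single size is selected per chromosome even though recombination rate
varies along it; per-region window sizes are out of scope.  The engine
is JC-only by design (matching the validation conditions); richer models
would change $k$ and the likelihoods but not the machinery.  The NNI
search is a local hill-climb and can in principle return a local
optimum, which the `blmin` floor and strong-signal regime make rare (the
tests cross-check exhaustive vs NNI agreement).  UFBoot-style
approximate bootstrapping is not implemented; the classical bootstrap is
slower per replicate, which is why support is off by default during
stepwise descents.
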