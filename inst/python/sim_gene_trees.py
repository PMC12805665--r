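#!/usr/bin/env python
"""Gene-tree simulation backend.

Reads a JSON model description (populations, split events, admixture
pulses, recombination, seed) expressed in coalescent units (one time unit
= 4Ne generations, so pairwise coalescence within a population has mean
0.5), runs a coalescent-with-recombination simulation with msprime, and
writes one row per locus:

    start <TAB> end <TAB> topology_id <TAB> newick

Locus boundaries are ALL recombination events in the history of the
sample (ms's segment semantics: a tree per segment within which no
recombination has occurred), which is why recombinant nodes are recorded;
adjacent loci can therefore carry identical genealogies, and the caller
may merge them for topology-only views.

Intervals are 0-based half-open in sites.  Newick branch lengths are in
substitutions/site (coalescent time times the model's mutation_scale).
The topology_id is the canonical unrooted leaf-labelled topology: the
tree is rooted at the lexicographically smallest taxon and children are
sorted recursively; branch lengths are ignored.

Usage: python sim_gene_trees.py <config.json> <out.tsv>
"""

import json
import sys

import msprime

# Internally the model is rescaled to generations with G generations per
# coalescent unit, purely for numerical conditioning; with ploidy=1 and
# initial_size=G/2 the pairwise coalescence time has mean G/2 generations
# = 0.5 coalescent units, the ms convention.
G = 20000.0


def build_demography(cfg):
    dem = msprime.Demography()
    for name in cfg["populations"]:
        dem.add_population(name=name, initial_size=G / 2)
    for ev in cfg["splits"]:
        dem.add_population_split(time=ev["time"] * G, derived=ev["derived"],
                                 ancestral=ev["ancestral"])
    for ev in cfg["pulses"]:
        # forward-time donor -> recipient == backward-time lineage movement
        # recipient -> donor with probability gamma
        dem.add_mass_migration(time=ev["time"] * G, source=ev["recipient"],
                               dest=ev["donor"], proportion=ev["gamma"])
    dem.sort_events()
    return dem


def effective_root(tree):
    r = tree.root
    while tree.num_children(r) == 1:
        r = tree.children(r)[0]
    return r


def effective_children(tree, u):
    out = []
    for c in tree.children(u):
        while tree.num_children(c) == 1:  # skip unary (recombinant) nodes
            c = tree.children(c)[0]
        out.append(c)
    return out


def canonical_id(tree, names):
    # unrooted: re-root at the lexicographically smallest leaf
    root = effective_root(tree)
    adj = {root: []}
    stack = [root]
    while stack:
        u = stack.pop()
        for c in effective_children(tree, u):
            adj.setdefault(u, []).append(c)
            adj.setdefault(c, []).append(u)
            stack.append(c)
    leaves = [u for u in adj if not tree.children(u)]
    start = min(leaves, key=lambda u: names[u])

    def canon2(u, frm):
        nbs = [v for v in adj[u] if v != frm]
        if not nbs:
            return names[u]
        parts = sorted(canon2(v, u) for v in nbs)
        if len(parts) == 1:  # suppress degree-2 nodes (e.g. the root)
            return parts[0]
        return "(" + ",".join(parts) + ")"

    return "(" + names[start] + "," + canon2(adj[start][0], start) + ");"


def newick(tree, names, scale):
    def sub(u):
        ch = effective_children(tree, u)
        if not ch:
            return names[u]
        parts = []
        for c in ch:
            bl = (tree.time(u) - tree.time(c)) * scale
            parts.append("%s:%.10g" % (sub(c), bl))
        return "(" + ",".join(parts) + ")"

    return sub(effective_root(tree)) + ";"


def main():
    cfg_path, out_path = sys.argv[1], sys.argv[2]
    with open(cfg_path) as fh:
        cfg = json.load(fh)
    dem = build_demography(cfg)
    samples = [msprime.SampleSet(1, population=t, ploidy=1)
               for t in cfg["taxa"]]
    length = int(cfg["length"])
    ts = msprime.sim_ancestry(
        samples=samples, demography=dem, ploidy=1,
        sequence_length=length,
        recombination_rate=cfg["rho"] / (G * length),
        discrete_genome=True,
        additional_nodes=msprime.NodeType.RECOMBINANT,
        coalescing_segments_only=False,
        random_seed=int(cfg["seed"]))
    names = {}
    for i, t in enumerate(cfg["taxa"]):
        names[i] = t
    scale = float(cfg["mutation_scale"]) / G
    # ms-style locus boundaries: every recombination event in the sample's
    # history (the recorded recombinant nodes).  Tree strings are computed
    # on the simplified (unary-free) tree sequence, once per distinct
    # genealogy -- adjacent loci may repeat a genealogy.
    bps = [int(x) for x in ts.breakpoints()]
    tss = ts.simplify()
    titer = tss.trees()
    cur = next(titer)
    cache_index = -1
    cache = ("", "")
    with open(out_path, "w") as out:
        out.write("# seed=%d rho=%g length=%d mutation_scale=%g\n"
                  % (cfg["seed"], cfg["rho"], length,
                     cfg["mutation_scale"]))
        out.write("start\tend\ttopology\tnewick\n")
        for i in range(len(bps) - 1):
            left, right = bps[i], bps[i + 1]
            while cur.interval.right <= left:
                cur = next(titer)
            if cur.index != cache_index:
                cache = (canonical_id(cur, names), newick(cur, names, scale))
                cache_index = cur.index
            out.write("%d\t%d\t%s\t%s\n" % (left, right, cache[0], cache[1]))


if __name__ == "__main__":
    main()
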