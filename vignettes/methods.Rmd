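---
title: "Methods: marker-set enrichment and key driver analysis across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-set enrichment and key driver analysis across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
what each stage computes, which assumptions it makes, which knobs matter,
what the synthetic-data generator does and does not emulate, and where the
design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## 1. From gene sets to GWAS marker space

The object under test is a *gene set* (a canonical pathway or a
co-expression module). GWAS association signal lives in *marker* space,
so each set is bridged through tissue-specific eQTLs: the set's eSNPs are
the union of its member genes' eQTL markers. Three filters define that
bridge:

* **eQTL significance** — only records with FDR < 5% in the requested
  tissue are used (`filter_eqtls()`, strict `<`, cis and trans pooled by
  default with a `cis_only` flag).
* **LD pruning** — markers within one LD block are statistically
  redundant; `prune_ld()` keeps exactly one representative per block.
  The retained marker is the one with the smallest GWAS p-value
  (deterministic tie-break by marker id); a `"first"` rule is available
  for p-value-agnostic pruning. Pruning is idempotent.
* **Background consistency** — pruning is performed *once* on the global
  eQTL-marker universe per species/tissue, and every per-set eSNP set is
  intersected with that pruned universe. Pruning independently per set
  would make observed/expected counts incomparable across sets; a single
  shared background guarantees that every eSNP set is a subset of the
  ranking the statistic is computed on.

Markers present in the eQTL table but absent from the GWAS file are
dropped (with a logged count): the statistic needs a p-value per marker.

## 2. The quantile-cutoff modified chi-square statistic

For a pruned background of `N` markers ranked by ascending GWAS p-value
(ties broken by marker id), and a grid of top-signal fractions
`f_1 > ... > f_n`, the enrichment statistic of an eSNP set of size `m` is

    chi = sum_i (O_i - E_i) / sqrt(E_i + kappa)

with `O_i` the number of set markers at or above rank `ceiling(f_i * N)`
and `E_i = m * f_i`. Summing over a *range* of cutoffs rather than fixing
one avoids the artefacts of any single p-value threshold; `kappa = 1`
stabilizes small sets whose expected counts approach zero.

Numerical choices worth stating:

* **Grid** — 10 points from the top 50% down to the top 0.1%
  (`make_grid(10, 0.5, 0.001)`), log-spaced. The endpoints and count are
  fixed by convention; the spacing between them is not, and log spacing
  resolves the signal-rich tail where linear spacing would spend most
  points on near-null cutoffs. Linear spacing is available.
* **Expected counts** — `E_i` uses the continuous expectation `m * f_i`,
  not the ceiled background rank. The difference is O(1) per cutoff and
  absorbed by `kappa`; on small backgrounds it leaves the null mean of
  `chi` slightly above zero, which the permutation standardization (next
  section) removes exactly.
* **Ties** — all rankings use stable `(p, marker id)` ordering, so
  results are permutation-invariant in the input row order.

## 3. Permutation null and error control

The null model asks: how does `chi` behave for a *random gene set of the
same size* mapped through the same eQTL/LD machinery? `null_distribution()`
draws `n_perm` (default 1000) uniform gene sets from the mappable
universe — genes with at least one eQTL marker surviving in the pruned
background; including structurally unmappable genes would deflate the
null — and recomputes `chi` for each. Sets of equal size share a null
(the draw is identical in distribution), cached with a size-derived seed
so results are independent of evaluation order.

The observed statistic is standardized, `z = (chi - mean)/sd`, and the
one-sided upper Gaussian tail gives `p`. The Gaussian approximation is
the default because resolving FDR < 5% across hundreds of sets from
empirical tails would need >= 1e5 permutations; an `"empirical"` mode
(add-one tail count) is available. Benjamini–Hochberg FDR is applied
across all tested sets; sets whose eSNP sets are empty are skipped and
reported, not errored. All significance thresholds in the package are
strict (`<`), matching the FDR < 5% convention.

## 4. Supersets

Significant sets are often redundant. Two sets are connected when their
overlap ratio (shared genes over the *smaller* set — the denominator is
configurable to union-based) exceeds 33% *and* the one-tailed
hypergeometric (Fisher's exact) p, Bonferroni-corrected over the number
of pairs tested in the round, is < 5%. Supersets are the connected
components of this graph — a single-round, order-independent procedure;
iterative agglomeration would depend on merge order, which nothing
specifies. Superset gene content is the union of members; ids are
assigned by decreasing component size with lexicographic tie-break, so
permuting the input yields identical output.

Each superset is then re-tested with the full MSEA machinery
(`confirm_supersets()`); supersets failing FDR < 5% are retained but
flagged and excluded downstream. Annotation (`annotate_set()`) is plain
hypergeometric overlap against a pathway collection: Bonferroni-corrected
p < 5% and >= 5 shared genes, top 5 by p; if nothing qualifies, a
fallback at raw p < 5e-3 (still >= 5 shared genes) is reported with a
`*` suffix. The FET universe is the number of genes with >= 1 eQTL in
context — the population sets are effectively drawn from.

## 5. Cross-species comparison

Supersets are translated through a strict 1:1 ortholog table (non-1:1
pairs are dropped at load). Unmappable genes are excluded from both the
numerator and denominator of every overlap, so sets are not penalized
for ortholog-table incompleteness. A pair matches when the adjusted
hypergeometric p is < 5% and either

* Jaccard index > 50% (`two_sided`), or
* one-sided overlap > 90% (`one_sided` — a subset relationship; the
  two-sided rule takes precedence in reporting).

Adjustment is Bonferroni over all cross-species pairs tested, mirroring
the merging step (BH available). The hypergeometric universe is the
ortholog-mappable gene count — nothing larger is observable by both
species. A superset may match several counterparts, so shared counts per
species can legitimately differ; classification is per species: shared
if >= 1 match, specific otherwise.

## 6. Key driver analysis

Candidates are network nodes with >= 5 neighbors (tiny neighborhoods
give unstable scores; the threshold is configurable and skipped
candidates are reported). For superset `S` mapped onto the network
(`S_net`), a candidate's score reuses the MSEA form collapsed to a
single membership bin — quantile cutoffs are defined on p-value
rankings, which do not exist for binary membership:

    score = (O_w - E_w) / sqrt(E_w + kappa)

with `O_w` the summed edge weight from the candidate to neighbors in
`S_net` and `E_w = W_total * |S_net| / |nodes|` its expectation under a
random node set. Edge handling: self-loops dropped, parallel edges
collapsed by maximum weight, missing weights default to 1 (no hub
penalty or reweighting — `kappa` already tempers small neighborhoods).
Neighborhoods are *undirected* at depth 1 by default: regulatory-network
edge orientations are uncertain under Markov equivalence, so the
inclusive default is robust; `out`/`in` modes and depth 2 (unit weights
on membership, as path weights have no natural product here) are flags.
Networks are typically DAGs, but nothing in the module assumes
acyclicity.

Significance again comes from permutation: `n_perm` random node sets of
size `|S_net|`, scores recomputed, Gaussian standardization — with one
deliberate deviation: the upper-tail p uses a 0.5 *continuity
correction* (`P(Z > (O - 0.5 - mean)/sd)`). In unit-weight networks
`O_w` is a small integer; the uncorrected Gaussian tail maps discrete
atoms above the 5% tail to p < 0.05 and measurably over-rejects on null
networks, while the corrected tail is conservative (never
anti-conservative) — the honest side to err on for a discovery screen.
BH FDR runs across all (candidate, superset) pairs; drivers are ranked
within superset by FDR with the standardized `z` as tie-break (`z`, not
the raw score, is invariant under uniform edge-weight rescaling, which
keeps rankings stable across weight conventions).

Top-driver subnetworks are the drivers plus their depth-1 neighborhoods
with induced edges; GWAS-hit flags overlay two hit lists with recent
hits taking precedence; driver–trait correlations are Pearson by default
(Spearman via flag) with zero-variance genes reported as missing.

## 7. The synthetic world

The generator produces every pipeline input with planted, recoverable
truth. What it emulates, and deliberately does not:

* **Genome** — LD blocks are contiguous index partitions and cis/trans
  is a label: downstream stages only ever use block membership and
  gene–marker links, never base-pair positions. No LD decay, allele
  frequencies, genotypes, or population structure.
* **eQTLs** — each gene gets `cis_per_gene` *dedicated* cis markers
  (sampled without replacement while the marker pool allows; real cis
  windows rarely share their strongest eSNP between genes), plus
  `floor(trans_fraction * n_genes)` random trans links. Generated FDRs
  sit below 5% so default filtering keeps them.
* **GWAS** — null markers are Uniform(0, 1); markers reachable from a
  planted set carry `p ~ Beta(a, 1)` with `a` in (0, 1] (mean
  `a/(a+1)`; `a = 1` is exactly null; markers hit by several sets take
  the smallest `a`). Beta(a, 1) is a standard stand-in for an enriched
  p-value distribution — the shape of real causal-locus signal is not
  characterized, so `a` is exposed as the effect knob rather than
  claimed to match any particular GWAS.
* **Gene sets** — random background sets are drawn from genes *outside*
  every planted set. This is what makes them null: in a small universe,
  sets drawn from the full gene pool contain a material fraction of
  causal genes and are then genuinely (not spuriously) enriched, which
  would make "no null set significant" an incoherent expectation.
  Engineered overlap pairs (forced shared fraction) exercise the merge
  stage; planted sets are included verbatim.
* **Networks** — DAGs grown by preferential attachment along a
  topological order (every edge points forward, so acyclicity is
  structural). Planted drivers receive a wired out-neighborhood
  (default 20 edges, >= 60% into their set's members) and are excluded
  as attachment parents so the composition stays as requested.
* **Species pairs** — a shared index core under human-style upper-case
  vs mouse-style title-case symbol conventions, with a generated 1:1
  ortholog table; shared planted sets are ortholog-identical, specific
  ones are drawn independently.
* **Expression/trait** — the trait is a latent factor `z`; driver genes
  are `r * z + sqrt(1 - r^2) * noise`, so their population correlation
  with the trait is exactly `r`; other genes are independent noise. Not
  suitable for co-expression module discovery (no module structure is
  simulated), which is out of scope.

Every generated artifact is a pure function of its config (one master
seed, re-keyed per stage by name), so bundles are hash-stable and the
pipeline manifest reproduces runs bit-identically.

A green test on this world therefore establishes: the statistics are
computed exactly (oracle equivalence), calibrated on null inputs, and
powerful against planted Beta-enriched signal and wired hubs. It does
*not* establish performance on real LD structure, correlated eQTLs,
polygenic backgrounds, or annotation-quality gene sets.

## 8. Defaults that matter

| Parameter | Default | Why |
|---|---|---|
| eQTL FDR | 0.05 (strict) | significance convention for eQTL inclusion |
| grid | 10 pts, 0.5 -> 0.001, log | endpoints/count fixed; log resolves the tail |
| kappa | 1 | variance stabilizer for small sets |
| n_perm | 1000 | resolves z-based p well; FDR ranking stable vs 500/2000 |
| merge ratio / alpha | 0.33 / 0.05 Bonferroni | the superset qualifying rule |
| match thresholds | JI 0.5, one-sided 0.9, adj p 0.05 | the shared/specific rules |
| KDA min neighbors | 5 | below this, scores are dominated by kappa |
| KDA mode / depth | undirected / 1 | orientation-robust; "neighbors" read literally |

## 9. Known limitations

* The Gaussian null is an approximation; for very small backgrounds or
  eSNP sets the `chi` null is skewed and extreme-tail p-values are
  approximate (the empirical mode bounds p at `1/(n_perm + 1)`).
* Bonferroni scopes (merge pairs, cross-species pairs, annotation
  collection size) are the conservative readings; BH alternatives exist
  where configured but change which supersets merge/match.
* KDA p-values are conservative by construction on sparse unit-weight
  networks (discreteness); power against planted hubs is unaffected in
  practice but near-threshold drivers may need larger `n_perm`.
* The ortholog step is strictly 1:1; paralog expansion and many-to-many
  orthology are out of scope.
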