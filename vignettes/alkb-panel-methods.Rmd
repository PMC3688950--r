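---
title: "Primer-panel coverage and clone-library diversity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Primer-panel coverage and clone-library diversity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alkbpanel)
```

## The problem

No single PCR primer pair amplifies the alkane monooxygenase gene *alkB*
across the full phylogenetic breadth of alkane-degrading bacteria: the gene
is too divergent at the nucleotide level, and every published primer pair
has a restricted target range. A practical workaround is to screen a set of
candidate primer pairs against a reference collection of strains, record
which pairs amplify which strains, and then pick the *combination* of
primers whose union detects as many strains as possible. The chosen panel
is then used to build one amplicon clone library per primer, and the
libraries are clustered into OTUs and compared to quantify how much extra
richness the combination strategy recovers.

`alkbpanel` implements both halves of that workflow: the panel-selection
analytics on a strain-by-primer detection matrix, and the clone-library
pipeline (OTU clustering, richness/diversity estimation, multi-library
comparison). The packaged fixtures — eight published *alkB* primer pairs
and the PCR outcomes of 43 heptadecane-degrading strains screened with
them — make the panel half fully reproducible at desk scale.

## Panel coverage and combination selection

A detection matrix `D` is boolean, strains by primers; a strain is covered
by a panel `P` when `D[s, p]` is true for at least one `p` in `P`. Coverage
percentages always use the full strain count in the denominator, including
strains that no primer detects (7 of the 43 packaged strains): the question
the statistic answers is "what fraction of known alkane degraders would
this panel see", not "what fraction of detectable ones".

Maximum-coverage panel selection is a set-cover-type problem. At the scale
panels are actually designed (here, 8 primers; 28 pairs, 56 triplets),
exhaustive enumeration is trivial, so `best_panel()` defaults to the exact
exhaustive search and reports *all* tied optima, with the lexicographically
first subset as the canonical winner. A greedy maximal-marginal-gain
variant is provided for comparison and for hypothetically large panels
(requests beyond `choose(n, k) > 1e6` subsets fall back to greedy with a
warning). Greedy ties are broken lexicographically at every step, which
makes the trace deterministic. On the packaged matrix, greedy at `k = 3`
reaches 32 of 43 strains while the exhaustive optimum `{d, e, f}` reaches
34 — a compact illustration of greedy suboptimality. Comparisons are made
on exact covered counts; percentages are rounded to one decimal for display
only.

One tension in the packaged data is worth stating: the matrix implies that
adding primer (c) to the optimal triplet `{d, e, f}` covers two additional
strains (`marginal_gain()` reports them). The package reports what the
matrix implies rather than asserting saturation at three primers.

## Primer-site matching

In-silico screening of degenerate primers uses per-position IUPAC matching
with two deliberate policies: inosine (I) matches all four template bases
(it is a universal-pairing analog), and a template `N` matches any primer
symbol — for screening, under-calling a binding site is the worse error.
Degeneracy is honored on the primer side only; template symbols other than
A/C/G/T/N are rejected, since templates are resolved sequences. Windows on
both strands are scored (the reverse strand as the reverse-complemented
primer against the plus strand), with two tunables: `max_mismatch`
(default 3) and `anchor_3prime` (default 3), the number of 3'-terminal
primer positions that must match exactly, because 3' fidelity dominates
polymerase extension. No thermodynamic model is attempted, and no mismatch
tolerance can claim to reproduce wet-lab PCR outcomes; the packaged
detection matrix is therefore treated as data, never as a prediction
target. Coordinates are 0-based half-open internally and 1-based inclusive
in reference-fragment reporting.

## OTU clustering

Distances between aligned clones use pairwise deletion: only columns with
an unambiguous base (A/C/G/T) in both sequences are compared, and the
distance is mismatches over compared columns. Gap runs are simply ignored
columns — no gap-compression dialect — which is the simplest defensible
rule and is stated as a potential deviation from other tools' distance
dialects. A pair with no comparable columns gets distance 1 plus a warning
rather than an error, so one degenerate pair cannot abort a library.

Clustering is agglomerative; merging continues while the minimal
inter-cluster linkage distance is at or below the cutoff, so "97%
similarity" OTUs use `cutoff = 0.03`. Average linkage is the default (the
average-neighbor convention of the clone-library era), with complete and
single selectable. The implementation stands on `stats::hclust`/`cutree`;
the test suite checks the resulting partitions against an independent
naive O(n^3) agglomerative oracle on random matrices, and checks the
standard coarse-to-fine ordering single ≤ average ≤ complete in cluster
counts. OTU representatives are the lexicographically first member id:
every clone is a single read, so there is no abundance signal within an
OTU to prefer one member over another, and lexicographic order is
deterministic.

## Richness and diversity estimators

All estimators take one library's OTU abundance vector (positive integer
counts; `f_j` denotes the number of OTUs with count exactly `j`, `N` the
clone total, `S_obs` the observed OTU count).

* **Chao1** — default is the bias-corrected form
  `S_obs + f1(f1-1)/(2(f2+1))`; the classic `S_obs + f1^2/(2 f2)` is
  selectable and falls back to bias-corrected when `f2 = 0`. The 95%
  interval is the log-normal interval of Chao (1987): with
  `T = S_hat - S_obs`, `K = exp(1.96 sqrt(log(1 + var/T^2)))`, bounds are
  `S_obs + T/K` and `S_obs + T*K`, degenerating to `[S_obs, S_obs]` when
  `T = 0`. The variance uses the standard form matched to the variant.
* **ACE** — rare/abundant cutoff 10 by default (configurable); when the
  rare group is entirely singletons the coverage term vanishes and the
  function falls back to Chao1 with a warning.
* **Shannon** — natural log by default; base selectable.
* **Good's coverage** — `1 - f1/N`, the probability that the next clone
  belongs to an already-seen OTU.
* **Rarefaction** — the hypergeometric closed form
  `E[S(n)] = S_obs - sum_i C(N - n_i, n)/C(N, n)` via `lchoose`, so no
  factorial overflow at any depth.
* **Boneh-style prediction** — the number of *new* OTUs expected in `m`
  further clones (default `m = N`, a doubling). The published estimator
  family admits several algebraic variants; this package's reading is an
  empirical unseen-pool model: size the unseen pool by the bias-corrected
  Chao term `S0 = f1(f1-1)/(2(f2+1))`, split the Good–Turing missing mass
  `f1/N` equally across it (per-clone rate `mu0 = f1/(N S0)`), and predict
  `B(m) = S0 (1 - (1 - mu0)^m)`. This construction is exactly simulable,
  and the tests hold it to its defining properties — zero at `m = 0`,
  non-decreasing and saturating at `S0`, zero without a singleton tail,
  and agreement with Monte-Carlo resampling of the fitted model within
  Monte-Carlo error.

Estimator values are cross-checked in the test suite against independent
closed-form hand evaluations and, where the quantity exists there, against
vegan (`estimateR`, `diversity`, `rarefy`).

## Library comparison

**Venn partitions** over 2–3 libraries default to observed incidence
counts, which reconstruct per-library richness exactly by
inclusion–exclusion (a tested invariant). A `chao_shared` mode is provided
for Chao-style Venn numbers: per-library totals become Chao1 points, and
pairwise shared richness uses a joint-rarity Chao analogue
`D12 + f11(f11-1)/(2(f22+1))` (`f11`/`f22` = OTUs that are singletons/
doubletons in *both* libraries), reconciled by inclusion–exclusion with
flooring at the observed region counts; the triple overlap stays observed.
The exact shared-richness formula used by legacy Venn calculators is not
recoverable, so the observed mode is the default and the tested surface.

**Richness gain** — how much the non-richest libraries add on top of the
richest (`hR` = observed richness of the richest library, ties broken
lexicographically and reported). Because "the sum of richness observed in
the other libraries but not in the richest" is ambiguous when the other
libraries share novel OTUs, both conventions are returned: the union
convention `100 |union(others) \ richest| / hR` (headline value, no double
counting) and the literal per-library sum.

**Jaccard/UPGMA** — incidence Jaccard dissimilarity
`1 - |shared|/|union|`, clustered by UPGMA with merge heights equal to the
average inter-cluster distance; cophenetic distances of the result equal
UPGMA linkage distances (tested against a naive oracle, and exact recovery
on ultrametric input).

**Neighbor joining** — Saitou–Nei via `ape::nj`, followed by a documented
cleanup: negative branch lengths (possible on non-additive input) are
clamped to zero with the deficit transferred to the first sister edge,
preserving path lengths where possible. Additive matrices are recovered
exactly (tested).

**Unweighted UniFrac** — for a community pair, the fraction of branch
length leading to leaves of exactly one community among branch length
leading to either. Significance is a permutation test that shuffles labels
among the leaves of the two communities being compared
(pairwise-restricted shuffling; whether historical analyses shuffled
across the whole tree instead is not recoverable, and the restricted
scheme is the exact conditional null for a pairwise comparison). The
default 100 permutations match clone-library practice; p-values use the
add-one convention `(b + 1)/(perms + 1)` so they are never zero, and the
Bonferroni column multiplies by the number of pairs tested in the call.
The distance implementation is vectorized over an edge-by-tip incidence
matrix and is checked against a recursive edge-walking oracle and against
picante; super-uniformity of the null p-value distribution is checked by
calibration over repeated interleaved-regime simulations.

## The synthetic-data generators

Real clone-library inputs for this analysis are archival Sanger sequences;
the package instead ships generators whose outputs carry the statistical
structure the pipeline assumes, so every stage is testable end to end.
All generators are pure functions of a `synthetic_spec` (seed mandatory;
the caller's RNG stream is left untouched).

* `gen_detection_matrix()` plants an optimal panel: covered strains
  (default 80% of 43, mirroring the packaged screen's scale) are
  partitioned into one block per planted primer, and off-panel primers
  detect random subsets capped below the smallest block, so the planted
  panel is the unique maximum-coverage subset — a ground truth for
  selection tests.
* `gen_clone_libraries()` mutates a random root sequence at
  `ceil(divergence * L)` random positions per phylotype; the minimum
  pairwise divergence is verified (and the draw repeated) so planted
  phylotypes are separated by at least the spec divergence — kept above
  twice the OTU cutoff in recovery tests. Default: 15 phylotypes, 400 nt,
  8% divergence, 3 libraries of 60 clones, a log-series abundance law
  (`x = 0.95`; the classic singleton-heavy clone-library shape, matching
  the coverage range such libraries typically report), and per-library
  phylotype inclusion weights (default: each library sees a random 60%
  subset) that emulate primer-specific amplification bias and the low
  sharing observed between primer libraries. Clones are exact template
  copies and the alignment is gap-free: no indels, no within-OTU
  micro-heterogeneity, no rate variation, no chimeras or read errors.
  Passing planted-recovery tests therefore demonstrates correctness of
  the clustering arithmetic, not robustness to real amplicon noise.
* `gen_labeled_tree()` draws a coalescent topology with independent
  exponential branch lengths; the clustered regime labels the two root
  clades as the two communities (maximal separation), the interleaved
  regime labels leaves independently of topology (the UniFrac null).

## Problem sizes and runtime choices

The test suite runs at desk scale by design: random templates of a few
hundred nt for primer-site oracles, 10–15 sequence distance matrices for
clustering oracles, libraries of 25–100 clones, 12–20 leaf trees, 50–100
permutations, and Monte-Carlo oracles of 5,000–20,000 replicates with
3-standard-error acceptance bands. These sizes keep each oracle comparison
sharp (the quantities compared are exact or within quantified Monte-Carlo
error) while the whole suite completes in well under a minute.

## Known limitations

* The detection matrix is data; no in-silico mismatch rule is claimed to
  predict wet-lab amplification outcomes.
* Distance and clustering dialects (gap handling, linkage) can differ from
  other OTU tools in ways that move individual assignments near the
  cutoff; the defaults are stated above and selectable where reasonable.
* The Boneh-style predictor is one documented reading of an
  under-specified estimator family and is validated by its properties, not
  against a reference implementation.
* `chao_shared` Venn mode is a documented approximation; quantitative
  conclusions about shared richness should prefer the observed mode plus
  explicit shared-species estimators.
* Weighted UniFrac, bootstrap support values, and taxonomic assignment of
  OTU representatives are out of scope.
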