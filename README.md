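# alkbpanel

Degenerate PCR primer panels and the clone libraries they produce, in one
package: coverage analytics and maximum-coverage combination selection on
strain-by-primer detection matrices, IUPAC/inosine-aware in-silico primer
matching, OTU clustering of aligned amplicons, richness/diversity
estimation, and multi-library comparison.

## The scientific problem

The alkane monooxygenase gene *alkB* is the standard biomarker for
aerobic alkane-degrading bacteria, but its nucleotide sequence is so
variable that no single primer pair amplifies it across the phylogenetic
range of known degraders — studies relying on one primer pair
systematically under-report diversity. The pragmatic remedy is a *panel*:
screen candidate primer pairs against a strain collection, record the
boolean detection matrix `D` (strains × primers), and choose the subset of
primers whose union covers the most strains,

```
cover(P) = |{ s : D[s, p] for some p in P }|,   P* = argmax_{|P| = k} cover(P).
```

Each chosen primer then yields its own amplicon clone library; clustering
the pooled clones into OTUs at 97% similarity and comparing libraries
(Chao1/ACE richness, Shannon diversity, Good's coverage, Boneh-style
prediction of unseen OTUs, rarefaction, Venn partitions, a richness-gain
statistic, Jaccard/UPGMA dendrograms, NJ trees, unweighted UniFrac with
permutation tests) quantifies how much extra diversity the combination
recovers.

The package ships the eight published *alkB*-targeting primer pairs and
the detection matrix of 43 heptadecane-degrading strains screened with
them as worked fixtures (`alkb_primers()`, `alkb_detection_matrix()`), and
a seeded synthetic-data generator for everything the fixtures cannot
cover. It is written for microbial ecologists designing or auditing
multi-primer biomarker surveys.

## Worked example

```r
library(alkbpanel)

dm <- alkb_detection_matrix()
dm
#> Detection matrix: 43 strains x 8 primers (a, b, c, d, e, f, g, h)
#> Positives per primer: a=8 b=8 c=9 d=10 e=21 f=19 g=8 h=19
#> Strains never detected: 7

primer_coverage(dm, "e")
#> Panel {e}: 21/43 strains covered (48.8%)

best_panel(dm, 3)                      # exhaustive over all 56 triplets
#> Panel {d,e,f}: 34/43 strains covered (79.1%)

best_panel(dm, 3, method = "greedy")   # greedy is suboptimal here
#> Panel {b,e,h}: 32/43 strains covered (74.4%)
#> Greedy selection trace:
#>  step primer gain cumulative
#>     1      e   21         21
#>     2      h    8         29
#>     3      b    3         32

marginal_gain(dm, c("d", "e", "f"), "c")
#> $gain
#> [1] 2
#> $added_ids
#> [1] "PBL 3.1"   "Cr_O 49.2"
```

The best single primer (e) sees less than half the strains; the exhaustive
best triplet {d, e, f} reaches 79% coverage — 30.2 percentage points more
than any single primer — while seven strains (genera *Cupriavidus*,
*Bacillus*, *Gordonia*, *Bosea*, *Rhizobium*) are invisible to every
primer tested. The marginal-gain call shows that a fourth primer (c)
would still add two strains.

Clone-library analysis, here on synthetic libraries with planted
phylotypes:

```r
spec <- synthetic_spec(seed = 11)
gl   <- gen_clone_libraries(spec)
tab  <- build_otu_table(cluster_otus(pairwise_distances(gl$alignment), 0.03),
                        gl$libraries)
tab
#> OTU table: 12 OTUs x 3 libraries, 180 sequences total

head(diversity_table(tab), 6)
#>   library      estimator     value    lower    upper
#> 1       d           sobs 8.0000000       NA       NA
#> 2       d          chao1 8.5000000 8.030262 16.26117
#> 3       d            ace 9.3936900       NA       NA
#> 4       d        shannon 1.5062998       NA       NA
#> 5       d goods_coverage 0.9666667       NA       NA
#> 6       d          boneh 0.4920352       NA       NA

richness_gain(tab)
#> Richest library: d (hR = 8 OTUs)
#> Richness gain: 50.0% (union of 4 novel phylotypes); 62.5% (literal sum, 5)
```

Library d observed 8 OTUs with Chao1 extrapolating to 8.5 (95% CI
8.0–16.3); Good's coverage of 0.97 says a further clone would almost
surely land in a seen OTU, and the Boneh value predicts ~0.5 new OTUs if
the library were doubled. The gain statistic says the other two libraries
add 50% more phylotypes than the richest library alone. `venn_partition()`,
`jaccard_dissimilarity()` + `upgma()`, `nj_tree()` and
`unifrac_unweighted()` complete the comparison; `run_pipeline()` chains
the whole analysis and writes TSV/JSON reports with a provenance block,
and `inst/cli/alkbpanel` exposes the same stages as shell subcommands.

## Documentation

The methods vignette (`vignettes/alkb-panel-methods.Rmd`) documents the
models and estimator formulas, every tunable default and why it was
chosen, what the synthetic generators do and do not emulate, and the
package's handling of degenerate cases.
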