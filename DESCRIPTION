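Package: alkbpanel
Title: Degenerate Primer Panel Coverage and Clone-Library Diversity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening degenerate (IUPAC/inosine) PCR primer panels
    against target sequences and for analysing the amplicon clone libraries
    such panels produce. Provides in-silico primer-site matching and amplicon
    prediction, coverage analytics and exhaustive/greedy maximum-coverage
    panel selection on strain-by-primer detection matrices, OTU clustering of
    aligned clone sequences at a similarity cutoff, alpha-diversity and
    richness estimation (Chao1 with log-normal confidence bounds, ACE,
    Shannon, Good's coverage, Boneh's prediction of unseen OTUs,
    rarefaction), and multi-library comparison (Venn partitions of shared
    richness, richness-gain statistics, Jaccard/UPGMA dendrograms,
    neighbor-joining trees, and unweighted UniFrac with permutation
    significance testing). Ships the alkB alkane-monooxygenase primer panel
    and strain detection matrix as worked fixtures, plus a synthetic-data
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
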