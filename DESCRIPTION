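Package: proteoscale
Title: Scaling of Proteome Size, Disorder and Interactions with Organismal Complexity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of organism and tissue complexity
    (measured as the number of distinct cell types) against proteome-level
    features: proteome information content (total amino acids over the longest
    isoform of each gene), intrinsic structural disorder from per-residue score
    tracks, disordered binding-site segmentation and aggregation, confidence-
    filtered binary protein-protein interaction statistics, alternative-splicing
    summaries, and SCOP superfamily expansion partitions. Includes the
    statistical layer used for such studies (log-log power-law fits, Pearson and
    Spearman correlations with two-tailed p-values, one-way ANOVA with
    Bonferroni pairwise comparisons, Mann-Whitney tests, and a random-subsample
    standard-deviation procedure) and seeded synthetic-data generators with
    known ground truth so every pipeline stage has a recovery test without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
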