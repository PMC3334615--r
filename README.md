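# proteoscale

Comparative analysis of **organismal and tissue complexity versus proteome
features**, for structural bioinformaticians studying why gene counts fail
to track complexity (the G-value paradox) and what does track it instead.

The package measures complexity *C* as the number of distinct cell types
(1 for bacteria, ~200 for human; for a tissue, the cell types composing
it) and relates it to:

* **PIC, the proteome information content** — total amino acids over the
  longest isoform of each gene (`compute_pic(..., "main")`), or over all
  splice variants (`"all"`). The headline model is the power law
  `PIC = a · C^k`, fitted by ordinary least squares in log-log space, with
  `k` ≈ 0.25 the canonical scale — equivalently, complexity grows roughly
  as the fourth power of PIC.
* **Intrinsic disorder** — per-residue scores in [0, 1]; a residue is
  disordered when its score is strictly above 0.5, a protein's disorder is
  the percentage of such residues, and a proteome's disorder is the
  unweighted mean over proteins.
* **Disordered binding sites** — called from binding-propensity tracks by
  the run-and-merge rule: ≥ 3 consecutive residues above 0.5 form a site;
  adjacent sites are independent only when ≥ 3 residues below 0.5 separate
  them (`segment_binding_sites()`).
* **Protein-protein interactions** — STRING-style tables, deduplicated and
  filtered at combined score ≥ 900 (`read_interactions()`,
  `filter_confidence()`, `degree_stats()`), with tissue restriction to
  pairs whose both partners are expressed (`restrict_to_tissue()`).
* **Alternative splicing** — percent of multi-exon genes with splice forms
  and mean splicing events per gene (`percent_multiexon_as()`,
  `mean_as_events_per_gene()`).
* **SCOP expansion partitions** — proteins grouped by whether they carry
  domains of superfamilies whose abundance correlates with complexity
  (R ≥ 0.8 expanding, R ≤ 0.2 non-expanding), compared by disorder
  (`partition_proteins()`, `compare_group_disorder()`).

A statistics layer (`fit_power_law()`, `cor_pearson()`, `cor_spearman()`,
`mann_whitney()`, `one_way_anova_bonferroni()`, `subsample_sd()`) and
seeded synthetic-data generators with known ground truth
(`simulate_species_panel()`, `simulate_tissue_panel()`, ...) complete the
pipeline, so every stage has a closed-loop recovery test without any
external downloads.

## Worked example

Simulate a 20-species (14 eukaryotes including 2 plants, 4 bacteria) and
12-tissue dataset, then run both reports:

```r
library(proteoscale)
dir <- tempfile("demo")
run_simulate(dir, n_species = 16, n_bacteria = 4, n_plants = 2,
             n_tissues = 12, seed = 1)

sp <- run_species_analysis(dir)
sp
#> <species_report> 20 species
#>   PIC ~ complexity (eukaryotes minus plants): <power_fit> y = 2.106e+04 * x^0.2389  (r2 = 0.4582, p = 0.00784, n = 14)
sp$stats$all_species$spearman_disorder
#> <correlation> spearman r = 0.9917, two-tailed p = 1.724e-17, n = 20

ti <- run_tissue_analysis(dir)
ti
#> <tissue_report> 12 tissues
#>   PPIs ~ binding sites: <power_fit> y = 0.0008997 * x^1.929  (r2 = 0.9978, p = 1.19e-14, n = 12)
```

The species fit recovers the generator's configured exponent (0.25) within
single-panel sampling scatter, and the tissue fit recovers the planted
quadratic coupling between binding-site totals and interaction totals.
Per-species metrics land in `reports/species_metrics.tsv`, per-tissue
summaries in `reports/tissue_summary.tsv`, and the statistics in JSON
reports alongside them, with the configuration echoed into each. Real data
replace any synthetic piece by dropping files in the same formats (FASTA
with `gene:<ID>` headers, three-column score-track TSV, STRING-style
interaction TSV, gene-splicing TSV, tissue tables).

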