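# coiaudit

Auditing DNA barcode (COI-5P) reference libraries and analysing bulk-sample
metabarcoding runs against them.

Large barcoding campaigns assemble libraries in which half of the haplotype
clusters have no Linnaean name ("dark taxa"), some named species are split
across several clusters (cryptic-diversity candidates, CDC) and some clusters
are shared by several named species (BIN sharing, BS). `coiaudit` is for
people who curate such libraries or monitor insect communities with them: it
computes the barcode-gap statistics, classifies the discordances, names the
dark clusters with interim "reverse taxonomy" labels, runs a complete
minibarcode metabarcoding pipeline against the library, and summarises
dark-taxa prevalence at the family level.

## The statistics at its core

* **Kimura 2-parameter distance.** For a sequence pair with transition
  proportion *P* and transversion proportion *Q* over the *n* comparable
  sites (pairwise deletion of gaps, Ns and ambiguity codes),

  d = −½·ln(1 − 2P − Q) − ¼·ln(1 − 2Q).

  Records with fewer than 500 unambiguous bases are excluded. Per species the
  audit reports the mean and maximum intraspecific divergence (meanISP,
  maxISP) and the minimum distance to the nearest neighbouring species, all
  on the percent scale.
* **Cluster proxy.** Haplotype clusters come from single-linkage clustering
  at 2.2% K2P (a published seed threshold for barcode index clustering); a
  species in ≥ 2 clusters is a *split* (CDC rank = number of clusters), a
  cluster holding ≥ 2 named species marks them *shared* (BS rank = species in
  the cluster). Split severity bands on maxISP: low ≤ 3%, 3% < mid ≤ 6%,
  high > 6%.
* **Metabarcoding pipeline.** Pair merging (ungapped overlap ≥ 40 bp),
  degenerate-primer trimming (detection ≥ 90% identity, untrimmed reads
  discarded), expected-error filtering (EE = Σ 10^(−Q/10) ≤ 1), exact
  dereplication, two-parent single-crossover de novo chimera removal, greedy
  centroid OTU clustering at 97% global-alignment identity, best-hit taxonomy
  assignment, filtering at ≥ 97% identity and ≥ 0.01% of per-sample reads,
  and OTU→cluster merging into presence/absence overviews.
* **Dark-taxa correlations.** One-sided Pearson tests of the family-level
  dark-taxa percentage against mid-range body size (negative direction) and
  checklist species richness (positive direction).

A seedable synthetic-data module generates reference libraries (controlled
intra/interspecific divergences, deep splits, merged species pairs, dark
taxa) and paired-end metabarcoding runs (log-normal abundances, sequencing
errors, chimeras) with full ground truth, so the whole workflow is testable
offline. Transcriptions of the published campaign tables (116 families; 122
multi-cluster species; the cluster-sharing cases) ship in `inst/extdata/`.

## Worked example

The numbered scripts under `analysis/` run the full study on synthetic data
(about five minutes in total):

```sh
Rscript analysis/01_simulate.R          # library + metabarcoding run -> results/sim/
Rscript analysis/02_library_audit.R     # audit, NJ tree, family summary -> results/audit/
Rscript analysis/03_metabarcoding.R     # pipeline + truth scoring      -> results/meta/
Rscript analysis/04_published_tables.R  # published-table reproductions -> results/published/
```

`02_library_audit.R` prints, for the default 120-species library:

```
audited 120 species (62 named, 58 interim-named dark)
clusters: 125; concordant 54, split 6 (9.68%), shared 2 (3.23%)
true splits recovered: 6/6
```

All six species simulated with a deep (6% K2P) second lineage are recovered
as splits, and the one simulated merged pair surfaces as the two shared
species. `03_metabarcoding.R` scores the pipeline against ground truth:

```
species recall above the 0.02% truth threshold: 1.000 (231/231)
false clusters in the final table: 0
chimeric reads whose sequence was flagged: 0.955 (of 178 surviving)
```

and `04_published_tables.R` reproduces the campaign's printed numbers from
the packaged tables: the 122 multi-cluster species partition into severity
bands 34/48/40; the dark-taxa percentage correlates with body size at
r = −0.415 (one-sided p = 0.00037) and with checklist richness at r = 0.334
(p = 0.0037) among families with dark taxa; 50,963/59,102 recovered
sequences = 86.23%.

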