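---
title: "Auditing a COI barcode library and metabarcoding against it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a COI barcode library and metabarcoding against it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coiaudit)
```

## The problem

A reference library for a hyperdiverse insect group couples each voucher's
COI-5P barcode to its taxonomy and to a haplotype-cluster id. Such libraries
are never clean: many clusters carry no binomial ("dark taxa"), some named
species scatter across several deep clusters (candidate cryptic species),
and some clusters contain several named species (either true barcode
failure or synonymy). `coiaudit` quantifies all of this and then uses the
library the way a biomonitoring project would: as the assignment target for
bulk-sample minibarcode metabarcoding.

This vignette documents the models, the parameter choices, and the design
decisions where the methods left room.

## Distances

K2P distances are computed per pair with *pairwise deletion*: a site is
dropped from a comparison when either base is not a plain A/C/G/T. The
original analyses do not state their deletion convention; pairwise deletion
matches common distance-tool behaviour and wastes the least data. For the
same reason the 500-bp minimum-length filter counts *unambiguous* bases, so
an N-padded record cannot slip through. Saturated pairs (1 − 2P − Q ≤ 0)
have no finite K2P distance; `pairwise_matrix()` records NA with a warning
by default and errors in strict mode. Exact replication of the BOLD
workbench's distances is not promised, since its conventions are
unpublished.

Alignment is deliberately out of scope: `pairwise_matrix()` demands
position-comparable input and errors otherwise. The synthetic generator
emits gapless homologous sequences; real users should pre-align (e.g. with
MUSCLE or MAFFT) — for a protein-coding, indel-poor marker like COI this is
uncontroversial.

## Clusters as a BIN proxy

The production BIN system (RESL) is proprietary and unpublished, so the
package substitutes single-linkage clustering at 2.2% K2P — a published
seed threshold for barcode index clustering — with a strict `<` at the
boundary. Outputs are labelled "cluster"; no claim of BIN-id equality is
made. Single linkage is the most permissive agglomeration, which makes the
split statistics conservative: a species only counts as split when no chain
of sub-threshold pairs connects its lineages.

Discordance classification follows the field's reading: a species in ≥ 2
clusters is a split (CDC rank = cluster count); a cluster with ≥ 2 *named*
species flags each as shared (BS rank = named-species count). Interim-named
and unnamed members never create sharing conflicts — an interim name is
derived from its cluster, so it would "share" by construction. Severity
bands partition split species on maxISP at 3% and 6%. The printed band
descriptions in the source campaign ("<3%", "3 to 6%", "6 to 12%") do not
cover the values its own table contains (up to 17.5%); the implemented
reading — low ≤ 3 < mid ≤ 6 < high — is the unique one that reproduces the
published 34/48/40 partition of all 122 table rows, which is why the
boundary cases sit in the lower band.

Interim names implement the "highest conflict-free taxonomy" rule: the
deepest rank on which all members with an assignment agree, suffixed with
the cluster id ("Megaselia sp. BOLD:ACD9573"-style); a unanimous binomial is
returned unchanged.

## Neighbour joining

`nj_tree()` is a self-contained Saitou–Nei implementation so that tie
behaviour is fully specified (ties in the Q criterion break on the
lexicographically smallest label pair) and negative branch-length estimates
are clamped to zero with a note. It reproduces additive matrices to 1e-9
and agrees with an independent implementation (`ape::nj`) on noisy ones;
both facts are tested. Newick output carries 6-decimal branch lengths.

## The metabarcoding pipeline

Stage defaults are the campaign's stated values: minimum merge overlap
40 bp, primer detection at ≥ 90% identity with IUPAC degeneracies and
discard-untrimmed semantics, expected-error ceiling 1.0, OTU clustering at
97% identity, assignment filter at 97% identity and 0.01% of per-sample
reads. Three points needed a decision:

* The phrase "zero expected errors ('fastq_maxee' 1)" is self-contradictory;
  the implementation follows the quoted tool parameter, EE ≤ 1.0.
* "Total read numbers below 0.01% of the summed reads per sample" is
  ambiguous between a per-sample and a whole-run total. The default zeroes
  counts below 0.01% of *that sample's* pre-filter total (the sentence
  anchors on "per sample"); `frac_scope = "global"` switches to dropping
  OTU rows below 0.01% of the grand total.
* Identity is end-to-end global alignment (match +1, mismatch −1, linear
  gap −2; identity = matches / alignment columns, terminal gaps included).
  Under that definition a 313-bp amplicon can never reach 97% against a
  full-length 658-bp barcode, so `run_metabarcoding()` windows the
  reference library to the amplified region before assignment
  (`ref_region`), exactly as one builds a minibarcode reference database.

Chimera removal is a documented simplification of de novo detectors: a
unique is flagged iff two parents, each at ≥ 2× its abundance, explain it
left/right of a crossover at ≥ 99% per-side identity, while neither parent
alone matches it at ≥ 99% overall (such near-matches are parent variants
and are kept). Bit-compatibility with uchime is a non-goal; the model is
matched to the simulator's chimera process, and only length-preserving
(equal-length) parent candidates are considered.

Merging consensus takes the higher-Phred base (forward mate on ties) and
the maximum Phred as the merged score; no posterior recalibration is
attempted. OTU ids are assigned in decreasing abundance order for stable
diffs, and every stage reports exact read accounting, a tested invariant.

## The synthetic study

The generator is first-class, tested code; its defaults are the study
conditions everything downstream is validated under.

* Library: six family archetypes spanning body sizes 0.5–35 mm with
  dark-taxon fractions 0.9 down to 0.08 (small families are the least
  named), 120 species, 2–5 haplotypes each, 658-bp barcodes. Substitutions
  follow a per-site categorical process with transition probability
  κ/(κ+2), κ = 4, no rate heterogeneity — the simplest process whose K2P
  estimate is consistent with the configured divergence. Expected pairwise
  divergences: 0.005 within species, 0.08 between congeners, 0.18 between
  families (keeping everything far from saturation), 0.06 between the two
  lineages of a split species. 5% of species are split (both lineages
  always sequenced), and 3% of species participate in a merged pair
  (identical founder haplotypes). Splits and merges are drawn among named
  species: a dark split would surface as two interim species and leave no
  testable ground truth.
* Metabarcoding: the default configuration mirrors a season-long campaign
  (90 bulk samples, ~6,000 reads each, 313-bp minibarcode inside the
  barcode at a fixed window, 2 × 250 bp reads, degenerate primers);
  per-sample communities are log-normal (σ = 1.5) over species present with
  probability 0.35, per-base error 0.001, 2% two-parent chimeras with a
  crossover uniform over the middle 60% of the amplicon. Per-sample
  sub-seeds derive from a stable hash of the sample id, so adding a sample
  never perturbs the others; read totals match the configuration exactly.
* Scaled runs: the shipped analysis scripts, the test suite and the
  acceptance script run a 120-species library and 6 samples × 1,500 reads —
  sizes chosen so the whole study reruns in minutes on one core while every
  per-sample truth abundance of interest stays above the 0.01% read filter.

What passing these simulations shows — and what it does not: the synthetic
reads have substitution errors only (no indels or homopolymer artefacts),
primers always sit at the read ends, abundances are log-normal without PCR
bias, and chimeras have exactly two parents and one crossover. Recovery
rates on real Illumina data will be lower and chimera detection weaker;
the simulations validate the *logic* of every stage and the exactness of
the bookkeeping, not platform-specific error tolerance.

## Numerical and degenerate-input conventions

Distances are reported in percent (×100) wherever species statistics are
printed, matching campaign tables; internal values stay full precision, and
printed ratios round to the table precision (integers for coverage ratios,
1–2 decimals for percentages). Species with one sequenced member report no
intraspecific statistics, get status `singleton_data`, a vacuous barcode-gap
flag, and are never silently dropped. Empty FASTA files read as empty
libraries; an empty library errors at audit. Ties everywhere break
lexicographically (cluster ids by smallest member, nearest-neighbour
species by name, greedy clustering by sequence, best hits by record id) so
every output is reproducible byte for byte.

## Dark-taxa correlations

`dark_taxa_correlation()` is one-sided in the direction the biology
predicts: negative against mid-range body size, positive against checklist
richness. Families without barcoded taxa are always excluded; the default
includes families with 0% dark taxa, with the exclusion variant one flag
away. The source campaign computed both variants without saying which
produced its headline coefficients; on the packaged family table the
exclusion variant reproduces them (r = −0.415 and 0.334, n = 63), and the
acceptance script reports that variant. Mid-range size is the arithmetic
midpoint of the printed interval, the only defensible reading of
"mid-range body size". One printed size range ("3–4.5.0") is read as
3.0–4.5.

## Known limitations

* Single-linkage at a fixed threshold is a proxy; cluster ids are not BINs
  and counts can differ from RESL's near the threshold.
* `pairwise_identity()` follows one exact scoring scheme; other tools'
  identity definitions (e.g. excluding terminal gaps) give slightly
  different values near the 97% boundary.
* The chimera filter is tuned to the two-parent single-crossover model;
  multi-parent or short-segment chimeras evade it by design.
* No denoising into exact sequence variants, no abundance-bias correction,
  single marker only.
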