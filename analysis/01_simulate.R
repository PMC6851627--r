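#!/usr/bin/env Rscript
# Build the synthetic study: a COI reference library with known splits,
# merges and dark taxa, and a Malaise-trap metabarcoding run over it.
# Outputs go to results/sim/ (FASTA library, ground-truth tables, per-sample
# FASTQ pairs, sample manifest).

suppressMessages(library(coiaudit))

seed <- 1L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

lib_cfg <- library_sim_config(seed = seed)
sim <- simulate_library(lib_cfg)
write_fasta(sim$records, file.path(out, "library.fasta"))

truth <- sim$truth
utils::write.table(truth$species, file.path(out, "truth_species.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(truth$records, file.path(out, "truth_records.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(truth$checklist, file.path(out, "checklist.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
if (!is.null(truth$merged_pairs)) {
  utils::write.table(truth$merged_pairs, file.path(out, "truth_merged_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
writeLines(truth$split_binomials, file.path(out, "truth_split_species.txt"))

cat(sprintf("library: %d records, %d species (%d dark), %d split, %d merged pairs\n",
            nrow(sim$records), nrow(truth$species),
            length(truth$dark_species), length(truth$split_species),
            if (is.null(truth$merged_pairs)) 0L else nrow(truth$merged_pairs)))

# metabarcoding run: scaled-down campaign (6 bulk samples x 1,500 reads)
meta_cfg <- meta_sim_config(seed = seed, n_samples = 6, reads_per_sample = 1500)
run <- simulate_metabarcoding_run(sim, truth, meta_cfg, out)
utils::write.table(run$truth$read_labels, file.path(out, "truth_read_labels.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(species_id = rownames(run$truth$sample_species_counts),
                              run$truth$sample_species_counts,
                              check.names = FALSE),
                   file.path(out, "truth_sample_counts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("metabarcoding run: %d samples x %d reads, %d chimeric reads\n",
            nrow(run$manifest), meta_cfg$reads_per_sample,
            length(run$truth$chimeric_read_ids)))
cat("wrote", out, "\n")
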