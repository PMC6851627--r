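# Ground-truth evaluation of a pipeline run over a simulated metabarcoding
# experiment: species recovery, false clusters, chimera flagging.

#' Compare a pipeline result against the simulator's ground truth
#'
#' @param res result of [run_metabarcoding()].
#' @param run result of [simulate_metabarcoding_run()] (carries the truth).
#' @param min_truth_frac per-sample truth abundance (fraction of reads) above
#'   which a species is expected to be recovered (default 2e-4, i.e. 0.02%).
#' @return list: \code{species_recall} (fraction of expected species/sample
#'   occurrences present in the final BIN table), \code{n_expected},
#'   \code{n_recovered}, \code{false_bins} (cluster ids in the table not
#'   explained by any species with reads), \code{chimera_flag_rate} (fraction
#'   of surviving chimeric reads whose sequence was flagged), and
#'   \code{n_chimeric_surviving}.
#' @export
pipeline_recovery <- function(res, run, min_truth_frac = 2e-4) {
  truth <- run$truth
  lib <- truth$library_truth
  counts <- truth$sample_species_counts
  reads_per_sample <- colSums(counts) + 0  # clean reads per sample
  clusters_of <- split(lib$species_cluster$cluster_id,
                       lib$species_cluster$species_id)
  pa <- res$presence
  present_cluster <- function(cids, s) {
    cids <- intersect(cids, rownames(pa))
    length(cids) > 0 && any(pa[cids, s] > 0)
  }
  n_expected <- 0L; n_recovered <- 0L
  for (s in colnames(counts)) {
    if (!(s %in% colnames(pa))) next
    thr <- max(1, min_truth_frac * run$config$reads_per_sample)
    expected <- rownames(counts)[counts[, s] >= thr]
    for (sp in expected) {
      n_expected <- n_expected + 1L
      if (present_cluster(clusters_of[[sp]], s)) n_recovered <- n_recovered + 1L
    }
  }
  # false clusters: rows of the final table not owned by any species present
  # in the simulated community (presence, not read count: a present species
  # can draw zero reads yet still parent chimeric amplicons)
  present <- truth$sample_species_present
  species_present <- if (!is.null(present)) {
    rownames(present)[rowSums(present) > 0]
  } else {
    rownames(counts)[rowSums(counts) > 0]
  }
  allowed <- unique(unlist(clusters_of[species_present]))
  false_bins <- setdiff(grep("^OTU:", rownames(pa), value = TRUE,
                             invert = TRUE), allowed)
  # chimera flagging, read-weighted over chimeric reads that reached the
  # dereplicated pool
  chim_rate <- NA_real_
  n_surv <- 0L
  if (!is.null(res$reads)) {
    chim_ids <- truth$chimeric_read_ids
    surv <- res$reads[res$reads$read_id %in% chim_ids, , drop = FALSE]
    n_surv <- nrow(surv)
    if (n_surv > 0) {
      chim_rate <- mean(surv$sequence %in% res$chimeras$sequence)
    }
  }
  list(species_recall = if (n_expected) n_recovered / n_expected else NA_real_,
       n_expected = n_expected, n_recovered = n_recovered,
       false_bins = false_bins,
       chimera_flag_rate = chim_rate, n_chimeric_surviving = n_surv)
}
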