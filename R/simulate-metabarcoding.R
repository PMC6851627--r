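# Synthetic bulk-sample (Malaise-trap style) metabarcoding runs over a
# simulated reference library: log-normal species abundances, per-base
# sequencing errors, Phred quality draws, and two-parent single-crossover
# chimeras, written as paired-end Phred-33 FASTQ per sample.

#' Configuration for the metabarcoding-run simulator
#'
#' Defaults emulate a season-long Malaise-trap campaign: 90 bulk samples at
#' roughly 6,000 usable reads each, a 313-bp minibarcode amplified with
#' degenerate primers, 2 x 250 bp reads.
#'
#' @param seed integer seed.
#' @param n_samples number of bulk samples.
#' @param reads_per_sample reads simulated per sample (exact).
#' @param abundance_meanlog,abundance_sdlog log-normal abundance model over
#'   the species present in a sample.
#' @param occupancy probability a library species occurs in a sample.
#' @param per_base_error substitution error rate per sequenced base.
#' @param chimera_rate fraction of reads that are two-parent chimeras.
#' @param phred_mean,phred_sd per-base Phred score model (truncated 2..40).
#' @param read_len length of each mate (bp).
#' @param fwd_primer,rev_primer degenerate primer sequences (IUPAC).
#' @param amplicon_start 1-based start of the amplified window in the
#'   reference barcode.
#' @param amplicon_len length of the amplified coding region (default 313).
#' @return validated config list of class \code{meta_sim_config}.
#' @export
meta_sim_config <- function(seed = 1L, n_samples = 90L,
                            reads_per_sample = 6000L,
                            abundance_meanlog = 0, abundance_sdlog = 1.5,
                            occupancy = 0.35, per_base_error = 0.001,
                            chimera_rate = 0.02, phred_mean = 35,
                            phred_sd = 3, read_len = 250L,
                            fwd_primer = "GGWACWGGWTGAACWGTWTAYCCYCC",
                            rev_primer = "TANACYTCNGGRTGNCCRAARAAYCA",
                            amplicon_start = 160L, amplicon_len = 313L) {
  stopifnot(n_samples >= 1, reads_per_sample > 0, read_len > 0,
            amplicon_len > 0, amplicon_start >= 1)
  for (p in c(occupancy, per_base_error, chimera_rate)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  check_alphabet(c(fwd_primer, rev_primer), "primer")
  amp_total <- amplicon_len + nchar(fwd_primer) + nchar(rev_primer)
  if (read_len >= amp_total) stop("read_len must be shorter than the primered amplicon")
  if (2L * read_len - amp_total < 40L) {
    stop("mates would overlap by less than 40 bp; increase read_len")
  }
  structure(list(seed = as.integer(seed), n_samples = as.integer(n_samples),
                 reads_per_sample = as.integer(reads_per_sample),
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog, occupancy = occupancy,
                 per_base_error = per_base_error, chimera_rate = chimera_rate,
                 phred_mean = phred_mean, phred_sd = phred_sd,
                 read_len = as.integer(read_len), fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer),
                 amplicon_start = as.integer(amplicon_start),
                 amplicon_len = as.integer(amplicon_len)),
            class = "meta_sim_config")
}

# stable per-sample sub-seed so adding a sample does not perturb others
sample_subseed <- function(seed, sample_id) {
  h <- sum(utf8ToInt(sample_id) * seq_len(nchar(sample_id)))
  (as.numeric(seed) * 48271 + h * 16807) %% 2147483647
}

# instantiate a degenerate IUPAC primer: each ambiguous position drawn
# uniformly from its degeneracy set
instantiate_primer <- function(primer) {
  bits <- enc_bits(primer)
  chars <- seq_chars(primer)
  amb <- which(!(chars %in% BASES))
  for (i in amb) {
    allowed <- BASES[bitwAnd(bits[i], c(1L, 2L, 4L, 8L)) > 0L]
    chars[i] <- sample(allowed, 1L)
  }
  paste(chars, collapse = "")
}

apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- seq_chars(s)
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a paired-end metabarcoding run over a reference library
#'
#' Every read is a primer-flanked window of one of the library's haplotypes
#' (or a single-crossover chimera of two amplicons, crossover uniform over
#' the middle 60%), with substitution errors and Phred scores drawn from the
#' quality model. Reads per sample match the config exactly. FASTQ pairs are
#' written per sample; truth is extended with read-level labels.
#'
#' @param library result of [simulate_library()] (or its \code{records}).
#' @param truth the matching ground truth (used for species labels).
#' @param config a \code{meta_sim_config}.
#' @param out_dir directory for FASTQ files and the manifest (created).
#' @return list: \code{manifest} data frame, \code{truth} (read labels,
#'   per-sample species read counts, chimeric read ids), \code{config}.
#' @export
simulate_metabarcoding_run <- function(library, truth, config, out_dir) {
  stopifnot(inherits(config, "meta_sim_config"))
  records <- if (is.data.frame(library)) library else library$records
  if (!nrow(records)) stop("empty reference library")
  amp_end <- config$amplicon_start + config$amplicon_len - 1L
  if (any(nchar(records$sequence) < amp_end)) {
    stop("amplicon window [", config$amplicon_start, ", ", amp_end,
         "] exceeds a reference sequence length")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rec_truth <- truth$records
  windows <- substr(records$sequence, config$amplicon_start, amp_end)
  by_species <- split(seq_len(nrow(records)), rec_truth$species_id[
    match(records$record_id, rec_truth$record_id)])
  species_ids <- names(by_species)
  n_sp <- length(species_ids)
  fp_len <- nchar(config$fwd_primer)
  rp_len <- nchar(config$rev_primer)
  amp_total <- config$amplicon_len + fp_len + rp_len
  rl <- config$read_len

  manifest <- NULL
  read_labels <- NULL
  sample_species_counts <- matrix(0L, n_sp, config$n_samples,
                                  dimnames = list(species_ids, NULL))
  sample_names <- sprintf("S%03d", seq_len(config$n_samples))
  colnames(sample_species_counts) <- sample_names
  sample_species_present <- sample_species_counts > 0L

  for (smp in seq_len(config$n_samples)) {
    sid <- sample_names[smp]
    set.seed(sample_subseed(config$seed, sid))
    present <- stats::runif(n_sp) < config$occupancy
    if (sum(present) < 2L) present[sample.int(n_sp, 2L)] <- TRUE
    w <- numeric(n_sp)
    w[present] <- stats::rlnorm(sum(present), config$abundance_meanlog,
                                config$abundance_sdlog)
    n_reads <- config$reads_per_sample
    n_chim <- stats::rbinom(1L, n_reads, config$chimera_rate)
    n_clean <- n_reads - n_chim
    counts <- as.vector(stats::rmultinom(1L, n_clean, w))
    sample_species_counts[, smp] <- counts
    sample_species_present[, smp] <- present | counts > 0L

    # clean amplicons
    sp_of_read <- rep.int(seq_len(n_sp), counts)
    amp <- character(n_reads)
    for (k in which(counts > 0L)) {
      recs <- by_species[[k]]
      idx <- which(sp_of_read == k)
      hap <- recs[sample.int(length(recs), length(idx), replace = TRUE)]
      amp[idx] <- windows[hap]
    }
    # chimeras: two abundance-weighted parents, one crossover in the middle 60%
    chim_flag <- c(rep(FALSE, n_clean), rep(TRUE, n_chim))
    lo <- max(1L, round(0.2 * config$amplicon_len))
    hi <- round(0.8 * config$amplicon_len)
    if (n_chim > 0L) {
      for (k in seq_len(n_chim)) {
        par_sp <- sample.int(n_sp, 2L, replace = FALSE, prob = w)
        pick <- function(spk) {
          recs <- by_species[[spk]]
          windows[recs[sample.int(length(recs), 1L)]]
        }
        a <- pick(par_sp[1]); b <- pick(par_sp[2])
        cx <- sample(seq.int(lo, hi), 1L)
        amp[n_clean + k] <- paste0(substr(a, 1L, cx),
                                   substr(b, cx + 1L, config$amplicon_len))
      }
    }
    # flank with instantiated primers, apply errors
    fps <- vapply(seq_len(n_reads), function(i) instantiate_primer(config$fwd_primer),
                  character(1))
    rps <- vapply(seq_len(n_reads), function(i) instantiate_primer(config$rev_primer),
                  character(1))
    mol <- paste0(fps, amp, revcomp(rps))
    mol <- apply_errors(mol, config$per_base_error)
    fwd <- substr(mol, 1L, rl)
    rev <- revcomp(substr(mol, amp_total - rl + 1L, amp_total))
    qdraw <- function() {
      q <- round(stats::rnorm(rl, config$phred_mean, config$phred_sd))
      pmin(pmax(q, 2L), 40L)
    }
    fq <- replicate(n_reads, qdraw(), simplify = FALSE)
    rq <- replicate(n_reads, qdraw(), simplify = FALSE)
    ids <- sprintf("%s_r%06d", sid, seq_len(n_reads))
    pairs <- data.frame(read_id = ids, forward_seq = fwd, reverse_seq = rev,
                        forward_qual = I(fq), reverse_qual = I(rq),
                        sample_id = sid, stringsAsFactors = FALSE)
    pf <- file.path(out_dir, paste0(sid, "_R1.fastq"))
    pr <- file.path(out_dir, paste0(sid, "_R2.fastq"))
    write_fastq_pair(pairs, pf, pr)
    manifest <- rbind(manifest, data.frame(
      sample_id = sid, site = sprintf("site%02d", ((smp - 1L) %% 9L) + 1L),
      date_start = as.character(as.Date("2016-05-01") + 14L * ((smp - 1L) %/% 9L)),
      date_end = as.character(as.Date("2016-05-14") + 14L * ((smp - 1L) %/% 9L)),
      path_fwd = pf, path_rev = pr, stringsAsFactors = FALSE))
    read_labels <- rbind(read_labels, data.frame(
      read_id = ids, sample_id = sid,
      species_id = c(species_ids[sp_of_read], rep(NA_character_, n_chim)),
      chimera = chim_flag, stringsAsFactors = FALSE))
  }
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  run_truth <- list(read_labels = read_labels,
                    sample_species_counts = sample_species_counts,
                    sample_species_present = sample_species_present,
                    chimeric_read_ids = read_labels$read_id[read_labels$chimera],
                    library_truth = truth)
  list(manifest = manifest, truth = run_truth, config = config)
}
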