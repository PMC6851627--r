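mk_pair <- function(fwd, rev, fq = NULL, rq = NULL, id = "r1") {
  data.frame(read_id = id, forward_seq = fwd, reverse_seq = rev,
             forward_qual = I(list(fq %||% rep(35L, nchar(fwd)))),
             reverse_qual = I(list(rq %||% rep(35L, nchar(rev)))),
             sample_id = "S1", stringsAsFactors = FALSE)
}

rand_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("pair merging picks the best ungapped overlap and enforces the minimum", {
  amp <- rand_seq(313, 101)
  fwd <- substr(amp, 1, 200)
  rev <- revcomp(substr(amp, 114, 313))   # 200 bp, overlap 87
  mg <- merge_pairs(mk_pair(fwd, rev))
  expect_equal(nrow(mg$merged), 1)
  expect_equal(nchar(mg$merged$sequence), 313)  # 200 + 200 - 87
  expect_equal(mg$merged$sequence, amp)
  # overlap 39 < 40 is rejected
  amp2 <- rand_seq(361, 102)
  mg2 <- merge_pairs(mk_pair(substr(amp2, 1, 200),
                             revcomp(substr(amp2, 162, 361))))
  expect_equal(nrow(mg2$merged), 0)
  expect_equal(mg2$rejected_ids, "r1")
  # identical full-length overlap: merged equals the forward read
  f3 <- rand_seq(150, 103)
  mg3 <- merge_pairs(mk_pair(f3, revcomp(f3)))
  expect_equal(mg3$merged$sequence, f3)
})

test_that("the higher-Phred base wins inside the overlap", {
  f <- paste0(strrep("A", 60), "C")        # last base disagrees
  r <- paste0(strrep("A", 60), "G")        # reverse-complemented r ends ...G? build explicitly
  # construct: true overlap is full length 61; forward says C, reverse says T at pos 61
  fwd <- paste0(strrep("A", 60), "C")
  rev_merged_view <- paste0(strrep("A", 60), "T")
  rev <- revcomp(rev_merged_view)
  fq <- c(rep(35L, 60), 10L)
  rq <- rev(c(rep(35L, 60), 30L))  # reverse qual stored in mate orientation
  mg <- merge_pairs(mk_pair(fwd, rev, fq = fq, rq = rq), min_overlap = 40,
                    max_mismatch_frac = 0.1)
  expect_equal(substr(mg$merged$sequence, 61, 61), "T")  # Phred 30 beats 10
  expect_equal(mg$merged$qual[[1]][61], 30L)
})

test_that("primer trimming detects degenerate primers at 90% identity", {
  fwdp <- "GGWACWGGWTGAACWGTWTAYCCYCC"
  revp <- "TANACYTCNGGRTGNCCRAARAAYCA"
  insert <- rand_seq(313, 104)
  mol <- paste0("GGAACAGGATGAACAGTATACCCTCC", insert, revcomp("TAAACTTCAGGGTGACCAAAAAATCA"))
  merged <- data.frame(read_id = "r1", sample_id = "S1", sequence = mol,
                       qual = I(list(rep(35L, nchar(mol)))),
                       stringsAsFactors = FALSE)
  tr <- trim_primers(merged, fwdp, revp)
  expect_equal(tr$trimmed$sequence, insert)
  expect_length(tr$trimmed$qual[[1]], 313)
  # one mismatch in a 26-base primer (25/26 = 96%) still detected
  mol2 <- paste0("TGAACAGGATGAACAGTATACCCTCC", insert,
                 revcomp("TAAACTTCAGGGTGACCAAAAAATCA"))
  merged2 <- merged; merged2$sequence <- mol2
  merged2$qual <- I(list(rep(35L, nchar(mol2))))
  expect_equal(trim_primers(merged2, fwdp, revp)$trimmed$sequence, insert)
  # forward primer absent -> discarded
  mol3 <- paste0(rand_seq(26, 105), insert,
                 revcomp("TAAACTTCAGGGTGACCAAAAAATCA"))
  merged3 <- merged; merged3$sequence <- mol3
  merged3$qual <- I(list(rep(35L, nchar(mol3))))
  tr3 <- trim_primers(merged3, fwdp, revp)
  expect_equal(nrow(tr3$trimmed), 0)
  expect_equal(tr3$discarded_ids, "r1")
})

test_that("expected errors sum the Phred error probabilities", {
  expect_equal(expected_errors(rep(20L, 100)), 1.0)
  expect_equal(expected_errors(rep(40L, 10)), 0.001)
  expect_equal(expected_errors(integer(0)), 0)
  reads <- data.frame(read_id = c("a", "b"), sample_id = "S1",
                      sequence = c("AAAA", "CCCC"),
                      qual = I(list(rep(20L, 100), rep(10L, 11))),
                      stringsAsFactors = FALSE)
  fl <- filter_by_ee(reads, max_ee = 1.0)
  expect_equal(fl$kept$read_id, "a")     # EE exactly 1.0 is kept
  expect_equal(fl$discarded_ids, "b")    # EE 1.1 is not
})

test_that("dereplication is scope-equivalent and abundance-sorted", {
  set.seed(41)
  seqs <- c("AAAA", "CCCC", "GGGG")
  reads <- data.frame(
    sequence = sample(rep(seqs, c(50, 30, 20))),
    sample_id = sample(rep(c("S1", "S2"), 50)),
    stringsAsFactors = FALSE)
  g <- dereplicate(reads, "global")
  expect_equal(g$uniques$abundance, c(50, 30, 20))
  expect_equal(sum(g$counts), 100)
  via_sample <- combine_derep(dereplicate(reads, "sample"))
  expect_identical(g, via_sample)
  # 100 identical reads -> one unique of abundance 100
  one <- dereplicate(data.frame(sequence = rep("ACGT", 100), sample_id = "S1",
                                stringsAsFactors = FALSE), "global")
  expect_equal(nrow(one$uniques), 1)
  expect_equal(one$uniques$abundance, 100)
  # a single-base difference keeps sequences apart
  two <- dereplicate(data.frame(sequence = c("ACGT", "ACGA"), sample_id = "S1",
                                stringsAsFactors = FALSE), "global")
  expect_equal(nrow(two$uniques), 2)
})

test_that("chimera filter flags two-parent crossovers and spares variants", {
  a <- rand_seq(200, 106)
  b_ch <- strsplit(a, "")[[1]]
  set.seed(107)
  mut <- sample(200, 24)                 # ~12% divergent second parent
  b_ch[mut] <- vapply(b_ch[mut], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  b <- paste(b_ch, collapse = "")
  chim <- paste0(substr(a, 1, 100), substr(b, 101, 200))
  derep <- list(
    uniques = data.frame(sequence = c(a, b, chim),
                         abundance = c(50, 40, 3), stringsAsFactors = FALSE),
    counts = matrix(c(50, 40, 3), 3, 1, dimnames = list(NULL, "S1")))
  rc <- remove_chimeras(derep)
  expect_equal(rc$flagged$sequence, chim)
  expect_equal(nrow(rc$kept$uniques), 2)
  expect_setequal(c(rc$flagged$parent_a, rc$flagged$parent_b), c(a, b))
  # the most abundant unique is never flagged (no eligible parents)
  expect_false(a %in% rc$flagged$sequence)
  # a sequence ~99.5% identical to one parent overall is kept as a variant
  var <- strsplit(a, "")[[1]]; var[5] <- setdiff(c("A","C","G","T"), var[5])[1]
  derep2 <- list(
    uniques = data.frame(sequence = c(a, b, paste(var, collapse = "")),
                         abundance = c(50, 40, 3), stringsAsFactors = FALSE),
    counts = matrix(c(50, 40, 3), 3, 1, dimnames = list(NULL, "S1")))
  expect_equal(nrow(remove_chimeras(derep2)$flagged), 0)
  # insufficient parent abundance skew -> kept
  derep3 <- derep
  derep3$uniques$abundance <- c(5, 4, 3)
  expect_equal(nrow(remove_chimeras(derep3)$flagged), 0)
})

test_that("taxonomy assignment reports best hits with deterministic ties", {
  refs <- as_records(c(R1 = rand_seq(313, 108), R2 = rand_seq(313, 109)),
                     species = c("Aus aus", "Bus bus"),
                     cluster = c("SBIN:00001", "SBIN:00002"))
  hit <- assign_taxonomy(refs$sequence[1], refs)
  expect_equal(hit$identity, 100)
  expect_equal(hit$species, "Aus aus")
  expect_equal(hit$cluster_id, "SBIN:00001")
  # one mismatch in 313 bp -> 99.68%
  q <- strsplit(refs$sequence[1], "")[[1]]
  q[100] <- setdiff(c("A", "C", "G", "T"), q[100])[1]
  hit2 <- assign_taxonomy(paste(q, collapse = ""), refs)
  expect_equal(hit2$identity, round(100 * 312 / 313, 2))
  # exact tie between two references -> lexicographically first record id
  refs_tie <- refs
  refs_tie$sequence[2] <- refs$sequence[1]
  refs_tie$record_id <- c("RB", "RA")
  hit3 <- assign_taxonomy(refs$sequence[1], refs_tie)
  expect_equal(hit3$hit_id, "RA")
})

test_that("OTU-table filtering drops low identity and zeroes sub-threshold counts", {
  otus <- data.frame(otu_id = c("OTU1", "OTU2", "OTU3"),
                     cluster_id = c("B1", "B2", "B3"),
                     identity = c(99.5, 96.9, 98.0),
                     family = "F", genus = "G", species = "S",
                     hit_id = "R1", centroid = "ACGT",
                     stringsAsFactors = FALSE)
  counts <- matrix(c(49991, 0,
                     100, 100,
                     4, 200), 3, 2, byrow = TRUE,
                   dimnames = list(NULL, c("S1", "S2")))
  # S1 pre-filter total = 50095 -> threshold ~5.01; the count of 4 is zeroed
  filt <- filter_otu_table(list(otus = otus, counts = counts),
                           min_identity = 97, min_read_frac = 1e-4)
  expect_false("OTU2" %in% filt$otus$otu_id)          # 96.9 < 97
  expect_equal(unname(filt$counts[filt$otus$otu_id == "OTU3", "S1"]), 0)
  expect_equal(unname(filt$counts[filt$otus$otu_id == "OTU3", "S2"]), 200)
  expect_equal(filt$removed$identity_reads, 200)
  # the global-scope variant drops whole rows below the grand-total fraction
  filt_g <- filter_otu_table(list(otus = otus, counts = counts),
                             min_identity = 0, min_read_frac = 0.005,
                             frac_scope = "global")
  expect_false("OTU3" %in% filt_g$otus$otu_id)  # 204 < 0.5% of 50395
  # empty tables pass through
  empty <- filter_otu_table(list(otus = otus[0, ], counts = counts[0, , drop = FALSE]))
  expect_equal(nrow(empty$otus), 0)
})

test_that("merging OTUs into BINs conserves reads and keeps the best taxonomy", {
  otus <- data.frame(otu_id = c("OTU1", "OTU2", "OTU3"),
                     cluster_id = c("B1", "B1", "B2"),
                     identity = c(100, 98.2, 99.0),
                     family = "F", genus = "G",
                     species = c("best", "worse", "other"),
                     hit_id = "R", centroid = c("AA", "CC", "GG"),
                     stringsAsFactors = FALSE)
  counts <- matrix(c(10, 1,
                     5, 2,
                     7, 0), 3, 2, byrow = TRUE,
                   dimnames = list(NULL, c("S1", "S2")))
  bins <- merge_otus_to_bins(list(otus = otus, counts = counts))
  expect_equal(nrow(bins$bins), 2)
  b1 <- bins$bins[bins$bins$cluster_id == "B1", ]
  expect_equal(bins$counts["B1", ], c(S1 = 15, S2 = 3))
  expect_equal(b1$identity, 100)
  expect_equal(b1$species, "best")
  expect_equal(sum(bins$counts), sum(counts))   # conservation
  # distinct BINs leave the table unchanged in size
  otus2 <- otus; otus2$cluster_id <- c("B1", "B2", "B3")
  expect_equal(nrow(merge_otus_to_bins(list(otus = otus2, counts = counts))$bins), 3)
  pa <- presence_absence(bins)
  expect_equal(pa["B2", ], c(S1 = 1, S2 = 0))
  expect_equal(rowSums(pa), c(B1 = 2, B2 = 1))
})

test_that("the pipeline ledger conserves reads through every stage", {
  sim <- tiny_library()
  out <- withr::local_tempdir()
  cfg <- meta_sim_config(seed = 9, n_samples = 2, reads_per_sample = 250,
                         chimera_rate = 0.04)
  run <- simulate_metabarcoding_run(sim, sim$truth, cfg, out)
  res <- run_metabarcoding(run$manifest, sim$records, cfg$fwd_primer,
                           cfg$rev_primer,
                           ref_region = c(cfg$amplicon_start, cfg$amplicon_len))
  led <- res$ledger
  per_read <- led[led$sample_id != "(all)", ]
  # within each stage row: kept + removed == in
  expect_true(all(per_read$n_kept + per_read$n_removed == per_read$n_in))
  # stage chaining per sample: merge out feeds trim, trim out feeds EE
  for (s in unique(per_read$sample_id)) {
    rows <- per_read[per_read$sample_id == s, ]
    expect_equal(rows$n_in[1], cfg$reads_per_sample)
    expect_equal(rows$n_kept[rows$stage == "merge"],
                 rows$n_in[rows$stage == "trim"])
    expect_equal(rows$n_kept[rows$stage == "trim"],
                 rows$n_in[rows$stage == "ee_filter"])
  }
  # dereplication conserves read totals into unique abundances
  ee_total <- sum(per_read$n_kept[per_read$stage == "ee_filter"])
  expect_equal(sum(res$uniques$counts), ee_total)
  # rerunning the pipeline on the same files is deterministic
  res2 <- run_metabarcoding(run$manifest, sim$records, cfg$fwd_primer,
                            cfg$rev_primer,
                            ref_region = c(cfg$amplicon_start, cfg$amplicon_len))
  expect_identical(res$bin_table, res2$bin_table)
})
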