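test_that("library simulation is deterministic for a fixed seed", {
  fams <- default_sim_families()[1:2, ]
  cfg <- library_sim_config(seed = 7, families = fams)
  a <- simulate_library(cfg)
  b <- simulate_library(cfg)
  expect_identical(a, b)
  c <- simulate_library(library_sim_config(seed = 8, families = fams))
  expect_false(identical(a$records$sequence, c$records$sequence))
})

test_that("split and merge fractions drive the ground truth", {
  fams <- data.frame(name = "Testidae", infraorder = "Brachycera",
                     n_species = 20L, size_lo = 1, size_hi = 5,
                     dark_fraction = 0.2, stringsAsFactors = FALSE)
  none <- simulate_library(library_sim_config(seed = 2, families = fams,
                                              split_fraction = 0,
                                              merge_fraction = 0))
  expect_length(none$truth$split_species, 0)
  expect_null(none$truth$merged_pairs)
  some <- simulate_library(library_sim_config(seed = 2, families = fams,
                                              split_fraction = 0.2,
                                              merge_fraction = 0.2))
  expect_length(some$truth$split_species, 4)
  expect_equal(nrow(some$truth$merged_pairs), 2)
  # merged pairs share a cluster id in the truth map
  mp <- some$truth$merged_pairs
  sc <- some$truth$species_cluster
  for (k in seq_len(nrow(mp))) {
    expect_identical(sc$cluster_id[sc$species_id == mp$species_a[k]],
                     sc$cluster_id[sc$species_id == mp$species_b[k]])
  }
  # split species own two cluster ids; both lineages are sequenced
  for (s in some$truth$split_species) {
    expect_length(sc$cluster_id[sc$species_id == s], 2)
    lin <- some$truth$records$lineage[some$truth$records$species_id == s]
    expect_setequal(unique(lin), 1:2)
  }
})

test_that("dark fraction controls unnamed species and realized intra divergence is on target", {
  fams <- data.frame(name = "Testidae", infraorder = "Brachycera",
                     n_species = 50L, size_lo = 1, size_hi = 5,
                     dark_fraction = 0.4, stringsAsFactors = FALSE)
  cfg <- library_sim_config(seed = 6, families = fams, hap_range = c(5L, 5L),
                            split_fraction = 0, merge_fraction = 0)
  sim <- simulate_library(cfg)
  expect_length(sim$truth$dark_species, 20)
  dark_recs <- sim$truth$records$species_id %in% sim$truth$dark_species
  expect_true(all(is.na(sim$records$species[dark_recs])))
  expect_true(all(!is.na(sim$records$species[!dark_recs])))
  # realized mean within-species K2P within +/-30% of the 0.005 target
  dm <- pairwise_matrix(sim$records, min_len = 500)
  sp <- setNames(sim$truth$records$species_id,
                 sim$truth$records$record_id)[dm$ids]
  within <- outer(sp, sp, "==") & upper.tri(dm$d)
  expect_equal(mean(dm$d[within]), 0.005, tolerance = 0.3)
})

test_that("metabarcoding run writes exact read counts and honours chimera/occupancy settings", {
  sim <- tiny_library()
  out <- withr::local_tempdir()
  cfg <- meta_sim_config(seed = 3, n_samples = 3, reads_per_sample = 120,
                         chimera_rate = 0, occupancy = 1)
  run <- simulate_metabarcoding_run(sim, sim$truth, cfg, out)
  expect_equal(nrow(run$manifest), 3)
  lab <- run$truth$read_labels
  expect_equal(as.vector(table(lab$sample_id)), rep(120L, 3))
  expect_length(run$truth$chimeric_read_ids, 0)
  # occupancy 1: every species occurs in every sample in truth (counts can
  # still be zero for rare species under the multinomial read draw)
  expect_true(all(run$truth$sample_species_present))
  expect_equal(colSums(run$truth$sample_species_counts),
               c(S001 = 120L, S002 = 120L, S003 = 120L))
  # FASTQ files exist, are paired, and re-read to the simulated counts
  pairs <- read_fastq_pairs(run$manifest$path_fwd[1], run$manifest$path_rev[1],
                            run$manifest$sample_id[1])
  expect_equal(nrow(pairs), 120)
  expect_equal(unique(nchar(pairs$forward_seq)), cfg$read_len)
})

test_that("metabarcoding run is reproducible and labels chimeras", {
  sim <- tiny_library()
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  cfg <- meta_sim_config(seed = 5, n_samples = 2, reads_per_sample = 150,
                         chimera_rate = 0.1)
  r1 <- simulate_metabarcoding_run(sim, sim$truth, cfg, out1)
  r2 <- simulate_metabarcoding_run(sim, sim$truth, cfg, out2)
  expect_identical(r1$truth$read_labels, r2$truth$read_labels)
  expect_identical(readLines(r1$manifest$path_fwd[1]),
                   readLines(r2$manifest$path_fwd[1]))
  expect_gt(length(r1$truth$chimeric_read_ids), 0)
  # chimeric reads carry no species label; clean reads always do
  lab <- r1$truth$read_labels
  expect_true(all(is.na(lab$species_id[lab$chimera])))
  expect_true(all(!is.na(lab$species_id[!lab$chimera])))
})

test_that("error-free single-species reads dereplicate to one unique sequence", {
  fams <- data.frame(name = "Testidae", infraorder = "Brachycera",
                     n_species = 2L, size_lo = 1, size_hi = 5,
                     dark_fraction = 0, stringsAsFactors = FALSE)
  sim <- simulate_library(library_sim_config(seed = 10, families = fams,
                                             hap_range = c(1L, 1L),
                                             split_fraction = 0,
                                             merge_fraction = 0, intra = 0))
  out <- withr::local_tempdir()
  cfg <- meta_sim_config(seed = 1, n_samples = 1, reads_per_sample = 100,
                         per_base_error = 0, chimera_rate = 0, occupancy = 1,
                         abundance_sdlog = 0)
  run <- simulate_metabarcoding_run(sim, sim$truth, cfg, out)
  pairs <- read_fastq_pairs(run$manifest$path_fwd[1], run$manifest$path_rev[1], "S001")
  mg <- merge_pairs(pairs)
  expect_equal(nrow(mg$merged), 100)
  tr <- trim_primers(mg$merged, cfg$fwd_primer, cfg$rev_primer)
  expect_equal(nrow(tr$trimmed), 100)
  dr <- dereplicate(tr$trimmed, "global")
  # two species, equal weights; every read collapses to its species amplicon
  expect_lte(nrow(dr$uniques), 2)
  expect_equal(sum(dr$uniques$abundance), 100)
  expect_equal(unique(nchar(dr$uniques$sequence)), 313L)
})
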