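dm_of <- function(d, ids) {
  dimnames(d) <- list(ids, ids)
  structure(list(ids = ids, d = d, excluded_ids = character(0)),
            class = "dist_matrix")
}

cl_of <- function(assignment) {
  members <- split(names(assignment), assignment)
  structure(list(assignment = assignment, clusters = members,
                 method = "single_linkage", threshold = 0.022),
            class = "cluster_assignment")
}

test_that("species statistics aggregate within-species pairs", {
  ids <- c("a1", "a2", "a3", "b1")
  d <- matrix(0, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.01
  d[1, 3] <- d[3, 1] <- 0.02
  d[2, 3] <- d[3, 2] <- 0.03
  d[4, 1:3] <- d[1:3, 4] <- 0.08
  sp <- setNames(c("Aus aus", "Aus aus", "Aus aus", "Bus bus"), ids)
  st <- species_stats(dm_of(d, ids), sp)
  arow <- st[st$species == "Aus aus", ]
  expect_equal(arow$mean_isp, 2)   # percent scale
  expect_equal(arow$max_isp, 3)
  expect_equal(arow$nn_dist, 8)
  # singleton species: isp fields absent, NN still computed
  brow <- st[st$species == "Bus bus", ]
  expect_true(is.na(brow$mean_isp) && is.na(brow$max_isp))
  expect_equal(brow$nn_species, "Aus aus")
  # identical members give zero divergence
  d0 <- matrix(0, 3, 3); d0[3, 1:2] <- d0[1:2, 3] <- 0.1
  st0 <- species_stats(dm_of(d0, c("x1", "x2", "y1")),
                       setNames(c("X x", "X x", "Y y"), c("x1", "x2", "y1")))
  expect_equal(st0$mean_isp[st0$species == "X x"], 0)
  expect_error(species_stats(dm_of(d, ids), sp[-1]), "without species")
})

test_that("discordance classification finds splits, sharing and concordance", {
  # two named species in one cluster -> both shared with rank 2
  sp <- setNames(c("Hylemya nigrimana", "Hylemya vagans", "Aus aus"),
                 c("r1", "r2", "r3"))
  cl <- cl_of(setNames(c("C1", "C1", "C2"), names(sp)))
  res <- classify_discordance(sp, cl)
  hy <- res$species[grepl("Hylemya", res$species$species), ]
  expect_true(all(hy$status == "shared"))
  expect_true(all(hy$bs_rank == 2))
  expect_equal(res$clusters$n_species_named[res$clusters$cluster_id == "C1"], 2)

  # one species across two clusters -> split with cdc_rank 2
  sp2 <- setNames(c("Napomyza cichorii", "Napomyza cichorii", "Aus aus"),
                  c("r1", "r2", "r3"))
  cl2 <- cl_of(setNames(c("X", "Y", "Z"), names(sp2)))
  res2 <- classify_discordance(sp2, cl2)
  nap <- res2$species[res2$species$species == "Napomyza cichorii", ]
  expect_equal(nap$status, "split")
  expect_equal(nap$cdc_rank, 2L)

  # bijective map -> all concordant
  sp3 <- setNames(c("A a", "A a", "B b"), c("r1", "r2", "r3"))
  cl3 <- cl_of(setNames(c("C1", "C1", "C2"), names(sp3)))
  res3 <- classify_discordance(sp3, cl3)
  expect_setequal(res3$species$status, c("concordant", "singleton_data"))

  # interim-named members never create sharing conflicts
  sp4 <- setNames(c("A a", "Testus sp. C1"), c("r1", "r2"))
  cl4 <- cl_of(setNames(c("C1", "C1"), names(sp4)))
  res4 <- classify_discordance(sp4, cl4)
  expect_false(any(res4$species$status == "shared"))
  expect_true(res4$clusters$contains_dark[1])
  expect_error(classify_discordance(sp4, cl_of(setNames("C1", "r1"))),
               "without cluster")
})

test_that("status counts partition the species set", {
  sim <- tiny_library()
  rep <- audit_report(sim$records)
  s <- rep$summary
  named <- rep$audit[rep$audit$named, ]
  expect_equal(s$n_concordant + s$n_singleton +
                 sum(named$status == "split") +
                 sum(named$status == "shared") + s$n_split_and_shared,
               s$n_named)
  # summed per-cluster named-species counts >= named species,
  # equality iff no species is split across clusters
  named_per_cluster <- rep$cluster_rows$n_species_named
  expect_equal(sum(named_per_cluster),
               s$n_named + sum(named$cdc_rank - 1, na.rm = TRUE))
})

test_that("severity bands use the 3/6 percent boundaries", {
  expect_equal(severity_band(c(3.71, 14.5, 3.0, 6.0, 6.01, 0.2, NA)),
               c("mid", "high", "low", "mid", "high", "low", "none"))
})

test_that("barcode gap flag compares maxISP with the nearest neighbour", {
  audit <- data.frame(species = c("a", "b", "c"),
                      max_isp = c(2, 8, NA), nn_dist = c(8, 2, 5),
                      stringsAsFactors = FALSE)
  fl <- barcode_gap_flag(audit)
  expect_equal(fl$gap, c(TRUE, FALSE, TRUE))
  expect_equal(fl$vacuous, c(FALSE, FALSE, TRUE))
})

test_that("interim names use the highest conflict-free rank", {
  tax <- data.frame(order = "Diptera", family = "Agromyzidae",
                    genus = "Melanagromyza", species = NA_character_,
                    stringsAsFactors = FALSE)[rep(1, 3), ]
  expect_equal(interim_name(tax, "BOLD:ACP6151"),
               "Melanagromyza sp. BOLD:ACP6151")
  # two genera but one family
  tax2 <- data.frame(order = "Diptera", family = "Tachinidae",
                     genus = c("Tachina", "Exorista"),
                     species = NA_character_, stringsAsFactors = FALSE)
  expect_equal(interim_name(tax2, "BOLD:AAG2112"),
               "Tachinidae sp. BOLD:AAG2112")
  # unanimous binomial survives unchanged
  tax3 <- data.frame(order = "Diptera", family = "Phoridae",
                     genus = "Megaselia", species = "Megaselia rufa",
                     stringsAsFactors = FALSE)[rep(1, 2), ]
  expect_equal(interim_name(tax3, "X"), "Megaselia rufa")
  # nothing shared at any rank
  tax4 <- data.frame(order = c("Diptera", "Coleoptera"), family = NA,
                     genus = NA, species = NA, stringsAsFactors = FALSE)
  expect_error(interim_name(tax4, "X"), "conflict-free")
})

test_that("the end-to-end audit recovers simulated splits and merges", {
  sim <- tiny_library()
  rep <- audit_report(sim$records)
  truth <- sim$truth
  split_binomials <- truth$species$binomial[
    truth$species$species_id %in% truth$split_species]
  aud <- rep$audit
  found_split <- aud$species[aud$status %in% c("split", "split_and_shared")]
  expect_setequal(intersect(found_split, split_binomials), split_binomials)
  mp <- truth$merged_pairs
  merged_binomials <- truth$species$binomial[
    match(c(mp$species_a, mp$species_b), truth$species$species_id)]
  found_shared <- aud$species[aud$status %in% c("shared", "split_and_shared")]
  expect_setequal(found_shared, merged_binomials)
  # no named species is falsely split
  false_split <- setdiff(found_split[found_split %in% aud$species[aud$named]],
                         split_binomials)
  expect_length(false_split, 0)
  expect_error(audit_report(sim$records[0, ]), "empty")
})

test_that("audit drives file outputs and the audit schema", {
  sim <- tiny_library()
  out <- withr::local_tempdir()
  rep <- run_library_audit(sim$records, out, newick = TRUE)
  expect_true(file.exists(file.path(out, "audit.tsv")))
  expect_true(file.exists(file.path(out, "clusters.tsv")))
  expect_true(file.exists(file.path(out, "nj_tree.nwk")))
  aud <- read_table(file.path(out, "audit.tsv"), "audit")
  expect_equal(nrow(aud), rep$summary$n_species_total)
})
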