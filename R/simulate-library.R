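# Synthetic COI reference libraries with ground truth.
#
# The generator emulates the statistical structure the audit assumes: shallow
# intraspecific variation, a deep interspecific gap, a small fraction of
# species split into two deep lineages (cryptic-diversity candidates), a
# small fraction of species pairs sharing one haplotype cluster, and unnamed
# ("dark") species whose frequency depends on family body size.

#' Default family panel for the library simulator
#'
#' Six family archetypes spanning the body-size spectrum, with dark-taxon
#' fractions decreasing with size (small-bodied families are the least
#' named, as observed in large barcoding campaigns).
#'
#' @return data frame with name, infraorder, n_species, size_lo, size_hi
#'   (mm) and dark_fraction.
#' @export
default_sim_families <- function() {
  data.frame(
    name = c("Cecidomyiidae", "Phoridae", "Sciaridae",
             "Mycetophilidae", "Tachinidae", "Syrphidae"),
    infraorder = c("Nematocera", "Brachycera", "Nematocera",
                   "Nematocera", "Brachycera", "Brachycera"),
    n_species = c(30L, 25L, 20L, 15L, 15L, 15L),
    size_lo = c(0.5, 0.5, 1.0, 2.0, 2.0, 3.5),
    size_hi = c(3.0, 6.0, 6.0, 15.0, 20.0, 35.0),
    dark_fraction = c(0.9, 0.6, 0.3, 0.3, 0.35, 0.08),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the reference-library simulator
#'
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @param families family panel data frame (see [default_sim_families()]).
#' @param hap_range min/max haplotypes sequenced per species.
#' @param intra expected within-species pairwise K2P (default 0.005).
#' @param inter expected between-species pairwise K2P (default 0.08).
#' @param split_fraction fraction of species given a second deep lineage.
#' @param split_divergence expected K2P between the two lineages of a split
#'   species (default 0.06).
#' @param merge_fraction fraction of species that participate in a merged
#'   pair (two named species sharing one haplotype cluster).
#' @param family_divergence expected K2P between species of different
#'   families (default 0.18, a realistic between-family COI divergence that
#'   keeps distances well below saturation).
#' @param kappa transition/transversion rate ratio of the substitution
#'   process (transition probability kappa/(kappa+2) given a mutation).
#' @param seq_len barcode length in bp (default 658).
#' @return validated config list of class \code{library_sim_config}.
#' @export
library_sim_config <- function(seed = 1L, families = default_sim_families(),
                               hap_range = c(2L, 5L), intra = 0.005,
                               inter = 0.08, split_fraction = 0.05,
                               split_divergence = 0.06, merge_fraction = 0.03,
                               family_divergence = 0.18,
                               kappa = 4, seq_len = 658L) {
  stopifnot(intra >= 0, inter >= 0, split_divergence >= 0, kappa > 0,
            seq_len > 0, hap_range[1] >= 1, hap_range[2] >= hap_range[1])
  for (f in c(split_fraction, merge_fraction)) {
    if (f < 0 || f > 1) stop("fractions must lie in [0, 1]")
  }
  if (any(families$dark_fraction < 0 | families$dark_fraction > 1)) {
    stop("dark_fraction must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), families = families,
                 hap_range = hap_range, intra = intra, inter = inter,
                 split_fraction = split_fraction,
                 split_divergence = split_divergence,
                 merge_fraction = merge_fraction,
                 family_divergence = family_divergence, kappa = kappa,
                 seq_len = as.integer(seq_len)),
            class = "library_sim_config")
}

BASES <- c("A", "C", "G", "T")
# transversion partners by base (two each); transitions are A<->G, C<->T
TRANSITION_OF <- c(A = "G", C = "T", G = "A", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), C = c("A", "G"),
                         G = c("C", "T"), T = c("A", "G"))

# mutate a base-character vector: each site substituted with probability p;
# given a substitution, transition with probability kappa/(kappa+2)
mutate_chars <- function(chars, p, kappa) {
  hit <- which(stats::runif(length(chars)) < p)
  if (!length(hit)) return(chars)
  is_ts <- stats::runif(length(hit)) < kappa / (kappa + 2)
  for (k in seq_along(hit)) {
    b <- chars[hit[k]]
    chars[hit[k]] <- if (is_ts[k]) {
      TRANSITION_OF[[b]]
    } else {
      sample(TRANSVERSIONS_OF[[b]], 1L)
    }
  }
  chars
}

#' Simulate a COI reference library with ground truth
#'
#' Each family evolves from a random ancestor; species founders diverge at
#' the interspecific target, haplotypes at the intraspecific target. Split
#' species carry two lineages separated by the split divergence (each lineage
#' gets at least one haplotype); merged species pairs share a founder
#' haplotype so their sequences fall in one cluster. Dark species (per-family
#' probability \code{dark_fraction}) lack a binomial; most keep their genus,
#' some only the family.
#'
#' @param config a \code{library_sim_config}.
#' @return list with \code{records} (sequence-record data frame; dark records
#'   have NA species) and \code{truth} (ground-truth list: per-record table,
#'   species/cluster map, split species, merged pairs, dark species, and the
#'   family checklist used).
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "library_sim_config"))
  set.seed(config$seed)
  fam <- config$families
  L <- config$seq_len

  genus_suffixes <- c("ella", "ina", "omyia", "odes")
  sp_counter <- 0L
  species_tab <- NULL
  for (fi in seq_len(nrow(fam))) {
    nsp <- fam$n_species[fi]
    stem <- sub("idae$", "", fam$name[fi])
    genera <- paste0(stem, genus_suffixes[seq_len(min(4L, nsp))])
    n_dark <- round(fam$dark_fraction[fi] * nsp)
    dark <- c(rep(TRUE, n_dark), rep(FALSE, nsp - n_dark))[sample.int(nsp)]
    for (si in seq_len(nsp)) {
      sp_counter <- sp_counter + 1L
      genus <- genera[((si - 1L) %% length(genera)) + 1L]
      species_tab <- rbind(species_tab, data.frame(
        species_id = sprintf("SP%04d", sp_counter),
        family = fam$name[fi], infraorder = fam$infraorder[fi],
        genus = genus,
        binomial = paste0(genus, " ", sprintf("num%03d", sp_counter)),
        dark = dark[si], stringsAsFactors = FALSE))
    }
  }
  n_species <- nrow(species_tab)
  # dark records sometimes lack even the genus
  species_tab$genus_known <- !species_tab$dark | stats::runif(n_species) < 0.7

  named_idx <- which(!species_tab$dark)
  n_split <- round(config$split_fraction * n_species)
  if (n_split > length(named_idx)) stop("impossible config: more splits than named species")
  split_idx <- if (n_split > 0) sample(named_idx, n_split) else integer(0)

  merge_candidates <- setdiff(named_idx, split_idx)
  n_merge_pairs <- floor(config$merge_fraction * n_species / 2)
  merged_pairs <- NULL
  if (n_merge_pairs > 0) {
    # pair within family so merged species are congeneric-plausible
    pool <- split(merge_candidates, species_tab$family[merge_candidates])
    pool <- pool[lengths(pool) >= 2]
    if (!length(pool)) stop("impossible config: no family has two named, unsplit species to merge")
    for (k in seq_len(n_merge_pairs)) {
      sizes <- lengths(pool)
      if (!any(sizes >= 2)) stop("impossible config: merge_fraction too high for the family panel")
      f <- sample(names(pool)[sizes >= 2], 1L)
      pr <- sort(sample(pool[[f]], 2L))
      pool[[f]] <- setdiff(pool[[f]], pr)
      merged_pairs <- rbind(merged_pairs, data.frame(
        species_a = species_tab$species_id[pr[1]],
        species_b = species_tab$species_id[pr[2]],
        idx_a = pr[1], idx_b = pr[2], stringsAsFactors = FALSE))
    }
  }

  # founders: order root -> family ancestor -> species founder, so
  # between-family distances sit near family_divergence, within-family
  # between-species distances near inter
  root <- sample(BASES, L, replace = TRUE)
  ancestors <- lapply(seq_len(nrow(fam)), function(i)
    mutate_chars(root, config$family_divergence / 2, config$kappa))
  names(ancestors) <- fam$name
  founders <- vector("list", n_species)
  for (i in seq_len(n_species)) {
    founders[[i]] <- mutate_chars(ancestors[[species_tab$family[i]]],
                                  config$inter / 2, config$kappa)
  }
  if (!is.null(merged_pairs)) {
    for (k in seq_len(nrow(merged_pairs))) {
      founders[[merged_pairs$idx_b[k]]] <- founders[[merged_pairs$idx_a[k]]]
    }
  }

  cluster_counter <- 0L
  new_cluster <- function() {
    cluster_counter <<- cluster_counter + 1L
    sprintf("SBIN:%05d", cluster_counter)
  }

  records <- NULL
  rec_truth <- NULL
  species_cluster <- NULL
  rec_counter <- 0L
  for (i in seq_len(n_species)) {
    st <- species_tab[i, ]
    k_hap <- sample(seq.int(config$hap_range[1], config$hap_range[2]), 1L)
    is_split <- i %in% split_idx
    if (is_split && k_hap < 2L) k_hap <- 2L
    if (is_split) {
      # two lineages diverging symmetrically from the species founder
      lin_founders <- list(
        mutate_chars(founders[[i]], config$split_divergence / 2, config$kappa),
        mutate_chars(founders[[i]], config$split_divergence / 2, config$kappa))
      lineage <- rep(1:2, length.out = k_hap)
      clusters <- c(new_cluster(), new_cluster())
    } else {
      lin_founders <- list(founders[[i]])
      lineage <- rep(1L, k_hap)
      merged_with_a <- !is.null(merged_pairs) && i %in% merged_pairs$idx_b
      clusters <- if (merged_with_a) {
        species_cluster$cluster_id[species_cluster$species_id ==
          merged_pairs$species_a[merged_pairs$idx_b == i]][1]
      } else {
        new_cluster()
      }
    }
    for (h in seq_len(k_hap)) {
      rec_counter <- rec_counter + 1L
      chars <- mutate_chars(lin_founders[[lineage[h]]], config$intra / 2,
                            config$kappa)
      records <- rbind(records, data.frame(
        record_id = sprintf("SIM%06d", rec_counter),
        order = "Diptera", family = st$family,
        genus = if (st$genus_known) st$genus else NA_character_,
        species = if (st$dark) NA_character_ else st$binomial,
        cluster_id = clusters[lineage[h]],
        sequence = paste(chars, collapse = ""), stringsAsFactors = FALSE))
      rec_truth <- rbind(rec_truth, data.frame(
        record_id = sprintf("SIM%06d", rec_counter),
        species_id = st$species_id, lineage = lineage[h],
        cluster_id = clusters[lineage[h]], stringsAsFactors = FALSE))
    }
    species_cluster <- rbind(species_cluster, data.frame(
      species_id = rep(st$species_id, length(unique(clusters))),
      cluster_id = unique(clusters), stringsAsFactors = FALSE))
  }

  checklist <- data.frame(
    family = fam$name, infraorder = fam$infraorder,
    species_reported = fam$n_species,
    size_lo = fam$size_lo, size_hi = fam$size_hi, stringsAsFactors = FALSE)

  truth <- list(
    species = species_tab,
    records = rec_truth,
    species_cluster = species_cluster,
    split_species = species_tab$species_id[split_idx],
    split_binomials = species_tab$binomial[split_idx],
    merged_pairs = merged_pairs,
    dark_species = species_tab$species_id[species_tab$dark],
    checklist = checklist,
    config = config
  )
  list(records = records, truth = truth)
}
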