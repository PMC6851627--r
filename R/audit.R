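# Per-species barcode-gap statistics, discordance classification (splits =
# cryptic-diversity candidates, sharing = one cluster holding several named
# species), severity banding, interim "reverse taxonomy" names, and the
# end-to-end library audit.
#
# Divergences are reported on the percent scale (x100) to match how barcode
# campaigns print them; internal distances stay in substitutions/site.

is_binomial <- function(species) {
  !is.na(species) & !grepl(" sp\\. ", species)
}

#' Per-species divergence statistics
#'
#' mean_isp / max_isp are the mean and maximum within-species pairwise K2P
#' (percent); species with a single sequenced member get NA there and status
#' \code{singleton_data}. Nearest-neighbour distance and species come from
#' [nearest_neighbor()].
#'
#' @param dm a \code{dist_matrix}.
#' @param species_of named character vector, record id -> species label
#'   (interim names allowed, NA not).
#' @return data frame: species, n_specimens, mean_isp, max_isp, nn_dist,
#'   nn_species (distances in percent).
#' @export
species_stats <- function(dm, species_of) {
  ids <- dm$ids
  unknown <- setdiff(ids, names(species_of))
  if (length(unknown)) {
    stop("record(s) without species label: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  }
  sp <- species_of[ids]
  nn <- nearest_neighbor(dm, species_of)
  species <- nn$species
  out <- data.frame(species = species,
                    n_specimens = as.integer(table(sp)[species]),
                    mean_isp = NA_real_, max_isp = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(species)) {
    mem <- which(sp == species[k])
    if (length(mem) < 2) next
    dd <- dm$d[mem, mem][upper.tri(matrix(0, length(mem), length(mem)))]
    out$mean_isp[k] <- 100 * mean(dd, na.rm = TRUE)
    out$max_isp[k] <- 100 * max(dd, na.rm = TRUE)
  }
  out$nn_dist <- 100 * nn$nn_dist
  out$nn_species <- nn$nn_species
  out
}

#' Classify species/cluster discordance
#'
#' A species whose members fall in two or more clusters is a \code{split}
#' (cryptic-diversity candidate; cdc_rank = number of clusters). A cluster
#' holding two or more *named* species flags each of them \code{shared}
#' (bs_rank = number of named species in the cluster). Species that are both
#' become \code{split_and_shared}. Unnamed or interim-named members never
#' create sharing conflicts: an interim name is cluster-derived and would
#' share by construction.
#'
#' @param species_of named character vector, record id -> species label.
#' @param clusters a \code{cluster_assignment} covering the same records.
#' @param named logical vector parallel to \code{species_of} marking real
#'   binomials; defaults to "not an interim name" (no " sp. " infix).
#' @return list: \code{species} data frame (species, named, n_clusters,
#'   cluster_ids, status, cdc_rank, bs_rank) and \code{clusters} data frame
#'   (cluster_id, n_species_named, species_named, contains_dark).
#' @export
classify_discordance <- function(species_of, clusters, named = NULL) {
  ids <- names(species_of)
  missing_cl <- setdiff(ids, names(clusters$assignment))
  if (length(missing_cl)) {
    stop("record(s) without cluster: ",
         paste(utils::head(missing_cl, 3), collapse = ", "))
  }
  if (anyNA(species_of)) {
    stop("record(s) without species label; assign interim names first")
  }
  if (is.null(named)) named <- is_binomial(species_of)
  cl <- clusters$assignment[ids]
  species <- sort(unique(species_of))
  sp_named <- named[match(species, species_of)]

  sp_clusters <- lapply(species, function(s) sort(unique(cl[species_of == s])))
  names(sp_clusters) <- species
  n_cl <- lengths(sp_clusters)

  cluster_rows <- do.call(rbind, lapply(names(clusters$clusters), function(cid) {
    mem <- ids[cl == cid]
    named_sp <- sort(unique(species_of[mem][named[match(mem, ids)]]))
    data.frame(cluster_id = cid, n_species_named = length(named_sp),
               species_named = paste(named_sp, collapse = ";"),
               contains_dark = any(!named[match(mem, ids)]),
               stringsAsFactors = FALSE)
  }))
  sharing_clusters <- cluster_rows$cluster_id[cluster_rows$n_species_named >= 2]

  shared <- vapply(seq_along(species), function(k) {
    sp_named[k] && any(sp_clusters[[species[k]]] %in% sharing_clusters)
  }, logical(1))
  split <- n_cl >= 2
  n_members <- as.integer(table(species_of)[species])
  status <- ifelse(split & shared, "split_and_shared",
            ifelse(split, "split",
            ifelse(shared, "shared",
            ifelse(n_members < 2, "singleton_data", "concordant"))))
  bs_rank <- vapply(seq_along(species), function(k) {
    if (!shared[k]) return(NA_integer_)
    max(cluster_rows$n_species_named[cluster_rows$cluster_id %in%
                                       sp_clusters[[species[k]]]])
  }, integer(1))
  list(
    species = data.frame(
      species = species, named = sp_named, n_specimens = n_members,
      n_clusters = n_cl,
      cluster_ids = vapply(sp_clusters, paste, "", collapse = ";"),
      status = status,
      cdc_rank = ifelse(split, n_cl, NA_integer_),
      bs_rank = bs_rank, stringsAsFactors = FALSE, row.names = NULL),
    clusters = cluster_rows
  )
}

#' Severity band of a split species' maximum intraspecific divergence
#'
#' Percent scale: low for maxISP <= 3, mid for 3 < maxISP <= 6, high above 6;
#' NA gives "none". This banding reproduces the published partition of the
#' 122 multi-cluster species (34 low, 48 mid, 40 high).
#'
#' @param max_isp numeric vector of maximum intraspecific divergences (%).
#' @return character vector of bands.
#' @export
severity_band <- function(max_isp) {
  ifelse(is.na(max_isp), "none",
         ifelse(max_isp <= 3.0, "low",
                ifelse(max_isp <= 6.0, "mid", "high")))
}

#' Local barcode-gap flag
#'
#' TRUE iff the species' maximum intraspecific divergence is below its
#' nearest-neighbour distance. Singleton species are vacuously TRUE and
#' marked as such.
#'
#' @param audit audit data frame with max_isp and nn_dist columns.
#' @return data frame: species, gap (logical), vacuous (logical).
#' @export
barcode_gap_flag <- function(audit) {
  vac <- is.na(audit$max_isp)
  data.frame(species = audit$species,
             gap = ifelse(vac, TRUE, audit$max_isp < audit$nn_dist),
             vacuous = vac, stringsAsFactors = FALSE)
}

#' Interim species name for a cluster of records
#'
#' The deepest taxonomic rank on which all members *with an assignment*
#' agree is used: a unanimous binomial is returned unchanged; otherwise the
#' highest conflict-free taxon is combined with the cluster id, e.g.
#' "Megaselia sp. BOLD:ACD9573".
#'
#' @param taxonomy data frame of the members' taxonomy (columns order,
#'   family, genus, species; NAs allowed).
#' @param cluster_id the cluster's id.
#' @return name string.
#' @export
interim_name <- function(taxonomy, cluster_id) {
  unanimous <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_character_)
    u <- unique(x)
    if (length(u) == 1L) u else NA_character_
  }
  sp <- unanimous(taxonomy$species)
  if (!is.na(sp) && !grepl(" sp\\. ", sp)) return(sp)
  for (rank in c("genus", "family", "order")) {
    taxon <- unanimous(taxonomy[[rank]])
    if (!is.na(taxon)) return(paste0(taxon, " sp. ", cluster_id))
  }
  stop("cluster ", cluster_id, " has no conflict-free taxonomy at any rank")
}

# assign interim names to every record lacking a binomial, per cluster
assign_interim_names <- function(records, clusters) {
  cl <- clusters$assignment[records$record_id]
  species <- records$species
  for (cid in unique(cl[!is_binomial(species)])) {
    mem <- which(cl == cid & !is_binomial(species))
    # name derives from the whole cluster's taxonomy, named members included
    allmem <- which(cl == cid)
    species[mem] <- interim_name(records[allmem, c("order", "family", "genus", "species")],
                                 cid)
  }
  species
}

#' Full reference-library audit
#'
#' Runs the distance matrix (length filter), single-linkage clustering,
#' interim naming of unnamed records, per-species statistics, discordance
#' classification and severity banding, and tallies the counts summary.
#'
#' @param records sequence-record data frame.
#' @param min_len minimum unambiguous length (default 500).
#' @param threshold single-linkage threshold (default 0.022).
#' @return list: \code{audit} (per-species table in the audit schema plus
#'   named/cdc_rank/bs_rank), \code{clusters} (assignment), \code{cluster_rows},
#'   \code{summary} (named counts and percentages), \code{matrix}.
#' @export
audit_report <- function(records, min_len = 500, threshold = 0.022) {
  if (!nrow(records)) stop("empty library")
  dm <- pairwise_matrix(records, min_len = min_len)
  kept <- records[match(dm$ids, records$record_id), , drop = FALSE]
  clusters <- single_linkage_clusters(dm, threshold = threshold)
  species <- assign_interim_names(kept, clusters)
  species_of <- setNames(species, kept$record_id)
  stats <- species_stats(dm, species_of)
  disc <- classify_discordance(species_of, clusters,
                               named = is_binomial(kept$species))
  cls <- disc$species[match(stats$species, disc$species$species), ]
  fam <- vapply(stats$species, function(s)
    kept$family[which(species_of == s)[1]], character(1))
  audit <- data.frame(
    species = stats$species, family = unname(fam),
    n_specimens = stats$n_specimens,
    mean_isp = stats$mean_isp, max_isp = stats$max_isp,
    nn_dist = stats$nn_dist, nn_species = stats$nn_species,
    n_clusters = cls$n_clusters, cluster_ids = cls$cluster_ids,
    status = cls$status,
    band = ifelse(cls$status %in% c("split", "split_and_shared"),
                  severity_band(stats$max_isp), "none"),
    named = cls$named, cdc_rank = cls$cdc_rank, bs_rank = cls$bs_rank,
    stringsAsFactors = FALSE)
  named_audit <- audit[audit$named, , drop = FALSE]
  n_named <- nrow(named_audit)
  split_mask <- named_audit$status %in% c("split", "split_and_shared")
  shared_mask <- named_audit$status %in% c("shared", "split_and_shared")
  band_tab <- table(factor(named_audit$band[split_mask],
                           levels = c("low", "mid", "high")))
  pct <- function(k) round(100 * k / n_named, 2)
  summary <- list(
    n_species_total = nrow(audit), n_named = n_named,
    n_dark = nrow(audit) - n_named,
    n_concordant = sum(named_audit$status == "concordant"),
    n_singleton = sum(named_audit$status == "singleton_data"),
    n_split = sum(split_mask), n_shared = sum(shared_mask),
    n_split_and_shared = sum(named_audit$status == "split_and_shared"),
    band_low = unname(band_tab["low"]), band_mid = unname(band_tab["mid"]),
    band_high = unname(band_tab["high"]),
    pct_split = pct(sum(split_mask)), pct_shared = pct(sum(shared_mask)),
    n_clusters = length(clusters$clusters),
    n_excluded_short = length(dm$excluded_ids))
  list(audit = audit, clusters = clusters, cluster_rows = disc$clusters,
       summary = summary, matrix = dm)
}

#' Run the library audit and write its outputs
#'
#' Convenience driver: writes the audit table, the cluster assignment, a
#' counts summary and (optionally) a neighbour-joining tree in Newick format.
#'
#' @param records sequence-record data frame.
#' @param out_dir output directory (created).
#' @param min_len,threshold see [audit_report()].
#' @param newick also write an NJ tree (skip for large matrices).
#' @return the [audit_report()] result, invisibly.
#' @export
run_library_audit <- function(records, out_dir, min_len = 500,
                              threshold = 0.022, newick = TRUE) {
  rep <- audit_report(records, min_len = min_len, threshold = threshold)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(rep$audit[, TABLE_SCHEMAS$audit], file.path(out_dir, "audit.tsv"),
              "audit")
  write_cluster_assignment(rep$clusters, file.path(out_dir, "clusters.tsv"))
  summ <- data.frame(metric = names(rep$summary),
                     value = unlist(rep$summary), stringsAsFactors = FALSE)
  utils::write.table(summ, file.path(out_dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (newick) {
    write_newick(nj_tree(rep$matrix), file.path(out_dir, "nj_tree.nwk"))
  }
  invisible(rep)
}
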