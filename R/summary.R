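# Family-level summaries (dark-taxa fractions, coverage ratios), one-sided
# Pearson correlations of darkness against body size and checklist richness,
# sequencing-yield arithmetic, and loaders for the packaged transcriptions
# of the published family / cryptic-diversity / cluster-sharing tables.

#' Family-level summary of an audited library
#'
#' One row per checklist family. A taxon counts as "dark" iff its species
#' label is interim or absent. Families without barcoded taxa get NA
#' pct_dark. ratio_barcoded is rounded to the nearest integer as barcode
#' campaigns print it; pct_dark stays full precision.
#'
#' @param audit per-species audit data frame (needs species, family, named,
#'   n_clusters columns, e.g. from [audit_report()]).
#' @param checklist data frame with family, infraorder, species_reported,
#'   size_lo, size_hi.
#' @return data frame in the family_summary schema.
#' @export
family_summary <- function(audit, checklist) {
  extra <- setdiff(unique(audit$family), checklist$family)
  if (length(extra)) {
    stop("family in audit but not in checklist: ",
         paste(extra, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(checklist)), function(i) {
    fam <- checklist$family[i]
    sub <- audit[audit$family == fam, , drop = FALSE]
    taxa <- nrow(sub)
    unnamed <- sum(!sub$named)
    n_cl <- length(unique(unlist(strsplit(sub$cluster_ids, ";", fixed = TRUE))))
    if (!taxa) n_cl <- 0L
    data.frame(
      family = fam, infraorder = checklist$infraorder[i],
      species_reported = checklist$species_reported[i],
      n_clusters = n_cl,
      ratio_barcoded = round(100 * n_cl / checklist$species_reported[i]),
      size_lo = checklist$size_lo[i], size_hi = checklist$size_hi[i],
      size_mid = (checklist$size_lo[i] + checklist$size_hi[i]) / 2,
      taxa_with_barcode = taxa, unnamed_with_barcode = unnamed,
      pct_dark = if (taxa > 0) 100 * unnamed / taxa else NA_real_,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-sided Pearson correlation of dark-taxa percentage with a covariate
#'
#' Tests the direction the biology predicts: negative against mid-range body
#' size (small families are less named), positive against the number of
#' species reported in the checklist. Families without barcoded taxa are
#' always excluded; families with 0% dark taxa are included by default, with
#' the exclusion variant one flag away.
#'
#' @param rows family-summary data frame (needs pct_dark and the covariate).
#' @param covariate "size_mid" or "species_reported".
#' @param include_zero_dark include families with pct_dark == 0 (default
#'   TRUE).
#' @return list: r, p (one-sided), n, direction, covariate.
#' @export
dark_taxa_correlation <- function(rows,
                                  covariate = c("size_mid", "species_reported"),
                                  include_zero_dark = TRUE) {
  covariate <- match.arg(covariate)
  use <- !is.na(rows$pct_dark) & !is.na(rows[[covariate]])
  if (!include_zero_dark) use <- use & rows$pct_dark > 0
  d <- rows[use, , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 usable family rows")
  x <- d[[covariate]]; y <- d$pct_dark
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in ", if (stats::sd(x) == 0) covariate else "pct_dark")
  }
  direction <- if (covariate == "size_mid") "less" else "greater"
  ct <- stats::cor.test(x, y, alternative = direction, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d),
       direction = direction, covariate = covariate)
}

#' Sanger sequencing yield report
#'
#' @param submitted specimens submitted for sequencing.
#' @param bidirectional_full specimens with a bidirectional full-length
#'   (658 bp) barcode.
#' @param unidirectional_ge500 specimens with a unidirectional 500-657 bp
#'   sequence.
#' @param below_500 specimens with a sequence under 500 bp.
#' @param failed specimens with no sequence recovered.
#' @return list of the counts, \code{recovered}, and percentages of
#'   submitted (2 decimals).
#' @export
yield_report <- function(submitted, bidirectional_full, unidirectional_ge500,
                         below_500, failed) {
  if (submitted <= 0) stop("submitted must be positive")
  recovered <- bidirectional_full + unidirectional_ge500 + below_500
  if (recovered + failed != submitted) {
    stop("component counts (", recovered, " recovered + ", failed,
         " failed) do not sum to submitted (", submitted, ")")
  }
  pct <- function(k) round(100 * k / submitted, 2)
  list(submitted = submitted, recovered = recovered,
       bidirectional_full = bidirectional_full,
       unidirectional_ge500 = unidirectional_ge500,
       below_500 = below_500, failed = failed,
       pct_recovered = pct(recovered),
       pct_bidirectional_full = pct(bidirectional_full),
       pct_unidirectional_ge500 = pct(unidirectional_ge500),
       pct_below_500 = pct(below_500), pct_failed = pct(failed))
}

#' Species- and specimen-level percentages for split/sharing tallies
#'
#' Printed the way campaign reports do: species percentages to 2 decimals,
#' specimen percentages to 1.
#'
#' @param k_species species in the category; \code{named_species} total named
#'   species.
#' @param m_specimens specimens in the category; \code{total_specimens}
#'   total studied specimens.
#' @return list(species_pct, specimen_pct).
#' @export
split_share_summary <- function(k_species, named_species, m_specimens,
                                total_specimens) {
  list(species_pct = round(100 * k_species / named_species, 2),
       specimen_pct = round(100 * m_specimens / total_specimens, 1))
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "coiaudit")
  if (!nzchar(p)) stop("packaged fixture not found: ", file)
  p
}

#' Published per-family table (transcribed)
#'
#' The campaign's family table: checklist species counts, cluster (BIN)
#' counts, coverage ratios, body-size ranges and dark-taxa percentages for
#' 116 Diptera families. Size ranges are parsed into numeric lo/hi/mid
#' (one printed range, "3-4.5.0", is read as 3.0-4.5).
#'
#' @return data frame with the printed columns plus size_lo, size_hi,
#'   size_mid.
#' @export
diptera_family_table <- function() {
  tab <- utils::read.delim(fixture_path("table1_families.tsv"),
                           stringsAsFactors = FALSE, na.strings = "N/A")
  rng <- tab$size_range_mm
  rng[rng == "3-4.5.0"] <- "3-4.5"
  tab$size_lo <- as.numeric(sub("-.*$", "", rng))
  tab$size_hi <- as.numeric(sub("^.*-", "", rng))
  tab$size_mid <- (tab$size_lo + tab$size_hi) / 2
  tab
}

#' Published cryptic-diversity-candidate table (transcribed)
#'
#' The 122 named species assigned to two or more clusters, with their
#' printed mean and maximum intraspecific divergences (percent) and cluster
#' ids (";"-separated).
#'
#' @return data frame: family, species, cdc_rank, mean_isp, max_isp, bins.
#' @export
cdc_species_table <- function() {
  utils::read.delim(fixture_path("table2_cdc.tsv"), stringsAsFactors = FALSE)
}

#' Published cluster-sharing table (transcribed)
#'
#' Named species sharing a cluster, grouped by the shared cluster id; the
#' lead row of each group carries the printed sharing rank.
#'
#' @return data frame: family, species, bs_rank (NA on member rows),
#'   mean_isp, max_isp, bin.
#' @export
bin_sharing_table <- function() {
  utils::read.delim(fixture_path("table3_bs.tsv"), stringsAsFactors = FALSE,
                    na.strings = c("N/A", ""))
}
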