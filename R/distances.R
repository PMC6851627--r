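# Kimura 2-parameter distances with pairwise deletion, the 500-bp length
# filter, pairwise matrices and nearest-neighbour extraction.
#
# Conventions: sequences must be position-comparable (equal length, e.g. from
# a common alignment). Sites where either base is not a plain A/C/G/T (gaps,
# Ns, ambiguity codes) are deleted pairwise, i.e. only from that comparison.

#' Transition/transversion site counts for one sequence pair
#'
#' @param seq_a,seq_b equal-length nucleotide strings.
#' @return object of class \code{site_counts}: list with \code{n} comparable
#'   sites, \code{s} transitions, \code{v} transversions and the proportions
#'   \code{P = s/n}, \code{Q = v/n}.
#' @export
site_counts <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("sequences differ in length (", nchar(seq_a), " vs ", nchar(seq_b),
         "); input must be position-comparable")
  }
  ea <- enc_acgt(seq_a)
  eb <- enc_acgt(seq_b)
  comp <- !is.na(ea) & !is.na(eb)
  n <- sum(comp)
  if (n == 0L) stop("no comparable sites")
  diff <- comp & (ea != eb)
  # with A=1, C=2, G=3, T=4 the transition pairs (A,G) and (C,T) are exactly
  # those with |code difference| == 2
  s <- sum(diff & abs(ea - eb) == 2L, na.rm = TRUE)
  v <- sum(diff, na.rm = TRUE) - s
  structure(list(n = n, s = s, v = v, P = s / n, Q = v / n),
            class = "site_counts")
}

#' Kimura 2-parameter distance from site counts
#'
#' d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q), in substitutions per site.
#'
#' @param counts a \code{site_counts} object, or any list with P and Q.
#' @return nonnegative numeric distance; zero iff P = Q = 0.
#' @export
k2p <- function(counts) {
  P <- counts$P; Q <- counts$Q
  if ((1 - 2 * P - Q) <= 0 || (1 - 2 * Q) <= 0) {
    stop("saturated pair: K2P distance undefined for P = ", signif(P, 4),
         ", Q = ", signif(Q, 4))
  }
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

#' Uncorrected p-distance from site counts
#'
#' @param counts a \code{site_counts} object.
#' @return (s + v) / n.
#' @export
p_distance <- function(counts) (counts$s + counts$v) / counts$n

#' Pairwise K2P distance matrix with the minimum-length filter
#'
#' Records with fewer than \code{min_len} unambiguous (A/C/G/T) bases are
#' excluded and listed in \code{excluded_ids}; N-padding cannot pass the
#' filter. Saturated pairs (K2P undefined) become NA with a warning, or an
#' error when \code{strict}.
#'
#' @param records sequence-record data frame ([read_fasta()] shape).
#' @param min_len minimum number of unambiguous bases (default 500).
#' @param strict error on saturated pairs instead of recording NA.
#' @return object of class \code{dist_matrix}: list with \code{ids},
#'   symmetric zero-diagonal matrix \code{d}, and \code{excluded_ids}.
#' @export
pairwise_matrix <- function(records, min_len = 500, strict = FALSE) {
  lens <- nchar(records$sequence)
  if (length(unique(lens)) > 1) {
    stop("sequences are not position-comparable (lengths ",
         paste(sort(unique(lens)), collapse = ", "),
         "); align them to a common length first")
  }
  good <- count_unambiguous(records$sequence) >= min_len
  excluded <- records$record_id[!good]
  keep <- records[good, , drop = FALSE]
  if (nrow(keep) < 2) {
    stop("fewer than 2 records survive the ", min_len, "-bp length filter")
  }
  ids <- keep$record_id
  enc <- vapply(keep$sequence, enc_acgt, integer(lens[1]), USE.NAMES = FALSE)
  # enc is L x n; column i is record i
  n_rec <- length(ids)
  d <- matrix(0, n_rec, n_rec, dimnames = list(ids, ids))
  n_sat <- 0L
  for (i in seq_len(n_rec - 1L)) {
    ei <- enc[, i]
    for (j in seq.int(i + 1L, n_rec)) {
      ej <- enc[, j]
      comp <- !is.na(ei) & !is.na(ej)
      n <- sum(comp)
      if (n == 0L) {
        msg <- paste0("no comparable sites between ", ids[i], " and ", ids[j])
        if (strict) stop(msg)
        warning(msg)
        d[i, j] <- d[j, i] <- NA_real_
        next
      }
      dd <- ei[comp] - ej[comp]
      ndiff <- sum(dd != 0L)
      s <- sum(abs(dd) == 2L)
      P <- s / n
      Q <- (ndiff - s) / n
      if ((1 - 2 * P - Q) <= 0 || (1 - 2 * Q) <= 0) {
        if (strict) {
          stop("saturated pair: ", ids[i], " vs ", ids[j])
        }
        n_sat <- n_sat + 1L
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
      }
    }
  }
  if (n_sat > 0L) {
    warning(n_sat, " saturated pair(s) dropped (distance set to NA)")
  }
  structure(list(ids = ids, d = d, excluded_ids = excluded),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("K2P distance matrix over", length(x$ids), "records")
  if (length(x$excluded_ids)) {
    cat(";", length(x$excluded_ids), "excluded by length filter")
  }
  cat("\n")
  invisible(x)
}

#' Write a distance matrix as a square TSV with id header row and column
#'
#' @param dm a \code{dist_matrix}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_dist_matrix <- function(dm, path) {
  tab <- data.frame(id = dm$ids, dm$d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Nearest-neighbour species distances
#'
#' For every species, the minimum distance over all (member, non-member)
#' pairs, with ties broken by the lexicographically smallest neighbour
#' species name.
#'
#' @param dm a \code{dist_matrix}.
#' @param species_of named character vector mapping record id to species
#'   label; every id in the matrix must be present and labelled.
#' @return data frame with species, nn_dist, nn_species.
#' @export
nearest_neighbor <- function(dm, species_of) {
  ids <- dm$ids
  missing_ids <- setdiff(ids, names(species_of))
  if (length(missing_ids)) {
    stop("no species label for record(s): ", paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  sp <- species_of[ids]
  if (anyNA(sp)) stop("NA species label; assign interim names first")
  species <- sort(unique(sp))
  if (length(species) < 2) {
    stop("nearest-neighbour distances need at least 2 species")
  }
  out <- data.frame(species = species, nn_dist = NA_real_,
                    nn_species = NA_character_, stringsAsFactors = FALSE)
  for (k in seq_along(species)) {
    mem <- sp == species[k]
    sub <- dm$d[mem, !mem, drop = FALSE]
    other_sp <- sp[!mem]
    if (all(is.na(sub))) next
    mn <- min(sub, na.rm = TRUE)
    hit_cols <- unique(which(sub == mn, arr.ind = TRUE)[, 2])
    out$nn_dist[k] <- mn
    out$nn_species[k] <- min(other_sp[hit_cols])
  }
  out
}
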