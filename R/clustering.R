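# Haplotype clustering: single-linkage BIN proxy, global-alignment identity,
# greedy centroid (OTU) clustering, and neighbour-joining trees.
#
# The single-linkage threshold of 2.2% K2P is a published seed threshold for
# barcode index clustering; outputs are labelled "cluster" and make no claim
# of equality with proprietary BIN assignments.

#' Single-linkage clusters of a distance matrix
#'
#' Two records share a cluster iff they are connected by a chain of pairs with
#' distance strictly below the threshold. NA distances never connect. Cluster
#' ids are deterministic: clusters sorted by their smallest member id and
#' numbered C000001, C000002, ...
#'
#' @param dm a \code{dist_matrix}.
#' @param threshold linkage threshold (strict \code{<}), default 0.022.
#' @return object of class \code{cluster_assignment}: list with
#'   \code{assignment} (named id -> cluster id), \code{clusters} (cluster id ->
#'   member ids), \code{method}, \code{threshold}.
#' @export
single_linkage_clusters <- function(dm, threshold = 0.022) {
  ids <- dm$ids
  n <- length(ids)
  adj <- !is.na(dm$d) & dm$d < threshold
  diag(adj) <- FALSE
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  members <- split(ids, comp)
  members <- lapply(members, sort)
  members <- members[order(vapply(members, `[`, "", 1L))]
  names(members) <- sprintf("C%06d", seq_along(members))
  assignment <- setNames(rep(names(members), lengths(members)),
                         unlist(members, use.names = FALSE))
  assignment <- assignment[ids]
  structure(list(assignment = assignment, clusters = members,
                 method = "single_linkage", threshold = threshold),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(x$method, "clustering at threshold", x$threshold, "->",
      length(x$clusters), "clusters over", length(x$assignment), "records\n")
  invisible(x)
}

#' Write a cluster assignment as TSV
#'
#' @param ca a \code{cluster_assignment}.
#' @param path output path.
#' @export
write_cluster_assignment <- function(ca, path) {
  tab <- data.frame(record_id = names(ca$assignment),
                    cluster_id = unname(ca$assignment),
                    method = ca$method, threshold = ca$threshold,
                    stringsAsFactors = FALSE)
  write_table(tab, path, "cluster_assignment")
}

IDENT_SUBST <- NULL  # built lazily: nucleotide +1/-1 substitution matrix

ident_subst_matrix <- function() {
  if (is.null(IDENT_SUBST)) {
    m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
    utils::assignInMyNamespace("IDENT_SUBST", m)
  }
  IDENT_SUBST
}

#' Fraction identity under global end-to-end alignment
#'
#' Needleman-Wunsch scores: match +1, mismatch -1, linear gap -2. The identity
#' is matches divided by alignment columns, terminal gap columns included.
#'
#' @param seq_a,seq_b non-empty nucleotide strings (unaligned allowed).
#' @return identity fraction in [0, 1].
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  identity_to_set(seq_a, seq_b)
}

# identity of one subject vs a character vector of patterns (vectorised)
identity_to_set <- function(subject, patterns) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(patterns),
    subject = Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = ident_subst_matrix(),
    gapOpening = 0, gapExtension = 2)
  m <- Biostrings::nmatch(aln)
  mm <- Biostrings::nmismatch(aln)
  # under match +1 / mismatch -1 / linear gap -2 the score determines the
  # gap-column count, so alignment columns come out arithmetically:
  # score = m - mm - 2 g  =>  g = (m - mm - score) / 2
  g <- (m - mm - Biostrings::score(aln)) / 2
  unname(m / (m + mm + g))
}

# ungapped identity for equal-length strings, NA when lengths differ
hamming_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_real_)
  ca <- seq_chars(a); cb <- seq_chars(b)
  sum(ca == cb) / length(ca)
}

#' Greedy centroid-based (OTU) clustering
#'
#' Unique sequences are processed in order of decreasing abundance (ties:
#' lexicographically smaller sequence first). Each is joined to the first
#' existing centroid with identity >= the threshold, else founds a new
#' centroid. OTU ids are assigned in decreasing order of final OTU abundance.
#'
#' @param uniques data frame with columns \code{sequence} and \code{abundance}
#'   (>= 1 each).
#' @param identity_threshold identity needed to join a centroid (default 0.97).
#' @param prefilter if TRUE, equal-length pairs whose ungapped identity
#'   already meets the threshold skip the alignment; results are unchanged,
#'   only faster.
#' @return list with \code{otus}: data frame (otu_id, centroid, abundance,
#'   n_members) and \code{membership}: integer vector mapping each input row
#'   to its otu_id.
#' @export
greedy_centroid_cluster <- function(uniques, identity_threshold = 0.97,
                                    prefilter = FALSE) {
  if (nrow(uniques) == 0) {
    return(list(otus = data.frame(otu_id = character(0), centroid = character(0),
                                  abundance = numeric(0), n_members = integer(0),
                                  stringsAsFactors = FALSE),
                membership = character(0)))
  }
  if (any(uniques$abundance < 1)) stop("abundances must be >= 1")
  ord <- order(-uniques$abundance, uniques$sequence)
  centroids <- character(0)
  cent_enc <- list()                   # cached utf8 encodings for prefilter
  member_of <- integer(nrow(uniques))  # centroid index per input row
  for (r in ord) {
    s <- uniques$sequence[r]
    joined <- 0L
    if (length(centroids)) {
      done <- FALSE
      if (prefilter) {
        se <- utf8ToInt(s)
        L <- length(se)
        for (k in seq_along(centroids)) {
          ce <- cent_enc[[k]]
          if (length(ce) != L) next
          if (sum(se == ce) / L >= identity_threshold) {
            joined <- k; done <- TRUE; break
          }
        }
      }
      if (!done) {
        ident <- identity_to_set(s, centroids)
        hit <- which(ident >= identity_threshold)
        if (length(hit)) joined <- hit[1]
      }
    }
    if (joined == 0L) {
      centroids <- c(centroids, s)
      cent_enc[[length(centroids)]] <- utf8ToInt(s)
      joined <- length(centroids)
    }
    member_of[r] <- joined
  }
  abund <- vapply(seq_along(centroids), function(k)
    sum(uniques$abundance[member_of == k]), numeric(1))
  nmem <- tabulate(member_of, nbins = length(centroids))
  # otu ids in decreasing abundance, ties by lexicographic centroid
  rank_ord <- order(-abund, centroids)
  otu_ids <- character(length(centroids))
  otu_ids[rank_ord] <- sprintf("OTU%06d", seq_along(centroids))
  list(
    otus = data.frame(otu_id = otu_ids[rank_ord],
                      centroid = centroids[rank_ord],
                      abundance = abund[rank_ord],
                      n_members = nmem[rank_ord],
                      stringsAsFactors = FALSE),
    membership = otu_ids[member_of]
  )
}
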