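# Independent oracles used to freeze expected values: brute-force site
# enumeration, exhaustive alignment enumeration for tiny strings, and the
# closed-form Pearson formula.

# per-position site counting by explicit loop (pairwise deletion)
oracle_site_counts <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  n <- s <- v <- 0L
  for (i in seq_along(ca)) {
    if (!(ca[i] %in% c("A", "C", "G", "T"))) next
    if (!(cb[i] %in% c("A", "C", "G", "T"))) next
    n <- n + 1L
    if (ca[i] == cb[i]) next
    pair <- sort(c(ca[i], cb[i]))
    if (identical(pair, c("A", "G")) || identical(pair, c("C", "T"))) {
      s <- s + 1L
    } else {
      v <- v + 1L
    }
  }
  list(n = n, s = s, v = v)
}

# K2P from a site-count triple (closed form, written independently)
oracle_k2p <- function(n, s, v) {
  P <- s / n; Q <- v / n
  -1 / 2 * log(1 - 2 * P - Q) - 1 / 4 * log(1 - 2 * Q)
}

# all global alignments of two tiny strings; returns the set of
# matches/columns identities achieved by maximum-score alignments under
# match +1 / mismatch -1 / gap -2
oracle_identity_set <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  res <- list()
  rec <- function(i, j, score, matches, cols) {
    if (i > length(ca) && j > length(cb)) {
      res[[length(res) + 1]] <<- c(score = score, ident = matches / cols)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      m <- ca[i] == cb[j]
      rec(i + 1, j + 1, score + ifelse(m, 1, -1), matches + m, cols + 1)
    }
    if (i <= length(ca)) rec(i + 1, j, score - 2, matches, cols + 1)
    if (j <= length(cb)) rec(i, j + 1, score - 2, matches, cols + 1)
  }
  rec(1, 1, 0, 0, 0)
  tab <- do.call(rbind, res)
  best <- max(tab[, "score"])
  sort(unique(round(tab[tab[, "score"] == best, "ident"], 12)))
}

# product-moment correlation straight from the definition
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# transitive closure single-linkage by repeated sweeps (no BFS shortcuts)
oracle_single_linkage <- function(d, threshold) {
  n <- nrow(d)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && !is.na(d[i, j]) && d[i, j] < threshold &&
            comp[j] != comp[i]) {
          old <- comp[j]
          comp[comp == old] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# random gapless test records of a given length
random_records <- function(n, len, seed = 1) {
  set.seed(seed)
  data.frame(
    record_id = sprintf("R%03d", seq_len(n)),
    order = "Diptera", family = "Testidae", genus = "Testus",
    species = sprintf("Testus sp%02d", seq_len(n)),
    cluster_id = NA_character_,
    sequence = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      character(1)),
    stringsAsFactors = FALSE)
}

# wrap plain sequences as a records data frame
as_records <- function(seqs, species = NULL, cluster = NULL, family = "Testidae") {
  n <- length(seqs)
  data.frame(
    record_id = names(seqs) %||% sprintf("R%03d", seq_len(n)),
    order = "Diptera", family = family, genus = "Testus",
    species = species %||% sprintf("Testus sp%02d", seq_len(n)),
    cluster_id = cluster %||% NA_character_,
    sequence = unname(seqs), stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small simulated library shared by several tests (built once per run)
tiny_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fams <- data.frame(
        name = c("Phoridae", "Syrphidae"),
        infraorder = c("Brachycera", "Brachycera"),
        n_species = c(12L, 10L), size_lo = c(0.5, 3.5),
        size_hi = c(6, 35), dark_fraction = c(0.5, 0.1),
        stringsAsFactors = FALSE)
      cfg <- library_sim_config(seed = 11, families = fams,
                                split_fraction = 0.1, merge_fraction = 0.1)
      cache <<- simulate_library(cfg)
    }
    cache
  }
})
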