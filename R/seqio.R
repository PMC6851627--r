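# Readers and writers for every external format the analyses touch.
#
# Sequence records travel as plain data frames with one row per record and
# columns: record_id, order, family, genus, species, cluster_id, sequence.
# Unnamed ("dark") records carry NA in the species column; taxonomy ranks
# that were never assigned are NA as well.

RECORD_COLS <- c("record_id", "order", "family", "genus", "species",
                 "cluster_id", "sequence")

#' Read a FASTA reference library
#'
#' Headers use the pipe dialect
#' \code{id|order|family|genus|species|cluster_id}; segments beyond the id are
#' optional and empty segments mean "not assigned". A bare \code{>id} header is
#' accepted. Sequences are uppercased; order is preserved.
#'
#' @param path path to a FASTA file.
#' @return data frame of sequence records (zero rows for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(empty_records())
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) return(empty_records())
  seqs <- toupper(as.character(set))
  headers <- names(set)
  fields <- strsplit(headers, "|", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- which(n_fields > 6 | !nzchar(vapply(fields, `[`, "", 1L)))
  if (length(bad)) {
    stop("malformed FASTA header at record ", bad[1], ": '", headers[bad[1]], "'")
  }
  grab <- function(i) {
    x <- vapply(fields, function(f) if (length(f) >= i) f[i] else "", character(1))
    x <- trimws(x)
    x[!nzchar(x)] <- NA_character_
    x
  }
  rec <- data.frame(
    record_id = grab(1), order = grab(2), family = grab(3),
    genus = grab(4), species = grab(5), cluster_id = grab(6),
    sequence = unname(seqs), stringsAsFactors = FALSE
  )
  if (anyDuplicated(rec$record_id)) {
    stop("duplicate record id: ", rec$record_id[duplicated(rec$record_id)][1])
  }
  if (any(!nzchar(rec$sequence))) {
    stop("empty sequence for record ", rec$record_id[!nzchar(rec$sequence)][1])
  }
  check_alphabet(rec$sequence)
  rec
}

empty_records <- function() {
  as.data.frame(setNames(rep(list(character(0)), length(RECORD_COLS)), RECORD_COLS),
                stringsAsFactors = FALSE)
}

#' Write sequence records as FASTA in the pipe-header dialect
#'
#' @param records data frame as returned by [read_fasta()].
#' @param path output path.
#' @param width line width for the sequence (default one line per record).
#' @return invisibly, the path.
#' @export
write_fasta <- function(records, path, width = Inf) {
  hdr <- function(i) {
    tax <- vapply(c("order", "family", "genus", "species", "cluster_id"),
                  function(col) {
                    v <- records[[col]][i]
                    if (is.na(v)) "" else v
                  }, character(1))
    paste0(">", paste(c(records$record_id[i], tax), collapse = "|"))
  }
  lines <- character(0)
  for (i in seq_len(nrow(records))) {
    s <- records$sequence[i]
    if (is.finite(width) && nchar(s) > width) {
      s <- substring(s, seq(1, nchar(s), width), pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
    }
    lines <- c(lines, hdr(i), s)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a pair of FASTQ files as paired-end reads
#'
#' Phred offset is fixed at 33. Mate ids must pair up after stripping a
#' trailing \code{/1}, \code{/2} or anything following the first space.
#'
#' @param path_fwd,path_rev FASTQ files for the forward and reverse mates.
#' @param sample_id sample the reads belong to.
#' @return data frame with columns read_id, forward_seq, reverse_seq,
#'   forward_qual, reverse_qual (list columns of integer Phred scores) and
#'   sample_id, in file order.
#' @export
read_fastq_pairs <- function(path_fwd, path_rev, sample_id) {
  read_one <- function(p) {
    # Biostrings warns about dropping its own metadata columns here; benign
    suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(p, quality.scoring = "phred"))
  }
  fwd <- read_one(path_fwd)
  rev <- read_one(path_rev)
  if (length(fwd) != length(rev)) {
    stop("mate files differ in record count at index ",
         min(length(fwd), length(rev)) + 1L,
         " (forward has ", length(fwd), ", reverse has ", length(rev), ")")
  }
  strip <- function(ids) sub("[/ ].*$", "", ids)
  idf <- strip(names(fwd)); idr <- strip(names(rev))
  mism <- which(idf != idr)
  if (length(mism)) {
    stop("mate ids do not pair up at record ", mism[1], ": '",
         idf[mism[1]], "' vs '", idr[mism[1]], "'")
  }
  qual_ints <- function(x) {
    lapply(suppressWarnings(as.character(Biostrings::quality(x))), phred_to_int)
  }
  data.frame(
    read_id = idf,
    forward_seq = suppressWarnings(as.character(fwd)),
    reverse_seq = suppressWarnings(as.character(rev)),
    forward_qual = I(qual_ints(fwd)), reverse_qual = I(qual_ints(rev)),
    sample_id = sample_id, stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write paired reads as two Phred-33 FASTQ files
#'
#' @param pairs data frame shaped like the result of [read_fastq_pairs()].
#' @param path_fwd,path_rev output paths for the two mates.
#' @return invisibly, c(path_fwd, path_rev).
#' @export
write_fastq_pair <- function(pairs, path_fwd, path_rev) {
  emit <- function(ids, seqs, quals, suffix, path) {
    qs <- vapply(quals, int_to_phred, character(1))
    if (any(nchar(qs) != nchar(seqs))) {
      stop("sequence/quality length mismatch at record ",
           which(nchar(qs) != nchar(seqs))[1])
    }
    lines <- as.vector(rbind(paste0("@", ids, suffix), seqs, "+", qs))
    writeLines(lines, path)
  }
  emit(pairs$read_id, pairs$forward_seq, pairs$forward_qual, "/1", path_fwd)
  emit(pairs$read_id, pairs$reverse_seq, pairs$reverse_qual, "/2", path_rev)
  invisible(c(path_fwd, path_rev))
}

# fixed column orders for every named table schema
TABLE_SCHEMAS <- list(
  audit = c("species", "family", "n_specimens", "mean_isp", "max_isp",
            "nn_dist", "nn_species", "n_clusters", "status", "band"),
  otu_table = c("otu_id", "cluster_id", "identity", "family", "genus",
                "species", "centroid"),
  family_summary = c("family", "infraorder", "species_reported", "n_clusters",
                     "ratio_barcoded", "size_lo", "size_hi", "size_mid",
                     "taxa_with_barcode", "unnamed_with_barcode", "pct_dark"),
  presence_absence = c("cluster_id"),
  cluster_assignment = c("record_id", "cluster_id", "method", "threshold"),
  ledger = c("stage", "sample_id", "n_in", "n_kept", "n_removed"),
  manifest = c("sample_id", "site", "date_start", "date_end",
               "path_fwd", "path_rev")
)

#' Write a table under a fixed, named schema
#'
#' Tables are tab-separated UTF-8 with a header row and a deterministic column
#' order. Schemas \code{otu_table} and \code{presence_absence} allow extra
#' per-sample count columns after the fixed prefix.
#'
#' @param rows data frame to write.
#' @param path output path.
#' @param schema_name one of \code{names(coiaudit:::TABLE_SCHEMAS)}.
#' @return invisibly, the path.
#' @export
write_table <- function(rows, path, schema_name) {
  cols <- TABLE_SCHEMAS[[schema_name]]
  if (is.null(cols)) stop("unknown table schema: ", schema_name)
  open <- schema_name %in% c("otu_table", "presence_absence")
  missing_cols <- setdiff(cols, names(rows))
  if (length(missing_cols)) {
    stop("schema '", schema_name, "' requires column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(rows), cols)
  if (length(extra) && !open) {
    stop("schema '", schema_name, "' does not allow column(s): ",
         paste(extra, collapse = ", "))
  }
  rows <- rows[, c(cols, extra), drop = FALSE]
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a table previously written with [write_table()]
#'
#' @param path file to read.
#' @param schema_name schema the file must conform to.
#' @return data frame.
#' @export
read_table <- function(path, schema_name) {
  cols <- TABLE_SCHEMAS[[schema_name]]
  if (is.null(cols)) stop("unknown table schema: ", schema_name)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(cols %in% names(tab))) {
    stop("file does not match schema '", schema_name, "': ", path)
  }
  tab
}

#' Read a sample manifest TSV
#'
#' @param path manifest file with columns sample_id, site, date_start,
#'   date_end, path_fwd, path_rev.
#' @return data frame; errors on duplicated sample ids.
#' @export
read_manifest <- function(path) {
  man <- read_table(path, "manifest")
  if (anyDuplicated(man$sample_id)) {
    stop("duplicate sample_id in manifest: ",
         man$sample_id[duplicated(man$sample_id)][1])
  }
  man
}

#' @rdname read_manifest
#' @param manifest data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  write_table(manifest, path, "manifest")
}
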