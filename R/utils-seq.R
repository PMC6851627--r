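# Low-level nucleotide helpers shared across modules.

IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

# bitmask encoding: A=1, C=2, G=4, T=8; ambiguity codes are unions
IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L, `-` = 0L)

IUPAC_COMP <- c(A = "T", C = "G", G = "C", T = "A",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-")

#' Reverse complement of IUPAC nucleotide strings
#'
#' @param x character vector of nucleotide strings (IUPAC codes and gaps
#'   allowed; case-insensitive, returned uppercase).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  comp <- chartr(paste(names(IUPAC_COMP), collapse = ""),
                 paste(IUPAC_COMP, collapse = ""), x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# split a sequence string into a character vector of bases
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# encode ACGT as 1..4, anything else (gap, N, ambiguity) as NA
ACGT_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)
enc_acgt <- function(s) {
  unname(ACGT_CODE[seq_chars(toupper(s))])
}

# encode with IUPAC bitmasks (unknown characters error)
enc_bits <- function(s) {
  ch <- seq_chars(toupper(s))
  bad <- !(ch %in% names(IUPAC_BITS))
  if (any(bad)) {
    stop("invalid nucleotide character(s): ",
         paste(unique(ch[bad]), collapse = ", "))
  }
  unname(IUPAC_BITS[ch])
}

check_alphabet <- function(s, what = "sequence") {
  ch <- unique(seq_chars(toupper(paste(s, collapse = ""))))
  bad <- setdiff(ch, IUPAC_CHARS)
  if (length(bad)) {
    stop(what, " contains non-IUPAC character(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

# number of unambiguous (A/C/G/T) bases in each sequence
count_unambiguous <- function(seqs) {
  vapply(seqs, function(s) sum(!is.na(enc_acgt(s))), integer(1), USE.NAMES = FALSE)
}

#' Decode a Phred-33 quality string to integer scores
#'
#' @param q character scalar (one quality string per call).
#' @return integer vector of Phred scores.
#' @export
phred_to_int <- function(q) {
  if (!nzchar(q)) return(integer(0))
  utf8ToInt(q) - 33L
}

#' Encode integer Phred scores as a Phred-33 quality string
#'
#' @param scores integer vector of Phred scores (>= 0).
#' @return character scalar.
#' @export
int_to_phred <- function(scores) {
  if (!length(scores)) return("")
  if (any(scores < 0L)) stop("Phred scores must be >= 0")
  intToUtf8(as.integer(scores) + 33L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
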