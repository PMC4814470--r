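#' @useDynLib spacerscope, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Integer encoding used throughout: A=1, C=2, G=3, T=4, anything else 0.
# Code 0 never matches (so N in a target is always a mismatch).
.CODE <- local({
  x <- integer(256L)
  x[utf8ToInt("A")] <- 1L; x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L; x[utf8ToInt("T")] <- 4L
  x[utf8ToInt("a")] <- 1L; x[utf8ToInt("c")] <- 2L
  x[utf8ToInt("g")] <- 3L; x[utf8ToInt("t")] <- 4L
  x
})
.BASES <- c("A", "C", "G", "T")

encode_seq <- function(x) .CODE[utf8ToInt(x)]

# n sequences of one common length -> n x L integer matrix
encode_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences must all have the same length")
  matrix(.CODE[utf8ToInt(paste(seqs, collapse = ""))],
         nrow = length(seqs), ncol = L, byrow = TRUE)
}

decode_seq <- function(codes) {
  if (any(codes < 1L | codes > 4L)) stop("cannot decode ambiguous base code")
  paste(.BASES[codes], collapse = "")
}

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings
#' (alphabet ACGTN, case-insensitive; N maps to N).
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Hamming distance between two equal-length DNA strings
#'
#' @param a,b DNA strings of equal length.
#' @return Integer number of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming() requires equal-length strings")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Generate random DNA sequences
#'
#' Uniform iid sequences over {A,C,G,T}; uses the current RNG state.
#'
#' @param n Number of sequences.
#' @param len Length of each sequence (recycled to `n`).
#' @return Character vector of `n` sequences.
#' @export
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(L)
    paste(sample(.BASES, L, replace = TRUE), collapse = ""), character(1))
}

# iid substitutions at rate `rate`; substituted base is uniform over the
# three alternatives
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  if (length(hit)) {
    v[hit] <- vapply(v[hit], function(b)
      sample(setdiff(.BASES, b), 1L), character(1))
    seq <- paste(v, collapse = "")
  }
  seq
}

assert_acgt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad))
    stop(sprintf("%s contains non-ACGT characters (first offender: %s)",
                 what, x[which(bad)[1L]]))
  invisible(x)
}

# round half away from zero (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)
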