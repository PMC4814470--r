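#' Scan target sequences for protospacers
#'
#' Exhaustive full-length ungapped scan: every window of each target (both
#' strands) whose Hamming distance to a query is at most `max_mismatch` is
#' reported as a hit. With the default `max_mismatch = 4`, windows at 5 or
#' more mismatches are excluded (the "< 5 mismatches" positivity rule).
#' Eight nucleotides upstream and downstream of each protospacer are
#' extracted in the protospacer's own orientation (downstream = 3' of the
#' protospacer on its strand); flanks truncated by a contig edge are
#' reported shorter and flagged.
#'
#' @param queries Named character vector of query spacer sequences (ACGT,
#'   length >= 20), or a data frame with `id` and `sequence` columns
#'   (`spacer_clusters` consensuses work via `cluster_id`/`consensus`).
#' @param targets Named character vector of target sequences, a
#'   [Biostrings::DNAStringSet], or a FASTA path. Ns in targets never match.
#' @param max_mismatch Maximum Hamming distance for a hit (default 4).
#' @param flank Flank width to extract (default 8).
#' @return Data frame of class `protospacer_hits`: `query`, `target`,
#'   `start`, `end` (0-based half-open plus-strand target coordinates),
#'   `strand`, `mismatches`, `upstream_flank`, `downstream_flank`,
#'   `flank_complete`.
#' @export
scan_protospacers <- function(queries, targets, max_mismatch = 4L,
                              flank = 8L) {
  q <- .as_query_set(queries)
  tg <- .as_target_set(targets)
  short <- nchar(q) < 20L
  if (any(short))
    stop(sprintf("query shorter than 20 nt rejected: %s",
                 paste(names(q)[short], collapse = ", ")))
  assert_acgt(q, "query")

  rows <- list()
  for (tn in names(tg)) {
    tseq <- tg[[tn]]
    enc_t <- encode_seq(tseq)
    tlen <- nchar(tseq)
    for (qn in names(q)) {
      qs <- q[[qn]]
      qlen <- nchar(qs)
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") qs else revcomp(qs)
        mm <- mismatch_scan_cpp(enc_t, encode_seq(pat))
        hit <- which(mm <= max_mismatch)
        for (h in hit) {
          s0 <- h - 1L                      # 0-based window start
          e0 <- s0 + qlen
          fl <- .extract_flanks(tseq, tlen, s0, e0, strand, flank)
          rows[[length(rows) + 1L]] <- data.frame(
            query = qn, target = tn, start = s0, end = e0,
            strand = strand, mismatches = mm[h],
            upstream_flank = fl$up, downstream_flank = fl$down,
            flank_complete = fl$complete, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(0), target = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               mismatches = integer(0), upstream_flank = character(0),
               downstream_flank = character(0), flank_complete = logical(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$target, out$start, out$strand, out$query), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protospacer_hits", "data.frame")
  out
}

.as_query_set <- function(queries) {
  if (is.data.frame(queries)) {
    ids <- if ("id" %in% names(queries)) queries$id else queries$cluster_id
    seqs <- if ("sequence" %in% names(queries)) queries$sequence
            else queries$consensus
    return(stats::setNames(seqs, ids))
  }
  if (is.null(names(queries)))
    names(queries) <- sprintf("query%03d", seq_along(queries))
  queries
}

.as_target_set <- function(targets) {
  if (methods::is(targets, "DNAStringSet"))
    return(stats::setNames(as.character(targets), names(targets)))
  if (is.character(targets) && length(targets) == 1L && file.exists(targets)) {
    x <- Biostrings::readDNAStringSet(targets)
    return(stats::setNames(as.character(x), sub("\\s.*$", "", names(x))))
  }
  if (is.null(names(targets)))
    names(targets) <- sprintf("target%03d", seq_along(targets))
  toupper(targets)
}

# flanks in protospacer orientation; 0-based half-open window [s0, e0)
.extract_flanks <- function(tseq, tlen, s0, e0, strand, flank) {
  left <- substr(tseq, max(s0 - flank, 0L) + 1L, s0)
  right <- substr(tseq, e0 + 1L, min(e0 + flank, tlen))
  if (strand == "+") {
    up <- left; down <- right
  } else {
    up <- revcomp(right); down <- revcomp(left)
  }
  list(up = up, down = down,
       complete = nchar(up) == flank && nchar(down) == flank)
}

#' Position base-count profile of protospacer flanks
#'
#' Aligns the (complete) 8-nt flanks of a hit set on the chosen side of the
#' protospacer and tallies base counts per position; per-position
#' information content is `IC_j = 2 + sum_b p_bj log2 p_bj` (bits, no
#' small-sample correction). Positions are numbered 1..flank away from the
#' protospacer: for downstream flanks position 1 is adjacent, for upstream
#' flanks position 1 is the base immediately 5' of the protospacer.
#'
#' @param hits `protospacer_hits` data frame (or any data frame with
#'   `upstream_flank`/`downstream_flank` and `flank_complete` columns).
#' @param side `"downstream"` (default) or `"upstream"`.
#' @param flank Flank width (default 8).
#' @return List of class `pam_profile`: `side`, `counts` (4 x flank base
#'   count matrix, rows A,C,G,T), `information_content` (bits per
#'   position), `n_hits`.
#' @export
pam_profile <- function(hits, side = c("downstream", "upstream"),
                        flank = 8L) {
  side <- match.arg(side)
  col <- paste0(side, "_flank")
  fl <- hits[[col]][hits$flank_complete & !grepl("[^ACGT]", hits[[col]])]
  if (length(fl) < 2L) stop("insufficient hits: need >= 2 complete flanks")
  if (side == "upstream") {
    # orient so that position 1 is adjacent to the protospacer
    fl <- vapply(fl, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
                 USE.NAMES = FALSE)
  }
  M <- encode_matrix(fl)
  counts <- matrix(0L, nrow = 4L, ncol = ncol(M),
                   dimnames = list(c("A", "C", "G", "T"),
                                   paste0("pos", seq_len(ncol(M)))))
  for (b in 1:4) counts[b, ] <- colSums(M == b)
  p <- sweep(counts, 2L, colSums(counts), "/")
  ic <- apply(p, 2L, function(v) 2 + sum(ifelse(v > 0, v * log2(v), 0)))
  structure(list(side = side, counts = counts,
                 information_content = unname(ic),
                 n_hits = length(fl)),
            class = "pam_profile")
}

#' @export
print.pam_profile <- function(x, ...) {
  cat(sprintf("PAM profile (%s, %d flanks)\n", x$side, x$n_hits))
  print(x$counts)
  cat("IC (bits):", paste(sprintf("%.2f", x$information_content),
                          collapse = " "), "\n")
  invisible(x)
}

#' Call a PAM motif from a flank profile
#'
#' Per position, emits the modal base when the information content reaches
#' `ic_min` and the modal base fraction reaches `consensus_fraction`, and N
#' otherwise. Leading and trailing Ns are retained so that the offsets of
#' the conserved positions remain readable (e.g. `NNAAAGNN`).
#'
#' @param profile A `pam_profile`.
#' @param ic_min Minimum information content in bits (default 0.5).
#' @param consensus_fraction Minimum modal base fraction (default 0.5).
#' @return Motif string over {A,C,G,T,N}, one character per flank position.
#' @export
call_pam <- function(profile, ic_min = 0.5, consensus_fraction = 0.5) {
  counts <- profile$counts
  ic <- profile$information_content
  vapply(seq_len(ncol(counts)), function(j) {
    tot <- sum(counts[, j])
    b <- which.max(counts[, j])
    if (ic[j] >= ic_min && counts[b, j] / tot >= consensus_fraction)
      rownames(counts)[b] else "N"
  }, character(1)) |> paste(collapse = "")
}
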