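#' Find CRISPR arrays anchored on a known repeat
#'
#' Locates full-length repeat occurrences on both strands (Hamming distance
#' to the supplied repeat at most `max_mismatch`) and chains consecutive
#' same-strand occurrences whose inter-repeat gaps fall within the spacer
#' length bounds. Maximal chains with at least `min_spacers` spacers are
#' emitted; spacers are reported in array order, oriented to the repeat
#' strand.
#'
#' @param genome Named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or a FASTA path.
#' @param repeat_seq Repeat sequence, 23-47 nt.
#' @param max_mismatch Repeat occurrence mismatch tolerance (default 5).
#' @param spacer_bounds Inclusive spacer length bounds (default `c(26, 50)`).
#' @param min_spacers Minimum spacers per array (default 3).
#' @return List of `crispr_array` objects: `target_id`, `start`, `end`
#'   (0-based half-open), `repeat_consensus`, `repeat_instances` (data
#'   frame: start, end, mismatches), `spacers` (oriented to the repeat
#'   strand), `orientation` (`+`/`-`).
#' @export
find_arrays_with_repeat <- function(genome, repeat_seq, max_mismatch = 5L,
                                    spacer_bounds = c(26L, 50L),
                                    min_spacers = 3L) {
  if (nchar(repeat_seq) < 23L || nchar(repeat_seq) > 47L)
    stop("repeat length must be within 23-47 nt")
  assert_acgt(repeat_seq, "repeat")
  tg <- .as_target_set(genome)
  arrays <- list()
  for (tn in names(tg)) {
    tseq <- tg[[tn]]
    enc_t <- encode_seq(tseq)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") repeat_seq else revcomp(repeat_seq)
      mm <- mismatch_scan_cpp(enc_t, encode_seq(pat))
      pos <- which(mm <= max_mismatch) - 1L        # 0-based starts
      if (length(pos) < 2L) next
      pos <- .greedy_nonoverlap(pos, mm[pos + 1L], nchar(repeat_seq))
      arrays <- c(arrays,
                  .chain_occurrences(tseq, tn, strand, pos,
                                     mm[pos + 1L], repeat_seq,
                                     spacer_bounds, min_spacers))
    }
  }
  arrays
}

# non-overlapping occurrence selection by (mismatches, position)
.greedy_nonoverlap <- function(pos, mm, width) {
  ord <- order(mm, pos)
  sel <- integer(0)
  for (i in ord) {
    if (!length(sel) ||
        all(pos[i] + width <= pos[sel] | pos[sel] + width <= pos[i]))
      sel <- c(sel, i)
  }
  sort(pos[sel])
}

.chain_occurrences <- function(tseq, tn, strand, pos, mm, repeat_seq,
                               spacer_bounds, min_spacers) {
  rlen <- nchar(repeat_seq)
  gaps <- diff(pos) - rlen
  in_bounds <- gaps >= spacer_bounds[1L] & gaps <= spacer_bounds[2L]
  # maximal runs of in-bound gaps
  runs <- rle(in_bounds)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (r in seq_along(runs$values)) {
    if (!runs$values[r] || runs$lengths[r] < min_spacers) next
    gi <- starts[r]:ends[r]                  # gap indices of this run
    occ <- gi[1L]:(gi[length(gi)] + 1L)      # repeat occurrence indices
    sp <- substr(rep(tseq, length(gi)),
                 pos[occ[-length(occ)]] + rlen + 1L, pos[occ[-1L]])
    if (strand == "-") sp <- rev(revcomp(sp))
    out[[length(out) + 1L]] <- structure(list(
      target_id = tn,
      start = pos[occ[1L]],
      end = pos[occ[length(occ)]] + rlen,
      repeat_consensus = repeat_seq,
      repeat_instances = data.frame(start = pos[occ],
                                    end = pos[occ] + rlen,
                                    mismatches = mm[occ]),
      spacers = sp,
      orientation = strand), class = "crispr_array")
  }
  out
}

#' @export
print.crispr_array <- function(x, ...) {
  cat(sprintf("CRISPR array on %s [%d, %d) strand %s: %d repeats, %d spacers\n",
              x$target_id, x$start, x$end, x$orientation,
              nrow(x$repeat_instances), length(x$spacers)))
  invisible(x)
}

#' De novo CRISPR array detection
#'
#' Minimal seed-and-extend detector honouring the structural constraints of
#' a CRISPR array: repeat length 23-47 nt, spacer length within
#' `spacer_bounds`, at least `min_spacers` spacers. Exact k-mers occurring
#' at least `min_spacers + 1` times with consecutive inter-occurrence
#' distances within [repeat_min + spacer_min, repeat_max + spacer_max] seed
#' candidate repeats, which are extended left and right by majority vote
#' across instances while column agreement stays at or above 70% (capped at
#' 47 nt). Candidates are validated by running the anchored finder with the
#' extended consensus; overlapping arrays are resolved in favour of most
#' repeat instances, then longest repeat. Orientation is reported as
#' `"unknown"` (the repeat's strand cannot be inferred without external
#' information).
#'
#' @param genome Named character vector, DNAStringSet, or FASTA path.
#' @param k Seed k-mer length (default 13).
#' @param spacer_bounds Inclusive spacer length bounds (default `c(26, 50)`).
#' @param repeat_bounds Inclusive repeat length bounds (default `c(23, 47)`).
#' @param min_spacers Minimum spacers per array (default 3).
#' @param max_mismatch Mismatch tolerance for validating repeat instances
#'   against the extended consensus (default 5).
#' @param agreement Minimum column agreement during extension (default 0.7).
#' @param trim_agreement After extension, edge columns whose agreement falls
#'   below this value are trimmed back (boundary refinement; default 0.9).
#' @return List of `crispr_array` objects (orientation `"unknown"`).
#' @export
find_arrays_denovo <- function(genome, k = 13L,
                               spacer_bounds = c(26L, 50L),
                               repeat_bounds = c(23L, 47L),
                               min_spacers = 3L, max_mismatch = 5L,
                               agreement = 0.7, trim_agreement = 0.9) {
  tg <- .as_target_set(genome)
  arrays <- list()
  gap_lo <- repeat_bounds[1L] + spacer_bounds[1L]
  gap_hi <- repeat_bounds[2L] + spacer_bounds[2L]
  for (tn in names(tg)) {
    tseq <- tg[[tn]]
    tlen <- nchar(tseq)
    if (tlen < 1000L) stop("de novo detection requires a genome of >= 1 kb")
    kmers <- substring(tseq, 1:(tlen - k + 1L), k:tlen)
    occ <- split(0:(tlen - k), kmers)                  # 0-based positions
    occ <- occ[lengths(occ) >= min_spacers + 1L]
    occ <- occ[!grepl("[^ACGT]", names(occ))]
    cands <- list()
    claimed <- rep(FALSE, tlen)          # genome span already explained
    # deterministic order: by first occurrence position
    occ <- occ[order(vapply(occ, min, numeric(1)))]
    for (km in names(occ)) {
      p <- occ[[km]]
      dp <- diff(p)
      if (any(dp < gap_lo) || any(dp > gap_hi)) next
      if (any(claimed[p + 1L])) next
      cons <- .extend_repeat(tseq, p, k, repeat_bounds[2L], agreement,
                             trim_agreement)
      if (nchar(cons$seq) < repeat_bounds[1L]) next
      found <- find_arrays_with_repeat(stats::setNames(tseq, tn), cons$seq,
                                       max_mismatch = max_mismatch,
                                       spacer_bounds = spacer_bounds,
                                       min_spacers = min_spacers)
      for (a in found) {
        a$orientation <- "unknown"
        cands[[length(cands) + 1L]] <- a
        claimed[(a$start + 1L):a$end] <- TRUE
      }
    }
    arrays <- c(arrays, .resolve_overlaps(cands))
  }
  arrays
}

# extend the seed across instances by majority vote; stop when column
# agreement drops below `agreement` or the repeat reaches max_len, then
# trim edge columns whose agreement is below `trim_agreement` (boundary
# refinement against chance extension into the spacers)
.extend_repeat <- function(tseq, starts, k, max_len, agreement,
                           trim_agreement) {
  tlen <- nchar(tseq)
  column <- function(off) {
    i <- starts + off + 1L                  # 1-based column positions
    i <- i[i >= 1L & i <= tlen]
    substring(tseq, i, i)
  }
  col_agree <- function(off) {
    cc <- column(off)
    if (length(cc) < length(starts)) return(0)
    max(table(cc)) / length(cc)
  }
  left <- 0L; right <- k - 1L               # offsets relative to seed start
  repeat {
    if (right - left + 1L >= max_len) break
    ext <- FALSE
    for (side in c("right", "left")) {
      off <- if (side == "right") right + 1L else left - 1L
      if (col_agree(off) >= agreement) {
        if (side == "right") right <- off else left <- off
        ext <- TRUE
        if (right - left + 1L >= max_len) break
      }
    }
    if (!ext) break
  }
  while (right > left && col_agree(right) < trim_agreement) right <- right - 1L
  while (left < right && col_agree(left) < trim_agreement) left <- left + 1L
  cons <- vapply(left:right, function(off) {
    tab <- sort(table(column(off)), decreasing = TRUE)
    names(tab)[1L]
  }, character(1))
  list(seq = paste(cons, collapse = ""), left = left, right = right)
}

# keep, among overlapping arrays, the one with most repeat instances then
# longest repeat (then leftmost for determinism)
.resolve_overlaps <- function(cands) {
  if (length(cands) < 2L) return(cands)
  n_inst <- vapply(cands, function(a) nrow(a$repeat_instances), integer(1))
  rep_len <- vapply(cands, function(a) nchar(a$repeat_consensus), integer(1))
  starts <- vapply(cands, `[[`, numeric(1), "start")
  ord <- order(-n_inst, -rep_len, starts)
  kept <- list()
  for (i in ord) {
    a <- cands[[i]]
    clash <- any(vapply(kept, function(b)
      b$target_id == a$target_id && a$start < b$end && b$start < a$end,
      logical(1)))
    if (!clash) kept[[length(kept) + 1L]] <- a
  }
  kept[order(vapply(kept, `[[`, numeric(1), "start"))]
}
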