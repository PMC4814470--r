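#' Quality-trim amplicon reads
#'
#' Trims 3' bases until the terminal base quality reaches `min_quality`,
#' discards reads that still contain ambiguous bases (N) after trimming,
#' and discards reads shorter than `min_length`. Kept/dropped counts are
#' recorded in the returned `stats`.
#'
#' @param reads A FASTQ path (Phred+33), a
#'   [Biostrings::QualityScaledDNAStringSet], or a character vector of read
#'   sequences (then `qualities` must be supplied).
#' @param qualities Character vector of Phred+33 quality strings, only when
#'   `reads` is a plain character vector.
#' @param min_quality Minimum terminal base quality (default 20).
#' @param min_length Minimum read length after trimming (default 50).
#' @return List of class `trimmed_reads`: `sequences` and `qualities`
#'   (named character vectors of kept reads) and `stats`
#'   (input / dropped_n / dropped_short / kept counts).
#' @export
trim_reads <- function(reads, qualities = NULL, min_quality = 20L,
                       min_length = 50L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    x <- .read_fastq_checked(reads)
    reads <- x$sequences
    qualities <- x$qualities
  } else if (methods::is(reads, "QualityScaledDNAStringSet")) {
    qualities <- as.character(methods::slot(reads, "quality"))
    reads <- as.character(reads)
  } else if (is.null(qualities)) {
    stop("qualities must be supplied when reads are given as plain sequences")
  }
  if (length(reads) != length(qualities))
    stop("reads and qualities differ in length")

  n_in <- length(reads)
  keep_len <- integer(n_in)
  for (i in seq_len(n_in)) {
    q <- utf8ToInt(qualities[[i]]) - 33L
    j <- length(q)
    while (j > 0L && q[j] < min_quality) j <- j - 1L
    keep_len[i] <- j
  }
  seqs <- substr(reads, 1L, keep_len)
  quals <- substr(qualities, 1L, keep_len)
  has_n <- grepl("[^ACGTacgt]", seqs) & nzchar(seqs)
  short <- !has_n & keep_len < min_length
  keep <- !has_n & !short
  out <- list(sequences = toupper(seqs[keep]), qualities = quals[keep],
              stats = list(input = n_in,
                           dropped_n = sum(has_n),
                           dropped_short = sum(short),
                           kept = sum(keep)))
  if (!is.null(names(reads))) names(out$sequences) <- names(reads)[keep]
  class(out) <- "trimmed_reads"
  out
}

# parse FASTQ via Biostrings; on failure, locate the offending record so the
# error names a record index
.read_fastq_checked <- function(path) {
  # suppressWarnings: the Biostrings reader warns about dropping the mcols
  # it created itself while attaching qualities
  x <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) {
      idx <- .locate_malformed_fastq(path)
      stop(sprintf("malformed FASTQ record %s in %s: %s",
                   ifelse(is.na(idx), "?", idx), path, conditionMessage(e)),
           call. = FALSE)
    })
  list(sequences = stats::setNames(as.character(x), names(x)),
       qualities = as.character(methods::slot(x, "quality")))
}

.locate_malformed_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  for (rec in seq_len(ceiling(n / 4))) {
    i <- (rec - 1L) * 4L + 1L
    if (i + 3L > n) return(rec)
    if (!startsWith(lines[i], "@")) return(rec)
    if (!startsWith(lines[i + 2L], "+")) return(rec)
    if (nchar(lines[i + 1L]) != nchar(lines[i + 3L])) return(rec)
  }
  NA_integer_
}

#' Locate direct-repeat occurrences on a read
#'
#' Finds all non-overlapping full-length windows on either strand within
#' `max_mismatch` Hamming distance of the repeat consensus, plus (optionally)
#' primer-truncated terminal matches of at least the primer length at the two
#' read ends. Overlaps are resolved greedily by fewest mismatches (full
#' matches preferred over partial, then leftmost).
#'
#' @param sequence Read sequence (ACGT/N; N never matches).
#' @param repeat_model A [repeat_model()].
#' @param max_mismatch Maximum Hamming distance to the consensus (default 5).
#' @param allow_terminal_partial Report primer-truncated terminal repeat
#'   matches (default TRUE).
#' @return Data frame with one row per match: `start`, `end` (0-based
#'   half-open read coordinates), `strand` (`+`/`-` = repeat orientation),
#'   `mismatches`, `full` (FALSE for terminal partial matches) and
#'   `observed` (the matched sequence oriented to the repeat's plus strand).
#' @export
find_repeat_matches <- function(sequence, repeat_model,
                                max_mismatch = 5L,
                                allow_terminal_partial = TRUE) {
  if (grepl("[^ACGT]", repeat_model$consensus))
    stop("repeat consensus contains ambiguous bases")
  ctx <- .repeat_context(repeat_model, max_mismatch, allow_terminal_partial)
  m <- .match_read(sequence, ctx)
  data.frame(start = m[, 1L], end = m[, 2L],
             strand = c("+", "-")[m[, 3L] + 1L],
             mismatches = m[, 4L], full = m[, 5L] == 1L,
             observed = .observed_repeats(sequence, m),
             stringsAsFactors = FALSE)
}

# precomputed encodings shared across reads of a site
.repeat_context <- function(repeat_model, max_mismatch, terminals) {
  cons <- repeat_model$consensus
  list(cons = cons,
       enc = encode_seq(cons),
       enc_rc = encode_seq(revcomp(cons)),
       max_mm = as.integer(max_mismatch),
       min_part = min(nchar(repeat_model$forward_primer),
                      nchar(repeat_model$reverse_primer)),
       terminals = isTRUE(terminals))
}

.match_read <- function(sequence, ctx) {
  repeat_match_cpp(encode_seq(sequence), ctx$enc, ctx$enc_rc,
                   ctx$max_mm, ctx$min_part, ctx$terminals)
}

.observed_repeats <- function(sequence, m) {
  if (nrow(m) == 0L) return(character(0))
  obs <- substr(rep(sequence, nrow(m)), m[, 1L] + 1L, m[, 2L])
  minus <- m[, 3L] == 1L
  if (any(minus)) obs[minus] <- revcomp(obs[minus])
  obs
}

#' Extract spacers between adjacent repeat matches
#'
#' Emits the sequence between each adjacent pair of repeat matches as a
#' spacer when its length lies within `length_bounds`. Spacers from reads
#' whose repeat matches lie on the minus strand are reverse-complemented
#' (and their order reversed) so that all records share the repeat's plus
#' orientation. Reads with mixed-strand matches are rejected.
#'
#' @param read Read sequence.
#' @param matches Data frame as returned by [find_repeat_matches()].
#' @param length_bounds Length-two integer vector of inclusive spacer length
#'   bounds (default `c(26, 50)`).
#' @param read_id,site Optional identifiers copied into the records.
#' @return Data frame with columns `read_id`, `site`, `sequence`, `length`,
#'   `left_variant`, `right_variant` (observed flanking repeat sequence, or
#'   `"terminal"`), or `NULL` for a mixed-strand read. The attribute
#'   `internal_repeats` carries the oriented sequences of full internal
#'   repeat copies flanked by emitted spacers on both sides.
#' @export
extract_spacers <- function(read, matches, length_bounds = c(26L, 50L),
                            read_id = NA_character_, site = NA_character_) {
  m <- as.matrix(matches[, c("start", "end")])
  strand <- matches$strand
  full <- matches$full
  obs <- matches$observed
  .spacers_from_matches(read, m, strand, full, obs, length_bounds,
                        read_id, site)
}

.spacers_from_matches <- function(read, m, strand, full, obs, length_bounds,
                                  read_id, site) {
  k <- nrow(m)
  if (k < 2L) return(.empty_spacer_df())
  if (length(unique(strand)) > 1L) return(NULL)      # mixed strand: reject
  st <- strand[1L]
  lab <- ifelse(full, obs, "terminal")
  gaps_from <- m[-k, 2L]
  gaps_to <- m[-1L, 1L]
  glen <- gaps_to - gaps_from
  ok <- glen >= length_bounds[1L] & glen <= length_bounds[2L]
  seqs <- substr(rep(read, k - 1L), gaps_from + 1L, gaps_to)
  ok <- ok & !grepl("[^ACGT]", seqs)
  left <- lab[-k]
  right <- lab[-1L]
  # internal repeats: full matches with an emitted spacer on both sides
  internal <- character(0)
  if (k > 2L) {
    mid <- 2L:(k - 1L)
    flanked <- full[mid] & ok[mid - 1L] & ok[mid]
    internal <- obs[mid][flanked]
  }
  seqs <- seqs[ok]; left <- left[ok]; right <- right[ok]
  if (st == "-") {
    seqs <- rev(revcomp(seqs))
    tmp <- left; left <- rev(right); right <- rev(tmp)
  }
  out <- data.frame(read_id = rep(read_id, length(seqs)),
                    site = rep(site, length(seqs)),
                    sequence = seqs, length = nchar(seqs),
                    left_variant = left, right_variant = right,
                    stringsAsFactors = FALSE)
  attr(out, "internal_repeats") <- internal
  out
}

.empty_spacer_df <- function() {
  out <- data.frame(read_id = character(0), site = character(0),
                    sequence = character(0), length = integer(0),
                    left_variant = character(0), right_variant = character(0),
                    stringsAsFactors = FALSE)
  attr(out, "internal_repeats") <- character(0)
  out
}

#' Extract all spacers from a set of reads
#'
#' Runs repeat matching and spacer extraction over every read of one site
#' and collects spacer records, internal repeat copies, and accounting
#' statistics.
#'
#' @param reads Character vector of read sequences (e.g.
#'   `trim_reads(...)$sequences`), optionally named with read ids.
#' @param repeat_model A [repeat_model()].
#' @param site Site label recorded on each spacer.
#' @param max_mismatch Repeat-match mismatch tolerance (default 5).
#' @param length_bounds Inclusive spacer length bounds (default `c(26, 50)`).
#' @param allow_terminal_partial Use primer-truncated terminal repeat
#'   matches (default TRUE).
#' @return List of class `spacer_extraction`: `spacers` (data frame of
#'   spacer records), `internal_repeats` (character vector of oriented full
#'   internal repeat sequences), `stats` (reads, mixed-strand rejected,
#'   spacers emitted).
#' @export
extract_site <- function(reads, repeat_model, site = "site1",
                         max_mismatch = 5L, length_bounds = c(26L, 50L),
                         allow_terminal_partial = TRUE) {
  ctx <- .repeat_context(repeat_model, max_mismatch, allow_terminal_partial)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("%s_read%06d", site, seq_along(reads))
  res <- vector("list", length(reads))
  internal <- vector("list", length(reads))
  n_mixed <- 0L
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    m <- .match_read(rd, ctx)
    if (nrow(m) < 2L) next
    obs <- .observed_repeats(rd, m)
    sp <- .spacers_from_matches(rd, m[, 1:2, drop = FALSE],
                                c("+", "-")[m[, 3L] + 1L], m[, 5L] == 1L,
                                obs, length_bounds, ids[i], site)
    if (is.null(sp)) { n_mixed <- n_mixed + 1L; next }
    if (nrow(sp)) res[[i]] <- sp
    internal[[i]] <- attr(sp, "internal_repeats")
  }
  res <- res[!vapply(res, is.null, logical(1))]
  spacers <- if (length(res)) do.call(rbind, res) else .empty_spacer_df()
  rownames(spacers) <- NULL
  structure(list(spacers = spacers,
                 internal_repeats = unlist(internal, use.names = FALSE),
                 stats = list(reads = length(reads),
                              mixed_strand = n_mixed,
                              spacers = nrow(spacers))),
            class = "spacer_extraction")
}

#' Tally internal direct-repeat variants
#'
#' Groups the full internal repeat copies (those flanked by emitted spacers
#' on both sides, hence unaffected by the amplification primers) by exact
#' sequence and reports counts and frequencies.
#'
#' @param x A `spacer_extraction` object, a list of them, or a character
#'   vector of internal repeat sequences.
#' @return Data frame (`variant`, `count`, `frequency`), sorted by
#'   descending count then sequence; frequencies sum to 1 (empty input gives
#'   an empty table).
#' @export
internal_repeat_table <- function(x) {
  seqs <- if (is.character(x)) x
  else if (inherits(x, "spacer_extraction")) x$internal_repeats
  else unlist(lapply(x, function(e) e$internal_repeats), use.names = FALSE)
  if (length(seqs) == 0L)
    return(data.frame(variant = character(0), count = integer(0),
                      frequency = numeric(0), stringsAsFactors = FALSE))
  tab <- table(seqs)
  out <- data.frame(variant = names(tab), count = as.integer(tab),
                    frequency = as.integer(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  out
}
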