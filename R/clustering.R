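#' Count-weighted consensus of equal-length sequences
#'
#' Per position, the count-weighted most frequent base; ties are broken by
#' fixed alphabet order A < C < G < T. This realises a "mean" sequence over
#' cluster members as a concrete DNA string usable as a search query.
#'
#' @param sequences Character vector of equal-length ACGT sequences.
#' @param counts Positive weights, one per sequence (default all 1).
#' @return Consensus DNA string.
#' @export
#' @examples
#' consensus_of(c("ACGT", "ACGA"), counts = c(2, 1))
consensus_of <- function(sequences, counts = rep(1L, length(sequences))) {
  if (length(sequences) == 0L) stop("no sequences")
  assert_acgt(sequences)
  if (length(unique(nchar(sequences))) != 1L)
    stop("consensus requires equal-length sequences")
  if (sum(counts) < 1) stop("total count must be >= 1")
  M <- encode_matrix(sequences)
  decode_seq(.consensus_codes(M, counts))
}

.consensus_codes <- function(M, counts) {
  L <- ncol(M)
  score <- matrix(0, nrow = 4L, ncol = L)
  for (b in 1:4) score[b, ] <- colSums(counts * (M == b))
  apply(score, 2L, which.max)   # first max -> A < C < G < T tie rule
}

#' Cluster spacers under a fixed substitution radius
#'
#' Partitions spacer sequences into clusters of biologically similar
#' sequences such that every member lies within `radius` substitutions
#' (Hamming distance) of its cluster's consensus centre. Sequences of
#' different lengths never co-cluster. Within each length class a bisecting
#' k-means over the sequences is used: start from a single cluster and
#' repeatedly split any cluster violating the radius certificate, seeding
#' the two centres with the most abundant member and the member farthest
#' from it, then running Lloyd iterations with consensus (weighted majority)
#' centres until the assignment stabilises. The procedure is fully
#' deterministic: input is canonicalised by sorting unique sequences, so
#' results do not depend on read order.
#'
#' @param records Character vector of spacer sequences (repeats allowed;
#'   multiplicity becomes abundance), or a data frame with a `sequence`
#'   column (e.g. `extract_site(...)$spacers`).
#' @param radius Maximum member-to-consensus Hamming distance (default 5).
#' @param site Optional site label stored on the output.
#' @param seed Unused; accepted for interface compatibility (the algorithm
#'   is deterministic).
#' @return Data frame of class `spacer_clusters`, one row per cluster:
#'   `cluster_id`, `site`, `consensus`, `abundance`, `n_members`,
#'   `max_radius`, `length`; sorted by descending abundance then consensus.
#'   The `members` attribute holds one data frame (`sequence`, `count`) per
#'   cluster.
#' @export
cluster_spacers <- function(records, radius = 5L, site = NA_character_,
                            seed = NULL) {
  seqs <- if (is.data.frame(records)) records$sequence else records
  if (length(seqs) == 0L) stop("no spacer records to cluster")
  assert_acgt(seqs, "spacer record")

  tab <- table(seqs)
  useq <- sort(names(tab))              # canonical order
  cnt <- as.integer(tab[useq])

  clusters <- list()
  for (L in sort(unique(nchar(useq)))) {
    in_class <- nchar(useq) == L
    clusters <- c(clusters,
                  .bisect_class(useq[in_class], cnt[in_class], radius))
  }
  df <- data.frame(
    consensus = vapply(clusters, `[[`, character(1), "consensus"),
    abundance = vapply(clusters, `[[`, integer(1), "abundance"),
    n_members = vapply(clusters, `[[`, integer(1), "n_members"),
    max_radius = vapply(clusters, `[[`, integer(1), "max_radius"),
    stringsAsFactors = FALSE)
  ord <- order(-df$abundance, df$consensus)
  df <- df[ord, , drop = FALSE]
  df <- cbind(cluster_id = sprintf("c%05d", seq_len(nrow(df))),
              site = site, df, length = nchar(df$consensus),
              stringsAsFactors = FALSE)
  rownames(df) <- NULL
  attr(df, "members") <- lapply(clusters[ord], `[[`, "members")
  attr(df, "radius") <- as.integer(radius)
  class(df) <- c("spacer_clusters", "data.frame")
  df
}

.bisect_class <- function(useq, cnt, radius) {
  M <- encode_matrix(useq)
  groups <- list()
  queue <- list(seq_along(useq))
  while (length(queue)) {
    idx <- queue[[1L]]
    queue <- queue[-1L]
    cons <- .consensus_codes(M[idx, , drop = FALSE], cnt[idx])
    d <- hamming_to_centre_cpp(M[idx, , drop = FALSE], cons)
    if (max(d) <= radius) {
      groups[[length(groups) + 1L]] <- idx
      next
    }
    halves <- .split_two(M, idx, cnt)
    queue <- c(queue, halves)
  }
  groups <- .merge_certified(M, cnt, groups, radius)
  lapply(groups, function(idx) {
    cons <- .consensus_codes(M[idx, , drop = FALSE], cnt[idx])
    d <- hamming_to_centre_cpp(M[idx, , drop = FALSE], cons)
    list(consensus = decode_seq(cons),
         abundance = sum(cnt[idx]),
         n_members = length(idx),
         max_radius = max(d),
         members = data.frame(sequence = useq[idx], count = cnt[idx],
                              stringsAsFactors = FALSE))
  })
}

# agglomerative polish: bisecting splits can strand members of one true
# group in separate certified clusters; merge any two clusters whose union
# still satisfies the radius certificate. Candidates are taken in order of
# ascending centre-to-centre distance (ties: larger combined abundance,
# then centre sequences), so the result is deterministic.
.merge_certified <- function(M, cnt, groups, radius) {
  repeat {
    k <- length(groups)
    if (k < 2L) return(groups)
    cent <- t(vapply(groups, function(idx)
      .consensus_codes(M[idx, , drop = FALSE], cnt[idx]),
      integer(ncol(M))))
    D <- hamming_cross_cpp(cent, cent)
    cand <- which(upper.tri(D) & D <= 2L * radius, arr.ind = TRUE)
    if (nrow(cand) == 0L) return(groups)
    ab <- vapply(groups, function(idx) sum(cnt[idx]), numeric(1))
    cent_str <- apply(cent, 1L, decode_seq)
    ord <- order(D[cand],
                 -(ab[cand[, 1L]] + ab[cand[, 2L]]),
                 cent_str[cand[, 1L]], cent_str[cand[, 2L]])
    merged <- FALSE
    for (m in ord) {
      i <- cand[m, 1L]; j <- cand[m, 2L]
      idx <- c(groups[[i]], groups[[j]])
      cons <- .consensus_codes(M[idx, , drop = FALSE], cnt[idx])
      if (max(hamming_to_centre_cpp(M[idx, , drop = FALSE], cons)) <= radius) {
        groups[[i]] <- idx
        groups[[j]] <- NULL
        merged <- TRUE
        break
      }
    }
    if (!merged) return(groups)
  }
}

# deterministic 2-means split: centres seeded with the most abundant member
# (ties: first in canonical order) and the member farthest from it
.split_two <- function(M, idx, cnt) {
  sub <- M[idx, , drop = FALSE]
  w <- cnt[idx]
  s1 <- which.max(w)
  d1 <- hamming_to_centre_cpp(sub, sub[s1, ])
  s2 <- which.max(d1)
  c1 <- sub[s1, ]; c2 <- sub[s2, ]
  assign_old <- rep(0L, length(idx))
  for (iter in seq_len(100L)) {
    a <- ifelse(hamming_to_centre_cpp(sub, c1) <=
                hamming_to_centre_cpp(sub, c2), 1L, 2L)
    if (all(a == assign_old)) break
    if (!any(a == 2L)) a[s2] <- 2L       # never let a side empty out
    if (!any(a == 1L)) a[s1] <- 1L
    assign_old <- a
    c1 <- .consensus_codes(sub[a == 1L, , drop = FALSE], w[a == 1L])
    c2 <- .consensus_codes(sub[a == 2L, , drop = FALSE], w[a == 2L])
  }
  list(idx[assign_old == 1L], idx[assign_old == 2L])
}

#' Cluster spacers for several sites
#'
#' @param spacers Data frame of spacer records with `site` and `sequence`
#'   columns, or a named list of character vectors.
#' @param radius Cluster radius (default 5).
#' @return Named list of `spacer_clusters` (one per site).
#' @export
cluster_sites <- function(spacers, radius = 5L) {
  by_site <- if (is.data.frame(spacers))
    split(spacers$sequence, spacers$site) else spacers
  out <- lapply(names(by_site), function(s)
    cluster_spacers(by_site[[s]], radius = radius, site = s))
  stats::setNames(out, names(by_site))
}
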