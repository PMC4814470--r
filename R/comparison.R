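#' Match clusters between two sites
#'
#' Greedy one-to-one matching of equal-length cluster consensuses by
#' ascending Hamming distance; ties are resolved by higher combined
#' abundance, then lexicographically by the consensus pair. Only pairs
#' within `max_mismatch` are matched; `max_mismatch = 0` gives exact
#' matching.
#'
#' @param a,b `spacer_clusters` data frames (need columns `consensus` and
#'   `abundance`).
#' @param max_mismatch Maximum consensus Hamming distance (default 5, the
#'   cluster radius).
#' @return Data frame of match edges: `idx_a`, `idx_b` (row indices),
#'   `consensus_a`, `consensus_b`, `distance`.
#' @export
match_clusters <- function(a, b, max_mismatch = 5L) {
  assert_acgt(a$consensus, "cluster consensus")
  assert_acgt(b$consensus, "cluster consensus")
  edges <- list()
  for (L in intersect(unique(nchar(a$consensus)), unique(nchar(b$consensus)))) {
    ia <- which(nchar(a$consensus) == L)
    ib <- which(nchar(b$consensus) == L)
    D <- hamming_cross_cpp(encode_matrix(a$consensus[ia]),
                           encode_matrix(b$consensus[ib]))
    cand <- which(D <= max_mismatch, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    dist <- D[cand]
    comb <- a$abundance[ia[cand[, 1L]]] + b$abundance[ib[cand[, 2L]]]
    key_a <- a$consensus[ia[cand[, 1L]]]
    key_b <- b$consensus[ib[cand[, 2L]]]
    ord <- order(dist, -comb, key_a, key_b)
    used_a <- logical(length(ia)); used_b <- logical(length(ib))
    for (k in ord) {
      ra <- cand[k, 1L]; rb <- cand[k, 2L]
      if (used_a[ra] || used_b[rb]) next
      used_a[ra] <- TRUE; used_b[rb] <- TRUE
      edges[[length(edges) + 1L]] <- data.frame(
        idx_a = ia[ra], idx_b = ib[rb],
        consensus_a = a$consensus[ia[ra]], consensus_b = b$consensus[ib[rb]],
        distance = D[ra, rb], stringsAsFactors = FALSE)
    }
  }
  if (length(edges) == 0L)
    return(data.frame(idx_a = integer(0), idx_b = integer(0),
                      consensus_a = character(0), consensus_b = character(0),
                      distance = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, edges)
  out <- out[order(out$idx_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared/unique cluster accounting across sites (Venn regions)
#'
#' Builds pairwise cluster match edges between every pair of sites and
#' groups clusters by the transitive closure (connected components) of
#' those edges. Each component is one putative spacer identity; its Venn
#' region is the set of sites it spans. A cluster is unique to its site iff
#' its component contains clusters from that site only.
#'
#' @param clusterings Named list of 2-4 `spacer_clusters` data frames.
#' @param max_mismatch Consensus match tolerance (default 5; use 0 for
#'   exact sharing).
#' @return List of class `sharing_report`: `region_components` (named count
#'   of components per Venn region), `clusters_by_site` (region x site
#'   matrix of per-site cluster counts), `percent_unique` (per site),
#'   `pairwise_shared_percent` (matrix; percentage of each row site's
#'   clusters matched in the column site), `edges` (all pairwise match
#'   edges), `max_mismatch`.
#' @export
venn_counts <- function(clusterings, max_mismatch = 5L) {
  n <- length(clusterings)
  if (n < 2L || n > 4L)
    stop("venn_counts supports 2-4 sites")
  sites <- names(clusterings)
  if (is.null(sites)) sites <- paste0("site", seq_len(n))

  node_id <- function(s, i) paste0(s, "#", i)
  nodes <- unlist(lapply(sites, function(s)
    node_id(s, seq_len(nrow(clusterings[[s]])))), use.names = FALSE)
  edge_rows <- list()
  edge_df <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    e <- match_clusters(clusterings[[i]], clusterings[[j]], max_mismatch)
    if (nrow(e)) {
      edge_rows[[length(edge_rows) + 1L]] <-
        cbind(node_id(sites[i], e$idx_a), node_id(sites[j], e$idx_b))
      edge_df[[length(edge_df) + 1L]] <-
        cbind(site_a = sites[i], site_b = sites[j], e)
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(nodes)
  if (length(edge_rows))
    g <- g + igraph::edges(t(do.call(rbind, edge_rows)))
  comp <- igraph::components(g)$membership

  node_site <- sub("#.*$", "", nodes)
  comp_sites <- tapply(node_site, comp[nodes], function(s)
    paste(sites[sort(unique(match(s, sites)))], collapse = "+"))
  region_components <- table(factor(unname(comp_sites)))

  # per-cluster region assignment
  cluster_region <- unname(comp_sites[as.character(comp[nodes])])
  regions <- sort(unique(cluster_region))
  cbs <- matrix(0L, nrow = length(regions), ncol = n,
                dimnames = list(regions, sites))
  for (r in regions) for (s in sites)
    cbs[r, s] <- sum(cluster_region == r & node_site == s)

  totals <- vapply(sites, function(s) sum(node_site == s), integer(1))
  unique_counts <- vapply(sites, function(s)
    if (s %in% regions) cbs[s, s] else 0L, integer(1))
  percent_unique <- 100 * unique_counts / totals

  pw <- matrix(0, n, n, dimnames = list(sites, sites))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    e <- if (i < j) match_clusters(clusterings[[i]], clusterings[[j]], max_mismatch)
    else match_clusters(clusterings[[j]], clusterings[[i]], max_mismatch)
    pw[i, j] <- 100 * nrow(e) / totals[i]
  }

  structure(list(region_components = c(region_components),
                 clusters_by_site = cbs,
                 percent_unique = percent_unique,
                 pairwise_shared_percent = pw,
                 edges = if (length(edge_df)) do.call(rbind, edge_df)
                         else NULL,
                 totals = totals,
                 max_mismatch = as.integer(max_mismatch)),
            class = "sharing_report")
}

#' Fraction of clusters holding a given abundance share
#'
#' Smallest set of clusters, taken in order of descending abundance (ties
#' broken lexicographically by consensus), whose cumulative abundance share
#' reaches `q`; returned as a percentage of the total cluster count. This
#' quantifies abundance concentration, e.g. "95% of all spacers fall within
#' x% of clusters".
#'
#' @param clusters `spacer_clusters` data frame (columns `consensus`,
#'   `abundance`) or a bare abundance vector.
#' @param q Target abundance share in `(0, 1]` (default 0.95).
#' @return Percentage (0-100) of clusters needed.
#' @export
abundance_concentration <- function(clusters, q = 0.95) {
  if (q <= 0 || q > 1) stop("q must lie in (0, 1]")
  if (is.data.frame(clusters)) {
    ab <- clusters$abundance
    ord <- order(-ab, clusters$consensus)
  } else {
    ab <- clusters
    ord <- order(-ab)
  }
  if (length(ab) == 0L) stop("no clusters")
  ab <- ab[ord]
  k <- which(cumsum(ab) >= q * sum(ab))[1L]
  100 * k / length(ab)
}

#' Detect self-complementary spacer cluster pairs
#'
#' Finds cluster pairs whose consensuses are reverse complements of each
#' other within `max_mismatch` substitutions - the signature of both
#' orientations of one protospacer having been acquired. A cluster whose
#' consensus is its own reverse complement is flagged as a palindrome
#' (`idx_a == idx_b`).
#'
#' @param clusters `spacer_clusters` data frame or character vector of
#'   consensuses.
#' @param max_mismatch Allowed Hamming distance between the reverse
#'   complement of one consensus and the other (default 0, exact).
#' @return Data frame: `idx_a`, `idx_b` (`idx_a <= idx_b`), `consensus_a`,
#'   `consensus_b`, `distance`, `palindrome`, and abundances when available.
#' @export
self_complementary_pairs <- function(clusters, max_mismatch = 0L) {
  cons <- if (is.data.frame(clusters)) clusters$consensus else clusters
  ab <- if (is.data.frame(clusters)) clusters$abundance
        else rep(NA_integer_, length(cons))
  assert_acgt(cons, "cluster consensus")
  out <- list()
  for (L in unique(nchar(cons))) {
    ii <- which(nchar(cons) == L)
    D <- hamming_cross_cpp(encode_matrix(revcomp(cons[ii])),
                           encode_matrix(cons[ii]))
    hit <- which(D <= max_mismatch, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    keep <- hit[, 1L] <= hit[, 2L]      # dedupe the symmetric relation
    hit <- hit[keep, , drop = FALSE]
    if (nrow(hit) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      idx_a = ii[hit[, 1L]], idx_b = ii[hit[, 2L]],
      consensus_a = cons[ii[hit[, 1L]]], consensus_b = cons[ii[hit[, 2L]]],
      distance = D[hit], palindrome = hit[, 1L] == hit[, 2L],
      abundance_a = ab[ii[hit[, 1L]]], abundance_b = ab[ii[hit[, 2L]]],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(idx_a = integer(0), idx_b = integer(0),
                      consensus_a = character(0), consensus_b = character(0),
                      distance = integer(0), palindrome = logical(0),
                      abundance_a = integer(0), abundance_b = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$idx_a, res$idx_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}
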