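#' Direct repeat model
#'
#' Bundles a direct repeat consensus, its natural sequence variants with
#' frequencies, and the two amplification primers that anneal within the
#' repeat. The forward primer matches a 3' portion (suffix) of the repeat
#' consensus and the reverse primer matches the reverse complement of a 5'
#' portion (prefix), so that an amplified fragment starts and ends with a
#' primer-truncated terminal repeat while any internal repeat copy is
#' complete and unaffected by the primers.
#'
#' @param consensus Repeat consensus, 23-47 nt of ACGT.
#' @param variants Character vector of repeat variant sequences, all the same
#'   length as the consensus. The first variant is conventionally the
#'   consensus itself.
#' @param variant_freqs Numeric vector of variant frequencies summing to 1
#'   (tolerance 1e-9).
#' @param forward_primer,reverse_primer Primer sequences. The forward primer
#'   must match a substring of the consensus and the reverse primer a
#'   substring of its reverse complement, each within `primer_mismatch`
#'   mismatches.
#' @param primer_mismatch Declared primer/consensus mismatch tolerance
#'   (default 0).
#' @return An object of class `repeat_model`.
#' @export
repeat_model <- function(consensus, variants = consensus, variant_freqs = 1,
                         forward_primer, reverse_primer,
                         primer_mismatch = 0L) {
  assert_acgt(consensus, "repeat consensus")
  if (nchar(consensus) < 23L || nchar(consensus) > 47L)
    stop("repeat consensus length must be within 23-47 nt")
  assert_acgt(variants, "repeat variant")
  if (any(nchar(variants) != nchar(consensus)))
    stop("all repeat variants must have the same length as the consensus")
  if (length(variant_freqs) != length(variants))
    stop("variant_freqs must have one entry per variant")
  if (abs(sum(variant_freqs) - 1) > 1e-9)
    stop("variant frequencies must sum to 1")
  if (!.primer_anneals(forward_primer, consensus, primer_mismatch))
    stop("forward primer does not anneal within the repeat consensus")
  if (!.primer_anneals(reverse_primer, revcomp(consensus), primer_mismatch))
    stop("reverse primer does not anneal within the repeat reverse complement")
  structure(list(consensus = consensus,
                 variants = variants,
                 variant_freqs = variant_freqs,
                 forward_primer = forward_primer,
                 reverse_primer = reverse_primer,
                 primer_mismatch = as.integer(primer_mismatch)),
            class = "repeat_model")
}

.primer_anneals <- function(primer, template, max_mm) {
  mm <- mismatch_scan_cpp(encode_seq(template), encode_seq(primer))
  length(mm) > 0L && min(mm) <= max_mm
}

#' @export
print.repeat_model <- function(x, ...) {
  cat("Direct repeat model\n")
  cat("  consensus (", nchar(x$consensus), " nt): ", x$consensus, "\n", sep = "")
  cat("  variants:", length(x$variants),
      sprintf("(freqs: %s)", paste(signif(x$variant_freqs, 3), collapse = ", ")), "\n")
  cat("  primers:", x$forward_primer, "/", x$reverse_primer, "\n")
  invisible(x)
}

#' Default synthetic 46-bp repeat model
#'
#' The direct repeat of the targeted type II system is not publicly
#' available, so the package ships a SYNTHETIC 46-nt stand-in with the same
#' structure: a 31-nt forward primer footprint (consensus suffix), a 25-nt
#' reverse primer footprint (consensus prefix, reverse-complemented), and
#' four variants mirroring the variant spectrum observed in internal repeat
#' copies of environmental amplicons: the consensus (65.6%), a single
#' substitution at position 6 (34%), plus two minor variants adding a
#' substitution at position 13 (0.2%) or 21 (0.1%). Frequencies are
#' normalised to sum to one.
#'
#' @return A `repeat_model`.
#' @export
default_repeat_model <- function() {
  cons <- "GTTGTGAATTGCTTTCAAAATTGTACTTATAATTACCAACTTAGAG"
  sub_at <- function(s, pos, base) {
    substr(s, pos, pos) <- base
    s
  }
  v2 <- sub_at(cons, 6L, "A")      # position 6: G -> A
  v3 <- sub_at(v2, 13L, "A")      # + position 13: T -> A
  v4 <- sub_at(v2, 21L, "C")      # + position 21: T -> C
  fr <- c(0.656, 0.34, 0.002, 0.001)
  repeat_model(consensus = cons,
               variants = c(cons, v2, v3, v4),
               variant_freqs = fr / sum(fr),
               forward_primer = substr(cons, nchar(cons) - 30L, nchar(cons)),
               reverse_primer = revcomp(substr(cons, 1L, 25L)))
}

#' Generate ground-truthed per-site spacer pools
#'
#' Draws unique spacers from a random sequence universe and assembles one
#' pool per sampling site with an exactly realised overlap design. Spacers
#' of equal length are kept pairwise at Hamming distance of at least
#' `2 * cluster_radius + 1` (rejection sampling) so that the true clusters
#' are unambiguous under the downstream clustering radius.
#'
#' The overlap design is given as a matrix of pairwise shared counts (each
#' count INCLUDING any higher-order sharing) plus a single count of spacers
#' shared by all sites. For three sites this determines every Venn region;
#' for four sites the triple-only regions are fixed at zero.
#'
#' @param pool_sizes Integer vector, one pool size per site.
#' @param pairwise_shared Symmetric integer matrix of pairwise shared-spacer
#'   counts (diagonal ignored); `NULL` (default) means no sharing.
#' @param all_shared Count of spacers common to all sites (default 0;
#'   must be `<=` every pairwise count).
#' @param length_weights Named numeric vector mapping spacer length to
#'   sampling weight; default uniform over 28-31 nt.
#' @param abundance Per-spacer sampling weight scheme: `"zipf"` (default,
#'   weight 1/rank over a site-specific random spacer order, emulating the
#'   strong abundance concentration seen in real spacer libraries) or
#'   `"uniform"`.
#' @param zipf_exponent Exponent of the Zipf weights (default 1).
#' @param cluster_radius Clustering radius the pools must be separable
#'   under (default 5).
#' @param site_names Optional site names (default `site1`, `site2`, ...).
#' @param seed Integer seed; the same seed reproduces identical pools.
#' @return An object of class `site_pools`: list with `site_names`, `pools`
#'   (list of character vectors), `weights` (per-site sampling weights),
#'   `regions` (exclusive Venn region membership), `design`, `seed`.
#' @export
make_site_pools <- function(pool_sizes, pairwise_shared = NULL,
                            all_shared = 0L,
                            length_weights = c(`28` = 1, `29` = 1,
                                               `30` = 1, `31` = 1),
                            abundance = c("zipf", "uniform"),
                            zipf_exponent = 1,
                            cluster_radius = 5L,
                            site_names = NULL, seed = 1L) {
  abundance <- match.arg(abundance)
  n_sites <- length(pool_sizes)
  if (n_sites < 1L) stop("need at least one site")
  if (is.null(site_names)) site_names <- paste0("site", seq_len(n_sites))
  if (is.null(pairwise_shared))
    pairwise_shared <- matrix(0L, n_sites, n_sites)
  pairwise_shared <- as.matrix(pairwise_shared)
  if (!isTRUE(all.equal(pairwise_shared, t(pairwise_shared))))
    stop("pairwise_shared must be symmetric")
  diag(pairwise_shared) <- 0L
  region_sizes <- .venn_region_sizes(pool_sizes, pairwise_shared,
                                     as.integer(all_shared))

  set.seed(as.integer(seed))
  lens <- as.integer(names(length_weights))
  if (any(lens < 26L | lens > 50L))
    stop("spacer lengths must lie within 26-50 nt")
  total <- sum(unlist(region_sizes))
  universe <- .draw_separated_spacers(total, lens, length_weights,
                                      min_dist = 2L * cluster_radius + 1L)

  # assign universe spacers to exclusive Venn regions in a fixed order
  regions <- list()
  off <- 0L
  for (rn in names(region_sizes)) {
    k <- region_sizes[[rn]]
    regions[[rn]] <- if (k > 0L) universe[off + seq_len(k)] else character(0)
    off <- off + k
  }

  pools <- lapply(seq_len(n_sites), function(i) {
    mem <- lapply(names(regions), function(rn) {
      sites_in <- as.integer(strsplit(rn, "+", fixed = TRUE)[[1]])
      if (i %in% sites_in) regions[[rn]] else character(0)
    })
    unlist(mem, use.names = FALSE)
  })
  names(pools) <- site_names
  stopifnot(lengths(pools) == pool_sizes)

  weights <- lapply(pools, function(p) {
    w <- switch(abundance,
                uniform = rep(1, length(p)),
                zipf = 1 / seq_along(p)^zipf_exponent)
    w <- w[sample.int(length(p))]   # random spacer-to-rank assignment
    w / sum(w)
  })

  structure(list(site_names = site_names, pools = pools, weights = weights,
                 regions = regions,
                 design = list(pool_sizes = pool_sizes,
                               pairwise_shared = pairwise_shared,
                               all_shared = as.integer(all_shared)),
                 cluster_radius = as.integer(cluster_radius),
                 seed = as.integer(seed)),
            class = "site_pools")
}

# exclusive Venn region sizes from pairwise-shared (inclusive counts) and the
# common-to-all count; regions named "1", "1+2", "1+2+3", ...
.venn_region_sizes <- function(pool_sizes, pairwise, all_shared) {
  n <- length(pool_sizes)
  if (n > 4L) stop("at most 4 sites are supported")
  sizes <- list()
  if (n == 1L) {
    sizes[["1"]] <- pool_sizes[1L]
    return(sizes)
  }
  t_all <- if (n == 2L) 0L else all_shared
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    excl <- pairwise[i, j] - t_all
    if (excl < 0L)
      stop("infeasible overlap design: all_shared exceeds a pairwise count")
    sizes[[paste(c(i, j), collapse = "+")]] <- excl
  }
  if (n >= 3L) sizes[[paste(seq_len(n), collapse = "+")]] <- t_all
  for (i in seq_len(n)) {
    shared_i <- sum(pairwise[i, -i]) - (n - 1L - 1L) * t_all
    uniq <- pool_sizes[i] - shared_i
    if (uniq < 0L)
      stop(sprintf("infeasible overlap design: site %d sharing exceeds its pool size", i))
    sizes[[as.character(i)]] <- uniq
  }
  if (n == 2L) {
    # pairwise count is the whole shared region
    s <- pairwise[1L, 2L]
    if (s > min(pool_sizes)) stop("infeasible overlap design: shared count exceeds a pool size")
  }
  sizes
}

.draw_separated_spacers <- function(n, lens, weights, min_dist,
                                    max_tries = 1000L) {
  out <- character(n)
  by_len <- split(integer(0), lens)   # indices of accepted spacers per length
  enc <- list()
  for (i in seq_len(n)) {
    ok <- FALSE
    for (tr in seq_len(max_tries)) {
      L <- lens[sample.int(length(lens), 1L, prob = weights)]
      cand <- random_dna(1L, L)
      key <- as.character(L)
      prev <- by_len[[key]]
      if (length(prev)) {
        d <- hamming_to_centre_cpp(enc[[key]], encode_seq(cand))
        if (min(d) < min_dist) next
      }
      out[i] <- cand
      by_len[[key]] <- c(prev, i)
      enc[[key]] <- rbind(enc[[key]], encode_seq(cand))
      ok <- TRUE
      break
    }
    if (!ok) stop("could not draw a sufficiently separated spacer universe")
  }
  out
}

#' Realised pairwise/total pool overlaps
#'
#' Exact set arithmetic over the emitted pools; used to verify that realised
#' overlaps equal the requested design.
#'
#' @param pools A `site_pools` object (or plain list of character vectors).
#' @return List with `pairwise` (matrix of pairwise intersection sizes) and
#'   `all` (size of the intersection across all sites).
#' @export
pool_overlaps <- function(pools) {
  pl <- if (inherits(pools, "site_pools")) pools$pools else pools
  n <- length(pl)
  pw <- matrix(0L, n, n, dimnames = list(names(pl), names(pl)))
  for (i in seq_len(n)) for (j in seq_len(n))
    pw[i, j] <- length(intersect(pl[[i]], pl[[j]]))
  list(pairwise = pw, all = length(Reduce(intersect, pl)))
}

#' Simulate repeat-anchored spacer amplicon reads
#'
#' Emits per-site reads with the structure
#' `primer-truncated repeat | spacer | full repeat | ... | spacer |
#' primer-truncated repeat`: a fragment carrying k spacers contains exactly
#' k-1 full internal repeat copies, drawn from the repeat model's variant
#' frequencies, while the two terminal repeats are truncated to the primer
#' footprints. Substitution errors are applied iid per base; each read is
#' emitted on a random strand. Ground truth (planted spacers, variant ids,
#' strand) is returned for every read.
#'
#' @param pools A `site_pools` object.
#' @param repeat_model A `repeat_model`.
#' @param reads_per_site Number of reads per site (recycled).
#' @param k_probs Probabilities of 1..5 spacers per fragment
#'   (default `c(0.4, 0.3, 0.15, 0.1, 0.05)`; the real distribution is
#'   unknown, see the package vignette).
#' @param error_rate Per-base substitution probability in `[0, 0.05]`
#'   (default 0.001).
#' @param quality One of `"constant"` (all Q30, default) or `"decay"`
#'   (linear 3' decay from Q30 to Q10 over the final 30% of the read).
#' @param both_strands Emit each read on a random strand (default TRUE).
#' @param out_dir If non-NULL, write one FASTQ (Phred+33) per site plus a
#'   TSV truth table and JSON manifest into this directory.
#' @param seed Integer seed; identical seed and configuration reproduce
#'   byte-identical output.
#' @return Object of class `synthetic_amplicons`: `reads` (per-site named
#'   character vectors), `qualities`, `truth` (data frame: read_id, site,
#'   n_spacers, spacers, variants, strand), `fastq` (paths or NULL),
#'   plus the generating configuration.
#' @export
simulate_amplicons <- function(pools, repeat_model = default_repeat_model(),
                               reads_per_site = 1000L,
                               k_probs = c(0.4, 0.3, 0.15, 0.1, 0.05),
                               error_rate = 0.001,
                               quality = c("constant", "decay"),
                               both_strands = TRUE,
                               out_dir = NULL, seed = 1L) {
  quality <- match.arg(quality)
  if (error_rate < 0 || error_rate > 0.05)
    stop("error_rate must lie in [0, 0.05]")
  if (any(lengths(pools$pools) == 0L)) stop("empty spacer pool")
  bad_len <- unlist(lapply(pools$pools, nchar))
  if (any(bad_len < 26L | bad_len > 50L))
    stop("pool contains a spacer outside the 26-50 nt length bounds")
  rm <- repeat_model
  fwd_foot <- substr(rm$consensus,
                     nchar(rm$consensus) - nchar(rm$forward_primer) + 1L,
                     nchar(rm$consensus))
  rev_foot <- substr(rm$consensus, 1L, nchar(rm$reverse_primer))
  n_sites <- length(pools$pools)
  reads_per_site <- rep_len(as.integer(reads_per_site), n_sites)
  k_probs <- k_probs / sum(k_probs)

  set.seed(as.integer(seed))
  reads <- quals <- stats::setNames(vector("list", n_sites), pools$site_names)
  truth <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    pool <- pools$pools[[s]]
    w <- pools$weights[[s]]
    n <- reads_per_site[s]
    ks <- sample.int(length(k_probs), n, replace = TRUE, prob = k_probs)
    site <- pools$site_names[s]
    rid <- sprintf("%s_read%06d", site, seq_len(n))
    sp_list <- var_list <- vector("list", n)
    seqs <- character(n)
    strands <- character(n)
    for (i in seq_len(n)) {
      k <- ks[i]
      idx <- sample.int(length(pool), k, replace = FALSE, prob = w)
      sp <- pool[idx]
      vi <- if (k > 1L)
        sample.int(length(rm$variants), k - 1L, replace = TRUE,
                   prob = rm$variant_freqs) else integer(0)
      parts <- character(2L * k + 1L)
      parts[1L] <- fwd_foot
      for (j in seq_len(k)) {
        parts[2L * j] <- sp[j]
        parts[2L * j + 1L] <- if (j < k) rm$variants[vi[j]] else rev_foot
      }
      rd <- mutate_seq(paste(parts, collapse = ""), error_rate)
      st <- if (both_strands && stats::runif(1) < 0.5) "-" else "+"
      if (st == "-") rd <- revcomp(rd)
      seqs[i] <- rd
      strands[i] <- st
      sp_list[[i]] <- sp
      var_list[[i]] <- vi
    }
    reads[[s]] <- stats::setNames(seqs, rid)
    quals[[s]] <- .quality_strings(nchar(seqs), quality)
    truth[[s]] <- data.frame(
      read_id = rid, site = site, n_spacers = ks,
      spacers = vapply(sp_list, paste, character(1), collapse = ","),
      variants = vapply(var_list, paste, character(1), collapse = ","),
      strand = strands, stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  fastq <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fastq <- file.path(out_dir, paste0(pools$site_names, ".fastq"))
    names(fastq) <- pools$site_names
    for (s in seq_len(n_sites)) {
      x <- Biostrings::DNAStringSet(reads[[s]])
      # writeXStringSet() warns about dropping the qualities it was handed
      # via mcols; the FASTQ written is complete, so silence it
      suppressWarnings(
        Biostrings::writeXStringSet(x, fastq[s], format = "fastq",
                                    qualities = Biostrings::BStringSet(quals[[s]])))
    }
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- list(sites = pools$site_names,
                     reads_per_site = reads_per_site,
                     error_rate = error_rate, seed = as.integer(seed),
                     repeat_consensus = rm$consensus,
                     variant_freqs = rm$variant_freqs)
    jsonlite::write_json(manifest, file.path(out_dir, "truth_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  structure(list(reads = reads, qualities = quals, truth = truth,
                 fastq = fastq, pools = pools, repeat_model = rm,
                 error_rate = error_rate, k_probs = k_probs,
                 seed = as.integer(seed)),
            class = "synthetic_amplicons")
}

.quality_strings <- function(lens, model) {
  if (model == "constant")
    return(vapply(lens, function(L) strrep("?", L), character(1)))  # Q30
  vapply(lens, function(L) {
    q <- rep(30L, L)
    tail_len <- ceiling(0.3 * L)
    if (tail_len > 1L) {
      i <- (L - tail_len + 1L):L
      q[i] <- as.integer(round(seq(30, 10, length.out = tail_len)))
    }
    intToUtf8(q + 33L)
  }, character(1))
}

#' Plant protospacers with a PAM into a random target genome
#'
#' Embeds each protospacer at a random non-overlapping locus on a random
#' strand of an iid-uniform background genome, writing the PAM's specified
#' (non-N) bases into the 8-nt flank immediately downstream of the
#' protospacer on the protospacer's own strand. `pam = "NNAAAG"` therefore
#' plants AAAG at downstream positions 3-6.
#'
#' @param protospacers Character vector of protospacer sequences (ACGT).
#' @param pam Motif over {A,C,G,T,N} placed left-aligned in the downstream
#'   flank; at most `flank` characters. Use `NULL` for no planted motif.
#' @param genome_length Total genome length (must accommodate all planted
#'   loci including their 8-nt flanks).
#' @param flank Flank width reserved on both sides of each locus (default 8).
#' @param seed Integer seed.
#' @param target_id Sequence name (default "synthetic_target").
#' @param out_fasta Optional path; if given, the genome is written as FASTA.
#' @return List with `sequence`, `truth` (data frame: spacer_id, spacer,
#'   start, end, strand; 0-based half-open plus-strand coordinates of the
#'   protospacer itself), `pam`, `target_id`, `seed`.
#' @export
make_target_genome <- function(protospacers, pam = NULL,
                               genome_length = 50000L, flank = 8L,
                               seed = 1L, target_id = "synthetic_target",
                               out_fasta = NULL) {
  if (!is.null(pam)) {
    if (nchar(pam) > flank)
      stop("PAM motif longer than the flank window")
    if (grepl("[^ACGTN]", pam)) stop("PAM motif must be over {A,C,G,T,N}")
  }
  n <- length(protospacers)
  if (n) assert_acgt(protospacers, "protospacer")
  cass_len <- nchar(protospacers) + 2L * flank
  if (sum(cass_len) > genome_length)
    stop("genome_length cannot accommodate the planted loci and flanks")

  set.seed(as.integer(seed))
  genome <- strsplit(random_dna(1L, genome_length), "", fixed = TRUE)[[1]]
  truth <- data.frame(spacer_id = character(0), spacer = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (n) {
    occupied <- matrix(integer(0), ncol = 2L)   # 1-based inclusive intervals
    ids <- if (is.null(names(protospacers)))
      sprintf("proto%03d", seq_len(n)) else names(protospacers)
    for (i in seq_len(n)) {
      Lc <- cass_len[i]
      for (tr in seq_len(10000L)) {
        s1 <- sample.int(genome_length - Lc + 1L, 1L)   # 1-based cassette start
        iv <- c(s1, s1 + Lc - 1L)
        if (nrow(occupied) == 0L ||
            all(iv[2L] < occupied[, 1L] | iv[1L] > occupied[, 2L])) break
        if (tr == 10000L) stop("could not place non-overlapping loci")
      }
      occupied <- rbind(occupied, iv)
      strand <- sample(c("+", "-"), 1L)
      up <- random_dna(1L, flank)
      down <- strsplit(random_dna(1L, flank), "", fixed = TRUE)[[1]]
      if (!is.null(pam)) {
        pv <- strsplit(pam, "", fixed = TRUE)[[1]]
        fix <- which(pv != "N")
        down[fix] <- pv[fix]
      }
      cassette <- paste0(up, protospacers[i], paste(down, collapse = ""))
      if (strand == "-") cassette <- revcomp(cassette)
      genome[s1:(s1 + Lc - 1L)] <- strsplit(cassette, "", fixed = TRUE)[[1]]
      p_start <- s1 - 1L + flank               # 0-based protospacer start
      truth <- rbind(truth, data.frame(
        spacer_id = ids[i], spacer = protospacers[i],
        start = p_start, end = p_start + nchar(protospacers[i]),
        strand = strand, stringsAsFactors = FALSE))
    }
  }
  sequence <- paste(genome, collapse = "")
  if (!is.null(out_fasta)) {
    x <- Biostrings::DNAStringSet(stats::setNames(sequence, target_id))
    Biostrings::writeXStringSet(x, out_fasta)
  }
  list(sequence = sequence, truth = truth, pam = pam,
       target_id = target_id, seed = as.integer(seed))
}
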