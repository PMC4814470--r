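test_that("site pools honour trivial and full-overlap designs", {
  p1 <- make_site_pools(10L, seed = 1)
  expect_length(p1$pools[[1]], 10L)
  expect_true(all(nchar(p1$pools[[1]]) %in% 28:31))
  expect_equal(anyDuplicated(p1$pools[[1]]), 0L)

  pw <- matrix(c(0L, 5L, 5L, 0L), 2, 2)
  p2 <- make_site_pools(c(5L, 5L), pw, seed = 2)
  expect_setequal(p2$pools[[1]], p2$pools[[2]])
})

test_that("3-site overlap design is realised exactly", {
  pw <- matrix(30L, 3, 3); diag(pw) <- 0L
  pools <- make_site_pools(c(100L, 100L, 100L), pw, all_shared = 10L,
                           seed = 11)
  ov <- pool_overlaps(pools)
  expect_equal(unname(ov$pairwise[upper.tri(ov$pairwise)]), rep(30L, 3))
  expect_equal(ov$all, 10L)
  expect_equal(unname(diag(ov$pairwise)), rep(100L, 3))
  # separation invariant: same-length spacers > 2*radius apart
  all_sp <- unique(unlist(pools$pools))
  for (L in unique(nchar(all_sp))) {
    s <- all_sp[nchar(all_sp) == L]
    if (length(s) < 2) next
    D <- outer(s, s, Vectorize(hamming))
    expect_gt(min(D[upper.tri(D)]), 2 * 5)
  }
})

test_that("infeasible overlap designs are rejected", {
  pw <- matrix(5L, 3, 3); diag(pw) <- 0L
  expect_error(make_site_pools(c(10L, 10L, 10L), pw, all_shared = 7L),
               "infeasible")
  pw2 <- matrix(c(0L, 20L, 20L, 0L), 2, 2)
  expect_error(make_site_pools(c(10L, 30L), pw2, seed = 1), "infeasible")
})

test_that("amplicon structure matches the forced spacer count", {
  pools <- make_site_pools(20L, seed = 3)
  rm <- mk_repeat()
  sim1 <- simulate_amplicons(pools, rm, reads_per_site = 50,
                             k_probs = c(1, 0, 0, 0, 0), error_rate = 0,
                             both_strands = FALSE, seed = 3)
  ex1 <- lapply(sim1$reads[[1]], function(rd)
    find_repeat_matches(rd, rm, max_mismatch = 0))
  expect_true(all(vapply(ex1, function(m) sum(m$full), integer(1)) == 0L))
  expect_true(all(sim1$truth$n_spacers == 1L))

  sim2 <- simulate_amplicons(pools, rm, reads_per_site = 50,
                             k_probs = c(0, 1, 0, 0, 0), error_rate = 0,
                             both_strands = FALSE, seed = 4)
  full_counts <- vapply(sim2$reads[[1]], function(rd)
    sum(find_repeat_matches(rd, rm, max_mismatch = 0)$full), integer(1))
  expect_true(all(full_counts == 1L))
})

test_that("internal repeat variants are sampled at declared frequencies", {
  cons <- mk_repeat()$consensus
  v2 <- with_mismatches(cons, 1, positions = 6)
  rm <- repeat_model(cons, variants = c(cons, v2),
                     variant_freqs = c(0.66, 0.34),
                     forward_primer = substr(cons, 19, 30),
                     reverse_primer = revcomp(substr(cons, 1, 10)))
  pools <- make_site_pools(30L, seed = 5)
  n <- 4000L
  sim <- simulate_amplicons(pools, rm, reads_per_site = n,
                            k_probs = c(0, 1, 0, 0, 0), error_rate = 0,
                            seed = 6)
  vi <- as.integer(sim$truth$variants)
  p_hat <- mean(vi == 1L)
  se <- sqrt(0.66 * 0.34 / n)
  expect_lt(abs(p_hat - 0.66), 3 * se)
})

test_that("identical seeds give byte-identical FASTQ output", {
  pools <- make_site_pools(15L, seed = 9)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  simulate_amplicons(pools, mk_repeat(), reads_per_site = 40,
                     error_rate = 0.01, out_dir = d1, seed = 42)
  simulate_amplicons(pools, mk_repeat(), reads_per_site = 40,
                     error_rate = 0.01, out_dir = d2, seed = 42)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("simulate_amplicons validates inputs", {
  pools <- make_site_pools(5L, seed = 1)
  expect_error(simulate_amplicons(pools, mk_repeat(), error_rate = 0.2),
               "error_rate")
  bad <- pools
  bad$pools[[1]][1] <- strrep("A", 60)   # outside 26-50
  expect_error(simulate_amplicons(bad, mk_repeat(), seed = 1), "26-50")
})

test_that("target genomes embed protospacers and PAM by construction", {
  sp <- random_dna(1, 30)
  g <- make_target_genome(sp, pam = "NNAAAG", genome_length = 2000,
                          seed = 7)
  tr <- g$truth
  expect_equal(nrow(tr), 1L)
  window <- substr(g$sequence, tr$start + 1, tr$end)
  planted <- if (tr$strand == "+") window else revcomp(window)
  expect_identical(planted, sp)
  # AAAG at downstream offsets 3-6 on the protospacer strand
  down <- if (tr$strand == "+")
    substr(g$sequence, tr$end + 1, tr$end + 8)
  else revcomp(substr(g$sequence, tr$start - 7, tr$start))
  expect_identical(substr(down, 3, 6), "AAAG")

  g0 <- make_target_genome(character(0), genome_length = 500, seed = 8)
  expect_equal(nrow(g0$truth), 0L)
  expect_equal(nchar(g0$sequence), 500L)
  expect_error(make_target_genome(sp, pam = "AAAGAAAGA",
                                  genome_length = 2000, seed = 1),
               "longer than the flank")
})

test_that("generator/scanner round-trip recovers planted loci exactly", {
  set.seed(977)   # distinct from the genome seed: identical seeds would
  sp <- random_dna(100, 30)   # replay the same base stream as the background
  g <- make_target_genome(sp, pam = "NNAAAG", genome_length = 50000,
                          seed = 21)
  hits <- scan_protospacers(stats::setNames(sp, g$truth$spacer_id),
                            c(t = g$sequence), max_mismatch = 4)
  hits0 <- hits[hits$mismatches == 0, ]
  expect_equal(nrow(hits0), 100L)
  expect_setequal(
    paste(hits0$query, hits0$start, hits0$end, hits0$strand),
    paste(g$truth$spacer_id, g$truth$start, g$truth$end, g$truth$strand))
})
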