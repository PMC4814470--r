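test_that("quality trimming implements the 3' rule, N and length filters", {
  q30 <- strrep("?", 60)
  # all-Q30, no N: unchanged
  tr <- trim_reads(random_dna(1, 60), qualities = q30)
  expect_equal(nchar(tr$sequences), 60L)
  expect_equal(tr$stats$kept, 1L)

  # read containing N: dropped (no ambiguous bases admitted)
  rd <- paste0(random_dna(1, 30), "N", random_dna(1, 29))
  tr <- trim_reads(rd, qualities = q30)
  expect_equal(tr$stats$dropped_n, 1L)
  expect_length(tr$sequences, 0L)

  # Q15 tail of 10 nt: exactly those 10 bases removed
  qual <- paste0(strrep("?", 60), strrep("0", 10))   # '0' = Q15
  tr <- trim_reads(random_dna(1, 70), qualities = qual)
  expect_equal(nchar(tr$sequences), 60L)

  # short after trimming: dropped
  tr <- trim_reads(random_dna(1, 70),
                   qualities = paste0(strrep("?", 30), strrep("0", 40)))
  expect_equal(tr$stats$dropped_short, 1L)
})

test_that("malformed FASTQ errors name a record index", {
  path <- tempfile(fileext = ".fastq")
  writeLines(c("@r1", "ACGT", "+", "IIII",
               "r2-missing-at", "ACGT", "+", "IIII"), path)
  expect_error(trim_reads(path), "record 2")
  unlink(path)
})

test_that("repeat matches honour strand, position and threshold boundary", {
  rm <- mk_repeat()
  cons <- rm$consensus
  m <- find_repeat_matches(paste0("AAA", cons, "CCC"), rm, max_mismatch = 0,
                           allow_terminal_partial = FALSE)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 3L)
  expect_equal(m$end, 3L + nchar(cons))
  expect_equal(m$strand, "+")
  expect_true(m$full)
  expect_identical(m$observed, cons)

  m2 <- find_repeat_matches(paste0("AAA", revcomp(cons), "CCC"), rm,
                            max_mismatch = 0,
                            allow_terminal_partial = FALSE)
  expect_equal(m2$strand, "-")
  expect_identical(m2$observed, cons)

  # max_mismatch boundary: distance max_mm + 1 is not a match
  for (mm in c(2L, 5L)) {
    at_mm <- with_mismatches(cons, mm)
    over <- with_mismatches(cons, mm + 1L)
    hit <- find_repeat_matches(paste0("GG", at_mm, "GG"), rm,
                               max_mismatch = mm,
                               allow_terminal_partial = FALSE)
    miss <- find_repeat_matches(paste0("GG", over, "GG"), rm,
                                max_mismatch = mm,
                                allow_terminal_partial = FALSE)
    expect_equal(hit$mismatches, mm)
    expect_equal(nrow(miss), 0L)
  }
})

test_that("spacers are extracted between repeats with length bounds", {
  rm <- mk_repeat()
  cons <- rm$consensus
  s1 <- random_dna(1, 30); s2 <- random_dna(1, 29)
  rd <- paste0(cons, s1, cons, s2, cons)
  m <- find_repeat_matches(rd, rm, max_mismatch = 0)
  rec <- extract_spacers(rd, m)
  expect_identical(rec$sequence, c(s1, s2))
  expect_identical(rec$left_variant, c(cons, cons))

  # a 25-nt inter-repeat gap emits nothing (bounds are 26-50)
  rd25 <- paste0(cons, random_dna(1, 25), cons)
  rec25 <- extract_spacers(rd25, find_repeat_matches(rd25, rm, 0))
  expect_equal(nrow(rec25), 0L)

  # mixed-strand matches reject the read
  rdmix <- paste0(cons, random_dna(1, 30), revcomp(cons))
  mmix <- find_repeat_matches(rdmix, rm, 0, allow_terminal_partial = FALSE)
  expect_equal(sort(unique(mmix$strand)), c("-", "+")[order(c("-", "+"))])
  expect_null(extract_spacers(rdmix, mmix))
})

test_that("strand invariance: reverse-complemented reads yield the same records", {
  rm <- mk_repeat()
  pools <- make_site_pools(25L, seed = 31)
  sim <- simulate_amplicons(pools, rm, reads_per_site = 150,
                            error_rate = 0.01, seed = 31)
  fwd <- extract_site(sim$reads[[1]], rm, site = "s")
  rev <- extract_site(revcomp(unname(sim$reads[[1]])), rm, site = "s")
  expect_identical(sort(fwd$spacers$sequence), sort(rev$spacers$sequence))
  expect_identical(sort(fwd$internal_repeats), sort(rev$internal_repeats))
})

test_that("raising max_mismatch never decreases the match count", {
  rm <- mk_repeat()
  set.seed(17)
  pools <- make_site_pools(20L, seed = 17)
  sim <- simulate_amplicons(pools, rm, reads_per_site = 60,
                            error_rate = 0.03, seed = 17)
  for (rd in sim$reads[[1]][1:30]) {
    n_prev <- -1L
    for (mm in 0:6) {
      n <- nrow(find_repeat_matches(rd, rm, max_mismatch = mm))
      expect_gte(n, n_prev)
      n_prev <- n
    }
  }
})

test_that("error-free extraction recovers the planted multiset; conservation holds", {
  rm <- mk_repeat()
  pw <- matrix(10L, 2, 2); diag(pw) <- 0L
  pools <- make_site_pools(c(40L, 40L), pw, seed = 8)
  sim <- simulate_amplicons(pools, rm, reads_per_site = 1500,
                            error_rate = 0, seed = 8)
  for (s in names(sim$reads)) {
    ex <- extract_site(sim$reads[[s]], rm, site = s)
    expect_identical(sort(ex$spacers$sequence), truth_multiset(sim, s))
    # conservation: per read, #records = #internal repeats + 1
    rec_per_read <- table(ex$spacers$read_id)
    k_truth <- sim$truth$n_spacers[sim$truth$site == s]
    names(k_truth) <- sim$truth$read_id[sim$truth$site == s]
    expect_equal(unname(c(rec_per_read)),
                 unname(k_truth[names(rec_per_read)]))
    expect_equal(length(ex$internal_repeats),
                 sum(k_truth - 1L))
  }
})

test_that("internal repeat table recovers planted variant frequencies", {
  cons <- mk_repeat()$consensus
  v2 <- with_mismatches(cons, 1, positions = 6)
  rm <- repeat_model(cons, variants = c(cons, v2),
                     variant_freqs = c(0.66, 0.34),
                     forward_primer = substr(cons, 19, 30),
                     reverse_primer = revcomp(substr(cons, 1, 10)))
  pools <- make_site_pools(30L, seed = 12)

  # single-spacer reads: no internal repeats at all
  sim1 <- simulate_amplicons(pools, rm, reads_per_site = 50,
                             k_probs = c(1, 0, 0, 0, 0), error_rate = 0,
                             seed = 12)
  ex1 <- extract_site(sim1$reads[[1]], rm)
  expect_equal(nrow(internal_repeat_table(ex1)), 0L)

  # two-spacer reads: one internal repeat each; frequencies within 3 SE
  n <- 3000L
  sim2 <- simulate_amplicons(pools, rm, reads_per_site = n,
                             k_probs = c(0, 1, 0, 0, 0), error_rate = 0,
                             seed = 13)
  ex2 <- extract_site(sim2$reads[[1]], rm)
  tab <- internal_repeat_table(ex2)
  expect_equal(sum(tab$count), n)
  expect_equal(sum(tab$frequency), 1)
  se <- sqrt(0.66 * 0.34 / n)
  expect_lt(abs(tab$frequency[tab$variant == cons] - 0.66), 3 * se)
  expect_lt(abs(tab$frequency[tab$variant == v2] - 0.34), 3 * se)
})
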