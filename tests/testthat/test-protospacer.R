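test_that("simple embeddings are found with correct strand and flanks", {
  set.seed(11)
  q <- random_dna(1, 30)
  up <- random_dna(1, 8); down <- random_dna(1, 8)
  target <- paste0(random_dna(1, 40), up, q, down, random_dna(1, 40))

  h <- scan_protospacers(c(q1 = q), c(t = target))
  expect_equal(nrow(h), 1L)
  expect_equal(h$mismatches, 0L)
  expect_equal(h$strand, "+")
  expect_equal(h$start, 48L)
  expect_identical(h$upstream_flank, up)
  expect_identical(h$downstream_flank, down)

  # reverse-complement embedding: minus-strand hit, flanks orientation-swapped
  target2 <- paste0(random_dna(1, 40), revcomp(paste0(up, q, down)),
                    random_dna(1, 40))
  h2 <- scan_protospacers(c(q1 = q), c(t = target2))
  expect_equal(h2$strand, "-")
  expect_identical(h2$upstream_flank, up)
  expect_identical(h2$downstream_flank, down)

  # contig-edge hit: truncated flank flagged
  h3 <- scan_protospacers(c(q1 = q), c(t = paste0(q, random_dna(1, 20))))
  expect_false(h3$flank_complete)
  expect_identical(h3$upstream_flank, "")
})

test_that("the < 5 mismatches boundary excludes 5-mismatch windows", {
  set.seed(12)
  q <- random_dna(1, 30)
  t4 <- paste0(random_dna(1, 30), with_mismatches(q, 4), random_dna(1, 30))
  t5 <- paste0(random_dna(1, 30), with_mismatches(q, 5), random_dna(1, 30))
  expect_equal(scan_protospacers(c(q = q), c(t = t4))$mismatches, 4L)
  expect_equal(nrow(scan_protospacers(c(q = q), c(t = t5))), 0L)
  expect_error(scan_protospacers(c(q = random_dna(1, 19)), c(t = t4)),
               "shorter than 20")
})

test_that("scanner equals the brute-force oracle and is strand-symmetric", {
  set.seed(13)
  target <- paste(random_dna(1, 20000), collapse = "")
  queries <- stats::setNames(random_dna(8, 30), paste0("q", 1:8))
  # plant some decoys at 0 and 4 mismatches
  substr(target, 501, 530) <- queries[1]
  substr(target, 1001, 1030) <- with_mismatches(queries[2], 4)
  substr(target, 2001, 2030) <- revcomp(with_mismatches(queries[3], 3))

  mm <- 4L
  got <- scan_protospacers(queries, c(t = target), max_mismatch = mm)
  oracle <- bf_scan(as.list(queries), target, mm)
  expect_equal(nrow(got), nrow(oracle))
  expect_setequal(paste(got$query, got$start, got$strand, got$mismatches),
                  paste(oracle$query, oracle$start, oracle$strand,
                        oracle$mismatches))

  # N never matches
  tN <- target
  substr(tN, 505, 505) <- "N"
  gotN <- scan_protospacers(queries, c(t = tN), max_mismatch = 0)
  expect_false(any(gotN$start == 500 & gotN$query == "q1"))

  # strand symmetry: scanning the reverse complement mirrors the hit set
  rcg <- scan_protospacers(queries, c(t = revcomp(target)), max_mismatch = mm)
  tlen <- nchar(target)
  expect_setequal(
    paste(got$query, got$start, got$mismatches, got$strand),
    paste(rcg$query, tlen - rcg$end, rcg$mismatches,
          ifelse(rcg$strand == "+", "-", "+")))
})

test_that("pam_profile computes counts and information content", {
  hits <- data.frame(
    upstream_flank = c("AAAAAAAA", "AAAAAAAA", "AAAAAAAA", "AAAAAAAA"),
    downstream_flank = c("AAGGCCTT", "AAGGCCTT", "AAGGCCTT", "AAGGCCTT"),
    flank_complete = TRUE, stringsAsFactors = FALSE)
  prof <- pam_profile(hits, side = "downstream")
  expect_equal(prof$information_content, rep(2, 8))
  expect_equal(unname(colSums(prof$counts)), rep(4L, 8))

  # uniform base usage at a position -> IC = 0 there
  hits2 <- data.frame(
    upstream_flank = rep("AAAAAAAA", 4),
    downstream_flank = paste0(c("A", "C", "G", "T"), "AAAAAAA"),
    flank_complete = TRUE, stringsAsFactors = FALSE)
  prof2 <- pam_profile(hits2, side = "downstream")
  expect_equal(prof2$information_content[1], 0)
  expect_equal(prof2$information_content[2], 2)

  expect_error(pam_profile(hits[1, , drop = FALSE], "downstream"),
               "insufficient hits")
})

test_that("planted PAM is called exactly; null flanks give all N", {
  set.seed(14)
  sp <- random_dna(60, 30)
  g <- make_target_genome(sp, pam = "NNAAAG", genome_length = 60000,
                          seed = 15)
  hits <- scan_protospacers(stats::setNames(sp, g$truth$spacer_id),
                            c(t = g$sequence))
  prof <- pam_profile(hits, "downstream")
  expect_true(all(prof$information_content[3:6] > 1.5))
  expect_true(all(prof$information_content[c(1, 2, 7, 8)] < 0.5))
  expect_identical(call_pam(prof), "NNAAAGNN")
  expect_identical(substr(call_pam(prof), 3, 6), "AAAG")

  # null: no planted motif -> all-N motif
  g0 <- make_target_genome(sp, pam = NULL, genome_length = 60000, seed = 16)
  hits0 <- scan_protospacers(stats::setNames(sp, g0$truth$spacer_id),
                             c(t = g0$sequence))
  expect_identical(call_pam(pam_profile(hits0, "downstream")), "NNNNNNNN")

  # single dominant position
  hits1 <- data.frame(
    upstream_flank = rep("AAAAAAAA", 10),
    downstream_flank = c(paste0(random_dna(10, 4), "G",
                                random_dna(10, 3))),
    flank_complete = TRUE, stringsAsFactors = FALSE)
  m <- call_pam(pam_profile(hits1, "downstream"))
  expect_identical(substr(m, 5, 5), "G")
})
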