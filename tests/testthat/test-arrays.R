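# force distinct first/last bases across spacers so the repeat boundary is
# identifiable: if e.g. every spacer started with A, the planted-repeat+A
# 47-mer would genuinely occur at every instance and no de novo method
# could prefer the 46-nt truth
force_boundaries <- function(spacers) {
  fb <- c("A", "C", "G", "T"); lb <- c("C", "G", "T", "A")
  for (i in seq_along(spacers)) {
    substr(spacers[i], 1, 1) <- fb[(i - 1) %% 4 + 1]
    substr(spacers[i], nchar(spacers[i]), nchar(spacers[i])) <-
      lb[(i - 1) %% 4 + 1]
  }
  spacers
}

# build a genome with a planted array: R s1 R s2 ... R
plant_array <- function(repeat_seq, spacers, flank_len = 5000, seed = 1) {
  set.seed(seed)
  array <- paste0(repeat_seq,
                  paste(vapply(seq_along(spacers), function(i)
                    paste0(spacers[i], repeat_seq), character(1)),
                    collapse = ""))
  left <- random_dna(1, flank_len)
  list(genome = paste0(left, array, random_dna(1, flank_len)),
       start = flank_len, spacers = spacers)
}

test_that("anchored finder recovers planted arrays and honours bounds", {
  set.seed(41)
  rep46 <- random_dna(1, 46)
  sp <- random_dna(3, 30)
  pl <- plant_array(rep46, sp, seed = 42)
  arr <- find_arrays_with_repeat(c(g = pl$genome), rep46)
  expect_length(arr, 1L)
  expect_identical(arr[[1]]$spacers, sp)
  expect_equal(arr[[1]]$start, pl$start)
  expect_equal(nrow(arr[[1]]$repeat_instances), 4L)
  expect_equal(arr[[1]]$orientation, "+")

  # two-spacer arrays are rejected (minimum three spacers)
  pl2 <- plant_array(rep46, random_dna(2, 30), seed = 43)
  expect_length(find_arrays_with_repeat(c(g = pl2$genome), rep46), 0L)

  # a 60-nt gap breaks the chain
  set.seed(44)
  bad <- paste0(random_dna(1, 3000), rep46, random_dna(1, 30), rep46,
                random_dna(1, 60), rep46, random_dna(1, 30), rep46,
                random_dna(1, 3000))
  expect_length(find_arrays_with_repeat(c(g = bad), rep46), 0L)

  expect_error(find_arrays_with_repeat(c(g = bad), random_dna(1, 20)),
               "23-47")
})

test_that("de novo finder recovers planted arrays without the repeat", {
  set.seed(45)
  rep46 <- random_dna(1, 46)
  sp <- force_boundaries(random_dna(4, c(28, 30, 31, 29)))
  pl <- plant_array(rep46, sp, seed = 46)
  arr <- find_arrays_denovo(c(g = pl$genome))
  expect_length(arr, 1L)
  a <- arr[[1]]
  expect_equal(a$orientation, "unknown")
  same <- identical(a$spacers, sp)
  flipped <- identical(a$spacers, rev(revcomp(sp)))
  expect_true(same || flipped)
  cons <- a$repeat_consensus
  d <- min(hamming(cons, rep46), hamming(cons, revcomp(rep46)))
  expect_lte(d, 2L)

  # anchored and de novo agree on the spacer list given the planted repeat
  anchored <- find_arrays_with_repeat(c(g = pl$genome), rep46)
  expect_identical(anchored[[1]]$spacers, if (same) a$spacers
                   else rev(revcomp(a$spacers)))
})

test_that("two arrays with distinct repeats are reported separately", {
  set.seed(47)
  repA <- random_dna(1, 46); repB <- random_dna(1, 36)
  spA <- force_boundaries(random_dna(3, 30))
  spB <- force_boundaries(random_dna(3, 30))
  genome <- paste0(
    random_dna(1, 3000),
    repA, spA[1], repA, spA[2], repA, spA[3], repA,
    random_dna(1, 3000),
    repB, spB[1], repB, spB[2], repB, spB[3], repB,
    random_dna(1, 3000))
  arr <- find_arrays_denovo(c(g = genome))
  expect_length(arr, 2L)
  sp_sets <- lapply(arr, function(a)
    sort(c(a$spacers, revcomp(a$spacers))))
  expect_true(any(vapply(sp_sets, identical, logical(1),
                         sort(c(spA, revcomp(spA))))))
  expect_true(any(vapply(sp_sets, identical, logical(1),
                         sort(c(spB, revcomp(spB))))))
})

test_that("random genomes yield no arrays in at least 9 of 10 runs", {
  fp <- 0L
  for (sd in 1:10) {
    set.seed(1000L + sd)
    g <- random_dna(1, 20000)
    if (length(find_arrays_denovo(c(g = g))) > 0) fp <- fp + 1L
  }
  expect_lte(fp, 1L)
})

test_that("strand invariance: reverse-complemented genome mirrors arrays", {
  set.seed(48)
  rep46 <- random_dna(1, 46)
  sp <- random_dna(3, 30)
  pl <- plant_array(rep46, sp, seed = 49)
  fwd <- find_arrays_with_repeat(c(g = pl$genome), rep46)
  rev_ <- find_arrays_with_repeat(c(g = revcomp(pl$genome)), rep46)
  expect_length(rev_, 1L)
  expect_equal(rev_[[1]]$orientation, "-")
  expect_identical(rev_[[1]]$spacers, fwd[[1]]$spacers)
  glen <- nchar(pl$genome)
  expect_equal(rev_[[1]]$start, glen - fwd[[1]]$end)
  expect_equal(rev_[[1]]$end, glen - fwd[[1]]$start)
})

test_that("emitted arrays satisfy the structural invariants", {
  set.seed(50)
  rep30 <- random_dna(1, 30)
  sp <- random_dna(5, c(26, 50, 30, 28, 45))
  pl <- plant_array(rep30, sp, seed = 51)
  for (a in find_arrays_with_repeat(c(g = pl$genome), rep30)) {
    expect_gte(length(a$spacers), 3L)
    expect_true(all(nchar(a$spacers) >= 26 & nchar(a$spacers) <= 50))
    expect_true(nchar(a$repeat_consensus) >= 23 &&
                  nchar(a$repeat_consensus) <= 47)
    inst <- a$repeat_instances
    expect_equal(nrow(inst), length(a$spacers) + 1L)
    # repeats and spacers alternate with no gaps
    expect_true(all(diff(inst$start) - (nchar(a$repeat_consensus) +
                                          nchar(a$spacers)) == 0))
  }
})
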