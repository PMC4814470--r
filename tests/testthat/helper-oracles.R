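# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written as naive/brute-force R code, independent
# of the package's scan kernels.

# small synthetic repeat model (30 nt, primers 12/10 nt) for fast unit tests
mk_repeat <- function() {
  cons <- "ATGACCGTTACAGGTCATTCCGGATAACTG"
  repeat_model(consensus = cons,
               forward_primer = substr(cons, 19, 30),
               reverse_primer = revcomp(substr(cons, 1, 10)))
}

# apply exactly the substitutions needed to place `x` at Hamming distance d
with_mismatches <- function(x, d, positions = seq_len(d)) {
  v <- strsplit(x, "")[[1]]
  for (p in positions) {
    v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  }
  paste(v, collapse = "")
}

# brute-force protospacer scan: per-window substring comparison, both strands
bf_scan <- function(queries, target, max_mm) {
  hits <- list()
  tlen <- nchar(target)
  for (qn in names(queries)) {
    qlen <- nchar(queries[[qn]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") queries[[qn]] else revcomp(queries[[qn]])
      pv <- utf8ToInt(pat)
      for (s in 0:(tlen - qlen)) {
        win <- utf8ToInt(substr(target, s + 1, s + qlen))
        mm <- sum(win != pv | !(win %in% utf8ToInt("ACGT")))
        if (mm <= max_mm)
          hits[[length(hits) + 1]] <- data.frame(
            query = qn, start = s, end = s + qlen, strand = strand,
            mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(data.frame(query = character(0),
                                       start = integer(0), end = integer(0),
                                       strand = character(0),
                                       mismatches = integer(0)))
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand, out$query), , drop = FALSE]
}

# independent ACE coding (standard abundance-based coverage estimator)
ace_oracle <- function(counts, cutoff = 10) {
  rare <- counts[counts <= cutoff]
  s_abund <- sum(counts > cutoff)
  s_rare <- length(rare)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace <= 0) return(NA_real_)
  i <- seq_len(cutoff)
  fi <- vapply(i, function(k) sum(rare == k), numeric(1))
  g2 <- max(s_rare / c_ace * sum(i * (i - 1) * fi) /
              (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + f1 / c_ace * g2
}

# planted truth spacer multiset for one site of a synthetic_amplicons object
truth_multiset <- function(sim, site) {
  sort(unlist(strsplit(sim$truth$spacers[sim$truth$site == site], ",")))
}

# vectorised brute-force scan oracle (shift-and-accumulate mismatch sums);
# an independent R coding of the same contract as the C++ per-window scan,
# fast enough for 100-kb targets
bf_scan_fast <- function(queries, target, max_mm) {
  tv <- utf8ToInt(target)
  acgt <- utf8ToInt("ACGT")
  tlen <- length(tv)
  hits <- list()
  for (qn in names(queries)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") queries[[qn]] else revcomp(queries[[qn]])
      qv <- utf8ToInt(pat)
      m <- length(qv)
      n <- tlen - m + 1
      if (n < 1) next
      cnt <- integer(n)
      for (j in seq_len(m)) {
        seg <- tv[j:(j + n - 1)]
        cnt <- cnt + as.integer(seg != qv[j] | !(seg %in% acgt))
      }
      s <- which(cnt <= max_mm)
      if (length(s))
        hits[[length(hits) + 1]] <- data.frame(
          query = qn, start = s - 1L, end = s - 1L + m, strand = strand,
          mismatches = cnt[s], stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(data.frame(query = character(0),
                                       start = integer(0), end = integer(0),
                                       strand = character(0),
                                       mismatches = integer(0)))
  do.call(rbind, hits)
}
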