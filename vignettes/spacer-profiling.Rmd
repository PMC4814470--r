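---
title: "Profiling CRISPR spacer repertoires from repeat-anchored amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling CRISPR spacer repertoires from repeat-anchored amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerscope)
```

## The measurement

A type II CRISPR array is an alternation of a near-identical direct repeat
(here modelled at 46 nt, legal range 23–47 nt) and variable spacers
(26–50 nt, typically 28–31 nt) acquired from foreign DNA. PCR primers that
anneal *inside* the repeat — one matching a 3' portion of the repeat, the
other the reverse complement of a 5' portion — amplify fragments of the
form

```
repeat-suffix | spacer | repeat | spacer | ... | spacer | repeat-prefix
```

A fragment carrying $k$ spacers contains exactly $k-1$ complete internal
repeat copies. Two consequences shape the whole analysis:

* the terminal repeats are overwritten by the primer sequence, so only
  **internal** repeat copies report the naturally occurring repeat
  variants;
* the ordering of spacers along the original array is lost — the data is
  a multiset of (spacer, flanking-variant) observations per site.

`spacerscope` turns per-site FASTQ files of such amplicons into spacer
records, radius-certified spacer clusters, richness/coverage estimates,
cross-site sharing reports, and (given target sequences) protospacer hits
with an inferred PAM.

## Model and parameter choices

### Repeat matching and spacer extraction

Repeat occurrences are found by an **ungapped Hamming scan** of the repeat
consensus over both strands of each read; there is no indel handling. The
error model of short-read amplicon data is substitution-dominated, the
repeat has fixed length, and a gapped aligner would add heuristic
nondeterminism for no benefit at these lengths. Defaults:

* `max_mismatch = 5` per 46-nt repeat copy (~11%): read-level tolerance is
  not dictated by the data; 5 matches the clustering radius so that a
  repeat copy carrying typical sequencing error is still anchored.
* Terminal primer-truncated copies are accepted from the primer length
  upward (`full = FALSE` in the match table).
* Overlapping candidate matches are resolved greedily by fewest
  mismatches, full before partial, then leftmost — fully deterministic.
* Reads whose repeat matches disagree in strand are discarded (an
  amplicon is a single-array fragment; mixed strands indicate a chimera
  or spurious match), counted in the extraction statistics.
* Coordinates are 0-based half-open internally; all spacers are
  reverse-complemented onto the repeat's plus strand so records from
  either read orientation are comparable.

The inter-repeat gap is emitted as a spacer only if its length lies in
[26, 50]; gaps outside the bounds are structural artefacts (tandem
repeats, deletions) rather than spacers.

### Clustering: a radius certificate, not a k

Sequencing error inflates apparent spacer diversity. The package groups
spacers so that *every member lies within `radius = 5` substitutions of
its cluster centre*, the count-weighted per-position majority sequence
(ties broken A < C < G < T so that the centre is always a concrete DNA
string usable as a search query). Spacers of different lengths never
co-cluster: a substitution count between sequences of unequal length is
undefined without an alignment, and with observed lengths 28–31 this
costs at most four length classes.

The number of clusters is *not* chosen in advance. Within a length class
the algorithm is a bisecting k-means over the sequences: start with one
cluster; while any cluster violates the radius certificate, split it by
2-means (centres seeded deterministically with the most abundant member
and the member farthest from it; Lloyd iterations with majority-consensus
centres). Bisecting alone, however, can strand members of one true group
on both sides of a split, leaving two certified clusters where one true
cluster exists — we measured 104 clusters recovered from a planted pool
of 100. The implementation therefore finishes with an **agglomerative
polish**: any two clusters are merged whenever the merged member set
still satisfies the radius certificate, taking candidate pairs in
ascending centre-distance order. Planted pools generated at pairwise
separation $> 2r$ can never merge, so the polish restores exactly the
planted clusters (recovery is 10/10 seeds at 0.5%/base error, 10 copies
per spacer). Input is canonicalised (unique sequences sorted, counts
aggregated) before clustering, so results are independent of read order;
the whole procedure is deterministic and the `seed` argument exists only
for interface compatibility.

### Richness, coverage, diversity

All estimators operate on the vector of cluster abundances:

* **Chao1**: classic form $S_{obs} + F_1^2/(2F_2)$ with the
  bias-corrected fallback $S_{obs} + F_1(F_1-1)/2$ when $F_2 = 0$, with
  the standard variance formulas for each branch and a log-normal 95%
  interval on the unseen-class count. (The always-bias-corrected variant
  used by some packages gives 5.33 rather than 6.0 on
  `c(1,1,2,2,5)`; the classic branch rule is the one under test here.)
* **ACE** with rare-class cutoff 10 (the field-standard default; nothing
  in the data dictates another value). When every rare class is a
  singleton the sample coverage $C_{ACE}$ is zero and the estimator is
  undefined; the function falls back to $S_{obs}$ with a warning rather
  than returning infinity. Its standard error is computed by the delta
  method over the rare frequency counts with a numeric gradient, the same
  approach as standard implementations.
* **Good's coverage** $C = 1 - F_1/N$, **Shannon** $-\sum p_i \ln p_i$
  and the unbiased **Simpson** concentration
  $\sum n_i(n_i-1)/(N(N-1))$ (undefined, and an error, for $N < 2$).
* **Estimated library coverage** is defined as
  $\mathrm{round}(100\, S_{obs}/S_{Chao1})$ with half-up rounding. Note
  that published tables of this kind can carry the Chao1- and ACE-based
  coverage columns in swapped positions relative to their richness
  columns; the package implements the definition consistent with the
  narrative quantities (observed/Chao1) and does not reproduce any
  column-label accident.

### Cross-site comparison

Whether two sites "share" a cluster is not well-defined without a
criterion; the package supports both an exact mode (`max_mismatch = 0`)
and a tolerant mode defaulting to the cluster radius (5). Matching
between two sites is **greedy one-to-one** on equal-length consensuses by
ascending Hamming distance (ties: larger combined abundance, then
lexicographic) — many-to-many matching would make Venn region counts
ill-defined. Regions over 2–4 sites are assigned by transitive closure of
the pairwise match edges; a cluster is unique to its site iff its
component contains no other site.

Abundance concentration reports the smallest fraction of clusters (taken
in descending abundance, ties lexicographic) holding a given share
(default 95%) of all spacers. Self-complementary detection flags cluster
pairs whose consensuses are reverse complements within a tolerance
(default exact), including self-palindromic consensuses; such pairs arise
when both orientations of one protospacer were acquired.

### Protospacer scanning and PAM inference

Published analyses of this kind typically use a seeded local aligner
(short-query BLAST) with a mismatch cut-off applied afterwards. The
package instead scans **every full-length ungapped window on both
strands** and reports windows with Hamming distance strictly below 5
mismatches (`max_mismatch = 4`). At query lengths of ~30 nt this is
strictly more sensitive than a word-seeded heuristic and removes its
nondeterminism; the mismatch rule is applied over the full spacer length
(the HSP-length alternative is not recoverable from a printed method).
`N` in a target never matches. Flanks of 8 nt are extracted on the
protospacer's own strand ("downstream" = 3' of the protospacer, the type
II PAM side); contig-edge truncation is flagged and truncated flanks are
excluded from profiles.

The PAM profile is the per-position base-count matrix of the aligned
flanks with information content $IC_j = 2 + \sum_b p_{bj}\log_2 p_{bj}$
bits, without small-sample correction ($n$ is reported; a correction
would obscure the raw conservation signal at the typical $n$ of tens to
hundreds of hits). A motif is called per position as the modal base where
$IC \ge 0.5$ bits **and** the modal fraction is $\ge 0.5$, else `N`;
flanking `N`s are retained (`NNAAAGNN`) so that offsets stay readable.

### Array finding

The anchored mode chains full-length repeat occurrences (both strands)
whose inter-repeat gaps lie within the spacer bounds and emits maximal
chains with at least 3 spacers — the three structural parameters (repeat
23–47, spacer 26–50, ≥ 3 spacers) are the entire contract. The de novo
mode is a minimal seed-and-extend reimplementation of that contract, not
a port of any existing tool: exact 13-mers occurring ≥ 4 times with
consecutive spacings in [repeat\_min + spacer\_min, repeat\_max +
spacer\_max] = [49, 97] seed a candidate repeat, which is extended by
majority vote while column agreement ≥ 70%. With few instances the 70%
rule can extend one column into the spacers by chance (with 4 instances,
a spurious column passes at probability ≈ 0.2), so extension is followed
by **boundary refinement**: edge columns with agreement below 0.9 are
trimmed. Error-free planted arrays have 100% column agreement and are
unaffected. Candidates are validated by the anchored finder; overlapping
candidates resolve to most instances, then longest repeat. Orientation is
reported `"unknown"` in de novo mode — the repeat strand cannot be
inferred without external information, and no leader-end inference is
attempted since spacer order information is lost in amplicon data anyway.

A genuine boundary ambiguity is worth noting: if every spacer in an array
begins with the same base, that base is indistinguishable from a final
repeat position — the longer repeat genuinely occurs at every instance —
and no detector can prefer the "true" boundary. The test fixtures
therefore plant arrays with distinct spacer edge bases, which is the
generic case.

## The synthetic community generator

The generator emulates the statistical structure of repeat-anchored
amplicon data with full ground truth:

* **Pools**: per-site sets of unique spacers, lengths 28–31 nt (uniform
  weights by default), drawn uniformly over {A,C,G,T} with rejection so
  that same-length spacers are pairwise $> 2r$ apart — planted clusters
  are unambiguous under the clustering radius. Overlap designs (pairwise
  shared counts plus a common-to-all count) are realised *exactly* by
  explicit Venn-region construction; infeasible designs error.
* **Abundances**: Zipf weights (exponent 1) over a random spacer order by
  default. Real spacer libraries are strongly concentrated (95% of
  spacers within 14–29% of clusters); a heavy-tailed default exercises
  that regime. `abundance = "uniform"` is available.
* **Reads**: each read carries $k \sim$ `k_probs` spacers (default
  `c(.4, .3, .15, .1, .05)` over 1..5 — the true per-read distribution of
  the motivating data is unknown; fragment sizes of 200–1000 bp imply
  roughly 1–10, and the default stays within the documented 1–5 support),
  sampled without replacement by abundance weight, joined by internal
  repeat variants drawn at the declared frequencies, terminally truncated
  to the primer footprints, emitted on a random strand. Errors are iid
  substitutions (no indels — the downstream model is substitution-only by
  design) at `error_rate` (default 0.001, typical of filtered short
  reads), applied across the whole read. Qualities are constant Q30 by
  default with an optional 3'-decay model to exercise the trimmer.
* **Repeat model**: the real 46-bp repeat of the motivating system is not
  publicly printed, so the default model is a clearly-labelled
  *synthetic* 46-nt stand-in with a 31/25-nt primer pair and four
  variants at frequencies 65.6% / 34% / 0.2% / 0.1% (normalised), the
  minor variants differing at positions 6, 6+13, and 6+21 — mirroring the
  observed variant spectrum of internal repeat copies.
* **Targets**: protospacers planted non-overlapping on random strands of
  an iid background with a PAM motif (e.g. `NNAAAG` ⇒ AAAG at downstream
  offsets 3–6) written into the 8-nt downstream flank on the protospacer
  strand.

Identical seeds reproduce byte-identical FASTQ/TSV/JSON outputs.

**What a green synthetic test does and does not establish.** The
generator's reads are structurally faithful (terminal truncation,
internal variants, both strands, substitution error) but idealised: no
chimeras, no PCR amplification bias, no indels, no quality-dependent
error, iid uniform background in targets. Recovery results on synthetic
data therefore establish the *correctness of the algorithms under the
declared model*, not performance on real libraries; in particular,
real-data cluster counts inherit PCR and coverage biases that no test
here measures. One caution for users writing their own simulations: two
stages seeded with the same integer replay the same RNG stream, so e.g. a
"random" target genome generated with the seed that generated the query
spacers will literally contain them — use distinct seeds per stage.

## Numerical and degenerate-input conventions

* Ambiguous bases: `N` never matches anywhere (scan, repeat match);
  spacer records and cluster inputs must be pure ACGT (reads containing
  N are dropped at trimming).
* All tie-breaks are documented fixed orders (A < C < G < T; mismatches
  then position; abundance then lexicographic) — no hidden randomness.
  The only RNG in the package is in the generator, always behind an
  explicit seed.
* Empty inputs: estimators, clustering and concentration error on empty
  vectors; `internal_repeat_table` returns an empty table;
  `self_complementary_pairs` and `match_clusters` return empty edge sets.
* Simpson's unbiased form is undefined for a single individual and
  errors; ACE falls back to $S_{obs}$ with a warning when undefined.
* Rounding of coverage percentages is half-up (`round_half_up`), not
  banker's.

## Known limitations

* Repeat matching and protospacer scanning are strictly ungapped; indel
  sequencing errors shift the repeat frame and typically cost the read
  (or the hit) rather than producing a wrong spacer.
* Cross-length spacer comparisons (clustering, sharing, self-complements)
  are not attempted; a one-base indel variant of a spacer appears as a
  separate length class.
* De novo array finding honours only the three structural parameters; it
  is not a reimplementation of any published detector's heuristics and
  will miss arrays whose repeats exceed the 5-mismatch instance
  tolerance.
* Venn accounting with tolerant matching can, in principle, chain
  clusters within one site through a cluster of another site; region
  counts are reported per component and per site so the effect is
  visible when it occurs.
* The pipeline is single-threaded; the Rcpp kernels make 10⁴-read sites
  interactive, but 10⁶-read libraries should be split per site.
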