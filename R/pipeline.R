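#' Default pipeline thresholds
#'
#' All defaults mirror the field-standard parameters used throughout the
#' package: Phred 20 quality trimming, 5-mismatch repeat matching, cluster
#' radius 5, 5-mismatch sharing tolerance, protospacer hits at fewer than
#' 5 mismatches, 8-nt PAM flanks.
#'
#' @return Named list of thresholds.
#' @export
default_thresholds <- function() {
  list(min_quality = 20L, min_length = 50L,
       max_mismatch_repeat = 5L, cluster_radius = 5L,
       sharing_mismatch = 5L, protospacer_max_mismatch = 4L,
       spacer_min = 26L, spacer_max = 50L,
       ic_min = 0.5, consensus_fraction = 0.5, flank = 8L,
       rare_cutoff = 10L)
}

#' Run the full spacer-profiling pipeline
#'
#' Orchestrates generate (optional) -> trim -> extract -> cluster ->
#' diversity -> compare -> scan/PAM from a single configuration and writes
#' a report bundle of TSV/JSON/FASTA files. Re-running with an identical
#' configuration produces byte-identical outputs (no timestamps are
#' written). Partial outputs are removed if any stage fails.
#'
#' @param config A list (or path to a JSON file) with elements:
#'   \describe{
#'     \item{synthetic}{optional list for the synthetic generator:
#'       `pool_sizes`, `pairwise_shared`, `all_shared`, `reads_per_site`,
#'       `error_rate`, `site_names` (all optional but `pool_sizes`).}
#'     \item{fastq}{named character vector of per-site FASTQ paths
#'       (alternative to `synthetic`).}
#'     \item{repeat}{optional repeat model specification (list with
#'       `consensus`, `variants`, `variant_freqs`, `forward_primer`,
#'       `reverse_primer`); default [default_repeat_model()].}
#'     \item{thresholds}{optional overrides of [default_thresholds()].}
#'     \item{targets}{optional FASTA path (or named sequences) to scan for
#'       protospacers; skipped when absent.}
#'     \item{seed}{integer seed, mandatory when `synthetic` is used.}
#'     \item{out_dir}{output directory.}
#'   }
#' @return Invisibly, a list with the in-memory stage results (`pools`,
#'   `extractions`, `clusterings`, `diversity`, `sharing`,
#'   `self_complementary`, `internal_repeats`, `hits`, `pam`) and `files`
#'   (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  th <- utils::modifyList(default_thresholds(),
                          as.list(config$thresholds %||% list()))
  rm <- .config_repeat_model(config[["repeat"]])
  written <- character(0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(path) { written <<- c(written, path); path }
  log_lines <- character(0)
  say <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))

  res <- tryCatch({
    say("spacerscope %s", as.character(utils::packageVersion("spacerscope")))
    say("thresholds: %s", jsonlite::toJSON(th, auto_unbox = TRUE))

    # ---- input reads -------------------------------------------------
    pools <- NULL
    if (!is.null(config$synthetic)) {
      if (is.null(config$seed))
        stop("config$seed is mandatory when the synthetic generator runs")
      sy <- config$synthetic
      pools <- make_site_pools(
        pool_sizes = sy$pool_sizes,
        pairwise_shared = sy$pairwise_shared,
        all_shared = sy$all_shared %||% 0L,
        site_names = sy$site_names,
        cluster_radius = th$cluster_radius,
        seed = config$seed)
      sim <- simulate_amplicons(
        pools, rm,
        reads_per_site = sy$reads_per_site %||% 1000L,
        error_rate = sy$error_rate %||% 0.001,
        out_dir = file.path(out_dir, "synthetic"),
        seed = config$seed)
      written <- c(written, sim$fastq,
                   file.path(out_dir, "synthetic",
                             c("truth.tsv", "truth_manifest.json")))
      fastq <- sim$fastq
      say("synthetic: %d sites, seed %d, error_rate %g",
          length(pools$pools), config$seed, sim$error_rate)
    } else if (!is.null(config$fastq)) {
      fastq <- unlist(config$fastq)
      if (is.null(names(fastq)))
        names(fastq) <- tools::file_path_sans_ext(basename(fastq))
      missing <- !file.exists(fastq)
      if (any(missing))
        stop("missing input FASTQ: ", paste(fastq[missing], collapse = ", "))
    } else stop("config must provide either synthetic or fastq inputs")

    # ---- trim + extract ---------------------------------------------
    extractions <- list()
    for (s in names(fastq)) {
      tr <- trim_reads(fastq[[s]], min_quality = th$min_quality,
                       min_length = th$min_length)
      say("trim %s: input=%d dropped_n=%d dropped_short=%d kept=%d",
          s, tr$stats$input, tr$stats$dropped_n, tr$stats$dropped_short,
          tr$stats$kept)
      ex <- extract_site(tr$sequences, rm, site = s,
                         max_mismatch = th$max_mismatch_repeat,
                         length_bounds = c(th$spacer_min, th$spacer_max))
      say("extract %s: reads=%d mixed_strand=%d spacers=%d",
          s, ex$stats$reads, ex$stats$mixed_strand, ex$stats$spacers)
      extractions[[s]] <- ex
    }
    spacers <- do.call(rbind, lapply(extractions, `[[`, "spacers"))
    rownames(spacers) <- NULL
    .write_tsv(spacers, emit(file.path(out_dir, "spacers.tsv")))
    irt <- internal_repeat_table(extractions)
    .write_tsv(irt, emit(file.path(out_dir, "internal_repeats.tsv")))

    # ---- cluster -----------------------------------------------------
    clusterings <- cluster_sites(spacers, radius = th$cluster_radius)
    cl_all <- do.call(rbind, lapply(clusterings, function(x)
      as.data.frame(x, stringsAsFactors = FALSE)))
    rownames(cl_all) <- NULL
    .write_tsv(cl_all, emit(file.path(out_dir, "clusters.tsv")))
    .write_consensus_fasta(clusterings,
                           emit(file.path(out_dir, "cluster_consensus.fasta")))
    say("clusters: %s",
        paste(sprintf("%s=%d", names(clusterings),
                      vapply(clusterings, nrow, integer(1))),
              collapse = " "))

    # ---- diversity ---------------------------------------------------
    div <- diversity_table(clusterings, rare_cutoff = th$rare_cutoff)
    .write_tsv(div, emit(file.path(out_dir, "diversity.tsv")))

    # ---- comparison --------------------------------------------------
    sharing <- NULL
    if (length(clusterings) >= 2L) {
      sharing <- venn_counts(clusterings, max_mismatch = th$sharing_mismatch)
      venn_df <- data.frame(region = names(sharing$region_components),
                            components = as.integer(sharing$region_components),
                            stringsAsFactors = FALSE)
      .write_tsv(venn_df, emit(file.path(out_dir, "venn_regions.tsv")))
      jsonlite::write_json(
        list(region_components = as.list(sharing$region_components),
             percent_unique = as.list(sharing$percent_unique),
             pairwise_shared_percent = sharing$pairwise_shared_percent,
             max_mismatch = sharing$max_mismatch),
        emit(file.path(out_dir, "sharing.json")),
        auto_unbox = TRUE, digits = NA)
    }
    selfc <- do.call(rbind, lapply(names(clusterings), function(s) {
      p <- self_complementary_pairs(clusterings[[s]])
      if (nrow(p)) cbind(site = s, p) else NULL
    }))
    if (is.null(selfc))
      selfc <- data.frame(site = character(0), idx_a = integer(0),
                          idx_b = integer(0))
    .write_tsv(selfc, emit(file.path(out_dir, "self_complementary.tsv")))
    conc <- vapply(clusterings, abundance_concentration, numeric(1))
    say("abundance concentration (95%% of spacers): %s",
        paste(sprintf("%s=%.1f%%", names(conc), conc), collapse = " "))

    # ---- protospacers / PAM -----------------------------------------
    hits <- NULL; pam <- NULL
    if (!is.null(config$targets)) {
      queries <- do.call(rbind, lapply(names(clusterings), function(s) {
        cl <- clusterings[[s]]
        data.frame(id = paste0(s, "|", cl$cluster_id),
                   sequence = cl$consensus, stringsAsFactors = FALSE)
      }))
      hits <- scan_protospacers(queries, config$targets,
                                max_mismatch = th$protospacer_max_mismatch,
                                flank = th$flank)
      .write_tsv(as.data.frame(hits),
                 emit(file.path(out_dir, "protospacer_hits.tsv")))
      say("protospacer scan: %d hits", nrow(hits))
      if (sum(hits$flank_complete) >= 2L) {
        pam <- pam_profile(hits, side = "downstream", flank = th$flank)
        motif <- call_pam(pam, ic_min = th$ic_min,
                          consensus_fraction = th$consensus_fraction)
        jsonlite::write_json(
          list(side = pam$side, n_hits = pam$n_hits,
               counts = pam$counts,
               information_content = pam$information_content,
               motif = motif),
          emit(file.path(out_dir, "pam_report.json")),
          auto_unbox = TRUE, digits = NA)
        say("PAM (downstream): %s", motif)
      } else say("PAM inference skipped: fewer than 2 complete flanks")
    } else say("protospacer/PAM stage skipped: no targets configured")

    writeLines(log_lines, emit(file.path(out_dir, "run_log.txt")))
    list(pools = pools, extractions = extractions,
         clusterings = clusterings, diversity = div, sharing = sharing,
         self_complementary = selfc, internal_repeats = irt,
         abundance_concentration = conc,
         hits = hits, pam = pam, files = written)
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.config_repeat_model <- function(spec) {
  if (is.null(spec)) return(default_repeat_model())
  if (inherits(spec, "repeat_model")) return(spec)
  repeat_model(consensus = spec$consensus,
               variants = spec$variants %||% spec$consensus,
               variant_freqs = spec$variant_freqs %||% 1,
               forward_primer = spec$forward_primer,
               reverse_primer = spec$reverse_primer,
               primer_mismatch = spec$primer_mismatch %||% 0L)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.write_consensus_fasta <- function(clusterings, path) {
  seqs <- unlist(lapply(names(clusterings), function(s) {
    cl <- clusterings[[s]]
    stats::setNames(cl$consensus,
                    sprintf("%s|%s|%d", s, cl$cluster_id, cl$abundance))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}
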