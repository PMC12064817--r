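# Pipeline orchestration: staged scan -> build -> score workflow, run
# configuration, deterministic text writers (BED3/BED12/GFF3/TSV), and the
# command functions behind the CLI script.

#' Run configuration with pipeline defaults
#'
#' Collects every tunable of the pipeline with its default: 500 bp windows
#' advanced by 250 bp; selection when the top/bottom 20% differ from the
#' median by more than 1 RPM and more than 1 unit of |log2 fold change|
#' (pseudocount 0.1 RPM); boundary refinement at 0.5 RPM pooled coverage
#' with a 50 bp gap tolerance; junction support >= 3 with introns >= 30 bp;
#' and the scoring windows/motifs of \code{\link{scoring_defaults}}.
#'
#' @param ... Overrides of any default, plus optional I/O fields used by
#'   the command functions: \code{genome_fasta}, \code{annotation},
#'   \code{samples} (list of \code{list(path=, id=, mapped_reads=)}),
#'   \code{models}, \code{out_dir}, \code{sim_dir}, \code{format},
#'   \code{seed}.
#' @return Named list of class \code{run_config}.
#' @export
run_config <- function(...) {
  cfg <- list(window = 500L, step = 250L,
              abs_diff_min = 1, log2fc_min = 1, pseudocount = 0.1,
              min_rpm = 0.5, max_gap = 50L,
              min_support = 3L, min_intron = 30L,
              seed = 42L,
              scoring = scoring_defaults())
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  structure(utils::modifyList(cfg, over), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return \code{read_run_config} returns a \code{run_config};
#'   \code{write_run_config} returns \code{path} invisibly.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config A \code{run_config}.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Scan a cohort for outlier-expressed intergenic regions
#'
#' Stage one of the pipeline: tiles the genome, builds the RPM coverage
#' matrix, applies the outlier selection rule, removes windows overlapping
#' annotated genes, and merges the survivors.
#'
#' @param samples List of \code{sample_alignment} objects (>= 5).
#' @param chrom_lengths Named chromosome lengths (or a \code{DNAStringSet}).
#' @param annotation \code{GRanges} of known gene spans.
#' @param config A \code{run_config}.
#' @return List with \code{stats} (all windows), \code{regions} (merged
#'   candidate \code{GRanges}) and \code{counts} (per-stage tallies).
#' @export
scan_cohort <- function(samples, chrom_lengths, annotation = GRanges(),
                        config = run_config()) {
  windows <- make_windows(chrom_lengths, config$window, config$step)
  m <- build_matrix(samples, windows)
  stats <- window_statistics(m, abs_diff_min = config$abs_diff_min,
                             log2fc_min = config$log2fc_min,
                             pseudocount = config$pseudocount)
  sel <- stats[stats$selected, , drop = FALSE]
  kept <- filter_known(sel, annotation)
  regions <- merge_windows(.stats_granges(kept))
  counts <- c(windows = nrow(stats), selected = nrow(sel),
              after_gene_filter = nrow(kept), merged = length(regions))
  message(sprintf(
    "scan: %d windows, %d selected, %d after gene filter, %d merged regions",
    counts[1], counts[2], counts[3], counts[4]))
  list(stats = stats, regions = regions, counts = counts)
}

# mean cohort RPM of a candidate over its exons
.candidate_mean_rpm <- function(candidate, samples) {
  vals <- vapply(samples, function(aln) {
    cov <- .raw_coverage(aln)
    tot <- sum(vapply(seq_along(candidate$exons), function(i)
      sum(.rle_window(cov, as.character(seqnames(candidate$exons))[i],
                      start(candidate$exons)[i], end(candidate$exons)[i])),
      numeric(1)))
    rpm_normalize(tot / sum(width(candidate$exons)), mapped_read_count(aln))
  }, numeric(1))
  mean(vals)
}

#' Expand candidate regions to transcripts and score them
#'
#' Stage two: each merged region is refined against pooled coverage,
#' junctions are collected and strand inferred, an exon chain is
#' assembled, and the candidate is scored and ranked. Regions with no
#' coverage at or above \code{min_rpm} are skipped with a warning.
#'
#' @param regions Merged candidate \code{GRanges} from
#'   \code{\link{scan_cohort}}.
#' @param samples List of \code{sample_alignment} objects.
#' @param genome \code{DNAStringSet}.
#' @param annotation \code{GRanges} of known gene spans (extension barrier).
#' @param config A \code{run_config}.
#' @return List with \code{candidates} (list of
#'   \code{transcript_candidate}), \code{junctions} (list of data.frames)
#'   and \code{scores} (ranked score-card data.frame).
#' @export
build_and_score <- function(regions, samples, genome,
                            annotation = GRanges(), config = run_config()) {
  pooled <- pooled_rpm_coverage(samples)
  candidates <- list(); junctions <- list(); cards <- list()
  for (i in seq_along(regions)) {
    refined <- extend_boundaries(regions[i], pooled,
                                 min_rpm = config$min_rpm,
                                 max_gap = config$max_gap,
                                 annotation = annotation)
    if (is.null(refined)) {
      warning("region ", i, " has no coverage >= min_rpm at build time; skipped")
      next
    }
    jx <- collect_junctions(samples, refined, genome = genome,
                            min_support = config$min_support,
                            min_intron = config$min_intron)
    strand <- infer_strand(jx)
    id <- sprintf("cand_%03d", length(candidates) + 1L)
    cand <- assemble_exons(refined, jx, strand = strand, id = id)
    card <- score_candidate(cand, genome, junctions = jx,
                            mean_rpm = .candidate_mean_rpm(cand, samples),
                            config = config$scoring)
    cand$strand <- card$strand  # orientation chosen during scoring
    candidates[[id]] <- cand
    junctions[[id]] <- jx
    cards[[id]] <- card
  }
  scores <- if (length(cards)) rank_candidates(do.call(rbind, cards))
            else data.frame()
  message(sprintf("build/score: %d candidates scored", length(candidates)))
  list(candidates = candidates, junctions = junctions, scores = scores)
}

#' Score user-supplied transcript models
#'
#' Score-only mode: takes existing transcript models (e.g. read from
#' BED12 with \code{\link{read_models_bed12}}) and scores them against the
#' genome, optionally using cohort alignments for junction validity and
#' the mean-RPM tie-breaker.
#'
#' @param models List of \code{transcript_candidate} objects.
#' @param genome \code{DNAStringSet}.
#' @param samples Optional list of \code{sample_alignment} objects.
#' @param config A \code{run_config}.
#' @return Ranked score-card data.frame.
#' @export
score_models <- function(models, genome, samples = NULL,
                         config = run_config()) {
  cards <- lapply(models, function(cand) {
    span <- GRanges(as.character(seqnames(cand$exons))[1],
                    IRanges(min(start(cand$exons)), max(end(cand$exons))))
    jx <- if (!is.null(samples))
      collect_junctions(samples, span, genome = genome,
                        min_support = config$min_support,
                        min_intron = config$min_intron) else NULL
    rpm <- if (!is.null(samples)) .candidate_mean_rpm(cand, samples)
           else NA_real_
    score_candidate(cand, genome, junctions = jx, mean_rpm = rpm,
                    config = config$scoring)
  })
  rank_candidates(do.call(rbind, cards))
}

#' Run the full discovery pipeline
#'
#' Scan, build and score in one call; optionally writes all standard
#' outputs (BED3 regions, window-stats TSV, GFF3 + BED12 transcript
#' models, ranked score TSV) into \code{out_dir}.
#'
#' @param samples List of \code{sample_alignment} objects.
#' @param genome \code{DNAStringSet}.
#' @param annotation \code{GRanges} of known gene spans.
#' @param config A \code{run_config}.
#' @param out_dir Optional output directory.
#' @return List combining the results of \code{\link{scan_cohort}} and
#'   \code{\link{build_and_score}}.
#' @export
run_pipeline <- function(samples, genome, annotation = GRanges(),
                         config = run_config(), out_dir = NULL) {
  scan <- scan_cohort(samples, genome, annotation, config)
  built <- build_and_score(scan$regions, samples, genome, annotation, config)
  res <- c(scan, built)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_regions_bed(scan$regions, file.path(out_dir, "regions.bed"))
    write_stats_tsv(scan$stats, file.path(out_dir, "window_stats.tsv"))
    write_candidates_gff3(built$candidates, file.path(out_dir, "candidates.gff3"))
    write_candidates_bed12(built$candidates, file.path(out_dir, "candidates.bed12"))
    write_scores_tsv(built$scores, file.path(out_dir, "scores.tsv"))
  }
  res
}

# ---- deterministic text writers (BED uses 0-based half-open starts) ----

#' Write merged regions as BED3
#' @param regions A \code{GRanges}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  writeLines(sprintf("%s\t%d\t%d", as.character(seqnames(regions)),
                     start(regions) - 1L, end(regions)), path)
  invisible(path)
}

#' Write window statistics as TSV
#' @param stats Window statistics data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_stats_tsv <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write ranked score cards as TSV
#' @param scores Score-card data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write transcript candidates as GFF3
#' @param candidates List of \code{transcript_candidate} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_candidates_gff3 <- function(candidates, path) {
  lines <- "##gff-version 3"
  for (cand in candidates) {
    chrom <- as.character(seqnames(cand$exons))[1]
    s <- min(start(cand$exons)); e <- max(end(cand$exons))
    st <- if (cand$strand %in% c("+", "-")) cand$strand else "."
    lines <- c(lines,
      sprintf("%s\tlncscout\tgene\t%d\t%d\t.\t%s\t.\tID=%s_g", chrom, s, e, st, cand$id),
      sprintf("%s\tlncscout\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s_g",
              chrom, s, e, st, cand$id, cand$id),
      sprintf("%s\tlncscout\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              chrom, start(cand$exons), end(cand$exons), st, cand$id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write transcript candidates as BED12
#' @param candidates List of \code{transcript_candidate} objects.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_candidates_bed12 <- function(candidates, path) {
  lines <- vapply(candidates, function(cand) {
    chrom <- as.character(seqnames(cand$exons))[1]
    s <- min(start(cand$exons)) - 1L; e <- max(end(cand$exons))
    st <- if (cand$strand %in% c("+", "-")) cand$strand else "."
    sizes <- paste0(paste(width(cand$exons), collapse = ","), ",")
    starts <- paste0(paste(start(cand$exons) - 1L - s, collapse = ","), ",")
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            chrom, s, e, cand$id, st, s, s, length(cand$exons), sizes, starts)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read transcript models from BED12
#'
#' @param path BED12 file path.
#' @return List of \code{transcript_candidate} objects (block structure
#'   becomes the exon chain).
#' @export
read_models_bed12 <- function(path) {
  tab <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 12L) stop("not a BED12 file: ", path)
  lapply(seq_len(nrow(tab)), function(i) {
    chrom <- tab[i, 1]; cs <- tab[i, 2]; id <- as.character(tab[i, 4])
    st <- tab[i, 6]; if (!st %in% c("+", "-")) st <- "*"
    sizes <- as.integer(strsplit(sub(",$", "", tab[i, 11]), ",")[[1]])
    offs <- as.integer(strsplit(sub(",$", "", tab[i, 12]), ",")[[1]])
    ex <- GRanges(chrom, IRanges(start = cs + offs + 1L, width = sizes),
                  strand = st)
    tss <- if (identical(st, "-")) max(end(ex)) else min(start(ex))
    end3 <- if (identical(st, "-")) min(start(ex)) else max(end(ex))
    structure(list(id = id, exons = ex, strand = st, tss = tss,
                   end3 = end3, n_ex = length(ex)),
              class = "transcript_candidate")
  })
}

# ---- command functions used by the CLI script ----

.cfg_samples <- function(config) {
  stopifnot(!is.null(config$samples))
  lapply(config$samples, function(s)
    sample_alignment(s$path,
                     sample_id = if (!is.null(s$id)) s$id else basename(s$path),
                     mapped_reads = s$mapped_reads))
}

.cfg_annotation <- function(config) {
  if (is.null(config$annotation)) GRanges() else read_annotation(config$annotation)
}

#' Pipeline subcommands
#'
#' Thin command wrappers used by the \command{lncscout} CLI script (in
#' \code{inst/cli}): \code{cmd_simulate} materializes a synthetic cohort,
#' \code{cmd_scan} runs the window scan and writes regions + stats,
#' \code{cmd_build_score} expands and scores scanned regions, and
#' \code{cmd_score_only} scores user-supplied BED12 models. All take a
#' \code{run_config} (or a YAML path understood by
#' \code{\link{read_run_config}}).
#'
#' @param config A \code{run_config} or path to a YAML config.
#' @return Invisibly, the result object of the underlying stage.
#' @export
cmd_simulate <- function(config) {
  config <- .as_config(config)
  dir <- if (!is.null(config$sim_dir)) config$sim_dir else "cohort"
  fx <- fixture_small(dir = dir,
                      format = if (!is.null(config$format)) config$format else "bam",
                      seed = config$seed)
  message("simulate: cohort written to ", fx$dir)
  invisible(fx)
}

#' @rdname cmd_simulate
#' @export
cmd_scan <- function(config) {
  config <- .as_config(config)
  samples <- .cfg_samples(config)
  genome <- read_genome(config$genome_fasta)
  res <- scan_cohort(samples, genome, .cfg_annotation(config), config)
  out <- if (!is.null(config$out_dir)) config$out_dir else "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_regions_bed(res$regions, file.path(out, "regions.bed"))
  write_stats_tsv(res$stats, file.path(out, "window_stats.tsv"))
  invisible(res)
}

#' @rdname cmd_simulate
#' @export
cmd_build_score <- function(config) {
  config <- .as_config(config)
  samples <- .cfg_samples(config)
  genome <- read_genome(config$genome_fasta)
  res <- run_pipeline(samples, genome, .cfg_annotation(config), config,
                      out_dir = if (!is.null(config$out_dir)) config$out_dir else ".")
  invisible(res)
}

#' @rdname cmd_simulate
#' @export
cmd_score_only <- function(config) {
  config <- .as_config(config)
  genome <- read_genome(config$genome_fasta)
  models <- read_models_bed12(config$models)
  samples <- if (!is.null(config$samples)) .cfg_samples(config) else NULL
  scores <- score_models(models, genome, samples, config)
  out <- if (!is.null(config$out_dir)) config$out_dir else "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_scores_tsv(scores, file.path(out, "scores.tsv"))
  invisible(scores)
}

.as_config <- function(config) {
  if (is.character(config)) read_run_config(config)
  else run_config(unclass(config))
}
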