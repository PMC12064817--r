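# Deterministic synthetic cohort: a random genome with decoy genes and
# planted intergenic transcripts whose promoter composition, core-promoter
# motif, poly(A)/T-rich 3' end, ORF and exon-intron structure are
# constructed analytically, plus simulated per-sample alignments in which
# each plant is expressed only in a minority of samples (the coverage
# structure the outlier selection rule looks for).

#' Specification of a synthetic cohort
#'
#' The defaults describe the bundled micro-cohort: 5 samples over a 50 kb
#' single-chromosome genome with 2 decoy genes and 2 planted intergenic
#' transcripts, each expressed at ~10x depth in 2 of 5 samples over a
#' sparse background. \code{library_size} is the nominal mapped-read count
#' used as RPM denominator: the micro-genome stands for a 50 kb slice of a
#' full-size library, so a simulated depth of d corresponds to d RPM and
#' the selection thresholds keep their usual meaning.
#'
#' @param n_samples Number of samples (>= 5).
#' @param genome_length Chromosome length in bp.
#' @param n_decoys Number of annotated decoy genes.
#' @param background_depth Expected background depth per base per sample.
#' @param plant_depth Target per-base depth of a plant in its expressing
#'   samples.
#' @param read_length Simulated read length in nt.
#' @param library_size Nominal mapped reads per sample (RPM denominator).
#' @param seed Integer seed; fully determines all outputs.
#' @return A list of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_samples = 5L, genome_length = 50000L,
                        n_decoys = 2L, background_depth = 0.05,
                        plant_depth = 10L, read_length = 100L,
                        library_size = 1e6, seed = 42L) {
  stopifnot(n_samples >= 5L, genome_length >= 10000L, read_length >= 20L)
  structure(list(n_samples = as.integer(n_samples),
                 genome_length = as.integer(genome_length),
                 n_decoys = as.integer(n_decoys),
                 background_depth = background_depth,
                 plant_depth = plant_depth,
                 read_length = as.integer(read_length),
                 library_size = library_size,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# run code under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic genome with decoy gene annotation
#'
#' Draws a uniform-composition random chromosome (named \code{chrS}) and
#' places \code{n_decoys} annotated decoy gene spans at fixed relative
#' positions. Byte-identical output for identical seeds.
#'
#' @param spec A \code{cohort_spec}.
#' @return List with \code{genome} (\code{DNAStringSet}) and
#'   \code{annotation} (\code{GRanges} of decoy gene spans).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  L <- spec$genome_length
  genome <- .with_seed(spec$seed, {
    DNAStringSet(setNames(
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      "chrS"))
  })
  # decoys sit in the first and last fifths; plants use the middle
  anchors <- c(0.1, 0.8, 0.04, 0.88)[seq_len(spec$n_decoys)]
  ann <- GRanges("chrS",
                 IRanges(start = round(anchors * L) + 1L,
                         width = 4000L))
  ann <- ann[end(ann) <= L]
  mcols(ann)$gene_id <- paste0("decoy_", seq_along(ann))
  seqlengths(ann) <- c(chrS = L)
  list(genome = genome, annotation = sort(ann))
}

#' Describe a transcript to plant
#'
#' A plant is an intergenic transcript whose sequence is written into the
#' genome so that its gene-body features are exactly known: block-composed
#' promoter with controllable G+C and G+T fractions, optional TATA box at
#' offset -28, optional ORF spanning all exons including the last, a
#' perfect/near-perfect/absent poly(A) hexamer, optional T-rich tail, and
#' canonical GT..AG introns.
#'
#' @param id Plant identifier.
#' @param tss 1-based genomic coordinate of the transcription start.
#' @param exon_lengths Exon lengths, 5' to 3'.
#' @param intron_lengths Intron lengths (one fewer than exons, >= 30 bp).
#' @param expressed_in Integer indices of the samples expressing the plant.
#' @param depth Target per-base depth in expressing samples.
#' @param promoter_gc,promoter_gt Target G+C and G+T fractions of the
#'   200 bp upstream promoter block.
#' @param tata Plant a TATAAA box at offset -28?
#' @param polya One of \code{"perfect"}, \code{"near"}, \code{"none"}.
#' @param trich Plant a T-rich run downstream of the poly(A) site?
#' @param orf Plant an ORF spanning all exons including the last?
#' @return A list of class \code{plant_spec}.
#' @export
plant_spec <- function(id, tss, exon_lengths, intron_lengths = integer(0),
                       expressed_in, depth = 10L,
                       promoter_gc = 0.7, promoter_gt = 0.7,
                       tata = TRUE, polya = c("perfect", "near", "none"),
                       trich = TRUE, orf = TRUE) {
  polya <- match.arg(polya)
  stopifnot(length(intron_lengths) == length(exon_lengths) - 1L,
            all(exon_lengths >= 60L), all(intron_lengths >= 30L))
  structure(list(id = id, tss = as.integer(tss), strand = "+",
                 exon_lengths = as.integer(exon_lengths),
                 intron_lengths = as.integer(intron_lengths),
                 expressed_in = as.integer(expressed_in),
                 depth = depth, promoter_gc = promoter_gc,
                 promoter_gt = promoter_gt, tata = tata, polya = polya,
                 trich = trich, orf = orf),
            class = "plant_spec")
}

#' Default plants of the micro-cohort
#'
#' Two intergenic plants: \code{plant_full}, a 3-exon transcript carrying
#' every scored feature (expected total score 4), and
#' \code{plant_minimal}, a single-exon transcript with GC/GT-skewed
#' promoter, no motif, no ORF, and a near-perfect poly(A) signal.
#'
#' @param spec A \code{cohort_spec}.
#' @return List of \code{plant_spec} objects.
#' @export
default_plants <- function(spec) {
  L <- spec$genome_length
  list(
    plant_spec("plant_full", tss = round(0.4 * L) + 1L,
               exon_lengths = c(300L, 200L, 250L),
               intron_lengths = c(150L, 150L),
               expressed_in = c(1L, 2L), depth = spec$plant_depth,
               tata = TRUE, polya = "perfect", trich = TRUE, orf = TRUE),
    plant_spec("plant_minimal", tss = round(0.64 * L) + 1L,
               exon_lengths = 600L, intron_lengths = integer(0),
               expressed_in = c(3L, 4L), depth = spec$plant_depth,
               tata = FALSE, polya = "near", trich = FALSE, orf = FALSE)
  )
}

# deterministic repetition of a pattern cut to length n
.fill <- function(pattern, n) {
  if (n <= 0L) return("")
  substr(strrep(pattern, ceiling(n / nchar(pattern))), 1L, n)
}

# 200 bp promoter with exact base counts arranged in G|C|A|T blocks (the
# block layout provably contains no TATA/Inr/DPE consensus), TATAAA
# overwritten at offsets -28..-23 when requested
.promoter_seq <- function(ps, up = 200L) {
  g <- max(ps$promoter_gc * ps$promoter_gt, ps$promoter_gc + ps$promoter_gt - 1)
  ng <- round(g * up)
  nc <- round(ps$promoter_gc * up) - ng
  nt <- round(ps$promoter_gt * up) - ng
  na <- up - ng - nc - nt
  if (min(ng, nc, nt, na) < 0L) stop("infeasible promoter composition targets")
  s <- paste0(strrep("G", ng), strrep("C", nc), strrep("A", na), strrep("T", nt))
  if (ps$tata) {
    # offset -28 relative to the TSS = promoter positions up-28+1 .. up-23
    substr(s, up - 27L, up - 22L) <- "TATAAA"
  }
  s
}

# realize the planted locus: list(promoter, exon_seqs, intron_seqs,
# downstream, spliced) -- all deterministic given the plant spec
.plant_sequences <- function(ps, downstream_len = 106L) {
  L <- sum(ps$exon_lengths)
  tail_seq <- if (ps$polya == "none") "" else {
    hex <- if (ps$polya == "perfect") "AATAAA" else "AATAAG"
    paste0("C", hex, if (ps$trich) strrep("T", 10L) else .fill("CTG", 10L))
  }
  body_len <- L - nchar(tail_seq)
  spliced <- if (ps$orf) {
    utr5 <- 55L + (body_len - 55L) %% 3L
    orf_len <- body_len - utr5          # multiple of 3 by construction
    stopifnot(orf_len >= 9L)
    paste0(.fill("GT", utr5), "ATG", .fill("GGT", orf_len - 6L), "TAA", tail_seq)
  } else {
    paste0(.fill("CTG", body_len), tail_seq)
  }
  stopifnot(nchar(spliced) == L)
  cum <- c(0L, cumsum(ps$exon_lengths))
  exon_seqs <- vapply(seq_along(ps$exon_lengths), function(i)
    substr(spliced, cum[i] + 1L, cum[i + 1L]), "")
  intron_seqs <- vapply(ps$intron_lengths, function(w)
    paste0("GT", strrep("C", w - 4L), "AG"), "")
  downstream <- if (ps$trich) strrep("T", downstream_len)
                else .fill("CTG", downstream_len)
  list(promoter = .promoter_seq(ps), exon_seqs = exon_seqs,
       intron_seqs = intron_seqs, downstream = downstream, spliced = spliced)
}

# genomic exon coordinates of a plant (1-based, genomic order)
.plant_exons <- function(ps) {
  starts <- integer(length(ps$exon_lengths))
  pos <- ps$tss
  for (i in seq_along(ps$exon_lengths)) {
    starts[i] <- pos
    pos <- pos + ps$exon_lengths[i]
    if (i < length(ps$exon_lengths)) pos <- pos + ps$intron_lengths[i]
  }
  GRanges("chrS", IRanges(starts, width = ps$exon_lengths), strand = ps$strand)
}

#' Write planted transcripts into a genome
#'
#' Rewrites each plant's locus (200 bp promoter, exons, introns, and the
#' ~100 bp downstream of the 3' end) so that its features are realized
#' exactly, then computes the expected score card of every plant directly
#' from the planted sequence and structure with the scoring functions,
#' independent of the discovery pipeline.
#'
#' @param genome \code{DNAStringSet} from \code{\link{generate_genome}}.
#' @param plants List of \code{plant_spec} objects.
#' @param annotation Optional \code{GRanges}; plants are checked to be
#'   intergenic with respect to it.
#' @return List with \code{genome} (edited), \code{plants}, and
#'   \code{truth}: a data.frame of plant coordinates, exon structure and
#'   expected sub-scores/total.
#' @export
plant_transcripts <- function(genome, plants, annotation = NULL) {
  chr <- as.character(genome[["chrS"]])
  L <- nchar(chr)
  spans <- lapply(plants, function(ps) {
    ex <- .plant_exons(ps)
    GRanges("chrS", IRanges(ps$tss - 200L, max(end(ex)) + 106L))
  })
  spans <- do.call(c, spans)
  if (any(start(spans) < 1L | end(spans) > L))
    stop("plant does not fit inside the genome")
  if (length(spans) > 1L && any(countOverlaps(spans, spans) > 1L))
    stop("planted loci overlap each other")
  if (!is.null(annotation) && length(annotation) &&
      any(overlapsAny(spans, annotation, ignore.strand = TRUE)))
    stop("plant declared intergenic overlaps the annotation: ",
         paste(plants[[which(overlapsAny(spans, annotation))[1]]]$id))

  truth_rows <- list()
  for (ps in plants) {
    seqs <- .plant_sequences(ps)
    ex <- .plant_exons(ps)
    substr(chr, ps$tss - 200L, ps$tss - 1L) <- seqs$promoter
    for (i in seq_along(ex)) {
      substr(chr, start(ex)[i], end(ex)[i]) <- seqs$exon_seqs[i]
      if (i < length(ex))
        substr(chr, end(ex)[i] + 1L, start(ex)[i + 1L] - 1L) <- seqs$intron_seqs[i]
    }
    substr(chr, max(end(ex)) + 1L, max(end(ex)) + nchar(seqs$downstream)) <-
      seqs$downstream
  }
  genome2 <- DNAStringSet(setNames(chr, "chrS"))

  for (ps in plants) {
    ex <- .plant_exons(ps)
    cand <- structure(list(id = ps$id, exons = ex, strand = ps$strand,
                           tss = ps$tss, end3 = max(end(ex)),
                           n_ex = length(ex)),
                      class = "transcript_candidate")
    jx <- if (length(ex) > 1L) {
      data.frame(chrom = "chrS",
                 intron_start = utils::head(end(ex), -1L) + 1L,
                 intron_end = utils::tail(start(ex), -1L) - 1L,
                 support = 999L, stringsAsFactors = FALSE)
    } else NULL
    if (!is.null(jx))
      jx$motif <- vapply(seq_len(nrow(jx)), function(i)
        paste0(substr(chr, jx$intron_start[i], jx$intron_start[i] + 1L),
               substr(chr, jx$intron_end[i] - 1L, jx$intron_end[i])), "")
    card <- score_candidate(cand, genome2, junctions = jx)
    card$exons <- paste(paste0(start(ex), "-", end(ex)), collapse = ",")
    card$expressed_in <- paste(ps$expressed_in, collapse = ",")
    card$depth <- ps$depth
    truth_rows[[ps$id]] <- card
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(genome = genome2, plants = plants, truth = truth)
}

# map a read of length rl starting at spliced coordinate a onto genomic
# blocks of an exon chain; returns list(pos, cigar)
.spliced_read <- function(exon_starts, exon_widths, a, rl) {
  cum <- c(0L, cumsum(exon_widths))
  b <- a + rl - 1L
  stopifnot(b <= cum[length(cum)])
  mlens <- integer(0); glo <- integer(0); ghi <- integer(0)
  for (j in seq_along(exon_widths)) {
    lo <- max(a, cum[j] + 1L); hi <- min(b, cum[j + 1L])
    if (lo > hi) next
    gs <- exon_starts[j] + (lo - cum[j] - 1L)
    ge <- exon_starts[j] + (hi - cum[j] - 1L)
    mlens <- c(mlens, hi - lo + 1L); glo <- c(glo, gs); ghi <- c(ghi, ge)
  }
  cig <- character(0)
  for (k in seq_along(mlens)) {
    if (k > 1L) cig <- c(cig, paste0(glo[k] - ghi[k - 1L] - 1L, "N"))
    cig <- c(cig, paste0(mlens[k], "M"))
  }
  list(pos = glo[1], cigar = paste(cig, collapse = ""))
}

# deterministic tiling of a transcript with boundary pile-up so that the
# first/last transcribed base keeps cohort-level coverage above threshold
.tile_starts <- function(spliced_len, rl, depth) {
  last <- spliced_len - rl + 1L
  if (last < 1L) return(integer(0))
  step <- max(1L, as.integer(floor(rl / depth)))
  c(seq.int(1L, last, by = step), rep(1L, 4L), rep(last, 4L))
}

#' Simulate per-sample alignments for a planted cohort
#'
#' Every sample receives sparse uniform background reads; each plant
#' additionally receives error-free reads tiling its spliced transcript
#' (spanning the planted junctions) in its expressing samples only, and
#' each decoy gene receives reads over an internal 1 kb block in two
#' samples, so that decoy windows are selected and then removed by the
#' known-gene filter. Output is one coordinate-sorted indexed BAM per
#' sample (or a bedGraph depth track plus the same nominal library size).
#' Fully deterministic given the spec's seed.
#'
#' @param genome Planted \code{DNAStringSet} from
#'   \code{\link{plant_transcripts}}.
#' @param plants List of \code{plant_spec} objects.
#' @param spec A \code{cohort_spec}.
#' @param dir Output directory (created if needed).
#' @param format \code{"bam"} or \code{"bedgraph"}.
#' @param annotation Decoy \code{GRanges}; when given, decoy expression is
#'   simulated inside each span.
#' @return List of \code{sample_alignment} objects.
#' @export
simulate_cohort <- function(genome, plants, spec, dir,
                            format = c("bam", "bedgraph"),
                            annotation = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- length(genome[["chrS"]])
  rl <- spec$read_length

  decoy_blocks <- list()
  if (!is.null(annotation) && length(annotation) > 0L) {
    for (k in seq_along(annotation)) {
      s <- start(annotation)[k] + 1000L
      decoy_blocks[[k]] <- list(
        start = s, end = min(s + 999L, end(annotation)[k]),
        expressed_in = (c(k - 1L, k + 1L) %% spec$n_samples) + 1L)
    }
  }

  samples <- vector("list", spec$n_samples)
  for (i in seq_len(spec$n_samples)) {
    reads <- .with_seed(spec$seed * 1000L + i, {
      n_bg <- rpois(1L, spec$background_depth * L / rl)
      pos <- if (n_bg > 0L) sample.int(L - rl + 1L, n_bg, replace = TRUE)
             else integer(0)
      data.frame(pos = pos, cigar = rep(paste0(rl, "M"), length(pos)),
                 stringsAsFactors = FALSE)
    })
    for (ps in plants) {
      if (!i %in% ps$expressed_in) next
      ex <- .plant_exons(ps)
      starts <- .tile_starts(sum(width(ex)), rl, ps$depth)
      pr <- lapply(starts, function(a)
        .spliced_read(start(ex), width(ex), a, rl))
      reads <- rbind(reads, data.frame(
        pos = vapply(pr, `[[`, integer(1), "pos"),
        cigar = vapply(pr, `[[`, "", "cigar"), stringsAsFactors = FALSE))
    }
    for (db in decoy_blocks) {
      if (!i %in% db$expressed_in) next
      starts <- .tile_starts(db$end - db$start + 1L, rl, spec$plant_depth)
      reads <- rbind(reads, data.frame(
        pos = db$start + starts - 1L,
        cigar = rep(paste0(rl, "M"), length(starts)),
        stringsAsFactors = FALSE))
    }
    reads <- reads[order(reads$pos), , drop = FALSE]
    sid <- sprintf("sample_%02d", i)
    samples[[i]] <- .write_sample(reads, sid, L, dir, format,
                                  spec$library_size)
  }
  samples
}

# emit one sample as sorted+indexed BAM or bedGraph
.write_sample <- function(reads, sid, chrom_len, dir, format, library_size) {
  if (format == "bam") {
    sam <- file.path(dir, paste0(sid, ".sam"))
    lines <- c(
      "@HD\tVN:1.6\tSO:unsorted",
      paste0("@SQ\tSN:chrS\tLN:", chrom_len),
      if (nrow(reads) > 0L)
        sprintf("r%06d\t0\tchrS\t%d\t60\t%s\t*\t0\t0\t*\t*",
                seq_len(nrow(reads)), reads$pos, reads$cigar))
    writeLines(lines, sam)
    bam <- suppressMessages(
      asBam(sam, file.path(dir, sid), overwrite = TRUE,
            indexDestination = TRUE))
    unlink(sam)
    sample_alignment(bam, sample_id = sid, mapped_reads = library_size)
  } else {
    gr <- .reads_to_blocks(reads)
    cov <- coverage(gr, width = setNames(chrom_len, "chrS"))
    path <- file.path(dir, paste0(sid, ".bedGraph"))
    covgr <- methods::as(cov, "GRanges")
    covgr <- covgr[covgr$score > 0]
    rtracklayer::export(covgr, path, format = "bedGraph")
    sample_alignment(path, sample_id = sid, mapped_reads = library_size)
  }
}

# expand pos+cigar reads into aligned-block GRanges (M advances both, N
# skips the reference)
.reads_to_blocks <- function(reads) {
  if (nrow(reads) == 0L)
    return(GRanges(seqnames = character(0), ranges = IRanges()))
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_len(nrow(reads))) {
    toks <- regmatches(reads$cigar[i], gregexpr("[0-9]+[MN]", reads$cigar[i]))[[1]]
    pos <- reads$pos[i]
    for (tok in toks) {
      n <- as.integer(sub("[MN]$", "", tok))
      if (grepl("M$", tok)) { out_s <- c(out_s, pos); out_e <- c(out_e, pos + n - 1L) }
      pos <- pos + n
    }
  }
  GRanges("chrS", IRanges(out_s, out_e))
}

#' Build the bundled micro-cohort
#'
#' Generates the default 5-sample, 50 kb, 2-plant, 2-decoy cohort into a
#' directory: genome FASTA, decoy GTF, per-sample alignments, the truth
#' table TSV and the spec as YAML. Regenerating with the same seed
#' reproduces the outputs exactly.
#'
#' @param dir Output directory; defaults to a fresh temporary directory.
#' @param format \code{"bam"} or \code{"bedgraph"}.
#' @param seed Cohort seed.
#' @return List with \code{dir}, \code{spec}, \code{genome},
#'   \code{annotation}, \code{plants}, \code{truth}, \code{samples}.
#' @export
fixture_small <- function(dir = tempfile("lncscout_fixture_"),
                          format = "bam", seed = 42L) {
  spec <- cohort_spec(seed = seed)
  gg <- generate_genome(spec)
  plants <- default_plants(spec)
  planted <- plant_transcripts(gg$genome, plants, gg$annotation)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- simulate_cohort(planted$genome, planted$plants, spec, dir,
                             format = format, annotation = gg$annotation)
  writeXStringSet(planted$genome, file.path(dir, "genome.fa"))
  .write_gtf(gg$annotation, file.path(dir, "decoys.gtf"))
  write.table(planted$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(spec), file.path(dir, "spec.yaml"))
  list(dir = dir, spec = spec, genome = planted$genome,
       annotation = gg$annotation, plants = planted$plants,
       truth = planted$truth, samples = samples)
}

# minimal GTF writer for gene spans
.write_gtf <- function(ann, path) {
  lines <- sprintf(
    "%s\tlncscout\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
    as.character(seqnames(ann)), start(ann), end(ann),
    ifelse(as.character(strand(ann)) == "*", ".", as.character(strand(ann))),
    mcols(ann)$gene_id)
  writeLines(lines, path)
}
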