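# Expansion of merged candidate regions to gene-body structures: boundary
# refinement from pooled coverage, splice-junction extraction from CIGAR N
# operations, strand inference from junction motifs, and exon-chain assembly.

#' Pooled mean RPM coverage across a cohort
#'
#' Averages the RPM-normalized per-base depth of all samples into one
#' genome-wide track, used to refine candidate boundaries.
#'
#' @param samples List of \code{sample_alignment} objects.
#' @return An \code{RleList} of mean RPM per base.
#' @export
pooled_rpm_coverage <- function(samples) {
  stopifnot(length(samples) >= 1L)
  covs <- lapply(samples, function(aln)
    .raw_coverage(aln) / (mapped_read_count(aln) / 1e6))
  chroms <- unique(unlist(lapply(covs, names)))
  out <- lapply(chroms, function(chrom) {
    xs <- lapply(covs, function(cv) if (chrom %in% names(cv)) cv[[chrom]] else NULL)
    xs <- xs[!vapply(xs, is.null, logical(1))]
    len <- max(vapply(xs, length, integer(1)))
    xs <- lapply(xs, function(x)
      if (length(x) < len) c(x, Rle(0, len - length(x))) else x)
    Reduce(`+`, xs) / length(samples)
  })
  names(out) <- chroms
  methods::as(out, "SimpleRleList")
}

#' Refine candidate boundaries against pooled coverage
#'
#' Starting from a merged window region, the boundary is first trimmed
#' inward past any leading/trailing bases whose pooled mean RPM falls below
#' \code{min_rpm} (merged windows are step-quantized, so they typically
#' overhang the expressed interval), then walked outward base-by-base:
#' the region grows while covered bases keep appearing, and stops once a
#' run of more than \code{max_gap} consecutive bases stays below
#' \code{min_rpm}. Extension never enters an annotated gene span.
#'
#' @param region Length-1 \code{GRanges} from \code{\link{merge_windows}}.
#' @param coverage Pooled RPM \code{RleList} from
#'   \code{\link{pooled_rpm_coverage}}.
#' @param min_rpm Minimum pooled mean RPM for a base to count as expressed.
#' @param max_gap Longest tolerated run of sub-threshold bases during
#'   extension, in bp.
#' @param annotation Optional \code{GRanges} of gene spans that the
#'   extension must not enter.
#' @param max_extend Upper bound on the extension examined per side, in bp
#'   (keeps memory bounded on chromosome-scale tracks).
#' @return A length-1 \code{GRanges}, or \code{NULL} when the region has no
#'   base at or above \code{min_rpm}.
#' @export
extend_boundaries <- function(region, coverage, min_rpm = 0.5, max_gap = 50L,
                              annotation = NULL, max_extend = 100000L) {
  stopifnot(length(region) == 1L)
  chrom <- as.character(seqnames(region))
  if (!chrom %in% names(coverage)) return(NULL)
  x <- coverage[[chrom]]
  len <- length(x)
  s <- max(1L, start(region)); e <- min(len, end(region))
  if (s > e) return(NULL)
  xs <- as.numeric(x[s:e])
  good <- which(xs >= min_rpm)
  if (length(good) == 0L) return(NULL)
  s2 <- s + good[1L] - 1L
  e2 <- s + good[length(good)] - 1L

  # hard walls from annotation: closest annotated base on each side
  lo_wall <- 1L; hi_wall <- len
  if (!is.null(annotation) && length(annotation) > 0L) {
    ann <- annotation[as.character(seqnames(annotation)) == chrom]
    left <- end(ann)[end(ann) < s2]
    right <- start(ann)[start(ann) > e2]
    if (length(left)) lo_wall <- max(left) + 1L
    if (length(right)) hi_wall <- min(right) - 1L
  }

  # distance we may advance along `v` (ordered away from the region) before
  # hitting a below-threshold run longer than max_gap
  advance <- function(v) {
    if (length(v) == 0L) return(0L)
    r <- rle(v)
    pos <- 0L; last_good <- 0L
    for (i in seq_along(r$lengths)) {
      if (r$values[i]) last_good <- pos + r$lengths[i]
      else if (r$lengths[i] > max_gap) break
      pos <- pos + r$lengths[i]
    }
    last_good
  }
  s3 <- s2; e3 <- e2
  lo_wall <- max(lo_wall, s2 - max_extend)
  hi_wall <- min(hi_wall, e2 + max_extend)
  if (s2 > lo_wall) {
    v <- rev(as.numeric(x[lo_wall:(s2 - 1L)])) >= min_rpm
    s3 <- s2 - advance(v)
  }
  if (e2 < hi_wall) {
    v <- as.numeric(x[(e2 + 1L):hi_wall]) >= min_rpm
    e3 <- e2 + advance(v)
  }
  GRanges(chrom, IRanges(s3, e3))
}

#' Extract splice junctions from spliced alignments
#'
#' Collects intron calls (CIGAR \code{N} operations) from all samples over
#' a region, aggregates their read support across the cohort, and keeps
#' junctions with support of at least \code{min_support} reads. Skips
#' shorter than \code{min_intron} are regarded as deletions, not introns.
#' The 4-mer splice motif (first two and last two intron bases) is read
#' from the genome when given.
#'
#' @param samples List of \code{sample_alignment} objects (BAM-backed
#'   samples contribute; bedGraph samples carry no junction information).
#' @param region Length-1 \code{GRanges}; only introns fully inside it are
#'   returned.
#' @param genome Optional \code{DNAStringSet} for motif extraction.
#' @param min_support Minimum supporting reads across the cohort.
#' @param min_intron Minimum intron length in bp.
#' @return A data.frame with columns \code{chrom}, \code{intron_start},
#'   \code{intron_end} (1-based, closed coordinates of the intron),
#'   \code{support}, \code{motif}; sorted by coordinate.
#' @export
collect_junctions <- function(samples, region, genome = NULL,
                              min_support = 3L, min_intron = 30L) {
  stopifnot(length(region) == 1L)
  chrom <- as.character(seqnames(region))
  empty <- data.frame(chrom = character(0), intron_start = integer(0),
                      intron_end = integer(0), support = integer(0),
                      motif = character(0), stringsAsFactors = FALSE)
  bams <- Filter(function(a) a$type == "bam", samples)
  if (length(bams) == 0L) return(empty)
  introns <- lapply(bams, function(aln) {
    g <- readGAlignments(aln$source,
                         param = ScanBamParam(which = region))
    unlist(junctions(g), use.names = FALSE)
  })
  introns <- do.call(c, introns)
  if (length(introns) == 0L) return(empty)
  introns <- introns[width(introns) >= min_intron &
                     start(introns) >= start(region) &
                     end(introns) <= end(region)]
  if (length(introns) == 0L) return(empty)
  key <- paste(start(introns), end(introns))
  tab <- table(key)
  uniq <- !duplicated(key)
  df <- data.frame(chrom = chrom,
                   intron_start = start(introns)[uniq],
                   intron_end = end(introns)[uniq],
                   support = as.integer(tab[key[uniq]]),
                   stringsAsFactors = FALSE)
  df <- df[df$support >= min_support, , drop = FALSE]
  df <- df[order(df$intron_start, df$intron_end), , drop = FALSE]
  df$motif <- if (!is.null(genome) && chrom %in% names(genome) && nrow(df)) {
    chr <- genome[[chrom]]
    vapply(seq_len(nrow(df)), function(i) {
      paste0(as.character(subseq(chr, df$intron_start[i], df$intron_start[i] + 1L)),
             as.character(subseq(chr, df$intron_end[i] - 1L, df$intron_end[i])))
    }, "")
  } else rep(NA_character_, nrow(df))
  rownames(df) <- NULL
  df
}

#' Infer transcript strand from splice motifs
#'
#' Canonical introns read \code{GT..AG} on the transcribed strand, so a
#' genomic \code{GTAG} motif votes for the plus strand and its reverse
#' complement \code{CTAC} for the minus strand. The majority over all
#' junctions wins; no junctions or a tie yields \code{"*"} (unknown), in
#' which case a candidate is scored in both orientations downstream.
#'
#' @param junctions Junction data.frame from \code{\link{collect_junctions}}.
#' @return One of \code{"+"}, \code{"-"}, \code{"*"}.
#' @export
infer_strand <- function(junctions) {
  if (is.null(junctions) || nrow(junctions) == 0L) return("*")
  plus <- sum(junctions$motif == "GTAG", na.rm = TRUE)
  minus <- sum(junctions$motif == "CTAC", na.rm = TRUE)
  if (plus > minus) "+" else if (minus > plus) "-" else "*"
}

#' Assemble an exon chain from a region and its junctions
#'
#' Exon boundaries are the region ends plus the donor/acceptor coordinates
#' of the retained junctions. Junctions whose introns overlap each other
#' are resolved greedily by read support (highest first), so one consistent
#' chain remains; with no junctions the candidate is a single exon spanning
#' the region.
#'
#' @param region Length-1 \code{GRanges} (refined candidate region).
#' @param junctions Junction data.frame from \code{\link{collect_junctions}};
#'   introns must lie inside the region.
#' @param strand Transcript strand (\code{"+"}, \code{"-"}, \code{"*"}).
#' @param id Candidate identifier.
#' @return An object of class \code{transcript_candidate}: list with
#'   \code{id}, \code{exons} (\code{GRanges}), \code{strand}, \code{tss},
#'   \code{end3} (1-based first/last transcribed base), \code{n_ex}.
#' @export
assemble_exons <- function(region, junctions = NULL, strand = "*",
                           id = "candidate_1") {
  stopifnot(length(region) == 1L)
  chrom <- as.character(seqnames(region))
  introns <- IRanges()
  if (!is.null(junctions) && nrow(junctions) > 0L) {
    if (any(junctions$intron_start <= start(region) |
            junctions$intron_end >= end(region)))
      stop("junction outside candidate region")
    j <- junctions[order(-junctions$support, junctions$intron_start), ,
                   drop = FALSE]
    acc <- IRanges()
    for (i in seq_len(nrow(j))) {
      cand <- IRanges(j$intron_start[i], j$intron_end[i])
      if (length(acc) == 0L || !any(overlapsAny(cand, acc)))
        acc <- c(acc, cand)
    }
    introns <- sort(acc)
  }
  exons_ir <- setdiff(IRanges(start(region), end(region)), introns)
  exons <- GRanges(chrom, exons_ir, strand = strand)
  tss <- if (identical(strand, "-")) max(end(exons)) else min(start(exons))
  end3 <- if (identical(strand, "-")) min(start(exons)) else max(end(exons))
  structure(list(id = id, exons = exons, strand = strand,
                 tss = tss, end3 = end3, n_ex = length(exons)),
            class = "transcript_candidate")
}

#' @export
print.transcript_candidate <- function(x, ...) {
  cat("<transcript_candidate> ", x$id, " (", x$strand, ") ",
      as.character(seqnames(x$exons))[1], ":",
      min(start(x$exons)), "-", max(end(x$exons)),
      ", ", x$n_ex, " exon(s)\n", sep = "")
  invisible(x)
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences in genomic order and reverse-complements
#' the result for minus-strand candidates, yielding the transcript 5' to 3'.
#'
#' @param candidate A \code{transcript_candidate}.
#' @param genome A \code{DNAStringSet}.
#' @return The spliced sequence as a character string.
#' @export
spliced_sequence <- function(candidate, genome) {
  stopifnot(inherits(candidate, "transcript_candidate"))
  chrom <- as.character(seqnames(candidate$exons))[1]
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  chr <- genome[[chrom]]
  if (min(start(candidate$exons)) < 1L || max(end(candidate$exons)) > length(chr))
    stop("exon outside chromosome bounds")
  parts <- vapply(seq_along(candidate$exons), function(i)
    as.character(subseq(chr, start(candidate$exons)[i], end(candidate$exons)[i])),
    "")
  s <- paste(parts, collapse = "")
  if (identical(candidate$strand, "-"))
    s <- as.character(reverseComplement(DNAString(s)))
  s
}

#' Count exons supported by valid splice junctions
#'
#' An internal exon boundary is \emph{valid} when a junction with the
#' canonical motif (\code{GT..AG} in transcript orientation, i.e. genomic
#' \code{GTAG} on plus and \code{CTAC} on minus) coincides with it. An exon
#' counts as junction-supported when every internal boundary it owns (one
#' for terminal exons, two for internal ones) is valid. Single-exon
#' candidates have no junctions and return 0.
#'
#' @param candidate A \code{transcript_candidate}.
#' @param junctions Junction data.frame from \code{\link{collect_junctions}}.
#' @param strand Orientation in which validity is judged; defaults to the
#'   candidate's strand (an unknown strand is judged as plus).
#' @return Integer count of junction-supported exons (\code{n_valid}).
#' @export
valid_junction_count <- function(candidate, junctions,
                                 strand = candidate$strand) {
  stopifnot(inherits(candidate, "transcript_candidate"))
  n_ex <- candidate$n_ex
  if (n_ex < 2L) return(0L)
  canonical <- if (identical(strand, "-")) "CTAC" else "GTAG"
  ex <- candidate$exons
  # boundary i sits between exon i and exon i+1
  boundary_ok <- vapply(seq_len(n_ex - 1L), function(i) {
    is <- end(ex)[i] + 1L
    ie <- start(ex)[i + 1L] - 1L
    if (is.null(junctions) || nrow(junctions) == 0L) return(FALSE)
    hit <- junctions$intron_start == is & junctions$intron_end == ie
    any(hit & junctions$motif == canonical, na.rm = TRUE)
  }, logical(1))
  exon_ok <- vapply(seq_len(n_ex), function(i) {
    owned <- c(if (i > 1L) i - 1L, if (i < n_ex) i)
    all(boundary_ok[owned])
  }, logical(1))
  sum(exon_ok)
}
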