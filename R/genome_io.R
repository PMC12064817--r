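# Readers for FASTA / GTF / BED / BAM / bedGraph, RPM normalization, and
# region read counting. All user-facing coordinates follow the Bioconductor
# convention (1-based, closed intervals, GRanges); BED and bedGraph files are
# converted on import/export by rtracklayer.

#' Read a genome FASTA file
#'
#' Loads all records of a (multi-)FASTA file into a \code{DNAStringSet}.
#' Sequence names are truncated at the first whitespace, as aligners do,
#' and bases are uppercased so that downstream motif and composition
#' computations see a single alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A named \code{DNAStringSet}, one entry per chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTacgt"), fa)
#' g <- read_genome(fa)
#' as.character(g$chr1)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  g <- tryCatch(
    readDNAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  names(g) <- sub("\\s.*$", "", names(g))
  # DNAStringSet accepts lowercase input; normalize for motif matching
  DNAStringSet(toupper(g))
}

#' Read a gene annotation as gene spans
#'
#' Imports a GTF or BED file and reduces it to one interval per gene: the
#' full genomic span from the first to the last base of the gene (exons and
#' introns). These spans are what the window scan filters against, because
#' candidate lncRNAs are required to be intergenic. BED intervals are taken
#' as-is; GTF features are grouped by \code{gene_id} (falling back to the
#' whole-file range per feature when no gene identifier is present).
#'
#' @param path Path to a GTF/GFF or BED file. The format is chosen from the
#'   file extension (\code{.gtf}, \code{.gff}, \code{.gff3}, \code{.bed}).
#' @return A \code{GRanges} of gene spans with a \code{gene_id} column.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("gtf", "gff", "gff3", "bed"))
    stop("unknown annotation format '.", ext, "' (expected GTF/GFF3 or BED)")
  # rtracklayer chokes on completely empty files; treat as empty annotation
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(GRanges(gene_id = character(0)))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (ext == "bed") "bed" else ext),
    error = function(e) stop("failed to parse '", path, "': ", conditionMessage(e))
  )
  if (ext == "bed") {
    ids <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name)
           else paste0("bed_", seq_along(gr))
    out <- granges(gr)
    strand(out) <- "*"
    mcols(out)$gene_id <- ids
    return(sort(out))
  }
  gid <- mcols(gr)$gene_id
  if (is.null(gid)) gid <- mcols(gr)$ID
  if (is.null(gid)) gid <- paste0("feature_", seq_along(gr))
  gid <- as.character(gid)
  gid[is.na(gid)] <- paste0("feature_", which(is.na(gid)))
  spans <- unlist(range(S4Vectors::split(granges(gr), gid)))
  strand(spans) <- "*"
  mcols(spans)$gene_id <- names(spans)
  names(spans) <- NULL
  sort(spans)
}

#' Describe one aligned sample
#'
#' Bundles the path to a sample's evidence (a coordinate-sorted, indexed BAM
#' or a bedGraph of raw per-base depth) with its identifier and the number
#' of mapped reads used as the RPM denominator. For BAM input the mapped
#' read count defaults to the number of primary mapped records in the file
#' (secondary and supplementary alignments excluded); for bedGraph input it
#' must be supplied, since the depth track no longer knows its library size.
#'
#' @param source Path to a BAM (with .bai index) or bedGraph file.
#' @param sample_id Sample label; defaults to the file name.
#' @param mapped_reads Mapped-read count for RPM normalization, or
#'   \code{NULL} to count primary mapped records from the BAM.
#' @return An object of class \code{sample_alignment}.
#' @export
sample_alignment <- function(source, sample_id = basename(source),
                             mapped_reads = NULL) {
  if (!file.exists(source)) stop("alignment file not found: ", source)
  type <- if (grepl("\\.bam$", source, ignore.case = TRUE)) "bam" else "bedgraph"
  if (type == "bam" && !file.exists(paste0(source, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", source)))
    stop("BAM index missing for '", source,
         "'; index it first (e.g. Rsamtools::indexBam)")
  if (type == "bedgraph" && is.null(mapped_reads))
    stop("mapped_reads must be given for bedGraph input")
  if (!is.null(mapped_reads) && mapped_reads <= 0)
    stop("mapped_reads must be positive")
  structure(
    list(sample_id = sample_id, source = source, type = type,
         mapped_reads = mapped_reads, cache = new.env(parent = emptyenv())),
    class = "sample_alignment"
  )
}

#' @export
print.sample_alignment <- function(x, ...) {
  cat("<sample_alignment> ", x$sample_id, " [", x$type, "] ", x$source, "\n",
      sep = "")
  invisible(x)
}

#' Number of mapped reads of a sample
#'
#' @param aln A \code{sample_alignment}.
#' @return Count of primary mapped read records (or the value supplied at
#'   construction time).
#' @export
mapped_read_count <- function(aln) {
  stopifnot(inherits(aln, "sample_alignment"))
  if (!is.null(aln$mapped_reads)) return(aln$mapped_reads)
  if (is.null(aln$cache$mapped)) {
    flag <- scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
                        isSupplementaryAlignment = FALSE)
    aln$cache$mapped <- countBam(aln$source,
                                 param = ScanBamParam(flag = flag))$records
  }
  aln$cache$mapped
}

# Genome-wide raw depth as an RleList, cached per sample. CIGAR N operations
# (skipped introns) contribute no depth.
.raw_coverage <- function(aln) {
  if (!is.null(aln$cache$cov)) return(aln$cache$cov)
  cov <- if (aln$type == "bam") {
    coverage(readGAlignments(aln$source))
  } else {
    gr <- rtracklayer::import(aln$source, format = "bedGraph")
    coverage(gr, weight = as.numeric(mcols(gr)$score))
  }
  aln$cache$cov <- cov
  cov
}

# Extract cov[chrom][start:end] (1-based, closed) as numeric, zero-padded
# beyond the recorded track.
.rle_window <- function(cov, chrom, start, end) {
  n <- end - start + 1L
  if (!chrom %in% names(cov)) return(numeric(n))
  x <- cov[[chrom]]
  lo <- max(1L, start)
  hi <- min(length(x), end)
  out <- numeric(n)
  if (hi >= lo)
    out[(lo - start + 1L):(hi - start + 1L)] <- as.numeric(x[lo:hi])
  out
}

#' Raw per-base depth over a region
#'
#' Counts, for every base of the region, the aligned bases of reads covering
#' it. Each aligned base of each read contributes once; intron skips
#' (CIGAR \code{N}) contribute nothing.
#'
#' @param aln A \code{sample_alignment}.
#' @param region A length-1 \code{GRanges}.
#' @return Numeric vector of length \code{width(region)} of raw depth.
#' @export
per_base_coverage <- function(aln, region) {
  stopifnot(inherits(aln, "sample_alignment"), length(region) == 1L)
  cov <- .raw_coverage(aln)
  .rle_window(cov, as.character(seqnames(region)), start(region), end(region))
}

#' Reads-per-million normalization
#'
#' Scales a raw quantity (read count or depth) by the sample's library size:
#' \code{raw / (mapped_reads / 1e6)}.
#'
#' @param raw Numeric vector of raw counts or depths.
#' @param mapped_reads Number of mapped reads in the sample.
#' @return RPM-normalized values.
#' @examples
#' rpm_normalize(500, 2e6)   # 250
#' @export
rpm_normalize <- function(raw, mapped_reads) {
  if (all(raw == 0)) return(raw * 0)
  if (mapped_reads <= 0)
    stop("mapped_reads must be > 0 when normalizing nonzero counts")
  raw / (mapped_reads / 1e6)
}

#' Count reads overlapping regions
#'
#' For each region, counts the reads whose aligned blocks (CIGAR M segments)
#' overlap the region by at least one base. A read is counted at most once
#' per region but may be counted in several regions; a read whose intron
#' merely spans a region does not count. This mirrors the default behaviour
#' of \code{bedtools multicov}.
#'
#' @param aln A \code{sample_alignment} backed by a BAM file.
#' @param regions A \code{GRanges} of regions.
#' @return Integer vector of per-region read counts.
#' @export
count_reads_in_regions <- function(aln, regions) {
  stopifnot(inherits(aln, "sample_alignment"))
  if (aln$type != "bam")
    stop("count_reads_in_regions requires BAM input")
  if (length(regions) == 0L) return(integer(0))
  reads <- readGAlignments(aln$source)
  blocks <- grglist(reads)  # aligned segments, introns removed
  countOverlaps(regions, blocks, ignore.strand = TRUE)
}
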