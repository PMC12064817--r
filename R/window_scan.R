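# Sliding-window coverage matrix, outlier selection rule, known-gene
# filtering, and merging of selected windows into candidate regions.

#' Tile chromosomes into sliding windows
#'
#' Generates fixed-length windows advanced by a fixed step across every
#' chromosome (defaults: 500 bp windows, 250 bp step). A trailing partial
#' window clipped at the chromosome end is kept only when it is not wholly
#' contained in the previous window, so a chromosome shorter than one window
#' yields a single window spanning it entirely.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths, or a
#'   \code{DNAStringSet} genome (lengths are taken from it).
#' @param window Window length in bp.
#' @param step Step between window starts in bp; \code{0 < step <= window}.
#' @return A sorted \code{GRanges} of windows with seqlengths set.
#' @examples
#' make_windows(c(chr1 = 1000))
#' @export
make_windows <- function(chrom_lengths, window = 500L, step = 250L) {
  if (is(chrom_lengths, "DNAStringSet"))
    chrom_lengths <- setNames(Biostrings::width(chrom_lengths),
                              names(chrom_lengths))
  stopifnot(window > 0, step > 0, step <= window)
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named by chromosome")
  pieces <- lapply(names(chrom_lengths), function(chrom) {
    len <- as.integer(chrom_lengths[[chrom]])
    if (len < 1L) return(NULL)
    s <- seq.int(1L, len, by = step)
    e <- pmin(s + window - 1L, len)
    keep <- rep(TRUE, length(s))
    if (length(s) > 1L)  # drop trailing windows contained in their predecessor
      keep[-1L] <- e[-1L] > e[-length(e)]
    GRanges(chrom, IRanges(s[keep], e[keep]))
  })
  gr <- do.call(c, pieces[!vapply(pieces, is.null, logical(1))])
  seqlengths(gr) <- chrom_lengths[seqlevels(gr)]
  gr
}

#' Build the windows-by-samples RPM coverage matrix
#'
#' Each cell is the mean per-base depth of one sample over one window,
#' RPM-normalized by that sample's mapped-read count. At least five samples
#' are required so that the top/bottom 20% of the cohort contains at least
#' one sample.
#'
#' @param samples List of \code{sample_alignment} objects.
#' @param windows \code{GRanges} of windows, e.g. from \code{make_windows}.
#' @return An object of class \code{coverage_matrix}: a list with elements
#'   \code{windows} (the \code{GRanges}), \code{samples} (character ids) and
#'   \code{values} (numeric matrix, windows x samples).
#' @export
build_matrix <- function(samples, windows) {
  if (length(samples) < 5L)
    stop("need >= 5 samples: the 20% sample quantile of the selection rule ",
         "must contain at least one sample")
  stopifnot(all(vapply(samples, inherits, logical(1), "sample_alignment")))
  chroms <- as.character(seqnames(windows))
  vals <- vapply(samples, function(aln) {
    cov <- .raw_coverage(aln)
    sums <- numeric(length(windows))
    for (chrom in unique(chroms)) {
      idx <- which(chroms == chrom)
      if (!chrom %in% names(cov)) next
      x <- cov[[chrom]]
      s <- start(windows)[idx]; e <- pmin(end(windows)[idx], length(x))
      ok <- s <= length(x)
      if (any(ok))
        sums[idx[ok]] <- viewSums(Views(x, start = s[ok], end = pmax(e[ok], s[ok])))
    }
    rpm_normalize(sums / width(windows), mapped_read_count(aln))
  }, numeric(length(windows)))
  vals <- matrix(vals, nrow = length(windows),
                 dimnames = list(NULL, vapply(samples, `[[`, "", "sample_id")))
  structure(list(windows = windows,
                 samples = colnames(vals),
                 values = vals),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat("<coverage_matrix> ", length(x$windows), " windows x ",
      length(x$samples), " samples\n", sep = "")
  invisible(x)
}

#' Per-window outlier statistics and selection
#'
#' For every window, the cohort values are summarized by their median and by
#' the means of the highest and lowest \code{ceiling(0.2 n)} samples. A
#' window is selected when, for either extreme, the absolute difference from
#' the median exceeds \code{abs_diff_min} RPM \emph{and} the absolute log2
#' fold change (with a pseudocount on both numerator and denominator)
#' exceeds \code{log2fc_min}. Testing both extremes captures windows driven
#' by a minority of highly expressing samples as well as windows silenced in
#' a minority.
#'
#' @param m A \code{coverage_matrix}.
#' @param abs_diff_min Threshold on the RPM difference from the median.
#' @param log2fc_min Threshold on |log2 fold change| versus the median.
#' @param pseudocount RPM pseudocount used in the fold change.
#' @return A data.frame with one row per window: \code{chrom}, \code{start},
#'   \code{end} (1-based, closed), \code{median}, \code{top_mean},
#'   \code{bottom_mean}, \code{abs_diff}, \code{log2fc}, \code{selected}.
#'   \code{abs_diff} and \code{log2fc} report the larger of the two extremes.
#' @export
window_statistics <- function(m, abs_diff_min = 1, log2fc_min = 1,
                              pseudocount = 0.1) {
  stopifnot(inherits(m, "coverage_matrix"))
  v <- m$values
  n <- ncol(v)
  if (n < 5L) stop("need >= 5 samples")
  k <- ceiling(0.2 * n)
  vs <- t(apply(v, 1L, sort.int, method = "quick"))
  if (nrow(v) == 1L) vs <- matrix(vs, nrow = 1L)
  bottom <- rowMeans(vs[, seq_len(k), drop = FALSE])
  top <- rowMeans(vs[, n - k + seq_len(k), drop = FALSE])
  med <- apply(v, 1L, median)
  d_top <- abs(top - med)
  d_bot <- abs(bottom - med)
  fc_top <- abs(log2((top + pseudocount) / (med + pseudocount)))
  fc_bot <- abs(log2((bottom + pseudocount) / (med + pseudocount)))
  sel <- (d_top > abs_diff_min & fc_top > log2fc_min) |
         (d_bot > abs_diff_min & fc_bot > log2fc_min)
  data.frame(
    chrom = as.character(seqnames(m$windows)),
    start = start(m$windows),
    end = end(m$windows),
    median = med,
    top_mean = top,
    bottom_mean = bottom,
    abs_diff = pmax(d_top, d_bot),
    log2fc = pmax(fc_top, fc_bot),
    selected = sel,
    stringsAsFactors = FALSE
  )
}

# data.frame of window stats -> GRanges
.stats_granges <- function(stats) {
  GRanges(stats$chrom, IRanges(stats$start, stats$end))
}

#' Remove windows overlapping annotated genes
#'
#' Drops every window that shares at least one base with any annotated gene
#' span, irrespective of strand: candidates are required to be intergenic.
#'
#' @param stats Window statistics data.frame from \code{window_statistics}
#'   (any data.frame with \code{chrom}/\code{start}/\code{end} works).
#' @param annotation \code{GRanges} of gene spans, e.g. from
#'   \code{\link{read_annotation}}. An empty annotation passes everything.
#' @return The subset of \code{stats} with no annotation overlap.
#' @export
filter_known <- function(stats, annotation) {
  if (length(annotation) == 0L || nrow(stats) == 0L) return(stats)
  hits <- overlapsAny(.stats_granges(stats), annotation, ignore.strand = TRUE)
  stats[!hits, , drop = FALSE]
}

#' Merge selected windows into candidate regions
#'
#' Coalesces overlapping and book-ended windows into maximal disjoint
#' regions (interval union). Adjacent step-spaced windows covering one
#' transcript therefore collapse into a single region.
#'
#' @param selected \code{GRanges} of selected windows, or a window
#'   statistics data.frame (its \code{selected} rows are used).
#' @return A sorted, disjoint \code{GRanges} of merged regions.
#' @export
merge_windows <- function(selected) {
  if (is.data.frame(selected)) {
    if ("selected" %in% names(selected))
      selected <- selected[selected$selected, , drop = FALSE]
    selected <- .stats_granges(selected)
  }
  reduce(sort(selected), ignore.strand = TRUE)
}
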