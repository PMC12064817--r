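# Shared fixtures and independent oracles used across the suite.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(Rsamtools)
})

# random DNA string
random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# a sequence with an exact count of `bases` among `n` characters
seq_with_fraction <- function(n, k, bases, filler) {
  v <- c(sample(bases, k, replace = TRUE), sample(filler, n - k, replace = TRUE))
  paste(sample(v), collapse = "")
}

# write a tiny BAM from (pos, cigar) reads; returns the BAM path
make_test_bam <- function(reads, dir = tempfile("bam_"), chrom = "chr1",
                          chrom_len = 10000L, sample = "s") {
  dir.create(dir, showWarnings = FALSE)
  sam <- file.path(dir, paste0(sample, ".sam"))
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len))
  if (nrow(reads) > 0L)
    lines <- c(lines, sprintf("q%04d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                              seq_len(nrow(reads)), chrom, reads$pos,
                              reads$cigar))
  writeLines(lines, sam)
  bam <- suppressMessages(Rsamtools::asBam(sam, file.path(dir, sample),
                                           overwrite = TRUE,
                                           indexDestination = TRUE))
  bam
}

# brute-force longest-ORF oracle: enumerate every ATG and walk to the first
# in-frame stop; longest wins, leftmost on ties
orf_oracle <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  best <- NULL
  for (i in seq_len(max(n - 2L, 0L))) {
    if (substr(s, i, i + 2L) != "ATG") next
    j <- i + 3L
    while (j + 2L <= n) {
      cod <- substr(s, j, j + 2L)
      if (cod %in% c("TAA", "TAG", "TGA")) {
        len <- j + 2L - i + 1L
        if (is.null(best) || len > best$length ||
            (len == best$length && i < best$start))
          best <- list(start = i, end = j + 2L, length = len)
        break
      }
      j <- j + 3L
    }
  }
  if (is.null(best)) list(start = NA_integer_, end = NA_integer_, length = 0L)
  else best
}

# per-base interval-union oracle for merge_windows on small coordinates
union_oracle <- function(starts, ends, limit) {
  covered <- rep(FALSE, limit)
  for (i in seq_along(starts)) covered[starts[i]:ends[i]] <- TRUE
  r <- rle(covered)
  pos <- cumsum(c(1L, r$lengths))
  data.frame(start = pos[-length(pos)][r$values],
             end = (pos[-1L] - 1L)[r$values])
}

# direct evaluation of the window selection rule on one row of values
selection_oracle <- function(v, abs_min = 1, fc_min = 1, pc = 0.1) {
  n <- length(v)
  k <- ceiling(0.2 * n)
  sv <- sort(v)
  bottom <- mean(sv[1:k])
  top <- mean(sv[(n - k + 1):n])
  med <- median(v)
  pass <- function(x) abs(x - med) > abs_min &&
    abs(log2((x + pc) / (med + pc))) > fc_min
  pass(top) || pass(bottom)
}
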