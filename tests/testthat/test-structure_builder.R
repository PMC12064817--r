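track <- function(covered_start, covered_end, len = 2000L, value = 1) {
  x <- numeric(len)
  x[covered_start:covered_end] <- value
  as(setNames(list(Rle(x)), "chrS"), "SimpleRleList")
}

test_that("extend_boundaries walks out to the covered interval", {
  cov <- track(401L, 1100L)
  r <- extend_boundaries(GRanges("chrS", IRanges(501, 1000)), cov)
  expect_equal(c(start(r), end(r)), c(401L, 1100L))

  # coverage exactly bounded by the region: unchanged
  cov2 <- track(501L, 1000L)
  r2 <- extend_boundaries(GRanges("chrS", IRanges(501, 1000)), cov2)
  expect_equal(c(start(r2), end(r2)), c(501L, 1000L))

  # an annotated gene is a hard wall
  ann <- GRanges("chrS", IRanges(1051, 2000))
  r3 <- extend_boundaries(GRanges("chrS", IRanges(501, 1000)), cov,
                          annotation = ann)
  expect_equal(end(r3), 1050L)

  # sub-threshold overhangs of a merged region are trimmed
  cov4 <- track(601L, 900L)
  r4 <- extend_boundaries(GRanges("chrS", IRanges(501, 1000)), cov4)
  expect_equal(c(start(r4), end(r4)), c(601L, 900L))

  # dead region
  expect_null(extend_boundaries(GRanges("chrS", IRanges(1, 100)), cov))
})

test_that("extension tolerates gaps up to max_gap and no further", {
  x <- numeric(2000)
  x[501:1000] <- 1
  x[1031:1200] <- 1   # 30-base gap, below default max_gap = 50
  x[1301:1500] <- 1   # 100-base gap, beyond it
  cov <- as(setNames(list(Rle(x)), "chrS"), "SimpleRleList")
  r <- extend_boundaries(GRanges("chrS", IRanges(501, 1000)), cov)
  expect_equal(end(r), 1200L)
})

test_that("collect_junctions extracts, aggregates and thresholds introns", {
  reads <- data.frame(pos = rep(101L, 3), cigar = rep("50M100N50M", 3))
  bam <- make_test_bam(reads)
  aln <- sample_alignment(bam, "s1")
  region <- GRanges("chr1", IRanges(1, 1000))
  jx <- collect_junctions(list(aln), region)
  expect_equal(nrow(jx), 1L)
  expect_equal(jx$intron_start, 151L)
  expect_equal(jx$intron_end, 250L)
  expect_equal(jx$support, 3L)

  # below min_support: dropped
  bam2 <- make_test_bam(reads[1:2, ], dir = tempfile("b2_"))
  jx2 <- collect_junctions(list(sample_alignment(bam2, "s2")), region)
  expect_equal(nrow(jx2), 0L)

  # one read in each of three samples aggregates to support 3
  alns <- lapply(1:3, function(i)
    sample_alignment(make_test_bam(reads[1, ], dir = tempfile("b3_")),
                     paste0("m", i)))
  jx3 <- collect_junctions(alns, region)
  expect_equal(jx3$support, 3L)

  # motif read from the genome
  chr <- paste(rep("A", 1000), collapse = "")
  substr(chr, 151, 152) <- "GT"; substr(chr, 249, 250) <- "AG"
  genome <- DNAStringSet(c(chr1 = chr))
  jx4 <- collect_junctions(list(aln), region, genome = genome)
  expect_equal(jx4$motif, "GTAG")
})

test_that("infer_strand votes by canonical splice motif", {
  j <- function(motifs) data.frame(chrom = "c", intron_start = 1,
                                   intron_end = 2, support = 3,
                                   motif = motifs)
  expect_equal(infer_strand(j(c("GTAG", "GTAG"))), "+")
  expect_equal(infer_strand(j("CTAC")), "-")
  expect_equal(infer_strand(j(c("GTAG", "CTAC"))), "*")
  expect_equal(infer_strand(NULL), "*")
})

test_that("assemble_exons builds the exon chain from junctions", {
  region <- GRanges("chrS", IRanges(401, 1100))
  jx <- data.frame(chrom = "chrS", intron_start = 701L, intron_end = 900L,
                   support = 5L, motif = "GTAG")
  cand <- assemble_exons(region, jx, strand = "+")
  expect_equal(start(cand$exons), c(401L, 901L))
  expect_equal(end(cand$exons), c(700L, 1100L))
  expect_equal(cand$n_ex, 2L)
  expect_equal(cand$tss, 401L)
  expect_equal(cand$end3, 1100L)

  # no junctions: single exon spanning the region
  single <- assemble_exons(region, NULL)
  expect_equal(single$n_ex, 1L)
  expect_equal(width(single$exons), 700L)

  # two compatible junctions: three sorted disjoint exons
  jx2 <- rbind(jx, data.frame(chrom = "chrS", intron_start = 951L,
                              intron_end = 1000L, support = 4L,
                              motif = "GTAG"))
  cand2 <- assemble_exons(region, jx2)
  expect_equal(cand2$n_ex, 3L)
  expect_true(all(diff(start(cand2$exons)) > 0))
  expect_true(all(start(cand2$exons)[-1] > end(cand2$exons)[-3]))

  # overlapping junctions: the better-supported one wins
  conflict <- rbind(jx, data.frame(chrom = "chrS", intron_start = 650L,
                                   intron_end = 850L, support = 9L,
                                   motif = "GTAG"))
  cand3 <- assemble_exons(region, conflict)
  expect_equal(start(cand3$exons), c(401L, 851L))

  bad <- data.frame(chrom = "chrS", intron_start = 100L, intron_end = 200L,
                    support = 5L, motif = "GTAG")
  expect_error(assemble_exons(region, bad), "outside")
})

test_that("spliced_sequence concatenates exons and honors strand", {
  genome <- DNAStringSet(c(chr1 = "ACGTTTGCA"))
  plus <- structure(list(id = "t", strand = "+",
                         exons = GRanges("chr1", IRanges(c(1, 7), c(3, 9))),
                         tss = 1L, end3 = 9L, n_ex = 2L),
                    class = "transcript_candidate")
  expect_equal(spliced_sequence(plus, genome), "ACGGCA")
  minus <- plus; minus$strand <- "-"
  expect_equal(spliced_sequence(minus, genome), "TGCCGT")
  single <- plus; single$exons <- GRanges("chr1", IRanges(2, 5))
  single$n_ex <- 1L
  expect_equal(spliced_sequence(single, genome), "CGTT")
  oob <- plus; oob$exons <- GRanges("chr1", IRanges(5, 20))
  expect_error(spliced_sequence(oob, genome), "bounds")
})

test_that("valid_junction_count requires canonical motifs at every boundary", {
  region <- GRanges("chrS", IRanges(401, 1100))
  jx <- data.frame(chrom = "chrS", intron_start = 701L, intron_end = 900L,
                   support = 5L, motif = "GTAG")
  cand <- assemble_exons(region, jx, strand = "+")
  expect_equal(valid_junction_count(cand, jx), 2L)

  jx_bad <- jx; jx_bad$motif <- "CTGC"
  cand_bad <- assemble_exons(region, jx_bad, strand = "+")
  expect_equal(valid_junction_count(cand_bad, jx_bad), 0L)

  # canonical on minus means CTAC
  jx_m <- jx; jx_m$motif <- "CTAC"
  cand_m <- assemble_exons(region, jx_m, strand = "-")
  expect_equal(valid_junction_count(cand_m, jx_m), 2L)
  expect_equal(valid_junction_count(cand_m, jx_m, strand = "+"), 0L)

  single <- assemble_exons(region, NULL)
  expect_equal(valid_junction_count(single, NULL), 0L)
})
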