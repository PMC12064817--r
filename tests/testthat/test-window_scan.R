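test_that("make_windows tiles chromosomes per the window/step policy", {
  w <- make_windows(c(chr1 = 1000L))
  expect_equal(start(w), c(1L, 251L, 501L))
  expect_equal(end(w), c(500L, 750L, 1000L))

  # chromosome shorter than one window: a single clipped window
  w2 <- make_windows(c(chr1 = 400L))
  expect_equal(length(w2), 1L)
  expect_equal(c(start(w2), end(w2)), c(1L, 400L))

  w3 <- make_windows(c(chr1 = 500L))
  expect_equal(length(w3), 1L)
  expect_equal(width(w3), 500L)

  # trailing partial window survives when not contained in its predecessor
  w4 <- make_windows(c(chr1 = 1100L))
  expect_equal(end(w4)[length(w4)], 1100L)
  expect_equal(start(w4)[length(w4)], 751L)

  expect_error(make_windows(c(chr1 = 1000L), window = 100L, step = 200L))
})

test_that("build_matrix computes mean per-base RPM per window", {
  dir <- tempfile("cohort_")
  dir.create(dir)
  # bedGraph samples: uniform depth 2 over 1 kb, library size 1e6
  mk <- function(id, depth, mapped) {
    p <- file.path(dir, paste0(id, ".bedGraph"))
    writeLines(sprintf("chr1\t0\t1000\t%d", depth), p)
    sample_alignment(p, id, mapped_reads = mapped)
  }
  samples <- lapply(1:5, function(i) mk(paste0("s", i), 2L, 1e6))
  m <- build_matrix(samples, make_windows(c(chr1 = 1000L)))
  expect_true(all(abs(m$values - 2) < 1e-12))
  expect_equal(dim(m$values), c(3L, 5L))

  # RPM scale invariance: doubling depth and library size changes nothing
  s_scaled <- c(lapply(1:4, function(i) mk(paste0("t", i), 2L, 1e6)),
                list(mk("t5", 4L, 2e6)))
  m2 <- build_matrix(s_scaled, make_windows(c(chr1 = 1000L)))
  expect_equal(m2$values[, 5], m$values[, 5])

  expect_error(build_matrix(samples[1:4], make_windows(c(chr1 = 1000L))),
               "20%")
})

matrix_of <- function(rows) {
  v <- do.call(rbind, rows)
  structure(list(
    windows = GRanges("chr1", IRanges(start = seq_len(nrow(v)) * 1000L,
                                      width = 500L)),
    samples = paste0("s", seq_len(ncol(v))),
    values = v), class = "coverage_matrix")
}

test_that("window_statistics implements the top/bottom-20%-vs-median rule", {
  m <- matrix_of(list(
    c(rep(0.1, 8), 10, 10),     # outlier high in 2/10 -> selected
    rep(3, 10),                 # flat -> not selected
    c(rep(5, 8), 5.5, 5.5),     # abs diff 0.5 fails regardless of fc
    c(0, 0, rep(10, 8))         # silenced in 2/10 -> selected (bottom arm)
  ))
  st <- window_statistics(m)
  expect_equal(st$selected, c(TRUE, FALSE, FALSE, TRUE))

  r1 <- st[1, ]
  expect_equal(r1$median, 0.1)
  expect_equal(r1$top_mean, 10)
  expect_equal(r1$abs_diff, 9.9)
  expect_equal(r1$log2fc, abs(log2(10.1 / 0.2)), tolerance = 1e-12)
  expect_true(all(st$bottom_mean <= st$median & st$median <= st$top_mean))
  # selection implies both thresholds
  expect_true(all(!st$selected | (st$abs_diff > 1 & st$log2fc > 1)))
})

test_that("selection is monotone in the expression of the top samples", {
  set.seed(11)
  for (i in 1:50) {
    v <- runif(10, 0, 5)
    m <- matrix_of(list(v))
    if (!window_statistics(m)$selected) next
    boosted <- v
    top_idx <- order(v, decreasing = TRUE)[1:2]
    boosted[top_idx] <- boosted[top_idx] + runif(2, 0, 20)
    expect_true(window_statistics(matrix_of(list(boosted)))$selected)
  }
})

test_that("filter_known removes windows touching gene spans (half-open safe)", {
  genes <- GRanges("chr1", IRanges(701, 900))
  stats <- data.frame(chrom = "chr1",
                      start = c(251L, 251L), end = c(750L, 700L),
                      selected = TRUE)
  out <- filter_known(stats, genes)
  expect_equal(nrow(out), 1L)
  expect_equal(out$end, 700L)  # book-ended window shares no base
  expect_identical(filter_known(stats, GRanges()), stats)
  # no residual overlap, exhaustively
  expect_true(all(countOverlaps(
    GRanges(out$chrom, IRanges(out$start, out$end)), genes) == 0L))
})

test_that("merge_windows coalesces overlapping and book-ended windows", {
  g <- function(s, e) GRanges("chr1", IRanges(s, e))
  expect_equal(start(merge_windows(c(g(1, 500), g(251, 750)))), 1L)
  expect_equal(end(merge_windows(c(g(1, 500), g(251, 750)))), 750L)
  m <- merge_windows(c(g(1, 500), g(501, 1000)))
  expect_equal(length(m), 1L)
  expect_equal(width(m), 1000L)
  m2 <- merge_windows(c(g(1, 500), g(751, 1250)))
  expect_equal(length(m2), 2L)
})

test_that("merge_windows equals the per-base union oracle", {
  set.seed(23)
  for (i in 1:10) {
    n <- sample(2:12, 1)
    s <- sample.int(9000L, n, replace = TRUE)
    e <- pmin(s + sample(50:800, n, replace = TRUE), 10000L)
    merged <- merge_windows(GRanges("chrX", IRanges(s, e)))
    oracle <- union_oracle(s, e, 10000L)
    expect_equal(start(merged), oracle$start)
    expect_equal(end(merged), oracle$end)
  }
})
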