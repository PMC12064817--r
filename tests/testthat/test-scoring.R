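test_that("composition scores follow the printed piecewise maps", {
  # GC: 0 below 0.4, (x-0.4)/0.15 in the middle, 1 above 0.55
  expect_equal(score_gc(0.30), 0)
  expect_equal(score_gc(0.475), 0.5)
  expect_equal(score_gc(0.60), 1)
  # G+T skew: 0 below 0.5, (x-0.5)/0.1, 1 above 0.6
  expect_equal(score_chargaff(0.45), 0)
  expect_equal(score_chargaff(0.55), 0.5)
  expect_equal(score_chargaff(0.65), 1)
  # T-rich: 0 below 0.3, sqrt((x-0.3)/0.1), 1 above 0.4
  expect_equal(score_trich(0.25), 0)
  expect_equal(score_trich(0.325), 0.5)
  expect_equal(score_trich(0.45), 1)
})

test_that("composition scores accept sequences and ignore N bases", {
  expect_equal(score_gc("GGGGGCAATT"), score_gc(0.6))
  expect_equal(score_gc("GGGGGCAATTNNNN"), score_gc(0.6))  # N masked out
  expect_equal(score_chargaff("GTGTGTACAC"), score_chargaff(0.6))
  expect_equal(score_trich("TTTAAAAAAA"), score_trich(0.3))
  expect_equal(score_trich(NULL), 0)
  expect_equal(score_trich(""), 0)
  expect_warning(s <- score_gc("NNNN"), "all-N")
  expect_equal(s, 0)
})

test_that("piecewise maps are continuous at their breakpoints and monotone", {
  eps <- 1e-9
  for (f in list(score_gc, score_chargaff, score_trich)) {
    lo <- if (identical(f, score_gc)) 0.4 else if (identical(f, score_chargaff)) 0.5 else 0.3
    hi <- if (identical(f, score_gc)) 0.55 else if (identical(f, score_chargaff)) 0.6 else 0.4
    expect_equal(f(lo), 0)
    expect_equal(f(hi), 1)
    # the sqrt ramp has infinite slope at its lower breakpoint, so the
    # tightest uniform continuity bound at +/- 1e-9 is sqrt(1e-8) = 1e-4
    expect_lt(abs(f(lo + eps) - f(lo - eps)), 1.001e-4)
    expect_lt(abs(f(hi + eps) - f(hi - eps)), 1.001e-4)
    grid <- seq(0, 1, by = 0.01)
    vals <- vapply(grid, f, numeric(1))
    expect_true(all(diff(vals) >= 0))
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("score_motif demands a perfect consensus in its positional window", {
  bg <- strrep("CTG", 40)  # motif-free background
  ctx <- function(insert, at, tss = 61L) {
    s <- substr(bg, 1, 120)
    substr(s, at, at + nchar(insert) - 1L) <- insert
    list(seq = s, tss = tss)
  }
  # TATA at -28 relative to the TSS
  c1 <- ctx("TATAAA", 61L - 28L)
  expect_equal(score_motif(c1$seq, c1$tss), 1)
  # no motif at all
  expect_equal(score_motif(substr(bg, 1, 120), 61L), 0)
  # right motif, wrong place
  c2 <- ctx("TATAAA", 61L + 40L)
  expect_equal(score_motif(c2$seq, c2$tss), 0)
  # Initiator overlapping the TSS (CCATTCC matches YYANWYY)
  c3 <- ctx("CCATTCC", 59L)
  expect_equal(score_motif(c3$seq, c3$tss), 1)
  # DPE downstream window (GGACA matches RGWYV at +28)
  c4 <- ctx("GGACA", 61L + 28L)
  expect_equal(score_motif(c4$seq, c4$tss), 1)
})

test_that("find_polya classifies perfect/near-perfect hits leftmost-first", {
  bg <- strrep("CTG", 30)
  with_insert <- function(insert, at) {
    s <- bg
    substr(s, at, at + nchar(insert) - 1L) <- insert
    s
  }
  hit <- find_polya(with_insert("AATAAA", 31L))
  expect_equal(hit$match_class, "perfect")
  expect_equal(hit$position, 31L)
  expect_equal(score_polya(hit), 1)

  near <- find_polya(with_insert("AATAAG", 31L))
  expect_equal(near$match_class, "near_perfect")
  expect_equal(score_polya(near), 0.5)

  # a later perfect hit beats an earlier near-perfect one
  s <- with_insert("AATAAG", 10L)
  substr(s, 40L, 45L) <- "AATAAA"
  expect_equal(find_polya(s)$position, 40L)

  none <- find_polya(bg)
  expect_equal(none$match_class, "none")
  expect_equal(score_polya(none), 0)
})

test_that("find_longest_orf matches definition on constructed cases", {
  o <- find_longest_orf("ATGAAATGA")
  expect_equal(o$length, 9L)
  expect_equal(o$n_orf, 1L)
  expect_true(o$includes_last_exon)
  expect_equal(o$p, 0.5)

  o2 <- find_longest_orf("CCCCCC")
  expect_equal(o2$n_orf, 0L)
  expect_equal(o2$p, 0)

  # ORF spanning exons 1-2 of 3, stop before the last exon
  s <- paste0("ATG", strrep("GGT", 20), "TAA", strrep("CCC", 10))
  o3 <- find_longest_orf(s, exon_lengths = c(30L, 40L, 26L))
  expect_equal(o3$n_orf, 2L)
  expect_false(o3$includes_last_exon)
  expect_equal(o3$p, 0)
})

test_that("find_longest_orf agrees with the brute-force oracle", {
  set.seed(31)
  for (i in 1:200) {
    s <- random_dna(sample(3:300, 1))
    got <- find_longest_orf(s)
    want <- orf_oracle(s)
    expect_equal(got$length, want$length, info = s)
    if (want$length > 0) expect_equal(got$start, want$start, info = s)
  }
})

test_that("score_orf and score_exons follow the printed formulas", {
  expect_equal(score_orf(1, 1, 0.5), 1)
  expect_equal(score_orf(1, 4, 0), 1 / 3)
  expect_equal(score_orf(0, 3, 0), 0)
  expect_error(score_orf(5, 4), "exceed")
  # monotone in n_orf for fixed n_ex
  vals <- vapply(0:6, function(k) score_orf(k, 6, 0), numeric(1))
  expect_true(all(diff(vals) >= 0))

  expect_equal(score_exons(0, 1), 0)
  expect_equal(score_exons(3, 4), 0.75)
  expect_equal(score_exons(5, 5), 1)
  expect_error(score_exons(2, 1), "exceed")
})

test_that("aggregate scores combine and bound correctly", {
  expect_equal(score_promoter(1, 1, 1), 1)
  expect_equal(score_promoter(1, 0.5, 0), 0.5)
  expect_equal(score_3utr(0.5, 1), 0.75)
  card <- list(s_prom = 0.5, s_3utr = 0.75, s_orf = 1 / 3, s_ex = 0.75)
  expect_equal(total_score(card), 0.5 + 0.75 + 1 / 3 + 0.75)

  set.seed(41)
  for (i in 1:100) {
    sm <- sample(c(0, 1), 1); sg <- runif(1); sc <- runif(1)
    sp <- score_polya(sample(c("perfect", "near_perfect", "none"), 1))
    st <- score_trich(runif(1))
    ne <- sample(1:6, 1); no <- sample(0:ne, 1)
    p <- if (no > 0) sample(c(0, 0.5), 1) else 0
    nv <- sample(0:ne, 1)
    parts <- c(score_promoter(sm, sg, sc), score_3utr(sp, st),
               score_orf(no, ne, p), score_exons(nv, ne))
    expect_true(all(parts >= 0 & parts <= 1))
    tot <- sum(parts)
    expect_true(tot >= 0 && tot <= 4)
  }
})

test_that("rank_candidates sorts by total, then mean RPM, then coordinate", {
  cards <- data.frame(id = c("a", "b", "c", "d"),
                      chrom = "chr1", start = c(500L, 100L, 300L, 200L),
                      total = c(3.0, 1.0, 2.5, 2.5),
                      mean_rpm = c(1, 1, 5, 9))
  r <- rank_candidates(cards)
  expect_equal(r$id, c("a", "d", "c", "b"))
  expect_equal(r$rank, 1:4)
  one <- rank_candidates(cards[1, ])
  expect_equal(one$rank, 1L)
})

test_that("scoring a transcript equals scoring its reverse-complement mirror", {
  set.seed(53)
  for (i in 1:5) {
    L <- 3000L
    chr <- random_dna(L)
    genome_fwd <- Biostrings::DNAStringSet(c(chrT = chr))
    genome_rev <- Biostrings::DNAStringSet(c(chrT = as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(chr)))))
    s <- 1200L; e <- 1799L
    fwd <- structure(list(id = "f", strand = "+",
                          exons = GRanges("chrT", IRanges(s, e), strand = "+"),
                          tss = s, end3 = e, n_ex = 1L),
                     class = "transcript_candidate")
    rev <- structure(list(id = "r", strand = "-",
                          exons = GRanges("chrT", IRanges(L - e + 1L, L - s + 1L),
                                          strand = "-"),
                          tss = L - s + 1L, end3 = L - e + 1L, n_ex = 1L),
                     class = "transcript_candidate")
    a <- score_candidate(fwd, genome_fwd)
    b <- score_candidate(rev, genome_rev)
    expect_equal(a$total, b$total)
    expect_equal(a[, c("s_gc", "s_charg", "s_motif", "s_polya", "s_trich",
                       "s_orf", "s_ex")],
                 b[, c("s_gc", "s_charg", "s_motif", "s_polya", "s_trich",
                       "s_orf", "s_ex")])
  }
})
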