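# Candidate-level scoring: extracts the promoter, TSS-context and 3'-end
# windows in transcript orientation, evaluates all sub-scores, and ranks.

#' Default scoring parameters
#'
#' Window extents and motif consensi used by \code{\link{score_candidate}}.
#' The promoter composition window covers 200 bp upstream of the TSS plus
#' the first 50 transcribed bases (250 nt); motifs are searched in a
#' +/- 40 bp context around the TSS; the poly(A) hexamer is searched in the
#' last 50 nt of the transcript plus 20 nt of downstream genomic sequence,
#' and the T-rich window spans up to 80 bp downstream of the hexamer.
#'
#' @return Named list of defaults, suitable for the \code{config} argument
#'   of \code{\link{score_candidate}}.
#' @export
scoring_defaults <- function() {
  list(promoter_up = 200L, promoter_down = 50L,
       motif_flank = 40L,
       tata = "TATAAA", inr = "YYANWYY", dpe = "RGWYV",
       tata_window = c(-33L, -23L), dpe_window = c(25L, 35L),
       polya_motif = "AATAAA", polya_tail = 50L, polya_down = 20L,
       trich_len = 80L)
}

# sense-strand window at offsets lo..hi relative to a genomic anchor
# (offset 0 = the anchor base, negative = upstream in transcript sense);
# returns list(seq=character, anchor_offset=1-based index of the anchor)
.sense_window <- function(chr, anchor, strand, lo, hi) {
  len <- length(chr)
  if (identical(strand, "-")) {
    gs <- max(1L, anchor - hi); ge <- min(len, anchor - lo)
    if (gs > ge) return(list(seq = "", anchor_offset = NA_integer_))
    s <- as.character(reverseComplement(subseq(chr, gs, ge)))
    list(seq = s, anchor_offset = ge - anchor + 1L)
  } else {
    gs <- max(1L, anchor + lo); ge <- min(len, anchor + hi)
    if (gs > ge) return(list(seq = "", anchor_offset = NA_integer_))
    list(seq = as.character(subseq(chr, gs, ge)),
         anchor_offset = anchor - gs + 1L)
  }
}

# score one orientation of a candidate; cand$strand must be "+" or "-"
.score_oriented <- function(cand, genome, junctions, cfg) {
  chrom <- as.character(seqnames(cand$exons))[1]
  chr <- genome[[chrom]]
  strand <- cand$strand
  tss <- if (identical(strand, "-")) max(end(cand$exons)) else min(start(cand$exons))
  end3 <- if (identical(strand, "-")) min(start(cand$exons)) else max(end(cand$exons))
  cand$tss <- tss; cand$end3 <- end3

  prom <- .sense_window(chr, tss, strand,
                        -cfg$promoter_up, cfg$promoter_down - 1L)$seq
  ctx <- .sense_window(chr, tss, strand, -cfg$motif_flank, cfg$motif_flank)
  s_gc <- score_gc(prom)
  s_charg <- score_chargaff(prom)
  s_motif <- if (nzchar(ctx$seq))
    score_motif(ctx$seq, ctx$anchor_offset, tata = cfg$tata, inr = cfg$inr,
                dpe = cfg$dpe, tata_window = cfg$tata_window,
                dpe_window = cfg$dpe_window) else 0
  s_prom <- score_promoter(s_motif, s_gc, s_charg)

  spliced <- spliced_sequence(cand, genome)
  tail_n <- min(cfg$polya_tail, nchar(spliced))
  tail_seq <- substr(spliced, nchar(spliced) - tail_n + 1L, nchar(spliced))
  down_len <- cfg$polya_down + cfg$trich_len + nchar(cfg$polya_motif)
  downstream <- .sense_window(chr, end3, strand, 1L, down_len)$seq
  combined <- paste0(tail_seq, downstream)
  search_seq <- substr(combined, 1L, tail_n + cfg$polya_down)
  hit <- find_polya(search_seq, motif = cfg$polya_motif)
  s_polya <- score_polya(hit)
  s_trich <- if (is.na(hit$position)) 0 else
    score_trich(substr(combined, hit$end + 1L, hit$end + cfg$trich_len))
  s_3utr <- score_3utr(s_polya, s_trich)

  exon_lengths <- width(cand$exons)
  if (identical(strand, "-")) exon_lengths <- rev(exon_lengths)
  orf <- find_longest_orf(spliced, exon_lengths)
  s_orf <- score_orf(orf$n_orf, cand$n_ex, orf$p)

  n_valid <- valid_junction_count(cand, junctions, strand = strand)
  s_ex <- score_exons(n_valid, cand$n_ex)

  data.frame(id = cand$id, chrom = chrom,
             start = min(start(cand$exons)), end = max(end(cand$exons)),
             strand = strand, tss = tss, end3 = end3, n_ex = cand$n_ex,
             n_valid = n_valid, n_orf = orf$n_orf,
             s_gc = s_gc, s_charg = s_charg, s_motif = s_motif,
             s_prom = s_prom, s_polya = s_polya, s_trich = s_trich,
             s_3utr = s_3utr, s_orf = s_orf, s_ex = s_ex,
             total = s_prom + s_3utr + s_orf + s_ex,
             stringsAsFactors = FALSE)
}

#' Score a transcript candidate
#'
#' Computes the full score card of a candidate: promoter GC/Chargaff
#' composition and motif presence, poly(A) and T-rich 3' end, longest-ORF
#' exon coverage, and junction-supported exon structure. A candidate with
#' unknown strand is scored in both orientations and the orientation with
#' the higher total is reported (flagged in \code{strand_ambiguous}).
#'
#' @param candidate A \code{transcript_candidate}.
#' @param genome A \code{DNAStringSet}.
#' @param junctions Junction data.frame from \code{\link{collect_junctions}}
#'   (used for the exon score); may be \code{NULL}.
#' @param mean_rpm Mean cohort expression of the candidate in RPM, carried
#'   into the score card as the ranking tie-breaker.
#' @param config Scoring parameters; see \code{\link{scoring_defaults}}.
#' @return One-row data.frame with all sub-scores, \code{total},
#'   \code{mean_rpm} and \code{strand_ambiguous}.
#' @export
score_candidate <- function(candidate, genome, junctions = NULL,
                            mean_rpm = NA_real_, config = scoring_defaults()) {
  stopifnot(inherits(candidate, "transcript_candidate"))
  cfg <- utils::modifyList(scoring_defaults(), config)
  if (candidate$strand %in% c("+", "-")) {
    card <- .score_oriented(candidate, genome, junctions, cfg)
    card$strand_ambiguous <- FALSE
  } else {
    cp <- candidate; cp$strand <- "+"
    cm <- candidate; cm$strand <- "-"
    a <- .score_oriented(cp, genome, junctions, cfg)
    b <- .score_oriented(cm, genome, junctions, cfg)
    card <- if (b$total > a$total) b else a
    card$strand_ambiguous <- TRUE
  }
  card$mean_rpm <- mean_rpm
  card
}

#' Rank scored candidates
#'
#' Orders score cards by decreasing total score; ties are broken by
#' decreasing mean cohort RPM and then by genomic coordinate, so the
#' ranking is deterministic.
#'
#' @param cards data.frame of score cards (rows from
#'   \code{\link{score_candidate}}).
#' @return The same data.frame, sorted, with a \code{rank} column.
#' @export
rank_candidates <- function(cards) {
  if (nrow(cards) == 0L) {
    cards$rank <- integer(0)
    return(cards)
  }
  rpm <- cards$mean_rpm
  rpm[is.na(rpm)] <- -Inf
  ord <- order(-cards$total, -rpm, cards$chrom, cards$start)
  out <- cards[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
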