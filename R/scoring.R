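# Candidate scoring: promoter composition (GC, Chargaff-violation), core
# promoter motifs (TATA/Inr/DPE), poly(A) signal and T-rich 3' region,
# longest-ORF coverage, and splice-supported exon structure. Every
# sub-score lies in [0, 1]; the ranking score is their weighted sum
# s_prom + s_3utr + s_orf + s_ex in [0, 4].

# fraction of `bases` among non-N characters of a sequence; NA if nothing left
.base_fraction <- function(seq, bases) {
  v <- strsplit(toupper(as.character(seq)), "")[[1]]
  v <- v[v != "N"]
  if (length(v) == 0L) return(NA_real_)
  sum(v %in% bases) / length(v)
}

# shared piecewise-linear ramp: 0 below lo, 1 above hi, linear (optionally
# through sqrt) in between; the printed branches use strict inequalities,
# so both breakpoints land in the closed middle branch (continuous).
.ramp <- function(frac, lo, hi, sqrt_ramp = FALSE) {
  if (is.na(frac)) {
    warning("composition undefined (all-N sequence); score set to 0")
    return(0)
  }
  if (frac < lo) return(0)
  if (frac > hi) return(1)
  y <- (frac - lo) / (hi - lo)
  if (sqrt_ramp) sqrt(y) else y
}

#' GC promoter score
#'
#' Piecewise-linear score of the G+C fraction of the promoter window:
#' 0 below 0.4, \code{(frac - 0.4)/0.15} between 0.4 and 0.55, 1 above
#' 0.55. N bases are excluded from the fraction.
#'
#' @param promoter Promoter sequence (character or \code{DNAString}), or a
#'   precomputed G+C fraction given as a bare number.
#' @return \code{s_gc} in [0, 1].
#' @examples
#' score_gc("GCGCGCAATT")   # 0.6 -> 1
#' score_gc(0.475)          # 0.5
#' @export
score_gc <- function(promoter) {
  frac <- if (is.numeric(promoter)) promoter
          else .base_fraction(promoter, c("G", "C"))
  .ramp(frac, 0.4, 0.55)
}

#' Chargaff second-rule violation score
#'
#' Within one strand Chargaff's second rule expects %A near %T and %G near
#' %C; a skew of G+T away from 0.5 violates it and is used here as a
#' promoter feature. The G+T fraction maps to 0 below 0.5, linearly to 1
#' at 0.6, and 1 above.
#'
#' @param promoter Promoter sequence, or a G+T fraction as a bare number.
#' @return \code{s_charg} in [0, 1].
#' @export
score_chargaff <- function(promoter) {
  frac <- if (is.numeric(promoter)) promoter
          else .base_fraction(promoter, c("G", "T"))
  .ramp(frac, 0.5, 0.6)
}

#' Core promoter motif score
#'
#' Binary score: 1 when a perfect consensus match of any of the three core
#' promoter elements lies in its expected positional window around the TSS,
#' 0 otherwise. Defaults: TATA box \code{TATAAA} starting 33 to 23 bases
#' upstream of the TSS, Initiator \code{YYANWYY} overlapping the TSS, and
#' DPE \code{RGWYV} starting 25 to 35 bases downstream. Consensi use IUPAC
#' codes; N bases in the sequence match nothing.
#'
#' @param context Sequence around the TSS (character or \code{DNAString}).
#' @param tss_offset 1-based position of the TSS base within \code{context}.
#' @param tata,inr,dpe Motif consensi (IUPAC).
#' @param tata_window,dpe_window Allowed motif start offsets relative to the
#'   TSS (TSS itself is offset 0).
#' @return \code{s_motif}, 0 or 1.
#' @export
score_motif <- function(context, tss_offset,
                        tata = "TATAAA", inr = "YYANWYY", dpe = "RGWYV",
                        tata_window = c(-33L, -23L),
                        dpe_window = c(25L, 35L)) {
  subject <- DNAString(toupper(as.character(context)))
  hit_starts <- function(motif) {
    if (length(subject) < nchar(motif)) return(integer(0))
    m <- matchPattern(DNAString(motif), subject, fixed = "subject")
    start(m)
  }
  rel <- function(p) p - tss_offset
  # TATA: start offset inside its upstream window
  ta <- rel(hit_starts(tata))
  if (any(ta >= tata_window[1] & ta <= tata_window[2])) return(1)
  # Initiator: match must cover the TSS base
  ist <- hit_starts(inr)
  if (any(ist <= tss_offset & ist + nchar(inr) - 1L >= tss_offset)) return(1)
  # DPE: start offset inside its downstream window
  dp <- rel(hit_starts(dpe))
  if (any(dp >= dpe_window[1] & dp <= dpe_window[2])) return(1)
  0
}

#' Total promoter score
#'
#' Arithmetic mean of the motif, GC and Chargaff sub-scores.
#'
#' @param s_motif,s_gc,s_charg Sub-scores in [0, 1].
#' @return \code{s_prom} in [0, 1].
#' @export
score_promoter <- function(s_motif, s_gc, s_charg) {
  (s_motif + s_gc + s_charg) / 3
}

#' Search a 3'-end window for the poly(A) signal
#'
#' Scans the window for the canonical hexamer \code{AATAAA}. An exact
#' occurrence is a \emph{perfect} hit; failing that, an occurrence with
#' exactly one mismatched base is a \emph{near-perfect} hit. Ties are
#' broken leftmost within each class, and a perfect hit anywhere beats a
#' near-perfect one. N bases count as mismatches.
#'
#' @param end3_seq 3'-end search window in transcript orientation.
#' @param motif Poly(A) hexamer consensus.
#' @return An object of class \code{polya_hit}: list with
#'   \code{match_class} (\code{"perfect"}, \code{"near_perfect"},
#'   \code{"none"}), \code{position} (1-based start of the hit within
#'   \code{end3_seq}, NA when none) and \code{end} (last base of the hit).
#' @export
find_polya <- function(end3_seq, motif = "AATAAA") {
  s <- toupper(as.character(end3_seq))
  k <- nchar(motif)
  n <- nchar(s)
  out <- function(cls, pos)
    structure(list(match_class = cls, position = pos,
                   end = if (is.na(pos)) NA_integer_ else pos + k - 1L),
              class = "polya_hit")
  if (n < k) return(out("none", NA_integer_))
  sv <- strsplit(s, "")[[1]]
  mv <- strsplit(motif, "")[[1]]
  mism <- vapply(seq_len(n - k + 1L), function(i) {
    w <- sv[i:(i + k - 1L)]
    sum(w != mv | w == "N")
  }, integer(1))
  if (any(mism == 0L)) return(out("perfect", which(mism == 0L)[1L]))
  if (any(mism == 1L)) return(out("near_perfect", which(mism == 1L)[1L]))
  out("none", NA_integer_)
}

#' Poly(A) signal score
#'
#' 1 for a perfect hexamer hit, 0.5 for a near-perfect (single-mismatch)
#' hit, 0 otherwise.
#'
#' @param hit A \code{polya_hit} from \code{\link{find_polya}} (a bare
#'   match-class string is also accepted).
#' @return \code{s_polya} in \{0, 0.5, 1\}.
#' @export
score_polya <- function(hit) {
  cls <- if (inherits(hit, "polya_hit")) hit$match_class else as.character(hit)
  switch(cls, perfect = 1, near_perfect = 0.5, 0)
}

#' T-rich 3' region score
#'
#' Scores the T fraction of the (up to) 80 bp downstream of the poly(A)
#' hit: 0 below 0.3, \code{sqrt((frac - 0.3)/0.1)} between 0.3 and 0.4,
#' 1 above 0.4. With no poly(A) hit there is no window and the score is 0.
#'
#' @param downstream Sequence downstream of the poly(A) site (at most
#'   80 bp are meaningful), a T fraction as a bare number, or \code{NULL} /
#'   empty when no poly(A) hit was found.
#' @return \code{s_trich} in [0, 1].
#' @export
score_trich <- function(downstream) {
  if (is.null(downstream)) return(0)
  if (is.numeric(downstream)) return(.ramp(downstream, 0.3, 0.4, sqrt_ramp = TRUE))
  if (nchar(as.character(downstream)) == 0L) return(0)
  .ramp(.base_fraction(downstream, "T"), 0.3, 0.4, sqrt_ramp = TRUE)
}

#' Total 3'UTR score
#'
#' Mean of the poly(A) and T-rich sub-scores.
#'
#' @param s_polya,s_trich Sub-scores in [0, 1].
#' @return \code{s_3utr} in [0, 1].
#' @export
score_3utr <- function(s_polya, s_trich) {
  (s_polya + s_trich) / 2
}

#' Longest open reading frame of a spliced transcript
#'
#' Finds the longest ATG-initiated, stop-terminated reading frame over the
#' three forward frames of the oriented spliced sequence (the stop codon is
#' part of the ORF). Ties are resolved leftmost. When exon lengths are
#' given, the ORF span is mapped back onto the exon chain to count the
#' exons it touches and whether the last exon is included.
#'
#' @param spliced Spliced transcript sequence, 5' to 3'.
#' @param exon_lengths Ordered exon lengths (5' to 3') summing to
#'   \code{nchar(spliced)}; defaults to a single exon.
#' @return A list with \code{start}, \code{end} (1-based spliced
#'   coordinates, NA when no ORF), \code{length}, \code{n_orf} (exons
#'   spanned; 0 when no ORF), \code{includes_last_exon}, and \code{p}
#'   (0.5 when the last exon is included, else 0).
#' @export
find_longest_orf <- function(spliced, exon_lengths = NULL) {
  s <- toupper(as.character(spliced))
  n <- nchar(s)
  if (is.null(exon_lengths)) exon_lengths <- n
  if (sum(exon_lengths) != n)
    stop("exon_lengths must sum to the spliced length")
  best <- NULL
  if (n >= 3L) {
    sv <- strsplit(s, "")[[1]]
    for (f in 0:2) {
      if (1L + f > n - 2L) next
      starts <- seq.int(1L + f, n - 2L, by = 3L)
      codons <- paste0(sv[starts], sv[starts + 1L], sv[starts + 2L])
      is_start <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      open <- NA_integer_
      for (i in seq_along(codons)) {
        if (is_stop[i]) {
          if (!is.na(open)) {
            len <- starts[i] + 2L - open + 1L
            if (is.null(best) || len > best$length ||
                (len == best$length && open < best$start))
              best <- list(start = open, end = starts[i] + 2L, length = len)
            open <- NA_integer_
          }
        } else if (is_start[i] && is.na(open)) {
          open <- starts[i]
        }
      }
    }
  }
  n_ex <- length(exon_lengths)
  if (is.null(best))
    return(list(start = NA_integer_, end = NA_integer_, length = 0L,
                n_orf = 0L, includes_last_exon = FALSE, p = 0))
  cum <- cumsum(exon_lengths)
  exon_of <- function(p) findInterval(p - 0.5, c(0, cum))
  e1 <- exon_of(best$start); e2 <- exon_of(best$end)
  incl <- e2 == n_ex
  list(start = best$start, end = best$end, length = best$length,
       n_orf = e2 - e1 + 1L, includes_last_exon = incl,
       p = if (incl) 0.5 else 0)
}

#' ORF score
#'
#' \code{(sqrt(n_orf / n_ex) + p) / 1.5}, where \code{n_orf} is the number
#' of exons spanned by the longest ORF, \code{n_ex} the exon count, and
#' \code{p} 0.5 when the last exon is part of the ORF. Without an ORF
#' (\code{n_orf = 0}) the score is 0.
#'
#' @param n_orf Exons spanned by the longest ORF.
#' @param n_ex Total exon count (>= 1).
#' @param p 0.5 if the last exon is included in the ORF, else 0.
#' @return \code{s_orf} in [0, 1].
#' @export
score_orf <- function(n_orf, n_ex, p = 0) {
  if (n_orf > n_ex) stop("n_orf cannot exceed n_ex")
  stopifnot(n_ex >= 1, n_orf >= 0)
  if (n_orf == 0) return(0)
  (sqrt(n_orf / n_ex) + p) / 1.5
}

#' Exon structure score
#'
#' 0 for single-exon candidates; otherwise the fraction
#' \code{n_valid / n_ex} of exons supported by valid (canonical) splice
#' junctions.
#'
#' @param n_valid Exons with valid splice junctions.
#' @param n_ex Total exon count (>= 1).
#' @return \code{s_ex} in [0, 1].
#' @export
score_exons <- function(n_valid, n_ex) {
  if (n_valid > n_ex) stop("n_valid cannot exceed n_ex")
  stopifnot(n_ex >= 1, n_valid >= 0)
  if (n_ex == 1) return(0)
  n_valid / n_ex
}

#' Total candidate score
#'
#' Sum of the promoter, 3'UTR, ORF and exon scores.
#'
#' @param card A score card (named list or one-row data.frame holding
#'   \code{s_prom}, \code{s_3utr}, \code{s_orf}, \code{s_ex}).
#' @return Total score in [0, 4].
#' @export
total_score <- function(card) {
  card$s_prom + card$s_3utr + card$s_orf + card$s_ex
}
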