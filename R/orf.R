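#' Six-frame translation
#'
#' Translates a DNA sequence in all six reading frames under the standard
#' genetic code. Stop codons are emitted as `"*"`; a trailing 1–2 bases that
#' do not fill a codon are dropped. Frames are ordered `+1, +2, +3, -1, -2,
#' -3`, where frame `-k` is frame `+k` of the reverse complement.
#'
#' @param seq DNA string over `{A,C,G,T,N}` of length >= 3.
#' @return named character vector of six peptide strings.
#' @examples
#' six_frame_translate("ATGGCCTAA")[["+1"]] # "MA*"
#' @export
six_frame_translate <- function(seq) {
  seq <- validate_dna(seq)
  if (nchar(seq) < 3L) stop("sequence must have length >= 3")
  rc <- revcomp(seq)
  frames <- c(
    "+1" = seq, "+2" = substring(seq, 2L), "+3" = substring(seq, 3L),
    "-1" = rc, "-2" = substring(rc, 2L), "-3" = substring(rc, 3L)
  )
  vapply(frames, translate_frame, character(1))
}

translate_frame <- function(s) {
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(s, 1L, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}

validate_dna <- function(seq) {
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("input error: sequence contains symbols outside {A,C,G,T,N}")
  }
  seq
}

#' Longest open reading frame per strand
#'
#' Scans the three forward frames (and, through the reverse complement, the
#' three reverse frames) for the longest ATG-initiated open reading frame.
#' An ORF runs from an ATG to the first in-frame stop codon, or to the end
#' of the frame when no stop follows (a truncated ORF still counts). The
#' reported length is in codons, excluding the stop.
#'
#' @param seq DNA string, length >= 3.
#' @return list with `plus` and `minus`, each a list of `codons` (longest
#'   ORF length in codons) and `nt` (its nucleotide length, `3 * codons`).
#' @export
longest_orf <- function(seq) {
  seq <- validate_dna(seq)
  scan_strand <- function(s) {
    best <- 0L
    for (off in 0:2) {
      n_cod <- (nchar(s) - off) %/% 3L
      if (n_cod < 1L) next
      codons <- substring(s, off + 1L + 3L * (seq_len(n_cod) - 1L), off + 3L * seq_len(n_cod))
      is_start <- codons == "ATG"
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      open_from <- NA_integer_
      for (i in seq_len(n_cod)) {
        if (is.na(open_from) && is_start[i]) open_from <- i
        if (!is.na(open_from) && is_stop[i]) {
          best <- max(best, i - open_from)
          open_from <- NA_integer_
        }
      }
      if (!is.na(open_from)) best <- max(best, n_cod - open_from + 1L)
    }
    best
  }
  plus <- scan_strand(seq)
  minus <- scan_strand(revcomp(seq))
  list(
    plus = list(codons = plus, nt = 3L * plus),
    minus = list(codons = minus, nt = 3L * minus)
  )
}

#' Built-in coding-potential score
#'
#' Scores the protein-coding potential of a transcript sequence from its ORF
#' features, separately on each strand. Per strand the score is
#' `s = min(L, 300) / 300 + C - 1`, where `L` is the longest ATG-initiated
#' ORF in the strand's three frames (codons, excluding the stop) and
#' `C = 3 L / mature length` is that ORF's coverage of the transcript. A
#' full-length ORF of >= 300 codons scores close to +1; a sequence without
#' any ATG scores -1. The transcript is called coding when
#' `max(s_plus, s_minus) > 0` (strictly positive), the sign convention of
#' the CPC-style classifiers this score stands in for. External score tables
#' are accepted as a drop-in by [filter_coding_potential()].
#'
#' @param seq DNA string, length >= 3.
#' @return list with `score_plus`, `score_minus`, `features` (per-strand ORF
#'   codon length and coverage) and `coding` (logical).
#' @export
score_coding_potential <- function(seq) {
  seq <- validate_dna(seq)
  if (nchar(seq) < 3L) stop("sequence must have length >= 3")
  orf <- longest_orf(seq)
  len <- nchar(seq)
  strand_score <- function(o) min(o$codons, 300L) / 300 + o$nt / len - 1
  s_plus <- strand_score(orf$plus)
  s_minus <- strand_score(orf$minus)
  list(
    score_plus = s_plus, score_minus = s_minus,
    features = list(
      plus = list(orf_codons = orf$plus$codons, orf_coverage = orf$plus$nt / len),
      minus = list(orf_codons = orf$minus$codons, orf_coverage = orf$minus$nt / len)
    ),
    coding = max(s_plus, s_minus) > 0
  )
}
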