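#' Built-in nucleotide homology search (seed and extend, ungapped)
#'
#' A deliberately small BLASTN-like searcher for transcript-vs-transcript
#' comparisons: exact seed words of length `word_size` are extended without
#' gaps in both directions under +1/-2 match/mismatch scoring with an X-drop
#' cutoff, and each high-scoring segment pair is assigned the Karlin–Altschul
#' expectation `E = K * m * n * exp(-lambda * S)` over the query length `m`
#' and the concatenated subject length `n`. The fixed parameters
#' `lambda = 1.28`, `K = 0.46` correspond to +1/-2 scoring; agreement with
#' NCBI BLASTN E-values to the digit is not a goal — the contract is
#' threshold behavior at `e_max`. An external BLAST outfmt-6 table read with
#' [read_hits_table()] can be used anywhere these results can.
#'
#' @param queries,subjects named character vectors of DNA sequences.
#' @param e_max report hits with `E <= e_max`.
#' @param word_size exact seed length.
#' @param match,mismatch ungapped extension scores.
#' @param xdrop stop extension when the running score drops this far below
#'   the best seen.
#' @param lambda,karlin_k Karlin–Altschul parameters.
#' @return data.frame of homology segments: `query_id`, `subject_id`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end` (1-based
#'   inclusive), `percent_identity`, `score`, `e_value`.
#' @export
homology_search <- function(queries, subjects, e_max = 1e-5, word_size = 11L,
                            match = 1, mismatch = -2, xdrop = 20,
                            lambda = 1.28, karlin_k = 0.46) {
  empty <- data.frame(
    query_id = character(), subject_id = character(),
    query_start = integer(), query_end = integer(),
    subject_start = integer(), subject_end = integer(),
    percent_identity = numeric(), score = numeric(), e_value = numeric(),
    stringsAsFactors = FALSE
  )
  if (!length(queries) || !length(subjects)) return(empty)
  n_total <- sum(nchar(subjects))
  out <- list()
  subj_chars <- lapply(subjects, function(s) strsplit(s, "")[[1L]])
  subj_index <- lapply(subjects, function(s) seed_index(s, word_size))
  for (qid in names(queries)) {
    q <- queries[[qid]]
    m <- nchar(q)
    if (m < word_size) next
    qc <- strsplit(q, "")[[1L]]
    q_words <- substring(q, seq_len(m - word_size + 1L), word_size:m)
    for (sid in names(subjects)) {
      sc <- subj_chars[[sid]]
      idx <- subj_index[[sid]]
      seen <- list() # per diagonal: covered query ranges
      for (qpos in seq_along(q_words)) {
        spos_all <- idx[[q_words[qpos]]]
        if (is.null(spos_all)) next
        for (spos in spos_all) {
          diag_key <- as.character(spos - qpos)
          cov <- seen[[diag_key]]
          if (!is.null(cov) && any(qpos >= cov[, 1L] & qpos <= cov[, 2L])) next
          hsp <- extend_seed(qc, sc, qpos, spos, word_size, match, mismatch, xdrop)
          seen[[diag_key]] <- rbind(cov, c(hsp$q_start, hsp$q_end))
          e_val <- karlin_k * m * n_total * exp(-lambda * hsp$score)
          if (e_val <= e_max) {
            out[[length(out) + 1L]] <- data.frame(
              query_id = qid, subject_id = sid,
              query_start = hsp$q_start, query_end = hsp$q_end,
              subject_start = hsp$s_start, subject_end = hsp$s_end,
              percent_identity = 100 * hsp$n_match / (hsp$q_end - hsp$q_start + 1L),
              score = hsp$score, e_value = e_val,
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (!length(out)) return(empty)
  res <- unique(do.call(rbind, out))
  res <- res[order(res$query_id, res$subject_id, res$e_value), , drop = FALSE]
  rownames(res) <- NULL
  res
}

seed_index <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(list())
  words <- substring(s, seq_len(n - w + 1L), w:n)
  split(seq_along(words), words)
}

# ungapped X-drop extension of an exact seed at (qpos, spos), both 1-based
extend_seed <- function(qc, sc, qpos, spos, w, match, mismatch, xdrop) {
  score <- w * match
  n_match <- w
  # extend right
  best <- score; cur <- score
  q_end <- qpos + w - 1L; s_end <- spos + w - 1L
  best_q_end <- q_end; best_s_end <- s_end; best_match_r <- 0L
  mr <- 0L
  i <- q_end + 1L; j <- s_end + 1L
  while (i <= length(qc) && j <= length(sc)) {
    hit <- qc[i] == sc[j]
    cur <- cur + if (hit) match else mismatch
    if (hit) mr <- mr + 1L
    if (cur > best) {
      best <- cur; best_q_end <- i; best_s_end <- j; best_match_r <- mr
    }
    if (cur < best - xdrop) break
    i <- i + 1L; j <- j + 1L
  }
  score_right <- best
  # extend left
  cur <- score_right; best <- score_right
  q_start <- qpos; s_start <- spos
  best_q_start <- q_start; best_s_start <- s_start; best_match_l <- 0L
  ml <- 0L
  i <- qpos - 1L; j <- spos - 1L
  while (i >= 1L && j >= 1L) {
    hit <- qc[i] == sc[j]
    cur <- cur + if (hit) match else mismatch
    if (hit) ml <- ml + 1L
    if (cur > best) {
      best <- cur; best_q_start <- i; best_s_start <- j; best_match_l <- ml
    }
    if (cur < best - xdrop) break
    i <- i - 1L; j <- j - 1L
  }
  list(
    q_start = best_q_start, q_end = best_q_end,
    s_start = best_s_start, s_end = best_s_end,
    score = best, n_match = n_match + best_match_r + best_match_l
  )
}

#' Intron-exon boundary conservation of a homology segment
#'
#' Tests whether each end of a conserved segment (in mature-transcript
#' coordinates, 1-based inclusive) coincides with an intron-exon junction of
#' the transcript, within `tolerance` bases. Junctions are the internal exon
#' boundaries only; the transcript's own ends do not count.
#'
#' @param query_start,query_end segment ends on the mature transcript.
#' @param ts a [transcript_set] containing the transcript.
#' @param transcript_id the transcript the segment lies on.
#' @param tolerance maximal distance (bases) to a junction.
#' @return list with `start` and `end`, each `"at_boundary"` or
#'   `"internal"`.
#' @export
boundary_conservation <- function(query_start, query_end, ts, transcript_id,
                                  tolerance = 0L) {
  ex <- ts[ts$transcript_id == transcript_id, , drop = FALSE]
  if (!nrow(ex)) stop(sprintf("unknown transcript '%s'", transcript_id))
  L <- sum(ex$end - ex$start)
  if (query_start < 1L || query_end > L || query_start > query_end) {
    stop("segment outside transcript length")
  }
  widths <- ex$end - ex$start
  if (ex$strand[1L] == "-") widths <- rev(widths)
  junctions <- cumsum(widths)[-length(widths)] # mature positions of exon ends
  flag <- function(pos, anchors) {
    if (length(anchors) && any(abs(pos - anchors) <= tolerance)) "at_boundary" else "internal"
  }
  list(
    start = flag(query_start, junctions + 1L),
    end = flag(query_end, junctions)
  )
}

#' Chain-based liftover of an interval
#'
#' Maps every base of a source interval through its containing chain block
#' and reports the mapped-base ratio. The lift succeeds when the ratio is at
#' least `min_ratio` (inclusive, matching liftOver's "minimum ratio of bases
#' that must remap") and all images fall on a single target chromosome and
#' orientation; the mapped interval is then the span `[min image, max image
#' + 1)`. An interval on a chromosome absent from the chain yields a failure
#' result, not an error.
#'
#' @param chrom,start,end the source interval (0-based half-open).
#' @param chain a [chain_mapping].
#' @param min_ratio minimal fraction of source bases with an image.
#' @return a list of class `lift_result`: `chrom`, `start`, `end` (source),
#'   `mapped_chrom`, `mapped_start`, `mapped_end` (or `NA` on failure),
#'   `mapped_base_ratio`, `orient`, `success`.
#' @export
liftover_map <- function(chrom, start, end, chain, min_ratio = 0.5) {
  stopifnot(start < end)
  b <- chain[chain$s_chrom == chrom, , drop = FALSE]
  lo <- pmax(start, b$s_start)
  hi <- pmin(end, b$s_end)
  keep <- lo < hi
  b <- b[keep, , drop = FALSE]
  lo <- lo[keep]
  hi <- hi[keep]
  mapped_bases <- sum(hi - lo)
  ratio <- mapped_bases / (end - start)
  fail <- function() {
    structure(list(
      chrom = chrom, start = start, end = end,
      mapped_chrom = NA_character_, mapped_start = NA_integer_,
      mapped_end = NA_integer_, mapped_base_ratio = ratio,
      orient = NA_character_, success = FALSE
    ), class = "lift_result")
  }
  if (nrow(b) == 0L || ratio < min_ratio) return(fail())
  if (length(unique(b$t_chrom)) != 1L || length(unique(b$orient)) != 1L) return(fail())
  orient <- b$orient[1L]
  img <- if (orient == "+") {
    cbind(b$t_start + (lo - b$s_start), b$t_start + (hi - b$s_start))
  } else {
    cbind(b$t_end - (hi - b$s_start), b$t_end - (lo - b$s_start))
  }
  structure(list(
    chrom = chrom, start = start, end = end,
    mapped_chrom = b$t_chrom[1L],
    mapped_start = min(img[, 1L]), mapped_end = max(img[, 2L]),
    mapped_base_ratio = ratio, orient = orient, success = TRUE
  ), class = "lift_result")
}

#' Count lifted loci overlapping target loci
#'
#' Counts source loci whose successfully lifted interval overlaps any target
#' locus by at least `min_bp` bases; each source locus is counted at most
#' once. Failed lifts are skipped.
#'
#' @param lifted named list of [liftover_map()] results (names are source
#'   locus ids).
#' @param target_loci [gene_loci] (or any data.frame with `chrom`, `start`,
#'   `end`, `gene_id`) on the target genome.
#' @param min_bp minimal overlap in bases.
#' @return list with `count` and `pairs` (data.frame `source_id`,
#'   `target_id`, `overlap_bp`).
#' @export
reciprocal_overlap_count <- function(lifted, target_loci, min_bp = 1L) {
  pairs <- list()
  for (src_id in names(lifted)) {
    lr <- lifted[[src_id]]
    if (!isTRUE(lr$success)) next
    tl <- target_loci[target_loci$chrom == lr$mapped_chrom, , drop = FALSE]
    if (!nrow(tl)) next
    ov <- pmin(lr$mapped_end, tl$end) - pmax(lr$mapped_start, tl$start)
    ok <- which(ov >= min_bp)
    for (j in ok) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        source_id = src_id, target_id = tl$gene_id[j], overlap_bp = ov[j],
        stringsAsFactors = FALSE
      )
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(source_id = character(), target_id = character(),
               overlap_bp = integer(), stringsAsFactors = FALSE)
  list(count = length(unique(pairs$source_id)), pairs = pairs)
}
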