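#' Transcript models
#'
#' A set of spliced transcript models is stored as a `transcript_set`: a
#' data.frame of exons with columns `transcript_id`, `gene_id`, `chrom`,
#' `strand`, `start`, `end` (0-based half-open) and an optional `biotype`
#' column carrying a truth label for synthetic data. The constructor
#' validates, per transcript: at least one exon; all exons on one chromosome
#' and strand; exons sorted ascending by start, pairwise disjoint with a gap
#' of at least one base between consecutive exons.
#'
#' @param exons data.frame with the columns above.
#' @return a validated `transcript_set` (data.frame subclass).
#' @examples
#' ts <- transcript_set(data.frame(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1", strand = "+",
#'   start = c(0, 200), end = c(100, 300)
#' ))
#' mature_lengths(ts)
#' @export
transcript_set <- function(exons) {
  req <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(exons))
  if (length(miss)) {
    stop("missing exon columns: ", paste(miss, collapse = ", "))
  }
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(!exons$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  if (any(exons$start < 0L) || any(exons$end <= exons$start)) {
    stop("exon intervals must satisfy 0 <= start < end")
  }
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  for (id in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == id, , drop = FALSE]
    if (length(unique(ex$chrom)) != 1L || length(unique(ex$strand)) != 1L) {
      stop(sprintf("transcript '%s': exons must share one chromosome and strand", id))
    }
    if (length(unique(ex$gene_id)) != 1L) {
      stop(sprintf("transcript '%s': exons must share one gene_id", id))
    }
    if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
      stop(sprintf("transcript '%s': exons must be disjoint with gaps >= 1", id))
    }
  }
  class(exons) <- c("transcript_set", "data.frame")
  exons
}

#' @rdname transcript_set
#' @param ts a `transcript_set`.
#' @export
transcript_ids <- function(ts) unique(ts$transcript_id)

#' @rdname transcript_set
#' @export
n_transcripts <- function(ts) length(transcript_ids(ts))

#' @rdname transcript_set
#' @export
mature_lengths <- function(ts) {
  w <- ts$end - ts$start
  vapply(split(w, ts$transcript_id), sum, integer(1))[transcript_ids(ts)]
}

#' @rdname transcript_set
#' @export
exon_counts <- function(ts) {
  table_ <- table(ts$transcript_id)
  setNames(as.integer(table_), names(table_))[transcript_ids(ts)]
}

#' @rdname transcript_set
#' @param ids transcript identifiers to keep.
#' @export
subset_transcripts <- function(ts, ids) {
  out <- ts[ts$transcript_id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' Genomic spans and gene loci
#'
#' `transcript_spans()` collapses a `transcript_set` to one genomic interval
#' per transcript (min exon start to max exon end). `gene_loci()` groups
#' transcripts on `gene_id` and returns one locus per gene with its covering
#' span and member transcripts.
#'
#' @param ts a `transcript_set`.
#' @return a data.frame; for `gene_loci()` with class `gene_loci` and columns
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `n_transcripts`, plus a
#'   list-column `transcript_ids`.
#' @export
transcript_spans <- function(ts) {
  sp <- do.call(rbind, lapply(split(seq_len(nrow(ts)), ts$transcript_id), function(i) {
    ex <- ts[i, , drop = FALSE]
    data.frame(
      transcript_id = ex$transcript_id[1L], gene_id = ex$gene_id[1L],
      chrom = ex$chrom[1L], strand = ex$strand[1L],
      start = min(ex$start), end = max(ex$end),
      stringsAsFactors = FALSE
    )
  }))
  sp <- sp[match(transcript_ids(ts), sp$transcript_id), , drop = FALSE]
  rownames(sp) <- NULL
  sp
}

#' @rdname transcript_spans
#' @export
gene_loci <- function(ts) {
  sp <- transcript_spans(ts)
  loci <- do.call(rbind, lapply(split(seq_len(nrow(sp)), sp$gene_id), function(i) {
    g <- sp[i, , drop = FALSE]
    data.frame(
      gene_id = g$gene_id[1L], chrom = g$chrom[1L],
      strand = if (length(unique(g$strand)) == 1L) g$strand[1L] else ".",
      start = min(g$start), end = max(g$end),
      n_transcripts = nrow(g),
      stringsAsFactors = FALSE
    )
  }))
  loci$transcript_ids <- lapply(split(sp$transcript_id, sp$gene_id), identity)[loci$gene_id]
  rownames(loci) <- NULL
  class(loci) <- c("gene_loci", "data.frame")
  loci
}

#' Convert spans or loci to GRanges
#'
#' Converts package-convention (0-based half-open) interval data.frames with
#' `chrom`/`start`/`end` columns into 1-based closed [GenomicRanges::GRanges].
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally `strand`.
#' @param ignore_strand set strand to `*` regardless of input.
#' @return a `GRanges` whose names follow `df$transcript_id` or `df$gene_id`
#'   when present.
#' @keywords internal
as_granges0 <- function(df, ignore_strand = TRUE) {
  strand <- if (!ignore_strand && "strand" %in% names(df)) {
    ifelse(df$strand == ".", "*", df$strand)
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  nm_col <- intersect(c("transcript_id", "gene_id"), names(df))
  if (length(nm_col)) names(gr) <- df[[nm_col[1L]]]
  gr
}

#' Extract mature (spliced) transcript sequences
#'
#' Concatenates the exon subsequences of each transcript in genomic order and
#' reverse-complements the result for minus-strand transcripts. Strand "."
#' is treated as "+". The returned sequence length always equals the mature
#' length of the transcript.
#'
#' @param ts a `transcript_set`.
#' @param genome a genome `DNAStringSet` (see [genome_sequence()]).
#' @return named character vector of mature sequences, one per transcript.
#' @export
extract_sequences <- function(ts, genome) {
  ids <- transcript_ids(ts)
  out <- vapply(ids, function(id) {
    ex <- ts[ts$transcript_id == id, , drop = FALSE]
    pieces <- vapply(seq_len(nrow(ex)), function(i) {
      genome_subseq(genome, ex$chrom[i], ex$start[i], ex$end[i])
    }, character(1))
    s <- paste(pieces, collapse = "")
    if (ex$strand[1L] == "-") revcomp(s) else s
  }, character(1))
  setNames(out, ids)
}

#' Splice-site dinucleotides
#'
#' For every intron of every multi-exon transcript, reports the donor
#' dinucleotide (first two intronic bases) and acceptor dinucleotide (last
#' two), read on the transcript's strand: minus-strand introns are
#' reverse-complemented so a canonical intron always reads GT..AG.
#'
#' @param ts a `transcript_set`.
#' @param genome a genome `DNAStringSet`.
#' @return data.frame with columns `transcript_id`, `intron_index`, `donor`,
#'   `acceptor`; zero rows when no transcript has an intron.
#' @export
splice_site_dinucleotides <- function(ts, genome) {
  rows <- list()
  for (id in transcript_ids(ts)) {
    ex <- ts[ts$transcript_id == id, , drop = FALSE]
    if (nrow(ex) < 2L) next
    strand <- ex$strand[1L]
    n_introns <- nrow(ex) - 1L
    for (i in seq_len(n_introns)) {
      i_start <- ex$end[i]
      i_end <- ex$start[i + 1L]
      if (i_end - i_start < 4L) {
        stop(sprintf(
          "transcript '%s': intron %d has length %d (< 4); cannot take donor and acceptor dinucleotides",
          id, i, i_end - i_start
        ))
      }
      left <- genome_subseq(genome, ex$chrom[1L], i_start, i_start + 2L)
      right <- genome_subseq(genome, ex$chrom[1L], i_end - 2L, i_end)
      if (strand == "-") {
        donor <- revcomp(right)
        acceptor <- revcomp(left)
        idx <- n_introns - i + 1L
      } else {
        donor <- left
        acceptor <- right
        idx <- i
      }
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = id, intron_index = idx,
        donor = donor, acceptor = acceptor, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(
      transcript_id = character(), intron_index = integer(),
      donor = character(), acceptor = character(), stringsAsFactors = FALSE
    ))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$transcript_id, out$intron_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a mature-coordinate range to genomic intervals
#'
#' Given one transcript's exons, maps a half-open range `[m_start, m_end)` on
#' the mature (spliced, strand-oriented) sequence to the corresponding set of
#' genomic intervals. Used by the synthetic generator to place UTRs and
#' repeats, and exposed for coordinate bookkeeping.
#'
#' @param ex exon rows of a single transcript (a `transcript_set` subset).
#' @param m_start,m_end 0-based half-open range on the mature sequence.
#' @return data.frame with `chrom`, `start`, `end` genomic intervals.
#' @export
mature_to_genomic <- function(ex, m_start, m_end) {
  L <- sum(ex$end - ex$start)
  if (m_start < 0 || m_end > L || m_start >= m_end) {
    stop("mature range outside transcript")
  }
  strand <- ex$strand[1L]
  ex <- ex[order(ex$start), , drop = FALSE]
  widths <- ex$end - ex$start
  # walk exons in transcription order
  ord <- if (strand == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
  out <- list()
  pos <- 0L
  for (i in ord) {
    w <- widths[i]
    lo <- max(m_start, pos)
    hi <- min(m_end, pos + w)
    if (lo < hi) {
      off1 <- lo - pos
      off2 <- hi - pos
      if (strand == "-") {
        g_start <- ex$end[i] - off2
        g_end <- ex$end[i] - off1
      } else {
        g_start <- ex$start[i] + off1
        g_end <- ex$start[i] + off2
      }
      out[[length(out) + 1L]] <- data.frame(
        chrom = ex$chrom[1L], start = g_start, end = g_end,
        stringsAsFactors = FALSE
      )
    }
    pos <- pos + w
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
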