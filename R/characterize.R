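#' Structural summary of a transcript set
#'
#' Computes the descriptive statistics usually reported for an identified
#' lincRNA catalog: transcript and locus counts, isoforms per locus, mean
#' mature length, mean exon count, mean exon length (pooled over all exons),
#' the fraction of two-exon transcripts, the fraction of canonical GT-AG
#' introns, and per-chromosome transcript counts.
#'
#' @param ts a non-empty [transcript_set].
#' @param genome genome `DNAStringSet` (for splice-site reading); may be
#'   `NULL`, in which case `fraction_canonical_splice` is `NA`.
#' @return a list of class `structure_summary`.
#' @export
transcript_stats <- function(ts, genome = NULL) {
  if (n_transcripts(ts) == 0L) stop("empty transcript set")
  loci <- gene_loci(ts)
  lens <- mature_lengths(ts)
  n_ex <- exon_counts(ts)
  spans <- transcript_spans(ts)
  frac_canon <- if (!is.null(genome) && any(n_ex >= 2L)) {
    splice_site_summary(ts, genome)
  } else NA_real_
  structure(list(
    n_transcripts = n_transcripts(ts),
    n_loci = nrow(loci),
    isoforms_per_locus = n_transcripts(ts) / nrow(loci),
    mean_length = mean(lens),
    length_range = range(lens),
    mean_exons = mean(n_ex),
    mean_exon_length = mean(ts$end - ts$start),
    fraction_two_exon = mean(n_ex == 2L),
    fraction_canonical_splice = frac_canon,
    per_chromosome = table(spans$chrom)
  ), class = "structure_summary")
}

#' @rdname transcript_stats
#' @param x a `structure_summary`.
#' @param ... unused.
#' @export
print.structure_summary <- function(x, ...) {
  cat(sprintf("%d transcripts over %d loci (%.2f isoforms/locus)\n",
              x$n_transcripts, x$n_loci, x$isoforms_per_locus))
  cat(sprintf("mean mature length %.1f bp; %.2f exons/transcript; mean exon %.1f bp\n",
              x$mean_length, x$mean_exons, x$mean_exon_length))
  cat(sprintf("two-exon fraction %.1f%%; canonical GT-AG introns %.1f%%\n",
              100 * x$fraction_two_exon, 100 * x$fraction_canonical_splice))
  invisible(x)
}

#' Exon length histogram
#'
#' Bins all exon lengths of a transcript set into half-open bins
#' `[e1, e2), [e2, e3), ...` defined by `bin_edges`; the last bin is closed
#' on the right. The counts always total the number of exons falling inside
#' the edge range.
#'
#' @param ts a [transcript_set].
#' @param bin_edges ascending numeric edges.
#' @return named integer vector of counts per bin.
#' @export
exon_length_histogram <- function(ts, bin_edges = c(0, 200, 400, 600, 800, 1000, Inf)) {
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE))
  w <- ts$end - ts$start
  idx <- findInterval(w, bin_edges, rightmost.closed = TRUE)
  n_bins <- length(bin_edges) - 1L
  counts <- tabulate(idx[idx >= 1L & idx <= n_bins], nbins = n_bins)
  names(counts) <- paste0("[", head(bin_edges, -1L), ",", bin_edges[-1L], ")")
  counts
}

#' Repeat-element content of transcripts
#'
#' For every transcript, intersects its exons with the union of overlapping
#' repeat features and reports the repeat-covered fraction of the mature
#' length. Overlapping repeat features are unioned before coverage counting;
#' family percentages, in contrast, are tallied per repeat feature that
#' overlaps any exon. The per-transcript fraction histogram uses ten 10%
#' bins `[0,10), ..., [90,100]`, with repeat-free transcripts in the first
#' bin.
#'
#' @param ts a [transcript_set].
#' @param repeats a repeat-feature data.frame ([read_repeat_table()]).
#' @return a list of class `repeat_summary` with fields `fraction` (named
#'   per-transcript), `n_with_repeat`, `fraction_with_repeat`,
#'   `fraction_ge_half_repeat`, `mean_repeat_fragment_bp`,
#'   `mean_length_repeat_bearing`, `mean_repeat_content_fraction` (mean
#'   fraction among repeat-bearing transcripts), `family_percentages`, and
#'   `fraction_histogram`.
#' @export
repeat_content <- function(ts, repeats) {
  ids <- transcript_ids(ts)
  lens <- mature_lengths(ts)
  rep_by_chrom <- if (nrow(repeats)) {
    split(seq_len(nrow(repeats)), repeats$chrom)
  } else list()
  covered <- setNames(integer(length(ids)), ids)
  feature_hit <- logical(nrow(repeats))
  for (id in ids) {
    ex <- ts[ts$transcript_id == id, , drop = FALSE]
    ri <- rep_by_chrom[[ex$chrom[1L]]]
    if (is.null(ri)) next
    rr <- IRanges::IRanges(repeats$start[ri] + 1L, repeats$end[ri])
    ex_r <- IRanges::IRanges(ex$start + 1L, ex$end)
    ov <- IRanges::findOverlaps(rr, ex_r)
    hit <- unique(S4Vectors::queryHits(ov))
    feature_hit[ri[hit]] <- TRUE
    if (length(hit)) {
      covered[id] <- sum(IRanges::width(IRanges::intersect(ex_r, IRanges::reduce(rr))))
    }
  }
  frac <- covered / lens
  bearing <- frac > 0
  fams <- repeats$family[feature_hit]
  fam_pct <- if (length(fams)) {
    tab <- 100 * table(fams) / length(fams)
    setNames(as.numeric(tab), names(tab))
  } else setNames(numeric(0), character(0))
  bins <- pmin(floor(frac * 10), 9) + 1L
  hist <- tabulate(bins, nbins = 10L)
  names(hist) <- paste0("[", seq(0, 90, 10), ",", seq(10, 100, 10), ")")
  structure(list(
    fraction = frac,
    n_with_repeat = sum(bearing),
    fraction_with_repeat = mean(bearing),
    fraction_ge_half_repeat = mean(frac >= 0.5),
    mean_repeat_fragment_bp = if (any(bearing)) mean(covered[bearing]) else NA_real_,
    mean_length_repeat_bearing = if (any(bearing)) mean(lens[bearing]) else NA_real_,
    mean_repeat_content_fraction = if (any(bearing)) mean(frac[bearing]) else NA_real_,
    family_percentages = fam_pct,
    fraction_histogram = hist
  ), class = "repeat_summary")
}

#' Nearest protein-coding neighbors of lincRNA loci
#'
#' For each lincRNA locus, finds the nearest non-overlapping protein-coding
#' locus on each side whose gap distance (between half-open spans) is
#' strictly positive and strictly below `window`. "Upstream" and
#' "downstream" are genomic left and right, independent of strand. Also
#' returns the deduplicated pooled neighbor gene list (the usual input to a
#' GO enrichment service) and the count of lincRNA loci having at least one
#' neighbor.
#'
#' @param linc_loci [gene_loci] of lincRNA genes.
#' @param protein_loci [gene_loci] of protein-coding genes.
#' @param window maximal distance in bases (exclusive).
#' @return a list of class `neighbor_assignment` with `assignments` (one row
#'   per lincRNA locus: upstream/downstream ids and distances),
#'   `neighbor_genes`, `n_with_neighbor`, `fraction_with_neighbor`.
#' @export
neighbor_analysis <- function(linc_loci, protein_loci, window = 10000L) {
  rows <- lapply(seq_len(nrow(linc_loci)), function(i) {
    l <- linc_loci[i, ]
    p <- protein_loci[protein_loci$chrom == l$chrom, , drop = FALSE]
    # exclude overlapping protein loci entirely
    p <- p[p$end <= l$start | p$start >= l$end, , drop = FALSE]
    up <- p[p$end <= l$start, , drop = FALSE]
    down <- p[p$start >= l$end, , drop = FALSE]
    up_d <- l$start - up$end
    down_d <- down$start - l$end
    pick <- function(cand, d) {
      ok <- d > 0 & d < window
      if (!any(ok)) return(list(id = NA_character_, dist = NA_integer_))
      j <- which(ok)[which.min(d[ok])]
      list(id = cand$gene_id[j], dist = d[j])
    }
    u <- pick(up, up_d)
    d <- pick(down, down_d)
    data.frame(
      linc_gene_id = l$gene_id,
      upstream_id = u$id, upstream_distance = u$dist,
      downstream_id = d$id, downstream_distance = d$dist,
      stringsAsFactors = FALSE
    )
  })
  assignments <- do.call(rbind, rows)
  neighbors <- unique(stats::na.omit(c(assignments$upstream_id, assignments$downstream_id)))
  with_n <- !is.na(assignments$upstream_id) | !is.na(assignments$downstream_id)
  structure(list(
    assignments = assignments,
    neighbor_genes = neighbors,
    n_with_neighbor = sum(with_n),
    fraction_with_neighbor = mean(with_n)
  ), class = "neighbor_assignment")
}

#' Fraction of canonical GT-AG introns
#'
#' @param ts a [transcript_set] containing at least one intron.
#' @param genome genome `DNAStringSet`.
#' @return fraction of introns whose (donor, acceptor) is (GT, AG).
#' @export
splice_site_summary <- function(ts, genome) {
  sites <- splice_site_dinucleotides(ts, genome)
  if (nrow(sites) == 0L) stop("no introns in transcript set")
  mean(sites$donor == "GT" & sites$acceptor == "AG")
}
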