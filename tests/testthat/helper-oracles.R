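# Independent brute-force oracles. These deliberately avoid the package's
# interval arithmetic: everything is computed by per-base membership.

# bases shared by two 0-based half-open intervals (same chromosome assumed)
brute_overlap_bp <- function(a_start, a_end, b_start, b_end) {
  length(intersect(seq.int(a_start, a_end - 1L), seq.int(b_start, b_end - 1L)))
}

# fraction of exonic bases covered by a set of intervals (one chromosome)
brute_coverage_fraction <- function(exon_df, iv_df) {
  exonic <- unlist(lapply(seq_len(nrow(exon_df)), function(i) {
    seq.int(exon_df$start[i], exon_df$end[i] - 1L)
  }))
  covered <- unique(unlist(lapply(seq_len(nrow(iv_df)), function(i) {
    seq.int(iv_df$start[i], iv_df$end[i] - 1L)
  })))
  if (is.null(covered)) covered <- integer(0)
  sum(exonic %in% covered) / length(exonic)
}

# per-base lift of a 0-based half-open interval through chain blocks
brute_lift <- function(chrom, start, end, chain) {
  images <- c()
  for (p in seq.int(start, end - 1L)) {
    b <- chain[chain$s_chrom == chrom & chain$s_start <= p & p < chain$s_end, ]
    if (nrow(b) == 1L) {
      img <- if (b$orient == "+") b$t_start + (p - b$s_start) else b$t_end - 1L - (p - b$s_start)
      images <- c(images, img)
    }
  }
  list(ratio = length(images) / (end - start), images = images)
}

# brute-force longest ATG-initiated ORF over both strands, counting codons
# (excluding the stop); truncated ORFs running off the end count too
brute_longest_orf_codons <- function(seq) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  best <- 0L
  for (s in c(seq, rc)) {
    n <- nchar(s)
    for (i in seq_len(max(0L, n - 2L))) {
      if (substr(s, i, i + 2L) != "ATG") next
      codons <- 0L
      j <- i
      while (j + 2L <= n) {
        cod <- substr(s, j, j + 2L)
        if (codons > 0L && cod %in% c("TAA", "TAG", "TGA")) break
        codons <- codons + 1L
        j <- j + 3L
      }
      best <- max(best, codons)
    }
  }
  best
}

# textbook pooled-variance two-sample t-test
brute_t_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p <- 2 * pt(-abs(t_stat), df = n1 + n2 - 2)
  list(statistic = t_stat, p_value = p)
}

# minimal transcript-set builder: one transcript from exon start/end vectors
make_tx <- function(id, starts, ends, chrom = "chr1", strand = "+", gene = NULL) {
  transcript_set(data.frame(
    transcript_id = id, gene_id = if (is.null(gene)) paste0("g_", id) else gene,
    chrom = chrom, strand = strand, start = starts, end = ends,
    stringsAsFactors = FALSE
  ))
}

rbind_ts <- function(...) {
  transcript_set(do.call(rbind, lapply(list(...), as.data.frame)))
}
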