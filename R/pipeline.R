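#' Filter reports
#'
#' Every filter stage returns its survivors together with a report entry
#' recording the stage name, its parameters, the input / removed / surviving
#' counts and the removed transcript ids. `filter_report()` assembles entries
#' into an auditable report satisfying, at every stage,
#' `n_input = n_removed + n_surviving`, with stage `k+1`'s input equal to
#' stage `k`'s survivors.
#'
#' @param entries list of stage entries as produced by the `filter_*`
#'   functions.
#' @return a `filter_report` object.
#' @export
filter_report <- function(entries) {
  for (e in entries) {
    stopifnot(e$n_input == e$n_removed + e$n_surviving,
              length(e$removed_ids) == e$n_removed)
  }
  n_in <- vapply(entries, function(e) e$n_input, numeric(1))
  n_surv <- vapply(entries, function(e) e$n_surviving, numeric(1))
  if (length(entries) > 1L && any(n_in[-1L] != n_surv[-length(n_surv)])) {
    stop("stage chaining broken: input of stage k+1 must equal survivors of stage k")
  }
  structure(list(entries = entries), class = "filter_report")
}

report_entry <- function(stage, params, ids_in, ids_out) {
  removed <- setdiff(ids_in, ids_out)
  list(
    stage = stage, params = params,
    n_input = length(ids_in), n_removed = length(removed),
    n_surviving = length(ids_out), removed_ids = removed
  )
}

#' @rdname filter_report
#' @param x a `filter_report`.
#' @param ... unused.
#' @export
as.data.frame.filter_report <- function(x, ...) {
  do.call(rbind, lapply(x$entries, function(e) {
    data.frame(
      stage = e$stage,
      parameters = paste(names(e$params), unlist(lapply(e$params, format)),
                         sep = "=", collapse = "; "),
      n_input = e$n_input, n_removed = e$n_removed, n_surviving = e$n_surviving,
      stringsAsFactors = FALSE
    )
  }))
}

#' @rdname filter_report
#' @export
print.filter_report <- function(x, ...) {
  cat("lincRNA filter cascade report\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @rdname filter_report
#' @param report a `filter_report`.
#' @param path_tsv,path_json output paths (either may be `NULL`).
#' @export
write_filter_report <- function(report, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    write.table(as.data.frame(report), path_tsv, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(report$entries, path_json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(report)
}

#' Stage 1: size and exon-count selection
#'
#' Removes single-exon transcripts and transcripts whose mature (spliced)
#' length is below `min_length`. A transcript survives iff it has at least
#' two exons **and** mature length `>= min_length` (the removal rule "less
#' than 200 bp" is strict, so a 200-bp transcript is kept).
#'
#' @param ts a [transcript_set].
#' @param min_length minimum mature length in bases.
#' @return list with `survivors` (a `transcript_set`) and `report` entry.
#' @export
filter_size_exons <- function(ts, min_length = 200L) {
  ids <- transcript_ids(ts)
  keep <- ids[exon_counts(ts) >= 2L & mature_lengths(ts) >= min_length]
  list(
    survivors = subset_transcripts(ts, keep),
    report = report_entry("size_exons", list(min_length = min_length, min_exons = 2L), ids, keep)
  )
}

#' Stage 2: protein-coding gene overlap
#'
#' Removes any transcript whose genomic span overlaps a protein-coding gene
#' locus span by at least `min_overlap` bases (default 1, i.e. any overlap
#' removes). The comparison is strand-agnostic and uses locus spans, not
#' exons; set `exon_level = TRUE` to require overlap with annotated exons of
#' the protein genes instead.
#'
#' @param ts a [transcript_set].
#' @param protein_loci a [gene_loci] data.frame of protein-coding genes (or,
#'   with `exon_level = TRUE`, a `transcript_set` of their exons).
#' @param min_overlap minimal overlap in bases that triggers removal.
#' @param exon_level compare against exons instead of locus spans.
#' @return list with `survivors` and `report`.
#' @export
filter_coding_overlap <- function(ts, protein_loci, min_overlap = 1L, exon_level = FALSE) {
  ids <- transcript_ids(ts)
  spans <- transcript_spans(ts)
  # with exon_level = TRUE the caller passes the protein genes' exon rows
  # (a transcript_set); both representations carry chrom/start/end
  ref <- protein_loci
  if (nrow(ref) == 0L || length(ids) == 0L) {
    keep <- ids
  } else {
    hits <- GenomicRanges::findOverlaps(
      as_granges0(spans), as_granges0(as.data.frame(ref)),
      minoverlap = min_overlap, ignore.strand = TRUE
    )
    keep <- ids[!seq_along(ids) %in% S4Vectors::queryHits(hits)]
  }
  list(
    survivors = subset_transcripts(ts, keep),
    report = report_entry("coding_gene_overlap",
                          list(min_overlap = min_overlap, exon_level = exon_level),
                          ids, keep)
  )
}

#' Stage 3: coding-potential filter
#'
#' Scores every transcript on both strands and removes those with a strictly
#' positive score on either strand (a score of exactly 0 survives). Scores
#' come from the built-in ORF-feature scorer ([score_coding_potential()]) or,
#' when `score_table` is supplied, from an external per-transcript table of
#' `score_plus` / `score_minus` (e.g. CPC output), which must cover every
#' transcript id.
#'
#' @param ts a [transcript_set].
#' @param genome genome `DNAStringSet` (needed for the built-in scorer).
#' @param score_table optional data.frame with columns `transcript_id`,
#'   `score_plus`, `score_minus`.
#' @return list with `survivors`, `report`, and `scores` (per-transcript).
#' @export
filter_coding_potential <- function(ts, genome = NULL, score_table = NULL) {
  ids <- transcript_ids(ts)
  if (is.null(score_table)) {
    if (is.null(genome)) stop("either a genome or a score table is required")
    seqs <- extract_sequences(ts, genome)
    scores <- do.call(rbind, lapply(ids, function(id) {
      s <- score_coding_potential(seqs[[id]])
      data.frame(transcript_id = id, score_plus = s$score_plus,
                 score_minus = s$score_minus, stringsAsFactors = FALSE)
    }))
  } else {
    missing_ids <- setdiff(ids, score_table$transcript_id)
    if (length(missing_ids)) {
      stop("score table missing transcript(s): ", paste(missing_ids, collapse = ", "))
    }
    scores <- score_table[match(ids, score_table$transcript_id), , drop = FALSE]
  }
  if (is.null(scores)) {
    scores <- data.frame(transcript_id = character(), score_plus = numeric(),
                         score_minus = numeric(), stringsAsFactors = FALSE)
  }
  max_score <- pmax(scores$score_plus, scores$score_minus)
  keep <- ids[!(max_score > 0)]
  list(
    survivors = subset_transcripts(ts, keep),
    report = report_entry("coding_potential",
                          list(rule = "max strand score > 0 removes",
                               scorer = if (is.null(score_table)) "built-in" else "external"),
                          ids, keep),
    scores = scores
  )
}

#' Stages 4 and 5: protein similarity and protein domain filters
#'
#' `filter_protein_similarity()` removes transcripts with at least one
#' protein-database hit at `e_value <= e_max` (the threshold is inclusive:
#' `E = 1e-5` exactly removes). `filter_domain_hits()` applies the same rule
#' to protein-domain hits from six-frame translations; a significant hit in
#' any frame removes the transcript.
#'
#' @param ts a [transcript_set].
#' @param hits a hit table ([read_hits_table()]) with `query_id` matching
#'   transcript ids.
#' @param e_max inclusive E-value removal threshold.
#' @return list with `survivors` and `report`.
#' @export
filter_protein_similarity <- function(ts, hits, e_max = 1e-5) {
  ids <- transcript_ids(ts)
  bad <- unique(hits$query_id[hits$e_value <= e_max])
  keep <- setdiff(ids, bad)
  list(
    survivors = subset_transcripts(ts, keep),
    report = report_entry("protein_similarity", list(e_max = e_max), ids, keep)
  )
}

#' @rdname filter_protein_similarity
#' @export
filter_domain_hits <- function(ts, hits, e_max = 1e-5) {
  ids <- transcript_ids(ts)
  bad <- unique(hits$query_id[hits$e_value <= e_max])
  keep <- setdiff(ids, bad)
  list(
    survivors = subset_transcripts(ts, keep),
    report = report_entry("protein_domain", list(e_max = e_max), ids, keep)
  )
}

#' Stage 6: small-RNA family filter
#'
#' Removes transcripts with an RNA-family hit whose `family_class` belongs
#' to the configured set of small-RNA classes.
#'
#' @param ts a [transcript_set].
#' @param hits an `rna_family` hit table.
#' @param small_rna_classes family classes that trigger removal.
#' @return list with `survivors` and `report`.
#' @export
filter_rna_families <- function(ts, hits,
                                small_rna_classes = c("snRNA", "snoRNA", "tRNA", "miRNA", "rRNA")) {
  ids <- transcript_ids(ts)
  bad <- unique(hits$query_id[hits$family_class %in% small_rna_classes])
  keep <- setdiff(ids, bad)
  list(
    survivors = subset_transcripts(ts, keep),
    report = report_entry("rna_families",
                          list(classes = paste(small_rna_classes, collapse = ",")),
                          ids, keep)
  )
}

#' Stage 7: UTR-fragment filter
#'
#' Computes, per transcript, the fraction of its mature length covered by
#' the union of annotated UTR intervals (on genomic coordinates) and
#' discards transcripts with coverage strictly greater than `max_frac`
#' ("more than 90%" discards, so exactly 0.9 survives). UTR intervals should
#' come from curated reference mRNAs (`NM_`-prefixed RefSeqs).
#'
#' @param ts a [transcript_set].
#' @param utr_intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) UTR intervals.
#' @param max_frac maximal tolerated UTR coverage fraction.
#' @return list with `survivors`, `report`, and `utr_fraction` per
#'   transcript.
#' @export
filter_utr_overlap <- function(ts, utr_intervals, max_frac = 0.9) {
  ids <- transcript_ids(ts)
  frac <- utr_coverage_fraction(ts, utr_intervals)
  keep <- ids[!(frac > max_frac)]
  list(
    survivors = subset_transcripts(ts, keep),
    report = report_entry("utr_fragment", list(max_frac = max_frac), ids, keep),
    utr_fraction = frac
  )
}

#' @rdname filter_utr_overlap
#' @export
utr_coverage_fraction <- function(ts, utr_intervals) {
  ids <- transcript_ids(ts)
  if (length(ids) == 0L) return(setNames(numeric(0), character(0)))
  utr_by_chrom <- if (nrow(utr_intervals)) {
    lapply(split(utr_intervals, utr_intervals$chrom), function(u) {
      IRanges::reduce(IRanges::IRanges(u$start + 1L, u$end))
    })
  } else list()
  lens <- mature_lengths(ts)
  covered <- vapply(ids, function(id) {
    ex <- ts[ts$transcript_id == id, , drop = FALSE]
    u <- utr_by_chrom[[ex$chrom[1L]]]
    if (is.null(u)) return(0L)
    ex_r <- IRanges::IRanges(ex$start + 1L, ex$end)
    sum(IRanges::width(IRanges::intersect(ex_r, u)))
  }, integer(1))
  setNames(covered / lens, ids)
}

#' Run the full lincRNA identification cascade
#'
#' Applies the seven filter stages in order: (1) size/exon count, (2)
#' protein-coding gene overlap, (3) coding potential, (4) protein
#' similarity, (5) protein domains, (6) small-RNA families, (7) UTR
#' fragments. Surviving transcripts are grouped into lincRNA gene loci on
#' their `gene_id`.
#'
#' @param ts a [transcript_set] of assembled transcripts.
#' @param genome genome `DNAStringSet`.
#' @param protein_loci [gene_loci] of annotated protein-coding genes.
#' @param utr_intervals UTR interval data.frame (see [filter_utr_overlap()]).
#' @param protein_hits,domain_hits,rna_family_hits hit tables for stages
#'   4–6; `NULL` means an empty table.
#' @param cpc_scores optional external coding-potential score table for
#'   stage 3.
#' @param config list of threshold overrides: `min_length`, `min_overlap`,
#'   `exon_level`, `e_max_protein`, `e_max_domain`, `small_rna_classes`,
#'   `max_utr_frac`.
#' @return list with `lincrnas` (surviving `transcript_set`), `loci`
#'   (their [gene_loci]), and `report` (a [filter_report]).
#' @export
run_pipeline <- function(ts, genome, protein_loci, utr_intervals,
                         protein_hits = NULL, domain_hits = NULL,
                         rna_family_hits = NULL, cpc_scores = NULL,
                         config = list()) {
  cfg <- utils::modifyList(list(
    min_length = 200L, min_overlap = 1L, exon_level = FALSE,
    e_max_protein = 1e-5, e_max_domain = 1e-5,
    small_rna_classes = c("snRNA", "snoRNA", "tRNA", "miRNA", "rRNA"),
    max_utr_frac = 0.9
  ), config)
  empty_hits <- hit_record()[0L, ]
  if (is.null(protein_hits)) protein_hits <- empty_hits
  if (is.null(domain_hits)) domain_hits <- empty_hits
  if (is.null(rna_family_hits)) rna_family_hits <- empty_hits

  s1 <- filter_size_exons(ts, cfg$min_length)
  s2 <- filter_coding_overlap(s1$survivors, protein_loci, cfg$min_overlap, cfg$exon_level)
  s3 <- filter_coding_potential(s2$survivors, genome, cpc_scores)
  s4 <- filter_protein_similarity(s3$survivors, protein_hits, cfg$e_max_protein)
  s5 <- filter_domain_hits(s4$survivors, domain_hits, cfg$e_max_domain)
  s6 <- filter_rna_families(s5$survivors, rna_family_hits, cfg$small_rna_classes)
  s7 <- filter_utr_overlap(s6$survivors, utr_intervals, cfg$max_utr_frac)

  report <- filter_report(list(s1$report, s2$report, s3$report, s4$report,
                               s5$report, s6$report, s7$report))
  lincrnas <- s7$survivors
  list(
    lincrnas = lincrnas,
    loci = if (n_transcripts(lincrnas)) gene_loci(lincrnas) else NULL,
    report = report
  )
}

#' Classify assembled transcripts as protein-coding
#'
#' A multi-exon transcript is called protein-coding when it has a nucleotide
#' alignment to a reference mRNA with percent identity `>= min_identity` and
#' alignment length covering `>= min_coverage` of that reference mRNA's
#' length (both thresholds inclusive).
#'
#' @param ts a [transcript_set] (single-exon transcripts are ignored).
#' @param reference_lengths named numeric vector: reference mRNA id ->
#'   mRNA length in bases.
#' @param alignments a nucleotide hit table of transcripts vs reference
#'   mRNAs.
#' @param min_identity minimal percent identity (0–100).
#' @param min_coverage minimal fraction of the reference mRNA covered.
#' @return character vector of protein-coding transcript ids.
#' @export
classify_protein_coding <- function(ts, reference_lengths, alignments,
                                    min_identity = 96, min_coverage = 0.9) {
  ids <- transcript_ids(ts)[exon_counts(ts) >= 2L]
  if (nrow(alignments) == 0L) return(character(0))
  unknown <- setdiff(unique(alignments$subject_id), names(reference_lengths))
  if (length(unknown)) {
    stop("reference length map missing mRNA(s): ", paste(unknown, collapse = ", "))
  }
  cov <- alignments$alignment_length / reference_lengths[alignments$subject_id]
  ok <- alignments$percent_identity >= min_identity & cov >= min_coverage
  intersect(ids, unique(alignments$query_id[ok]))
}
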