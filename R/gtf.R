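#' Read and write transcript models as GTF
#'
#' `read_gtf()` parses the exon features of an Ensembl-dialect GTF file into
#' a [transcript_set]; `write_gtf()` is its inverse. GTF coordinates
#' (1-based, inclusive) are converted to the package's 0-based half-open
#' convention at this boundary, so a GTF exon `start=101 end=200` becomes the
#' interval `[100, 200)` of length 100.
#'
#' Attribute fields must contain `transcript_id` and `gene_id` in the
#' standard `key "value";` syntax; a `biotype` attribute, when present, is
#' kept as a truth label. Malformed attribute fields raise a parse error
#' naming the offending line. When a genome is supplied, exons outside
#' chromosome bounds (or on unknown chromosomes) raise a coordinate error.
#'
#' @param path GTF file path.
#' @param genome optional genome `DNAStringSet` used to validate coordinates.
#' @return `read_gtf()`: a `transcript_set`.
#' @export
read_gtf <- function(path, genome = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  rows <- list()
  for (ln in which(keep)) {
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L) {
      stop(sprintf("GTF parse error at line %d: expected 9 tab-separated fields, got %d", ln, length(fields)))
    }
    if (fields[3L] != "exon") next
    attrs <- gtf_attributes(fields[9L], ln)
    for (key in c("transcript_id", "gene_id")) {
      if (is.na(attrs[key])) {
        stop(sprintf("GTF parse error at line %d: missing attribute '%s'", ln, key))
      }
    }
    start1 <- suppressWarnings(as.integer(fields[4L]))
    end1 <- suppressWarnings(as.integer(fields[5L]))
    if (is.na(start1) || is.na(end1) || start1 < 1L || end1 < start1) {
      stop(sprintf("GTF parse error at line %d: bad coordinates '%s'..'%s'", ln, fields[4L], fields[5L]))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = unname(attrs["transcript_id"]),
      gene_id = unname(attrs["gene_id"]),
      chrom = fields[1L], strand = fields[7L],
      start = start1 - 1L, end = end1,
      biotype = unname(attrs["biotype"]),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop(sprintf("no exon features found in '%s'", path))
  exons <- do.call(rbind, rows)
  if (all(is.na(exons$biotype))) exons$biotype <- NULL
  if (!is.null(genome)) {
    for (i in seq_len(nrow(exons))) {
      if (!exons$chrom[i] %in% names(genome)) {
        stop(sprintf("coordinate error: transcript '%s' on unknown chromosome '%s'",
                     exons$transcript_id[i], exons$chrom[i]))
      }
      len <- length(genome[[exons$chrom[i]]])
      if (exons$end[i] > len) {
        stop(sprintf("coordinate error: exon of '%s' ends at %d beyond chromosome '%s' length %d",
                     exons$transcript_id[i], exons$end[i], exons$chrom[i], len))
      }
    }
  }
  transcript_set(exons)
}

# parse one GTF attribute field; returns named character vector
gtf_attributes <- function(field, line_no) {
  out <- c(transcript_id = NA_character_, gene_id = NA_character_, biotype = NA_character_)
  parts <- strsplit(field, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  parts <- parts[nzchar(parts)]
  for (p in parts) {
    m <- regmatches(p, regexec('^(\\S+) "([^"]*)"$', p))[[1L]]
    if (length(m) != 3L) {
      stop(sprintf("GTF parse error at line %d: malformed attribute '%s'", line_no, p))
    }
    if (m[2L] %in% names(out)) out[m[2L]] <- m[3L]
  }
  out
}

#' @rdname read_gtf
#' @param ts a `transcript_set`.
#' @param source source field to write (column 2).
#' @return `write_gtf()`: the path, invisibly.
#' @export
write_gtf <- function(ts, path, source = "lincseek") {
  has_biotype <- "biotype" %in% names(ts)
  lines <- character(0)
  for (id in transcript_ids(ts)) {
    ex <- ts[ts$transcript_id == id, , drop = FALSE]
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', ex$gene_id[1L], id)
    if (has_biotype && !is.na(ex$biotype[1L])) {
      attrs <- paste0(attrs, sprintf(' biotype "%s";', ex$biotype[1L]))
    }
    lines <- c(lines, sprintf(
      "%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
      ex$chrom, source, ex$start + 1L, ex$end, ex$strand, attrs
    ))
  }
  writeLines(lines, path)
  invisible(path)
}
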