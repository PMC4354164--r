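#' Similarity, domain and RNA-family hit tables
#'
#' `read_hits_table()` parses tab-separated hit tables into a uniform
#' data.frame of hit records used by the filter cascade. Three dialects are
#' supported, selected by `source_kind`:
#'
#' * `"nucleotide"` / `"protein"` — 12-column BLAST tabular (outfmt 6):
#'   `query, subject, pident, length, mismatch, gapopen, qstart, qend,
#'   sstart, send, evalue, bitscore`.
#' * `"domain"` — 6 columns: `query, domain, evalue, bitscore, qstart, qend`
#'   (an HMMER domain-table reduced to the fields the filter consumes).
#' * `"rna_family"` — 5 columns: `query, family, family_class, evalue,
#'   bitscore` (an Rfam hit list; `family_class` is e.g. `tRNA`, `snoRNA`).
#'
#' All dialects yield the same columns: `query_id`, `subject_id`,
#' `percent_identity`, `alignment_length`, `query_start`, `query_end`,
#' `subject_start`, `subject_end`, `bit_score`, `e_value`, `source_kind`,
#' `family_class` (columns not present in a dialect are `NA`). Query/subject
#' coordinates are 1-based inclusive, as printed by the upstream tools.
#'
#' @param path file path; an empty file yields a zero-row table.
#' @param source_kind one of `"nucleotide"`, `"protein"`, `"domain"`,
#'   `"rna_family"`.
#' @return data.frame of hit records (class `hit_table`).
#' @export
read_hits_table <- function(path, source_kind = c("nucleotide", "protein", "domain", "rna_family")) {
  source_kind <- match.arg(source_kind)
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  lines <- readLines(path)
  lines_keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  n_cols <- switch(source_kind, nucleotide = 12L, protein = 12L, domain = 6L, rna_family = 5L)
  rows <- vector("list", length(lines_keep))
  for (k in seq_along(lines_keep)) {
    ln <- lines_keep[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) != n_cols) {
      stop(sprintf("hit-table parse error at line %d: expected %d columns, got %d", ln, n_cols, length(f)))
    }
    if (source_kind %in% c("nucleotide", "protein")) {
      ev <- parse_evalue(f[11L], ln)
      rows[[k]] <- hit_record(
        query_id = f[1L], subject_id = f[2L],
        percent_identity = as.numeric(f[3L]), alignment_length = as.integer(f[4L]),
        query_start = as.integer(f[7L]), query_end = as.integer(f[8L]),
        subject_start = as.integer(f[9L]), subject_end = as.integer(f[10L]),
        bit_score = as.numeric(f[12L]), e_value = ev, source_kind = source_kind
      )
    } else if (source_kind == "domain") {
      ev <- parse_evalue(f[3L], ln)
      rows[[k]] <- hit_record(
        query_id = f[1L], subject_id = f[2L], e_value = ev,
        bit_score = as.numeric(f[4L]),
        query_start = as.integer(f[5L]), query_end = as.integer(f[6L]),
        source_kind = source_kind
      )
    } else {
      ev <- parse_evalue(f[4L], ln)
      rows[[k]] <- hit_record(
        query_id = f[1L], subject_id = f[2L], family_class = f[3L],
        e_value = ev, bit_score = as.numeric(f[5L]), source_kind = source_kind
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else hit_record()[0L, ]
  class(out) <- c("hit_table", "data.frame")
  out
}

parse_evalue <- function(x, line_no) {
  ev <- suppressWarnings(as.numeric(x))
  if (is.na(ev) || ev < 0) {
    stop(sprintf("hit-table parse error at line %d: bad E-value '%s'", line_no, x))
  }
  ev
}

#' @rdname read_hits_table
#' @param query_id,subject_id,percent_identity,alignment_length
#'   hit fields; see above.
#' @param query_start,query_end,subject_start,subject_end 1-based inclusive
#'   alignment coordinates.
#' @param bit_score,e_value alignment scores; `e_value` must be `>= 0`.
#' @param family_class RNA family class for `rna_family` hits.
#' @export
hit_record <- function(query_id = character(0), subject_id = NA_character_,
                       percent_identity = NA_real_, alignment_length = NA_integer_,
                       query_start = NA_integer_, query_end = NA_integer_,
                       subject_start = NA_integer_, subject_end = NA_integer_,
                       bit_score = NA_real_, e_value = NA_real_,
                       source_kind = NA_character_, family_class = NA_character_) {
  if (length(query_id) == 0L) {
    return(data.frame(
      query_id = character(), subject_id = character(),
      percent_identity = numeric(), alignment_length = integer(),
      query_start = integer(), query_end = integer(),
      subject_start = integer(), subject_end = integer(),
      bit_score = numeric(), e_value = numeric(),
      source_kind = character(), family_class = character(),
      stringsAsFactors = FALSE
    ))
  }
  df <- data.frame(
    query_id = query_id, subject_id = subject_id,
    percent_identity = percent_identity, alignment_length = alignment_length,
    query_start = query_start, query_end = query_end,
    subject_start = subject_start, subject_end = subject_end,
    bit_score = bit_score, e_value = e_value,
    source_kind = source_kind, family_class = family_class,
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(!is.na(df$e_value) & df$e_value < 0)) stop("e_value must be >= 0")
    bad <- !is.na(df$query_start) & !is.na(df$query_end) & df$query_start > df$query_end
    if (any(bad)) stop("query_start must be <= query_end")
    pid <- df$percent_identity
    if (any(!is.na(pid) & (pid < 0 | pid > 100))) stop("percent_identity must be in [0, 100]")
  }
  df
}

#' @rdname read_hits_table
#' @param hits a hit table.
#' @export
write_hits_table <- function(hits, path) {
  kind <- if (nrow(hits)) hits$source_kind[1L] else "nucleotide"
  lines <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    lines[i] <- if (kind %in% c("nucleotide", "protein")) {
      sprintf("%s\t%s\t%.2f\t%d\t0\t0\t%d\t%d\t%d\t%d\t%s\t%.1f",
              h$query_id, h$subject_id, h$percent_identity, h$alignment_length,
              h$query_start, h$query_end, h$subject_start, h$subject_end,
              format(h$e_value, scientific = TRUE), h$bit_score)
    } else if (kind == "domain") {
      sprintf("%s\t%s\t%s\t%.1f\t%d\t%d", h$query_id, h$subject_id,
              format(h$e_value, scientific = TRUE), h$bit_score,
              h$query_start, h$query_end)
    } else {
      sprintf("%s\t%s\t%s\t%s\t%.1f", h$query_id, h$subject_id, h$family_class,
              format(h$e_value, scientific = TRUE), h$bit_score)
    }
  }
  writeLines(lines, path)
  invisible(path)
}
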