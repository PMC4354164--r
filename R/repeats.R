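#' Repeat-element annotation tables
#'
#' `read_repeat_table()` reads repeat/transposable-element annotations into a
#' data.frame of repeat features with columns `chrom`, `start`, `end`
#' (0-based half-open), `family`, `name`. Two dialects are accepted:
#'
#' * RepeatMasker `.out` style: whitespace-separated with the usual 2–3
#'   header lines; chromosome, begin and end are taken from columns 5–7 and
#'   the repeat class/family string from column 11.
#' * A simplified 5-column TSV: `chrom, start (1-based), end, family, name`.
#'
#' Family strings are collapsed on the text before `"/"` into the closed set
#' `SINE, LINE, LTR, DNA, Simple_repeat, Low_complexity`; anything else maps
#' to `Other` (so `"SINE/tRNA"` becomes `SINE` and `"Satellite"` becomes
#' `Other`).
#'
#' @param path file path.
#' @return data.frame of repeat features.
#' @export
read_repeat_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rm_style <- length(lines) > 0L && grepl("^\\s*SW\\s", lines[1L])
  if (rm_style) {
    body <- lines[!grepl("^\\s*(SW|score|$)", lines)]
    rows <- lapply(body, function(l) {
      f <- strsplit(trimws(l), "\\s+")[[1L]]
      if (length(f) < 11L) stop(sprintf("repeat-table parse error: too few columns in '%s'", l))
      data.frame(chrom = f[5L], start1 = as.integer(f[6L]), end = as.integer(f[7L]),
                 family_raw = f[11L], name = f[10L], stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
  } else {
    if (!length(lines)) {
      return(data.frame(chrom = character(), start = integer(), end = integer(),
                        family = character(), name = character(), stringsAsFactors = FALSE))
    }
    rows <- lapply(seq_along(lines), function(i) {
      f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
      if (length(f) != 5L) {
        stop(sprintf("repeat-table parse error at line %d: expected 5 columns, got %d", i, length(f)))
      }
      data.frame(chrom = f[1L], start1 = as.integer(f[2L]), end = as.integer(f[3L]),
                 family_raw = f[4L], name = f[5L], stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
  }
  if (any(is.na(tab$start1)) || any(is.na(tab$end)) || any(tab$start1 > tab$end)) {
    stop("coordinate error: repeat start must be <= end")
  }
  data.frame(
    chrom = tab$chrom, start = tab$start1 - 1L, end = tab$end,
    family = repeat_family(tab$family_raw), name = tab$name,
    stringsAsFactors = FALSE
  )
}

#' @rdname read_repeat_table
#' @param family_string raw RepeatMasker class/family strings.
#' @export
repeat_family <- function(family_string) {
  known <- c("SINE", "LINE", "LTR", "DNA", "Simple_repeat", "Low_complexity")
  base <- sub("/.*$", "", family_string)
  ifelse(base %in% known, base, "Other")
}

#' @rdname read_repeat_table
#' @param repeats a repeat-feature data.frame.
#' @export
write_repeat_table <- function(repeats, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s", repeats$chrom, repeats$start + 1L,
                   repeats$end, repeats$family, repeats$name)
  writeLines(lines, path)
  invisible(path)
}
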