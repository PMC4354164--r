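#' Chain mappings between two genomes
#'
#' A chain mapping is a data.frame of ungapped aligned blocks with columns
#' `chain_id`, `s_chrom`, `s_start`, `s_end` (source genome, 0-based
#' half-open), `t_chrom`, `t_start`, `t_end` (target genome, forward-strand
#' coordinates) and `orient` (`"+"` or `"-"`). Within a chain, blocks are
#' non-overlapping, strictly increasing on the source, and each block's
#' source and target widths are equal. For `orient == "+"` the source base
#' `p` in a block maps to `t_start + (p - s_start)`; for `"-"` it maps to
#' `t_end - 1 - (p - s_start)` (images run right to left on the target
#' forward strand).
#'
#' @param blocks data.frame with the columns above.
#' @return a validated `chain_mapping` data.frame.
#' @export
chain_mapping <- function(blocks) {
  req <- c("chain_id", "s_chrom", "s_start", "s_end", "t_chrom", "t_start", "t_end", "orient")
  miss <- setdiff(req, names(blocks))
  if (length(miss)) stop("missing chain columns: ", paste(miss, collapse = ", "))
  for (col in c("s_start", "s_end", "t_start", "t_end")) blocks[[col]] <- as.integer(blocks[[col]])
  if (any(blocks$s_end - blocks$s_start != blocks$t_end - blocks$t_start)) {
    stop("chain blocks must have equal source and target widths")
  }
  if (any(blocks$s_end <= blocks$s_start)) stop("chain block widths must be >= 1")
  if (any(!blocks$orient %in% c("+", "-"))) stop("orient must be '+' or '-'")
  blocks <- blocks[order(blocks$chain_id, blocks$s_start), , drop = FALSE]
  for (id in unique(blocks$chain_id)) {
    b <- blocks[blocks$chain_id == id, , drop = FALSE]
    if (length(unique(b$s_chrom)) != 1L || length(unique(b$t_chrom)) != 1L ||
        length(unique(b$orient)) != 1L) {
      stop(sprintf("chain '%s': blocks must share chromosomes and orientation", id))
    }
    if (nrow(b) > 1L && any(b$s_start[-1L] < b$s_end[-nrow(b)])) {
      stop(sprintf("chain '%s': blocks must be non-overlapping and increasing on the source", id))
    }
  }
  rownames(blocks) <- NULL
  class(blocks) <- c("chain_mapping", "data.frame")
  blocks
}

#' Read / write UCSC-style chain files (ungapped-block subset)
#'
#' The on-disk format is the UCSC chain format restricted to the blocks this
#' package models: each `chain` header line is
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart
#' qEnd id`, followed by `size dt dq` block lines and a final bare `size`.
#' As in UCSC liftOver chains, the *target* (`t`) side is the genome being
#' lifted **from** (this package's source) and the *query* (`q`) side the
#' genome being lifted **to**. Minus-orientation chains store query
#' coordinates on the reverse strand; they are converted to forward-strand
#' coordinates on read.
#'
#' @param path chain file path.
#' @return `read_chain()`: a [chain_mapping].
#' @export
read_chain <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path))
  lines <- readLines(path)
  rows <- list()
  i <- 1L
  chain_n <- 0L
  while (i <= length(lines)) {
    l <- trimws(lines[i])
    if (!nzchar(l)) { i <- i + 1L; next }
    h <- strsplit(l, "\\s+")[[1L]]
    if (h[1L] != "chain" || length(h) < 13L) {
      stop(sprintf("chain parse error at line %d: expected chain header", i))
    }
    chain_n <- chain_n + 1L
    s_chrom <- h[3L]; s_pos <- as.integer(h[6L])
    t_chrom <- h[8L]; q_size <- as.integer(h[9L]); orient <- h[10L]
    q_pos <- as.integer(h[11L])
    chain_id <- h[13L]
    i <- i + 1L
    repeat {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      size <- as.integer(f[1L])
      t_fwd <- if (orient == "+") {
        c(q_pos, q_pos + size)
      } else {
        c(q_size - (q_pos + size), q_size - q_pos)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chain_id = chain_id, s_chrom = s_chrom, s_start = s_pos, s_end = s_pos + size,
        t_chrom = t_chrom, t_start = t_fwd[1L], t_end = t_fwd[2L], orient = orient,
        stringsAsFactors = FALSE
      )
      i <- i + 1L
      if (length(f) == 1L) break
      s_pos <- s_pos + size + as.integer(f[2L])
      q_pos <- q_pos + size + as.integer(f[3L])
    }
  }
  chain_mapping(do.call(rbind, rows))
}

#' @rdname read_chain
#' @param chain a [chain_mapping].
#' @param s_sizes,t_sizes named integer vectors of chromosome sizes for the
#'   source and target genomes; defaults to the maximal block end per
#'   chromosome.
#' @export
write_chain <- function(chain, path, s_sizes = NULL, t_sizes = NULL) {
  size_of <- function(sizes, chrom, fallback) {
    if (!is.null(sizes) && chrom %in% names(sizes)) as.integer(sizes[[chrom]]) else fallback
  }
  out <- character(0)
  for (id in unique(chain$chain_id)) {
    b <- chain[chain$chain_id == id, , drop = FALSE]
    b <- b[order(b$s_start), , drop = FALSE]
    orient <- b$orient[1L]
    s_size <- size_of(s_sizes, b$s_chrom[1L], max(b$s_end))
    t_size <- size_of(t_sizes, b$t_chrom[1L], max(b$t_end))
    # query coordinates in strand-local space
    q <- if (orient == "+") {
      cbind(b$t_start, b$t_end)
    } else {
      cbind(t_size - b$t_end, t_size - b$t_start)
    }
    out <- c(out, sprintf(
      "chain 1000 %s %d + %d %d %s %d %s %d %d %s",
      b$s_chrom[1L], s_size, min(b$s_start), max(b$s_end),
      b$t_chrom[1L], t_size, orient, min(q[, 1L]), max(q[, 2L]), id
    ))
    sizes <- b$s_end - b$s_start
    n <- nrow(b)
    if (n > 1L) {
      dt <- b$s_start[-1L] - b$s_end[-n]
      dq <- q[-1L, 1L] - q[-n, 2L]
      out <- c(out, sprintf("%d\t%d\t%d", sizes[-n], dt, dq))
    }
    out <- c(out, sprintf("%d", sizes[n]), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Invert a chain mapping
#'
#' Swaps the source and target sides of every block, preserving orientation
#' semantics, so that lifting through the inverse undoes a complete lift.
#'
#' @param chain a [chain_mapping].
#' @return the inverted `chain_mapping`.
#' @export
invert_chain <- function(chain) {
  chain_mapping(data.frame(
    chain_id = chain$chain_id,
    s_chrom = chain$t_chrom, s_start = chain$t_start, s_end = chain$t_end,
    t_chrom = chain$s_chrom, t_start = chain$s_start, t_end = chain$s_end,
    orient = chain$orient, stringsAsFactors = FALSE
  ))
}
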