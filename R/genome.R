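#' Genome sequences
#'
#' A genome is represented as a named [Biostrings::DNAStringSet], one entry
#' per chromosome, uppercase over the alphabet `{A, C, G, T, N}`. These
#' helpers construct and validate such an object and extract subsequences
#' using the package's 0-based half-open coordinate convention.
#'
#' @param seqs named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @return `genome_sequence()` returns a validated `DNAStringSet`.
#' @examples
#' g <- genome_sequence(c(chr1 = "ACGTACGT"))
#' genome_subseq(g, "chr1", 0, 4)
#' @export
genome_sequence <- function(seqs) {
  if (is.character(seqs)) {
    seqs <- Biostrings::DNAStringSet(toupper(seqs))
  }
  if (!methods::is(seqs, "DNAStringSet")) {
    stop("'seqs' must be a character vector or DNAStringSet")
  }
  nm <- names(seqs)
  if (is.null(nm) || anyNA(nm) || any(nm == "") || anyDuplicated(nm)) {
    stop("every chromosome must have a unique non-empty name")
  }
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("chromosome length must be > 0")
  }
  bad <- Biostrings::alphabetFrequency(seqs, baseOnly = TRUE)[, "other"]
  n_count <- Biostrings::letterFrequency(seqs, "N")
  if (any(bad - n_count > 0)) {
    stop("genome sequences may only contain A, C, G, T, N")
  }
  seqs
}

#' @rdname genome_sequence
#' @param genome a `DNAStringSet` as returned by `genome_sequence()`.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open coordinates on the chromosome.
#' @return `genome_subseq()` returns the subsequence as a character string.
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop(sprintf("unknown chromosome '%s'", chrom))
  }
  len <- length(genome[[chrom]])
  if (start < 0 || end > len || start >= end) {
    stop(sprintf(
      "coordinate error: [%d, %d) outside chromosome '%s' of length %d",
      start, end, chrom, len
    ))
  }
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

#' @rdname genome_sequence
#' @param path FASTA file path.
#' @export
read_genome_fasta <- function(path) {
  genome_sequence(Biostrings::readDNAStringSet(path))
}

#' @rdname genome_sequence
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' @param seq character DNA string over `{A,C,G,T,N}`.
#' @return the reverse complement as a character string.
#' @keywords internal
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
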