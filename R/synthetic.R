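#' Configuration for the synthetic dataset generator
#'
#' Bundles every knob of the deterministic toy-data generator. The defaults
#' are the package's frozen study conditions: a 2 x 200 kb genome carrying
#' 30 lincRNA transcripts over 25 loci (five loci spliced into two
#' isoforms), 30 protein-coding transcripts (one third of them at loci
#' absent from the protein annotation, emulating incomplete annotation), and
#' ten decoys each of the single-exon, short (< 200 bp), UTR-fragment and
#' small-RNA-like classes. LincRNA exon counts follow P(2,3,4 exons) =
#' (0.66, 0.25, 0.09) and mature lengths are uniform on 600–1500 bp; 65% of
#' lincRNAs carry a repeat whose covered fraction is Beta(1, 2.56); the
#' ortholog genome differs by 5% substitutions. Identical configurations
#' produce byte-identical outputs.
#'
#' @param seed integer seed driving every random choice.
#' @param n_chromosomes,chrom_length genome shape.
#' @param n_lincrna,n_coding,n_single_exon,n_short,n_utr_fragment,n_small_rna
#'   transcript counts per class (`n_lincrna` counts transcripts, not loci).
#' @param n_isoform_loci lincRNA loci carrying a second isoform.
#' @param lincrna_exon_probs probabilities of 2/3/4 exons for lincRNAs.
#' @param lincrna_length_range,coding_length_range,intron_length_range
#'   mature-length and intron-length ranges (bases).
#' @param coding_exon_range exon-count range for coding transcripts.
#' @param coding_unannotated_frac fraction of coding transcripts planted at
#'   loci left out of the protein annotation.
#' @param repeat_bearing_prob probability a lincRNA carries >= 1 repeat.
#' @param repeat_frac_shape Beta shape parameters of the repeat-covered
#'   fraction among bearers.
#' @param repeat_family_probs named categorical distribution over repeat
#'   families.
#' @param ortholog_substitution_rate per-base substitution probability in
#'   the ortholog genome, in `[0, 0.3]`.
#' @param ortholog_unmappable_frac fraction of lincRNA loci whose chain
#'   blocks are deleted (unmappable regions).
#' @param ct_noise_sd Gaussian noise SD (cycles) for Ct tables.
#' @return a validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_chromosomes = 2L, chrom_length = 200000L,
                             n_lincrna = 30L, n_coding = 30L, n_single_exon = 10L,
                             n_short = 10L, n_utr_fragment = 10L, n_small_rna = 10L,
                             n_isoform_loci = 5L,
                             lincrna_exon_probs = c("2" = 0.66, "3" = 0.25, "4" = 0.09),
                             lincrna_length_range = c(600L, 1500L),
                             coding_length_range = c(900L, 1500L),
                             coding_exon_range = c(4L, 8L),
                             intron_length_range = c(100L, 400L),
                             coding_unannotated_frac = 1 / 3,
                             repeat_bearing_prob = 0.65,
                             repeat_frac_shape = c(1, 2.56),
                             repeat_family_probs = c(
                               SINE = 0.36, LINE = 0.22, LTR = 0.155,
                               Simple_repeat = 0.12, Low_complexity = 0.0725,
                               DNA = 0.05, Other = 0.0225
                             ),
                             ortholog_substitution_rate = 0.05,
                             ortholog_unmappable_frac = 0.2,
                             ct_noise_sd = 0.2) {
  cfg <- list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.integer(chrom_length),
    n_lincrna = as.integer(n_lincrna), n_coding = as.integer(n_coding),
    n_single_exon = as.integer(n_single_exon), n_short = as.integer(n_short),
    n_utr_fragment = as.integer(n_utr_fragment), n_small_rna = as.integer(n_small_rna),
    n_isoform_loci = as.integer(n_isoform_loci),
    lincrna_exon_probs = lincrna_exon_probs,
    lincrna_length_range = lincrna_length_range,
    coding_length_range = coding_length_range,
    coding_exon_range = coding_exon_range,
    intron_length_range = intron_length_range,
    coding_unannotated_frac = coding_unannotated_frac,
    repeat_bearing_prob = repeat_bearing_prob,
    repeat_frac_shape = repeat_frac_shape,
    repeat_family_probs = repeat_family_probs,
    ortholog_substitution_rate = ortholog_substitution_rate,
    ortholog_unmappable_frac = ortholog_unmappable_frac,
    ct_noise_sd = ct_noise_sd
  )
  counts <- unlist(cfg[grep("^n_", names(cfg))])
  if (any(counts < 0L)) stop("all counts must be >= 0")
  probs <- c(cfg$lincrna_exon_probs, cfg$repeat_family_probs,
             cfg$repeat_bearing_prob, cfg$coding_unannotated_frac,
             cfg$ortholog_unmappable_frac)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$ortholog_substitution_rate < 0 || cfg$ortholog_substitution_rate > 0.3) {
    stop("ortholog substitution rate must lie in [0, 0.3]")
  }
  if (cfg$n_isoform_loci > cfg$n_lincrna %/% 2L) stop("too many isoform loci")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate the toy genome
#'
#' Draws every base i.i.d. uniformly from A/C/G/T using the configured seed;
#' chromosomes are named `chr1, chr2, ...`.
#'
#' @param cfg a [synthetic_config].
#' @return a genome `DNAStringSet`.
#' @export
generate_genome <- function(cfg) {
  set.seed(cfg$seed)
  seqs <- vapply(seq_len(cfg$n_chromosomes), function(i) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_length, replace = TRUE), collapse = "")
  }, character(1))
  genome_sequence(setNames(seqs, paste0("chr", seq_len(cfg$n_chromosomes))))
}

# ---- internal construction helpers ----------------------------------------

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_composition <- function(total, n_parts, min_part) {
  extra <- total - n_parts * min_part
  stopifnot(extra >= 0L)
  cuts <- sort(sample.int(extra + 1L, n_parts - 1L, replace = TRUE) - 1L)
  as.integer(min_part + diff(c(0L, cuts, extra)))
}

new_placer <- function(genome_chars, pad = 200L) {
  occupied <- lapply(genome_chars, function(x) matrix(integer(0), ncol = 2L))
  list(
    place = function(span_len) {
      for (attempt in seq_len(1000L)) {
        ci <- sample(length(genome_chars), 1L)
        chrom_len <- nchar(genome_chars[[ci]])
        if (chrom_len - span_len - pad < 1L) next
        s <- sample.int(chrom_len - span_len - pad, 1L) + pad %/% 2L
        occ <- occupied[[ci]]
        if (nrow(occ) == 0L ||
            all(s + span_len + pad <= occ[, 1L] | s >= occ[, 2L] + pad)) {
          occupied[[ci]] <<- rbind(occ, c(s, s + span_len))
          return(list(chrom = names(genome_chars)[ci], start = s))
        }
      }
      stop("generation error: could not place locus after 1000 attempts")
    }
  )
}

# build exon intervals for a locus starting at genomic `start`
build_exons <- function(chrom, start, strand, exon_widths, intron_lengths) {
  n <- length(exon_widths)
  starts <- integer(n)
  pos <- start
  for (i in seq_len(n)) {
    starts[i] <- pos
    pos <- pos + exon_widths[i] + if (i < n) intron_lengths[i] else 0L
  }
  data.frame(
    chrom = chrom, strand = strand, start = starts,
    end = starts + exon_widths, stringsAsFactors = FALSE
  )
}

genomic_span_of <- function(exon_widths, intron_lengths) {
  sum(exon_widths) + sum(intron_lengths)
}

# read/write mature sequence against a character-vector genome
read_mature <- function(genome_chars, ex) {
  pieces <- substring(genome_chars[[ex$chrom[1L]]], ex$start + 1L, ex$end)
  s <- paste(pieces, collapse = "")
  if (ex$strand[1L] == "-") revcomp(s) else s
}

write_mature <- function(genome_chars, ex, mature) {
  ex <- ex[order(ex$start), , drop = FALSE]
  widths <- ex$end - ex$start
  stopifnot(nchar(mature) == sum(widths))
  genomic_seq <- if (ex$strand[1L] == "-") revcomp(mature) else mature
  offs <- cumsum(c(0L, widths))
  chrom <- ex$chrom[1L]
  for (i in seq_len(nrow(ex))) {
    piece <- substr(genomic_seq, offs[i] + 1L, offs[i + 1L])
    substr(genome_chars[[chrom]], ex$start[i] + 1L, ex$end[i]) <- piece
  }
  genome_chars
}

# force canonical GT..AG introns (on the transcript strand)
write_splice_sites <- function(genome_chars, ex) {
  ex <- ex[order(ex$start), , drop = FALSE]
  chrom <- ex$chrom[1L]
  minus <- ex$strand[1L] == "-"
  for (i in seq_len(nrow(ex) - 1L)) {
    i_start <- ex$end[i]
    i_end <- ex$start[i + 1L]
    left <- if (minus) "CT" else "GT"   # minus strand: genomic left is acceptor
    right <- if (minus) "AC" else "AG"
    substr(genome_chars[[chrom]], i_start + 1L, i_start + 2L) <- left
    substr(genome_chars[[chrom]], i_end - 1L, i_end) <- right
  }
  genome_chars
}

# overwrite codons so no open reading stretch reaches `threshold` codons in
# any of the six frames; returns the edited mature string
suppress_orfs <- function(mature, threshold) {
  chars <- strsplit(mature, "")[[1L]]
  L <- length(chars)
  write_codon <- function(chars, frame, codon_idx) {
    # frame: 1..3 forward offsets 0..2; 4..6 reverse offsets 0..2
    if (frame <= 3L) {
      off <- frame - 1L
      pos <- off + 3L * (codon_idx - 1L) + 1L
      chars[pos:(pos + 2L)] <- c("T", "A", "A")
    } else {
      off <- frame - 4L
      rc_pos <- off + 3L * (codon_idx - 1L) + 1L   # position in revcomp string
      pos_hi <- L - rc_pos + 1L                    # mature position of rc_pos
      chars[(pos_hi - 2L):pos_hi] <- c("T", "T", "A")
    }
    chars
  }
  for (pass in seq_len(100L)) {
    edited <- FALSE
    seq_fwd <- paste(chars, collapse = "")
    seq_rev <- revcomp(seq_fwd)
    for (frame in 1:6) {
      s <- if (frame <= 3L) seq_fwd else seq_rev
      off <- if (frame <= 3L) frame - 1L else frame - 4L
      n_cod <- (nchar(s) - off) %/% 3L
      if (n_cod < threshold) next
      codons <- substring(s, off + 1L + 3L * (seq_len(n_cod) - 1L), off + 3L * seq_len(n_cod))
      open_from <- NA_integer_
      i <- 1L
      while (i <= n_cod) {
        if (is.na(open_from) && codons[i] == "ATG") open_from <- i
        if (!is.na(open_from) && codons[i] %in% STOP_CODONS) open_from <- NA_integer_
        if (!is.na(open_from) && (i - open_from + 1L) >= threshold) {
          chars <- write_codon(chars, frame, i)
          edited <- TRUE
          break
        }
        i <- i + 1L
      }
      if (edited) break
    }
    if (!edited) return(paste(chars, collapse = ""))
  }
  stop("generation error: ORF suppression did not converge")
}

orf_suppression_threshold <- function(mature_length) {
  # guarantees ORF coverage <= 3/7 and hence a negative coding score
  min(99L, as.integer(mature_length %/% 7L))
}

#' Plant labelled transcripts in a genome
#'
#' Edits the genome in place to plant the configured transcript classes at
#' non-overlapping loci and returns the transcript models, the planted-truth
#' table, the protein-coding annotation, the UTR interval set, and synthetic
#' protein / domain / RNA-family hit tables:
#'
#' * **lincRNA** — 2–4 exons, mature length within the configured range,
#'   canonical GT..AG introns written into every intron, and every open
#'   reading stretch suppressed below the [orf_suppression_threshold()] in
#'   all six frames, so the class scores non-coding by construction.
#' * **coding** — a single long ORF (ATG, no internal stop, terminal TAA)
#'   covering ~85% of the mature length, flanked by annotated 5'/3' UTRs.
#'   Annotated coding genes are written to the protein annotation;
#'   "unannotated" ones are not (they must fall to the coding-potential
#'   stage). Both get Swiss-Prot-style and Pfam-style hits.
#' * **single_exon**, **short** (< 200 bp) — structural decoys.
#' * **utr_fragment** — two-exon transcripts planted wholly inside the 3'
#'   UTR of dedicated host genes that appear in the UTR annotation but not
#'   in the protein annotation, so only the UTR-coverage stage can remove
#'   them.
#' * **small_rna_like** — 70–150 nt single-exon transcripts with an
#'   Rfam-style family hit.
#'
#' @param cfg a [synthetic_config].
#' @param genome genome `DNAStringSet` from [generate_genome()].
#' @return list with `genome` (edited), `transcripts` ([transcript_set] with
#'   `biotype` truth labels), `truth` (data.frame `transcript_id`, `class`),
#'   `protein_annotation` (`transcript_set`), `utr_intervals` (data.frame
#'   `chrom`, `start`, `end`, `ref_id`), and `hits` (list of `protein`,
#'   `domain`, `rna_family` hit tables).
#' @export
plant_transcripts <- function(cfg, genome) {
  set.seed(cfg$seed + 1L)
  genome_chars <- as.list(setNames(as.character(genome), names(genome)))
  placer <- new_placer(genome_chars)
  exon_rows <- list()
  truth_rows <- list()
  annot_rows <- list()
  utr_rows <- list()
  hit_protein <- list()
  hit_domain <- list()
  hit_rna <- list()
  tx_counter <- 0L
  new_tx_id <- function() {
    tx_counter <<- tx_counter + 1L
    sprintf("CUFF.%d", tx_counter)
  }
  add_exons <- function(id, gene, ex, class) {
    exon_rows[[length(exon_rows) + 1L]] <<- data.frame(
      transcript_id = id, gene_id = gene, chrom = ex$chrom, strand = ex$strand,
      start = ex$start, end = ex$end, biotype = class, stringsAsFactors = FALSE
    )
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      transcript_id = id, gene_id = gene, class = class, stringsAsFactors = FALSE
    )
  }

  # ---- lincRNAs: primaries + isoforms --------------------------------------
  n_primary <- cfg$n_lincrna - cfg$n_isoform_loci
  for (k in seq_len(n_primary)) {
    is_isoform_locus <- k <= cfg$n_isoform_loci
    n_ex <- if (is_isoform_locus) {
      sample(3:4, 1L)
    } else {
      as.integer(sample(names(cfg$lincrna_exon_probs), 1L, prob = cfg$lincrna_exon_probs))
    }
    mature <- sample(cfg$lincrna_length_range[1L]:cfg$lincrna_length_range[2L], 1L)
    repeat {
      widths <- random_composition(mature, n_ex, 60L)
      if (!is_isoform_locus || mature - widths[2L] >= 300L) break
    }
    introns <- sample(cfg$intron_length_range[1L]:cfg$intron_length_range[2L],
                      n_ex - 1L, replace = TRUE)
    strand <- sample(c("+", "-"), 1L)
    loc <- placer$place(genomic_span_of(widths, introns))
    ex <- build_exons(loc$chrom, loc$start, strand, widths, introns)
    genome_chars <- write_splice_sites(genome_chars, ex)

    gene <- sprintf("CUFF.G%d", k)
    id_a <- new_tx_id()
    add_exons(id_a, gene, ex, "lincRNA")
    iso_exons <- if (is_isoform_locus) ex[-2L, , drop = FALSE] else NULL
    id_b <- if (is_isoform_locus) new_tx_id() else NULL
    if (is_isoform_locus) add_exons(id_b, gene, iso_exons, "lincRNA")

    # suppress ORFs on every isoform until all are clean (edits share bases)
    for (pass in seq_len(20L)) {
      clean <- TRUE
      for (exi in c(list(ex), if (is_isoform_locus) list(iso_exons))) {
        m <- read_mature(genome_chars, exi)
        thr <- orf_suppression_threshold(nchar(m))
        m2 <- suppress_orfs(m, thr)
        if (m2 != m) {
          clean <- FALSE
          genome_chars <- write_mature(genome_chars, exi, m2)
        }
      }
      if (clean) break
      if (pass == 20L) stop("generation error: isoform ORF suppression did not converge")
    }
  }

  # ---- coding genes (annotated, unannotated) and UTR hosts -----------------
  n_unannot <- as.integer(round(cfg$n_coding * cfg$coding_unannotated_frac))
  n_hosts <- max(1L, cfg$n_utr_fragment %/% 2L)
  host_utr3 <- list()
  plant_coding_gene <- function(idx, kind) {
    strand <- sample(c("+", "-"), 1L)
    if (kind == "host") {
      # hosts carry a long 3' UTR wholly inside the terminal exon so that
      # UTR-fragment decoys fit inside it
      mature <- sample(1200:1500, 1L)
      orf_nt <- 3L * as.integer((0.55 * mature) %/% 3L)
      u5 <- as.integer(0.05 * mature)
      u3 <- mature - u5 - orf_nt
      n_ex <- 3L
      others <- random_composition(mature - (u3 + 40L), n_ex - 1L, 60L)
      widths <- if (strand == "-") c(u3 + 40L, others) else c(others, u3 + 40L)
    } else {
      mature <- sample(cfg$coding_length_range[1L]:cfg$coding_length_range[2L], 1L)
      orf_nt <- 3L * as.integer((0.85 * mature) %/% 3L)
      u5 <- as.integer(0.07 * mature)
      u3 <- mature - u5 - orf_nt
      n_ex <- sample(cfg$coding_exon_range[1L]:cfg$coding_exon_range[2L], 1L)
      widths <- random_composition(mature, n_ex, 60L)
    }
    introns <- sample(cfg$intron_length_range[1L]:cfg$intron_length_range[2L],
                      n_ex - 1L, replace = TRUE)
    loc <- placer$place(genomic_span_of(widths, introns))
    ex <- build_exons(loc$chrom, loc$start, strand, widths, introns)
    genome_chars <<- write_splice_sites(genome_chars, ex)

    n_codons <- orf_nt %/% 3L - 2L # between ATG and TAA
    body <- sample(setdiff(mkAllCodons(), STOP_CODONS), n_codons, replace = TRUE)
    m <- read_mature(genome_chars, ex)
    orf_seq <- paste0("ATG", paste(body, collapse = ""), "TAA")
    substr(m, u5 + 1L, u5 + orf_nt) <- orf_seq
    genome_chars <<- write_mature(genome_chars, ex, m)

    utr5 <- mature_to_genomic(ex, 0L, u5)
    utr3 <- mature_to_genomic(ex, mature - u3, mature)
    ref_id <- sprintf("NM_%04d", idx)
    if (kind != "unannotated") {
      utr_rows[[length(utr_rows) + 1L]] <<- cbind(rbind(utr5, utr3), ref_id = ref_id)
    }
    if (kind == "host") host_utr3[[length(host_utr3) + 1L]] <<- cbind(utr3, strand = strand)
    if (kind == "annotated") {
      annot_rows[[length(annot_rows) + 1L]] <<- data.frame(
        transcript_id = sprintf("PT%04d", idx), gene_id = sprintf("PG%04d", idx),
        chrom = ex$chrom, strand = ex$strand, start = ex$start, end = ex$end,
        stringsAsFactors = FALSE
      )
    }
    if (kind != "host") {
      id <- new_tx_id()
      add_exons(id, sprintf("CUFF.GC%d", idx), ex, "coding")
      hit_protein[[length(hit_protein) + 1L]] <<- hit_record(
        query_id = id, subject_id = sprintf("SP%04d", idx),
        percent_identity = 97.5, alignment_length = orf_nt %/% 3L,
        query_start = 1L, query_end = orf_nt %/% 3L,
        subject_start = 1L, subject_end = orf_nt %/% 3L,
        bit_score = 250, e_value = 1e-30, source_kind = "protein"
      )
      hit_domain[[length(hit_domain) + 1L]] <<- hit_record(
        query_id = id, subject_id = sprintf("PF%05d", idx),
        e_value = 1e-12, bit_score = 80,
        query_start = 5L, query_end = orf_nt %/% 3L - 5L,
        source_kind = "domain"
      )
    }
    invisible(NULL)
  }
  idx <- 0L
  for (k in seq_len(cfg$n_coding - n_unannot)) { idx <- idx + 1L; plant_coding_gene(idx, "annotated") }
  for (k in seq_len(n_unannot)) { idx <- idx + 1L; plant_coding_gene(idx, "unannotated") }
  for (k in seq_len(n_hosts)) { idx <- idx + 1L; plant_coding_gene(idx, "host") }

  # ---- structural decoys ---------------------------------------------------
  for (k in seq_len(cfg$n_single_exon)) {
    w <- sample(500:2000, 1L)
    loc <- placer$place(w)
    ex <- build_exons(loc$chrom, loc$start, sample(c("+", "-"), 1L), w, integer(0))
    add_exons(new_tx_id(), sprintf("CUFF.GSE%d", k), ex, "single_exon")
  }
  for (k in seq_len(cfg$n_short)) {
    mature <- sample(120:199, 1L)
    widths <- random_composition(mature, 2L, 40L)
    intron <- sample(cfg$intron_length_range[1L]:cfg$intron_length_range[2L], 1L)
    loc <- placer$place(genomic_span_of(widths, intron))
    ex <- build_exons(loc$chrom, loc$start, sample(c("+", "-"), 1L), widths, intron)
    add_exons(new_tx_id(), sprintf("CUFF.GSH%d", k), ex, "short")
  }
  for (k in seq_len(cfg$n_small_rna)) {
    w <- sample(70:150, 1L)
    loc <- placer$place(w)
    ex <- build_exons(loc$chrom, loc$start, sample(c("+", "-"), 1L), w, integer(0))
    id <- new_tx_id()
    add_exons(id, sprintf("CUFF.GSR%d", k), ex, "small_rna_like")
    fam_class <- sample(c("tRNA", "snoRNA", "miRNA", "snRNA"), 1L)
    hit_rna[[length(hit_rna) + 1L]] <- hit_record(
      query_id = id, subject_id = sprintf("RF%05d", k), family_class = fam_class,
      e_value = 1e-10, bit_score = 60, source_kind = "rna_family"
    )
  }

  # ---- UTR fragments inside host 3' UTRs -----------------------------------
  if (cfg$n_utr_fragment > 0L) {
    for (k in seq_len(cfg$n_utr_fragment)) {
      host <- host_utr3[[((k - 1L) %% length(host_utr3)) + 1L]]
      host <- host[which.max(host$end - host$start), , drop = FALSE]
      u_w <- host$end - host$start
      stopifnot(u_w >= 330L)
      # two exons inside the UTR interval; alternate placement per fragment
      off <- if (k %% 2L == 0L) 10L else 0L
      e1 <- c(host$start + off, host$start + off + 140L)
      e2 <- c(host$start + off + 190L, host$start + u_w - 10L)
      ex <- data.frame(
        chrom = host$chrom, strand = host$strand,
        start = c(e1[1L], e2[1L]), end = c(e1[2L], e2[2L]),
        stringsAsFactors = FALSE
      )
      add_exons(new_tx_id(), sprintf("CUFF.GUF%d", k), ex, "utr_fragment")
    }
  }

  exons <- do.call(rbind, exon_rows)
  transcripts <- transcript_set(exons)
  truth <- do.call(rbind, truth_rows)
  protein_annotation <- transcript_set(do.call(rbind, annot_rows))
  utr_intervals <- do.call(rbind, utr_rows)
  rownames(utr_intervals) <- NULL
  bind_hits <- function(rows) {
    out <- if (length(rows)) do.call(rbind, rows) else hit_record()[0L, ]
    class(out) <- c("hit_table", "data.frame")
    out
  }
  list(
    genome = genome_sequence(unlist(genome_chars)),
    transcripts = transcripts,
    truth = truth,
    protein_annotation = protein_annotation,
    utr_intervals = utr_intervals,
    hits = list(
      protein = bind_hits(hit_protein),
      domain = bind_hits(hit_domain),
      rna_family = bind_hits(hit_rna)
    )
  )
}

mkAllCodons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Plant repeat annotations over transcripts
#'
#' Draws, per transcript, whether it bears a repeat
#' (`repeat_bearing_prob`) and, for bearers, a covered fraction from the
#' configured Beta distribution; a contiguous stretch of the mature sequence
#' of that size is then mapped to genomic coordinates and emitted as repeat
#' features with family labels drawn from `repeat_family_probs`. Repeat
#' features are annotations only; the underlying sequence is not modified.
#'
#' @param cfg a [synthetic_config].
#' @param genome genome `DNAStringSet` (bounds checking only).
#' @param ts the [transcript_set] to annotate (typically the lincRNA class).
#' @return a repeat-feature data.frame (`chrom`, `start`, `end`, `family`,
#'   `name`).
#' @export
plant_repeats <- function(cfg, genome, ts) {
  set.seed(cfg$seed + 2L)
  if (cfg$repeat_bearing_prob == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      family = character(), name = character(), stringsAsFactors = FALSE))
  }
  rows <- list()
  i <- 0L
  for (id in transcript_ids(ts)) {
    if (stats::runif(1) > cfg$repeat_bearing_prob) next
    ex <- ts[ts$transcript_id == id, , drop = FALSE]
    L <- sum(ex$end - ex$start)
    frac <- stats::rbeta(1, cfg$repeat_frac_shape[1L], cfg$repeat_frac_shape[2L])
    covered <- max(20L, min(L, as.integer(round(frac * L))))
    m_start <- sample.int(L - covered + 1L, 1L) - 1L
    fam <- sample(names(cfg$repeat_family_probs), 1L, prob = cfg$repeat_family_probs)
    pieces <- mature_to_genomic(ex, m_start, m_start + covered)
    for (p in seq_len(nrow(pieces))) {
      i <- i + 1L
      rows[[i]] <- data.frame(
        chrom = pieces$chrom[p], start = pieces$start[p], end = pieces$end[p],
        family = fam, name = sprintf("R%d", i), stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      family = character(), name = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Generate an ortholog genome with a chain mapping
#'
#' Copies the genome, applies i.i.d. substitutions at the configured rate,
#' and builds an identity chain split into blocks, deleting the blocks under
#' a chosen fraction of lincRNA loci (the "unmappable" set). Ortholog
#' transcript models are emitted, at the image coordinates, for every
#' mappable lincRNA.
#'
#' @param cfg a [synthetic_config].
#' @param genome source genome `DNAStringSet`.
#' @param linc_ts [transcript_set] of the planted lincRNA class.
#' @return list with `genome` (the ortholog `DNAStringSet`, chromosomes
#'   renamed `oChr*`), `chain` (a [chain_mapping]), `ortholog_transcripts`
#'   (a `transcript_set` on the ortholog genome), `ortholog_map`
#'   (data.frame `transcript_id`, `ortholog_id`), and `unmappable_genes`.
#' @export
generate_ortholog <- function(cfg, genome, linc_ts) {
  set.seed(cfg$seed + 3L)
  chars <- as.list(setNames(as.character(genome), names(genome)))
  bases <- c("A", "C", "G", "T")
  for (chrom in names(chars)) {
    v <- strsplit(chars[[chrom]], "")[[1L]]
    hit <- which(stats::runif(length(v)) < cfg$ortholog_substitution_rate)
    if (length(hit)) {
      v[hit] <- vapply(v[hit], function(b) sample(setdiff(bases, b), 1L), character(1))
      chars[[chrom]] <- paste(v, collapse = "")
    }
  }
  target_name <- function(chrom) sub("^chr", "oChr", chrom)

  loci <- gene_loci(linc_ts)
  n_unmap <- as.integer(round(nrow(loci) * cfg$ortholog_unmappable_frac))
  unmap_idx <- if (n_unmap > 0L) sample(nrow(loci), n_unmap) else integer(0)
  unmappable <- loci[unmap_idx, , drop = FALSE]

  blocks <- list()
  for (chrom in names(genome)) {
    L <- length(genome[[chrom]])
    holes <- unmappable[unmappable$chrom == chrom, , drop = FALSE]
    hole_r <- if (nrow(holes)) {
      IRanges::reduce(IRanges::IRanges(pmax(1L, holes$start - 50L + 1L),
                                       pmin(L, holes$end + 50L)))
    } else IRanges::IRanges()
    kept <- IRanges::gaps(hole_r, start = 1L, end = L)
    # split each kept segment at a few random interior points (10 bp gaps)
    for (si in seq_along(kept)) {
      s0 <- IRanges::start(kept)[si] - 1L
      e0 <- IRanges::end(kept)[si]
      cuts <- sort(sample(seq.int(s0 + 1000L, max(s0 + 1001L, e0 - 1000L), by = 1L),
                          min(2L, max(0L, (e0 - s0) %/% 50000L))))
      seg_starts <- c(s0, cuts + 10L)
      seg_ends <- c(cuts, e0)
      ok <- seg_starts < seg_ends
      blocks[[length(blocks) + 1L]] <- data.frame(
        chain_id = paste0("chain_", chrom),
        s_chrom = chrom, s_start = seg_starts[ok], s_end = seg_ends[ok],
        t_chrom = target_name(chrom), t_start = seg_starts[ok], t_end = seg_ends[ok],
        orient = "+", stringsAsFactors = FALSE
      )
    }
  }
  chain <- chain_mapping(do.call(rbind, blocks))

  mappable <- loci[setdiff(seq_len(nrow(loci)), unmap_idx), , drop = FALSE]
  keep_ids <- unlist(mappable$transcript_ids)
  ortho_ex <- linc_ts[linc_ts$transcript_id %in% keep_ids, , drop = FALSE]
  ortho_map <- data.frame(
    transcript_id = keep_ids,
    ortholog_id = paste0("ORTH_", keep_ids),
    stringsAsFactors = FALSE
  )
  ortho_ex$transcript_id <- paste0("ORTH_", ortho_ex$transcript_id)
  ortho_ex$gene_id <- paste0("ORTHG_", ortho_ex$gene_id)
  ortho_ex$chrom <- target_name(ortho_ex$chrom)
  if ("biotype" %in% names(ortho_ex)) ortho_ex$biotype <- NULL
  names(chars) <- target_name(names(chars))
  list(
    genome = genome_sequence(unlist(chars)),
    chain = chain,
    ortholog_transcripts = transcript_set(ortho_ex),
    ortholog_map = ortho_map,
    unmappable_genes = unmappable$gene_id
  )
}

#' Generate a synthetic qPCR Ct table
#'
#' For each design row (condition, gene, true fold-change vs the calibrator)
#' emits `n_replicates` target Ct values `base_ct - log2(fold) + e` and
#' reference-gene Ct values `ref_ct + e`, with `e ~ Normal(0, noise_sd)`.
#'
#' @param design data.frame with columns `condition`, `gene`, `fold`
#'   (fold > 0).
#' @param n_replicates replicates per condition and gene.
#' @param noise_sd Gaussian Ct noise in cycles (0 gives exact recovery).
#' @param seed integer seed.
#' @param reference reference gene id.
#' @param base_ct,ref_ct baseline cycle thresholds of target and reference.
#' @return a [ct_table] containing target and reference records.
#' @export
generate_ct_table <- function(design, n_replicates = 6L, noise_sd = 0.2,
                              seed = 1L, reference = "HPRT",
                              base_ct = 25, ref_ct = 20) {
  stopifnot(all(design$fold > 0))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(design))) {
    ct_vals <- base_ct - log2(design$fold[i]) + stats::rnorm(n_replicates, 0, noise_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = design$condition[i], gene = design$gene[i],
      replicate = seq_len(n_replicates), ct = ct_vals, stringsAsFactors = FALSE
    )
  }
  for (cond in unique(design$condition)) {
    rows[[length(rows) + 1L]] <- data.frame(
      condition = cond, gene = reference,
      replicate = seq_len(n_replicates),
      ct = ref_ct + stats::rnorm(n_replicates, 0, noise_sd),
      stringsAsFactors = FALSE
    )
  }
  ct_table(do.call(rbind, rows))
}

#' Generate the complete synthetic dataset
#'
#' Runs [generate_genome()], [plant_transcripts()], [plant_repeats()] (over
#' the lincRNA class), [generate_ortholog()] and [generate_ct_table()] under
#' one configuration and returns all pieces. `write_dataset()` serializes
#' them as plain-text files (FASTA, GTF, TSV, chain, CSV) into a directory.
#'
#' @param cfg a [synthetic_config].
#' @return list with components `config`, `genome`, `transcripts`, `truth`,
#'   `protein_annotation`, `utr_intervals`, `hits`, `repeats`, `ortholog`,
#'   `ct`.
#' @export
simulate_dataset <- function(cfg = synthetic_config()) {
  genome0 <- generate_genome(cfg)
  planted <- plant_transcripts(cfg, genome0)
  linc_ids <- planted$truth$transcript_id[planted$truth$class == "lincRNA"]
  linc_ts <- subset_transcripts(planted$transcripts, linc_ids)
  repeats <- plant_repeats(cfg, planted$genome, linc_ts)
  ortholog <- generate_ortholog(cfg, planted$genome, linc_ts)
  ct_design <- data.frame(
    condition = c("GM", "DM1", "DM3", "DM5"),
    gene = "linc1",
    fold = c(1, 2, 4, 8),
    stringsAsFactors = FALSE
  )
  ct <- generate_ct_table(ct_design, n_replicates = 6L, noise_sd = cfg$ct_noise_sd,
                          seed = cfg$seed + 4L)
  list(
    config = cfg,
    genome = planted$genome,
    transcripts = planted$transcripts,
    truth = planted$truth,
    protein_annotation = planted$protein_annotation,
    utr_intervals = planted$utr_intervals,
    hits = planted$hits,
    repeats = repeats,
    ortholog = ortholog,
    ct = ct
  )
}

#' @rdname simulate_dataset
#' @param ds a dataset from `simulate_dataset()`.
#' @param dir output directory (created if absent).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_genome_fasta(ds$genome, p("genome.fa"))
  write_gtf(ds$transcripts, p("transcripts.gtf"))
  write_gtf(ds$protein_annotation, p("protein_annotation.gtf"))
  write.table(ds$truth, p("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ds$utr_intervals, p("utr_intervals.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_repeat_table(ds$repeats, p("repeats.tsv"))
  write_hits_table(ds$hits$protein, p("swissprot_hits.tsv"))
  write_hits_table(ds$hits$domain, p("pfam_hits.tsv"))
  write_hits_table(ds$hits$rna_family, p("rfam_hits.tsv"))
  write_genome_fasta(ds$ortholog$genome, p("ortholog_genome.fa"))
  write_chain(ds$ortholog$chain, p("ortholog.chain"),
              s_sizes = setNames(Biostrings::width(ds$genome), names(ds$genome)),
              t_sizes = setNames(Biostrings::width(ds$ortholog$genome),
                                 names(ds$ortholog$genome)))
  write_gtf(ds$ortholog$ortholog_transcripts, p("ortholog_lincrnas.gtf"))
  write_ct_table(ds$ct, p("ct_table.csv"))
  invisible(dir)
}

#' @rdname simulate_dataset
#' @param path UTR interval TSV path (columns `chrom`, `start`, `end`,
#'   `ref_id`; 0-based half-open).
#' @export
read_utr_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
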