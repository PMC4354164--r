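test_that("identical configurations give byte-identical serialized datasets", {
  cfg <- synthetic_config(seed = 11L, chrom_length = 60000L, n_lincrna = 6L,
                          n_coding = 6L, n_single_exon = 2L, n_short = 2L,
                          n_utr_fragment = 2L, n_small_rna = 2L, n_isoform_loci = 1L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 10L)
  for (f in files) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("generated genome is uniform A/C/G/T with GC near one half", {
  cfg <- synthetic_config(seed = 3L, n_chromosomes = 2L, chrom_length = 10000L)
  g <- generate_genome(cfg)
  expect_equal(length(g), 2L)
  expect_equal(unname(Biostrings::width(g)), c(10000L, 10000L))
  gc <- sum(Biostrings::letterFrequency(g, "GC")) / sum(Biostrings::width(g))
  expect_lt(abs(gc - 0.5), 0.05)
  expect_identical(as.character(g), as.character(generate_genome(cfg)))
})

test_that("planted classes satisfy their construction contracts", {
  ds <- default_dataset()
  truth <- ds$truth
  ts <- ds$transcripts
  lens <- mature_lengths(ts)
  n_ex <- exon_counts(ts)

  linc_ids <- truth$transcript_id[truth$class == "lincRNA"]
  linc <- subset_transcripts(ts, linc_ids)
  # canonical GT-AG introns on every lincRNA intron
  sites <- splice_site_dinucleotides(linc, ds$genome)
  expect_true(all(sites$donor == "GT" & sites$acceptor == "AG"))
  # ORFs capped below 100 codons, verified by the brute-force scan
  seqs <- extract_sequences(linc, ds$genome)
  orf_codons <- vapply(seqs, brute_longest_orf_codons, integer(1))
  expect_true(all(orf_codons < 100L))
  expect_true(all(lens[linc_ids] >= 300L))
  expect_true(all(n_ex[linc_ids] >= 2L))

  short_ids <- truth$transcript_id[truth$class == "short"]
  expect_true(all(lens[short_ids] <= 199L))
  expect_true(all(n_ex[truth$transcript_id[truth$class == "single_exon"]] == 1L))

  small_ids <- truth$transcript_id[truth$class == "small_rna_like"]
  expect_true(all(lens[small_ids] >= 70L & lens[small_ids] <= 150L))
  expect_true(all(small_ids %in% ds$hits$rna_family$query_id))

  # coding transcripts carry a long ORF covering >= 80% of the mature length
  coding_ids <- truth$transcript_id[truth$class == "coding"]
  cod_seqs <- extract_sequences(subset_transcripts(ts, coding_ids), ds$genome)
  for (id in coding_ids) {
    orf <- longest_orf(cod_seqs[[id]])
    expect_gte(3 * max(orf$plus$codons, orf$minus$codons) / lens[[id]], 0.8)
  }

  # UTR fragments lie (almost) wholly inside annotated UTR intervals
  frag_ids <- truth$transcript_id[truth$class == "utr_fragment"]
  frac <- utr_coverage_fraction(subset_transcripts(ts, frag_ids), ds$utr_intervals)
  expect_true(all(frac >= 0.95))
})

test_that("planted repeats follow the configured coverage and family mix", {
  cfg0 <- synthetic_config(repeat_bearing_prob = 0)
  ds <- default_dataset()
  linc <- dataset_lincrnas(ds)
  expect_equal(nrow(plant_repeats(cfg0, ds$genome, linc)), 0L)

  # a transcript fully covered by one planted repeat has fraction 1.0
  ts1 <- make_tx("t1", 100L, 400L)
  rep1 <- data.frame(chrom = "chr1", start = 100L, end = 400L,
                     family = "SINE", name = "r", stringsAsFactors = FALSE)
  rc <- repeat_content(ts1, rep1)
  expect_equal(unname(rc$fraction), 1)

  # family mix recovery: 0.4 SINE / 0.3 LINE / 0.3 LTR over many transcripts
  many <- transcript_set(data.frame(
    transcript_id = sprintf("m%d", 1:600), gene_id = sprintf("m%d", 1:600),
    chrom = "chr1", strand = "+",
    start = seq(0L, by = 600L, length.out = 600L),
    end = seq(0L, by = 600L, length.out = 600L) + 500L,
    stringsAsFactors = FALSE
  ))
  cfg_mix <- synthetic_config(
    seed = 9L, repeat_bearing_prob = 1,
    repeat_family_probs = c(SINE = 0.4, LINE = 0.3, LTR = 0.3)
  )
  reps <- plant_repeats(cfg_mix, ds$genome, many)
  props <- table(reps$family) / nrow(reps)
  expect_lt(abs(props[["SINE"]] - 0.4), 0.07)
  expect_lt(abs(props[["LINE"]] - 0.3), 0.07)
  expect_lt(abs(props[["LTR"]] - 0.3), 0.07)
})

test_that("ortholog genome, chain and planted pairs behave as configured", {
  ds <- default_dataset()
  linc <- dataset_lincrnas(ds)
  # substitution rate 0 and no deletions: the chain lifts intervals onto
  # themselves (modulo the renamed chromosome)
  cfg_id <- synthetic_config(ortholog_substitution_rate = 0, ortholog_unmappable_frac = 0)
  orth0 <- generate_ortholog(cfg_id, ds$genome, linc)
  sp <- transcript_spans(linc)
  for (i in sample(nrow(sp), 5L)) {
    lr <- liftover_map(sp$chrom[i], sp$start[i], sp$end[i], orth0$chain)
    expect_true(lr$success)
    expect_equal(lr$mapped_base_ratio, 1)
    expect_equal(c(lr$mapped_start, lr$mapped_end), c(sp$start[i], sp$end[i]))
  }
  # default fixture: ~5% substitutions in remapped loci
  orth <- ds$ortholog
  loci <- gene_loci(linc)
  mappable <- setdiff(loci$gene_id, orth$unmappable_genes)
  idents <- vapply(mappable, function(g) {
    l <- loci[loci$gene_id == g, ]
    lr <- liftover_map(l$chrom, l$start, l$end, orth$chain)
    if (!lr$success || (lr$mapped_end - lr$mapped_start) != (l$end - l$start)) return(NA_real_)
    a <- strsplit(genome_subseq(ds$genome, l$chrom, l$start, l$end), "")[[1]]
    b <- strsplit(genome_subseq(orth$genome, lr$mapped_chrom, lr$mapped_start, lr$mapped_end), "")[[1]]
    mean(a == b)
  }, numeric(1))
  expect_lt(abs(mean(idents, na.rm = TRUE) - 0.95), 0.02)
  # loci in deleted blocks fail the lift at min_ratio 0.5
  for (g in orth$unmappable_genes) {
    l <- loci[loci$gene_id == g, ]
    expect_false(liftover_map(l$chrom, l$start, l$end, orth$chain)$success)
  }
})

test_that("synthetic Ct tables plant recoverable fold-changes", {
  design <- data.frame(condition = c("GM", "DM"), gene = "g", fold = c(1, 4))
  ct0 <- generate_ct_table(design, n_replicates = 4L, noise_sd = 0, seed = 2L)
  q0 <- ddct_quantify(ct0, "g", "HPRT", "GM")
  expect_equal(q0$mean_fold[q0$condition == "GM"], 1)
  expect_equal(q0$mean_fold[q0$condition == "DM"], 4)
  ct1 <- generate_ct_table(design, n_replicates = 6L, noise_sd = 0.2, seed = 7L)
  q1 <- ddct_quantify(ct1, "g", "HPRT", "GM")
  fold <- q1$mean_fold[q1$condition == "DM"]
  expect_gt(fold, 3.0)
  expect_lt(fold, 5.3)
})
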