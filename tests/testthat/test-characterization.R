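test_that("structure summary computes the documented arithmetic", {
  ts <- rbind_ts(
    make_tx("a", c(0L, 200L), c(50L, 250L)),    # 100 bp
    make_tx("b", c(1000L, 1400L), c(1200L, 1500L)) # 300 bp
  )
  st <- transcript_stats(ts)
  expect_equal(st$mean_length, 200)
  expect_equal(st$n_loci, 2L)
  expect_equal(st$isoforms_per_locus, 1)
  expect_equal(st$fraction_two_exon, 1)
  expect_error(transcript_stats(subset_transcripts(ts, character(0))), "empty")
})

test_that("isoforms per locus equals transcripts over loci on the fixture", {
  ds <- default_dataset()
  linc <- dataset_lincrnas(ds)
  st <- transcript_stats(linc, ds$genome)
  expect_equal(st$n_transcripts, 30L)
  expect_equal(st$n_loci, 25L)
  expect_equal(st$isoforms_per_locus, 30 / 25)
  expect_equal(st$fraction_canonical_splice, 1)
})

test_that("exon length histogram uses half-open bins and conserves counts", {
  ts <- make_tx("t", c(0L, 1000L), c(200L, 1399L)) # exons of 200 and 399 bp
  h <- exon_length_histogram(ts, c(0, 200, 400))
  expect_equal(unname(h), c(0L, 2L)) # 200 falls in the second bin
  ds <- default_dataset()
  h2 <- exon_length_histogram(ds$transcripts, c(0, 100, 200, 400, 800, Inf))
  expect_equal(sum(h2), nrow(ds$transcripts))
  expect_equal(sum(exon_length_histogram(subset_transcripts(ts, character(0)))), 0L)
})

test_that("repeat coverage unions overlapping features but counts families per feature", {
  ts <- make_tx("t", 0L, 200L)
  reps <- data.frame(
    chrom = "chr1", start = c(0L, 50L), end = c(100L, 150L),
    family = c("SINE", "LINE"), name = c("r1", "r2"), stringsAsFactors = FALSE
  )
  rc <- repeat_content(ts, reps)
  expect_equal(unname(rc$fraction), 0.75) # union covers 150 of 200
  expect_equal(sum(rc$family_percentages), 100)
  expect_equal(unname(rc$family_percentages[c("SINE", "LINE")]), c(50, 50))
  # no overlapping repeat: fraction 0, excluded from n_with_repeat
  ts2 <- rbind_ts(make_tx("t", 0L, 200L), make_tx("u", 5000L, 5400L))
  rc2 <- repeat_content(ts2, reps)
  expect_equal(rc2$n_with_repeat, 1L)
  expect_equal(unname(rc2$fraction["u"]), 0)
  expect_equal(sum(rc2$fraction_histogram), 2L)
})

test_that("repeat coverage matches the per-base union oracle", {
  set.seed(303)
  for (i in 1:500) {
    n_ex <- sample(1:3, 1)
    starts <- sort(sample(seq(0L, 400L, 10L), n_ex))
    ends <- starts + sample(10:50, n_ex, replace = TRUE)
    ok <- c(TRUE, ends[-n_ex] < starts[-1])
    ts <- make_tx("t", as.integer(starts[ok]), as.integer(ends[ok]))
    n_rep <- sample(1:5, 1)
    rs <- sample.int(450, n_rep)
    reps <- data.frame(chrom = "chr1", start = rs,
                       end = rs + sample(5:100, n_rep, replace = TRUE),
                       family = "SINE", name = paste0("r", seq_len(n_rep)),
                       stringsAsFactors = FALSE)
    got <- unname(repeat_content(ts, reps)$fraction)
    want <- brute_coverage_fraction(as.data.frame(ts), reps)
    expect_equal(got, want, info = paste("case", i))
  }
})

test_that("neighbor assignment respects gaps, overlaps and the 10 kb window", {
  linc <- gene_loci(make_tx("L", 1000L, 2000L, gene = "L"))
  prot <- gene_loci(rbind_ts(
    make_tx("p1", 2500L, 4000L, gene = "P_down"),
    make_tx("p2", 1500L, 2500L, gene = "P_overlap"),
    make_tx("p3", 12000L, 13000L, gene = "P_far"),
    make_tx("p4", 0L, 500L, gene = "P_up")
  ))
  na_ <- neighbor_analysis(linc, prot)
  a <- na_$assignments
  expect_equal(a$downstream_id, "P_down")
  expect_equal(a$downstream_distance, 500L)
  expect_equal(a$upstream_id, "P_up")
  expect_equal(a$upstream_distance, 500L)
  expect_false("P_overlap" %in% na_$neighbor_genes)
  # gap of exactly 10 kb is excluded (strict < 10 kb)
  prot2 <- gene_loci(make_tx("p", 12000L, 12500L, gene = "P_edge"))
  na2 <- neighbor_analysis(linc, prot2)
  expect_true(is.na(na2$assignments$downstream_id))
  expect_equal(na2$n_with_neighbor, 0L)
})

test_that("neighbor distances are symmetric under coordinate reflection", {
  L <- 50000L
  linc_tx <- make_tx("L", 20000L, 21000L, gene = "L")
  prot_tx <- rbind_ts(
    make_tx("p1", 15000L, 18000L, gene = "A"),
    make_tx("p2", 22000L, 23000L, gene = "B")
  )
  fwd <- neighbor_analysis(gene_loci(linc_tx), gene_loci(prot_tx))
  reflect <- function(ts) {
    d <- as.data.frame(ts)
    new_start <- L - d$end
    d$end <- L - d$start
    d$start <- new_start
    transcript_set(d)
  }
  rev_ <- neighbor_analysis(gene_loci(reflect(linc_tx)), gene_loci(reflect(prot_tx)))
  expect_equal(fwd$assignments$upstream_distance, rev_$assignments$downstream_distance)
  expect_equal(fwd$assignments$downstream_distance, rev_$assignments$upstream_distance)
  expect_equal(fwd$assignments$upstream_id, rev_$assignments$downstream_id)
})

test_that("splice-site summary reports the canonical fraction", {
  ds <- default_dataset()
  expect_equal(splice_site_summary(dataset_lincrnas(ds), ds$genome), 1)
  # one non-canonical intron among ten
  ts_rows <- lapply(1:10, function(i) {
    off <- (i - 1L) * 300L
    make_tx(paste0("t", i), c(off, off + 150L), c(off + 50L, off + 200L))
  })
  ts <- do.call(rbind_ts, ts_rows)
  chars <- strsplit(strrep("A", 3000), "")[[1]]
  for (i in 1:10) {
    off <- (i - 1L) * 300L
    donor <- if (i == 1L) c("G", "C") else c("G", "T")
    chars[(off + 51):(off + 52)] <- donor
    chars[(off + 149):(off + 150)] <- c("A", "G")
  }
  g2 <- genome_sequence(c(chr1 = paste(chars, collapse = "")))
  expect_equal(splice_site_summary(ts, g2), 0.9)
  expect_error(splice_site_summary(make_tx("s", 0L, 100L), g2), "no introns")
})
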