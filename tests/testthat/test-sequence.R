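test_that("mature sequence extraction splices and strand-corrects", {
  g <- genome_sequence(c(chr1 = "AACGTT"))
  expect_equal(unname(extract_sequences(make_tx("t", 2L, 5L), g)), "CGT")
  # minus strand, exons [0,3) + [4,6): spliced "AACTT" -> revcomp "AAGTT"
  ts <- make_tx("t", c(0L, 4L), c(3L, 6L), strand = "-")
  expect_equal(unname(extract_sequences(ts, g)), "AAGTT")
  # strand "." behaves as "+"
  ts2 <- make_tx("t", c(0L, 4L), c(3L, 6L), strand = ".")
  expect_equal(unname(extract_sequences(ts2, g)), "AACTT")
  # out-of-bounds exon is a coordinate error
  expect_error(extract_sequences(make_tx("t", 2L, 9L), g), "coordinate error")
})

test_that("extracted length equals the sum of exon lengths", {
  ds <- default_dataset()
  linc <- dataset_lincrnas(ds)
  seqs <- extract_sequences(linc, ds$genome)
  expect_equal(nchar(seqs), mature_lengths(linc)[names(seqs)])
})

test_that("splice-site dinucleotides read on the transcript strand", {
  #            0123456789012345
  g <- genome_sequence(c(chr1 = "AAAGTTTTAGCCCCCC"))
  ts <- make_tx("t", c(0L, 10L), c(3L, 13L))
  s <- splice_site_dinucleotides(ts, g)
  expect_equal(s$donor, "GT")
  expect_equal(s$acceptor, "AG")
  # minus strand: genomic intron reading CT..AC gives GT..AG after correction
  g2 <- genome_sequence(c(chr1 = "AAACTTTTACCCCCCC"))
  ts2 <- make_tx("t", c(0L, 10L), c(3L, 13L), strand = "-")
  s2 <- splice_site_dinucleotides(ts2, g2)
  expect_equal(s2$donor, "GT")
  expect_equal(s2$acceptor, "AG")
  # single-exon transcript: empty result, not an error
  expect_equal(nrow(splice_site_dinucleotides(make_tx("t", 0L, 5L), g)), 0L)
  # intron of length 3 cannot yield two disjoint dinucleotides
  ts3 <- make_tx("t", c(0L, 6L), c(3L, 9L))
  expect_error(splice_site_dinucleotides(ts3, g), "intron")
})

test_that("six-frame translation follows the standard code and frame order", {
  expect_equal(unname(six_frame_translate("ATGGCCTAA")[["+1"]]), "MA*")
  # frame -1 equals frame +1 of the reverse complement, checked by hand:
  # revcomp("TTACATGGC") = "GCCATGTAA" -> GCC ATG TAA -> "AM*"
  expect_equal(unname(six_frame_translate("TTACATGGC")[["-1"]]), "AM*")
  fr <- six_frame_translate("ATGG")
  expect_equal(names(fr), c("+1", "+2", "+3", "-1", "-2", "-3"))
  expect_equal(nchar(fr[["+1"]]), 1L)
  expect_equal(fr[["+3"]], "")   # too short after the offset
  expect_error(six_frame_translate("ATXG"), "input error")
})

test_that("longest_orf agrees with a brute-force six-frame scan", {
  set.seed(42)
  for (i in 1:60) {
    seq <- paste(sample(c("A", "C", "G", "T"), sample(30:200, 1), replace = TRUE),
                 collapse = "")
    got <- longest_orf(seq)
    expect_equal(max(got$plus$codons, got$minus$codons),
                 brute_longest_orf_codons(seq),
                 info = paste("seq:", seq))
  }
})

test_that("coding-potential score has the documented extremes and sign rule", {
  # one ORF spanning the whole sequence, >= 300 codons -> coding, score ~ 1
  body <- strrep("GCT", 320)
  seq <- paste0("ATG", body, "TAA")
  s <- score_coding_potential(seq)
  expect_true(s$coding)
  expect_gt(s$score_plus, 0.9)
  # no ATG anywhere on either strand: both scores exactly -1
  s2 <- score_coding_potential(strrep("C", 120))
  expect_equal(s2$score_plus, -1)
  expect_equal(s2$score_minus, -1)
  expect_false(s2$coding)
  expect_error(score_coding_potential("AC%GT"), "input error")
})
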