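random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

test_that("homology search finds self-matches and honors the seed requirement", {
  set.seed(404)
  q <- c(q1 = random_dna(500))
  s <- c(s1 = q[["q1"]], s2 = random_dna(500))
  h <- homology_search(q, s)
  self <- h[h$subject_id == "s1", ]
  expect_gte(nrow(self), 1L)
  expect_gte(self$query_end[1] - self$query_start[1] + 1L, 490L)
  expect_lt(self$e_value[1], 1e-50)
  expect_equal(self$percent_identity[1], 100)
  # a query sharing no 11-mer with any subject yields nothing
  q2 <- c(q = strrep("AC", 50))
  s2 <- c(s = strrep("GT", 50))
  expect_equal(nrow(homology_search(q2, s2)), 0L)
  expect_equal(nrow(homology_search(character(0), s)), 0L)
})

test_that("homology search is symmetric on exact matches and E decreases with score", {
  set.seed(405)
  a <- c(a = random_dna(300))
  b <- c(b = paste0(random_dna(40), a[["a"]], random_dna(40)))
  ab <- homology_search(a, b)
  ba <- homology_search(b, a)
  expect_equal(nrow(ab), 1L)
  expect_equal(nrow(ba), 1L)
  expect_equal(ab$score, ba$score)
  # monotonicity of the Karlin-Altschul expectation in the raw score
  short <- c(q = substr(a[["a"]], 1, 100))
  h_short <- homology_search(short, b)
  expect_gt(h_short$e_value[1], ab$e_value[1])
  expect_gt(ab$score[1], h_short$score[1])
})

test_that("planted ortholog pairs are all recovered at E <= 1e-5", {
  ds <- default_dataset()
  linc <- dataset_lincrnas(ds)
  q <- extract_sequences(linc, ds$genome)
  s <- extract_sequences(ds$ortholog$ortholog_transcripts, ds$ortholog$genome)
  h <- homology_search(q, s)
  m <- ds$ortholog$ortholog_map
  found <- mapply(function(a, b) any(h$query_id == a & h$subject_id == b),
                  m$transcript_id, m$ortholog_id)
  expect_true(all(found))
  expect_true(all(h$e_value <= 1e-5))
})

test_that("boundary flags follow exon junction arithmetic", {
  ts <- make_tx("t", c(0L, 500L), c(300L, 900L)) # mature exons of 300 + 400
  expect_equal(boundary_conservation(301L, 700L, ts, "t"),
               list(start = "at_boundary", end = "internal"))
  expect_equal(boundary_conservation(10L, 250L, ts, "t"),
               list(start = "internal", end = "internal"))
  expect_equal(boundary_conservation(303L, 650L, ts, "t", tolerance = 5L)$start,
               "at_boundary")
  expect_equal(boundary_conservation(100L, 300L, ts, "t")$end, "at_boundary")
  expect_error(boundary_conservation(10L, 800L, ts, "t"), "outside")
})

test_that("liftover handles identity, inclusive ratio and missing chromosomes", {
  ident <- chain_mapping(data.frame(
    chain_id = "c", s_chrom = "chr1", s_start = 0L, s_end = 1000L,
    t_chrom = "oChr1", t_start = 0L, t_end = 1000L, orient = "+",
    stringsAsFactors = FALSE
  ))
  lr <- liftover_map("chr1", 100L, 300L, ident)
  expect_true(lr$success)
  expect_equal(c(lr$mapped_start, lr$mapped_end), c(100L, 300L))
  expect_equal(lr$mapped_base_ratio, 1)
  # half the interval in a deleted block: ratio exactly 0.5 still succeeds
  half <- chain_mapping(data.frame(
    chain_id = "c", s_chrom = "chr1", s_start = 0L, s_end = 200L,
    t_chrom = "oChr1", t_start = 0L, t_end = 200L, orient = "+",
    stringsAsFactors = FALSE
  ))
  lr2 <- liftover_map("chr1", 100L, 300L, half)
  expect_equal(lr2$mapped_base_ratio, 0.5)
  expect_true(lr2$success)
  lr3 <- liftover_map("chrX", 0L, 100L, ident)
  expect_false(lr3$success)
  expect_equal(lr3$mapped_base_ratio, 0)
})

test_that("liftover equals the per-base oracle on random fragmented chains", {
  set.seed(506)
  for (i in 1:500) {
    # random fragmented chain over [0, 400)
    cuts <- sort(sample(seq(10L, 390L, 5L), sample(2:6, 1)))
    edges <- unique(c(0L, cuts, 400L))
    keep <- runif(length(edges) - 1L) > 0.3
    if (!any(keep)) keep[1] <- TRUE
    blocks <- data.frame(
      chain_id = "c", s_chrom = "chr1",
      s_start = head(edges, -1L)[keep], s_end = edges[-1L][keep],
      t_chrom = "oChr1", orient = "+", stringsAsFactors = FALSE
    )
    blocks$t_start <- blocks$s_start + 1000L
    blocks$t_end <- blocks$s_end + 1000L
    chain <- chain_mapping(blocks)
    iv <- sort(sample.int(400L, 2L))
    if (iv[1] == iv[2]) iv[2] <- iv[2] + 1L
    got <- liftover_map("chr1", iv[1], iv[2], chain, min_ratio = 0.5)
    want <- brute_lift("chr1", iv[1], iv[2], chain)
    expect_equal(got$mapped_base_ratio, want$ratio, info = paste("case", i))
    if (got$success) {
      expect_equal(c(got$mapped_start, got$mapped_end),
                   c(min(want$images), max(want$images) + 1L))
      expect_gte(want$ratio, 0.5)
    } else {
      expect_lt(want$ratio, 0.5)
    }
  }
})

test_that("a complete lift through the inverse chain returns the original interval", {
  ds <- default_dataset()
  chain <- ds$ortholog$chain
  inv <- invert_chain(chain)
  loci <- gene_loci(dataset_lincrnas(ds))
  for (i in seq_len(nrow(loci))) {
    fwd <- liftover_map(loci$chrom[i], loci$start[i], loci$end[i], chain)
    if (!fwd$success || fwd$mapped_base_ratio < 1) next
    back <- liftover_map(fwd$mapped_chrom, fwd$mapped_start, fwd$mapped_end, inv)
    expect_true(back$success)
    expect_equal(c(back$mapped_start, back$mapped_end), c(loci$start[i], loci$end[i]))
  }
})

test_that("reciprocal overlap counting uses a >= 1 bp rule", {
  lifted <- list(
    a = liftover_map("chr1", 100L, 200L, chain_mapping(data.frame(
      chain_id = "c", s_chrom = "chr1", s_start = 0L, s_end = 1000L,
      t_chrom = "oChr1", t_start = 0L, t_end = 1000L, orient = "+",
      stringsAsFactors = FALSE
    )))
  )
  targets_touch <- data.frame(gene_id = "T", chrom = "oChr1", start = 199L, end = 300L)
  targets_apart <- data.frame(gene_id = "T", chrom = "oChr1", start = 200L, end = 300L)
  expect_equal(reciprocal_overlap_count(lifted, targets_touch)$count, 1L)
  expect_equal(reciprocal_overlap_count(lifted, targets_apart)$count, 0L)
})
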