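make_ct <- function(conds, target_ct, ref_ct, gene = "g", reference = "HPRT") {
  rows <- list()
  for (i in seq_along(conds)) {
    n <- length(target_ct[[i]])
    rows[[length(rows) + 1L]] <- data.frame(
      condition = conds[i], gene = gene, replicate = seq_len(n),
      ct = target_ct[[i]], stringsAsFactors = FALSE
    )
    rows[[length(rows) + 1L]] <- data.frame(
      condition = conds[i], gene = reference, replicate = seq_len(n),
      ct = ref_ct[[i]], stringsAsFactors = FALSE
    )
  }
  ct_table(do.call(rbind, rows))
}

test_that("ddCt arithmetic: 0 -> fold 1, +1 -> 0.5, -2 -> 4", {
  ct <- make_ct(c("cal", "same", "up", "down"),
                list(rep(25, 3), rep(25, 3), rep(23, 3), rep(26, 3)),
                list(rep(20, 3), rep(20, 3), rep(20, 3), rep(20, 3)))
  q <- ddct_quantify(ct, "g", "HPRT", "cal")
  expect_equal(q$mean_fold[q$condition == "same"], 1)
  expect_equal(q$mean_fold[q$condition == "up"], 4)    # ddCt = -2
  expect_equal(q$mean_fold[q$condition == "down"], 0.5) # ddCt = +1
  expect_equal(q$sem_fold, q$sd_fold / sqrt(q$n))
})

test_that("ddCt is invariant to adding a constant to every Ct", {
  ct <- generate_ct_table(data.frame(condition = c("A", "B"), gene = "g", fold = c(1, 3)),
                          n_replicates = 5L, noise_sd = 0.3, seed = 8L)
  shifted <- ct
  shifted$ct <- shifted$ct + 7.5
  q1 <- ddct_quantify(ct, "g", "HPRT", "A")
  q2 <- ddct_quantify(ct_table(shifted), "g", "HPRT", "A")
  expect_equal(q1$mean_fold, q2$mean_fold, tolerance = 1e-12)
})

test_that("ddCt errors name missing pairings and calibrators", {
  ct <- make_ct("cal", list(rep(25, 3)), list(rep(20, 3)))
  expect_error(ddct_quantify(ct, "g", "HPRT", "nope"), "calibrator")
  broken <- ct[!(ct$gene == "HPRT" & ct$replicate == 2L), ]
  expect_error(ddct_quantify(ct_table(broken), "g", "HPRT", "cal"), "cal 2")
})

test_that("percent input follows the dilution-adjusted identity", {
  expect_equal(percent_input(25, 25, 1), 100)
  expect_equal(percent_input(25, 25, 0.01), 1, tolerance = 1e-9)
  # IP enriched by 3 cycles over the adjusted input
  expect_equal(percent_input(25 - log2(100) - 3, 25, 0.01), 800, tolerance = 1e-9)
  expect_error(percent_input(25, 25, 0), "input_fraction")
  # identity holds for any Ct
  for (ct in c(10, 18.3, 30)) expect_equal(percent_input(ct, ct, 1), 100)
})

test_that("two-sample t matches the textbook pooled formula to 1e-9", {
  set.seed(607)
  for (i in 1:100) {
    x <- rnorm(sample(3:10, 1), mean = runif(1, -2, 2))
    y <- rnorm(sample(3:10, 1), mean = runif(1, -2, 2))
    got <- two_sample_t(x, y)
    want <- brute_t_test(x, y)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-9)
  }
  same <- c(1, 2, 3)
  r <- two_sample_t(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_lt(two_sample_t(c(1, 2, 3), c(11, 12, 13))$p_value, 0.01)
  expect_error(two_sample_t(c(1, 1, 1), c(1, 1, 1)), "variance")
})

test_that("fraction enrichment reports nuclear/cytoplasmic ratios", {
  base <- data.frame(
    condition = "cells", gene = rep(c("g", "HPRT"), each = 6),
    replicate = rep(1:3, 4),
    fraction = rep(rep(c("nuclear", "cytoplasmic"), each = 3), 2),
    ct = c(rep(24, 3), rep(26, 3), rep(20, 6)),
    stringsAsFactors = FALSE
  )
  ct <- ct_table(base)
  # nuclear dCt = 4, cytoplasmic dCt = 6 -> ratio 2^2 = 4 (nuclear-enriched)
  expect_equal(fraction_enrichment(ct, "g", reference = "HPRT"), 4)
  even <- base
  even$ct[even$gene == "g"] <- 24
  expect_equal(fraction_enrichment(ct_table(even), "g", reference = "HPRT"), 1)
  expect_error(fraction_enrichment(ct_table(base[base$fraction == "nuclear", ]), "g",
                                   reference = "HPRT"), "missing fraction")
})

test_that("noisy simulations recover the planted fold within 10% at the median", {
  set.seed(708)
  folds <- replicate(200, {
    seed <- sample.int(1e6, 1)
    ct <- generate_ct_table(data.frame(condition = c("cal", "trt"), gene = "g",
                                       fold = c(1, 4)),
                            n_replicates = 6L, noise_sd = 0.2, seed = seed)
    q <- ddct_quantify(ct, "g", "HPRT", "cal")
    q$mean_fold[q$condition == "trt"]
  })
  expect_lt(abs(median(folds) - 4) / 4, 0.10)
})
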