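#' qPCR cycle-threshold tables
#'
#' A Ct table is a data.frame with columns `condition` (sample/condition
#' label), `gene`, `replicate` (integer, unique within condition x gene) and
#' `ct` (cycles, finite and > 0); an optional `fraction` column
#' (`nuclear` / `cytoplasmic` / `whole`) supports fractionation analyses.
#' `read_ct_table()` / `write_ct_table()` exchange this layout as CSV with a
#' header.
#'
#' @param df data.frame with the columns above.
#' @return a validated `ct_table` data.frame.
#' @export
ct_table <- function(df) {
  req <- c("condition", "gene", "replicate", "ct")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing Ct columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(df$ct)) || any(df$ct <= 0)) stop("Ct values must be finite and > 0")
  key <- paste(df$condition, df$gene, df$replicate,
               if ("fraction" %in% names(df)) df$fraction else "")
  if (anyDuplicated(key)) stop("replicate indices must be unique within (condition, gene)")
  class(df) <- c("ct_table", "data.frame")
  df
}

#' @rdname ct_table
#' @param path CSV path.
#' @export
read_ct_table <- function(path) {
  ct_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname ct_table
#' @param ct a `ct_table`.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = Ct(target) - Ct(reference)`; `ddCt` subtracts the
#' mean calibrator-condition dCt; the fold-change is `2^-ddCt`. Replicate
#' pairing of target and reference wells is positional (by replicate index).
#' Results are aggregated per condition with mean, SD, SEM
#' (`SEM = SD / sqrt(n)`) and n; both dispersion measures are reported.
#'
#' @param ct a [ct_table].
#' @param target target gene id.
#' @param reference reference (housekeeping) gene id.
#' @param calibrator condition label used as the calibrator.
#' @return data.frame of class `quant_result`: one row per condition with
#'   `mean_fold`, `sd_fold`, `sem_fold`, `n`, `mean_ddct`.
#' @export
ddct_quantify <- function(ct, target, reference, calibrator) {
  dct <- delta_ct(ct, target, reference)
  if (!calibrator %in% dct$condition) {
    stop(sprintf("calibrator condition '%s' not present", calibrator))
  }
  cal <- mean(dct$dct[dct$condition == calibrator])
  dct$ddct <- dct$dct - cal
  dct$fold <- 2^(-dct$ddct)
  agg <- do.call(rbind, lapply(split(dct, dct$condition), function(d) {
    data.frame(
      condition = d$condition[1L],
      mean_fold = mean(d$fold),
      sd_fold = stats::sd(d$fold),
      sem_fold = stats::sd(d$fold) / sqrt(nrow(d)),
      n = nrow(d),
      mean_ddct = mean(d$ddct),
      stringsAsFactors = FALSE
    )
  }))
  agg <- agg[match(unique(dct$condition), agg$condition), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("quant_result", "data.frame")
  agg
}

# per-replicate dCt with positional reference pairing
delta_ct <- function(ct, target, reference, fraction = NULL) {
  sel <- function(gene) {
    d <- ct[ct$gene == gene, , drop = FALSE]
    if (!is.null(fraction)) d <- d[d$fraction == fraction, , drop = FALSE]
    d
  }
  tg <- sel(target)
  rf <- sel(reference)
  if (!nrow(tg)) stop(sprintf("no Ct records for target gene '%s'", target))
  key_t <- paste(tg$condition, tg$replicate)
  key_r <- paste(rf$condition, rf$replicate)
  miss <- setdiff(key_t, key_r)
  if (length(miss)) {
    stop("missing reference Ct for (condition, replicate): ", paste(miss, collapse = "; "))
  }
  data.frame(
    condition = tg$condition, replicate = tg$replicate,
    dct = tg$ct - rf$ct[match(key_t, key_r)],
    stringsAsFactors = FALSE
  )
}

#' RIP enrichment by the percent-input method
#'
#' Adjusts the input Ct for the fraction of lysate saved as input
#' (`adjusted = ct_input - log2(1 / input_fraction)`) and reports
#' `100 * 2^(adjusted - ct_ip)`. With `ct_ip == ct_input` and the whole
#' lysate as input the result is 100%.
#'
#' @param ct_ip Ct of the immunoprecipitated sample.
#' @param ct_input Ct of the input sample.
#' @param input_fraction fraction of lysate saved as input, in `(0, 1]`.
#'   There is no default: report it from the experiment.
#' @return percent of input (vectorized).
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction) {
  if (any(input_fraction <= 0) || any(input_fraction > 1)) {
    stop("input_fraction must be in (0, 1]")
  }
  adjusted <- ct_input - log2(1 / input_fraction)
  100 * 2^(adjusted - ct_ip)
}

#' Two-tailed unpaired Student's t-test
#'
#' Classical equal-variance two-sample t-test (Welch available via
#' `var_equal = FALSE`), returning the t statistic and the two-tailed
#' p-value from the t distribution with `n1 + n2 - 2` degrees of freedom.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @param var_equal pool the variances (Student) or not (Welch).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs n >= 2")
  if (stats::var(x) + stats::var(y) == 0) stop("zero pooled variance")
  fit <- stats::t.test(x, y, var.equal = var_equal, alternative = "two.sided")
  list(statistic = unname(fit$statistic), p_value = fit$p.value,
       df = unname(fit$parameter))
}

#' Nuclear/cytoplasmic enrichment ratio
#'
#' Computes `2^-(dCt_nuclear - dCt_cytoplasmic)` with dCt taken against a
#' reference gene within each fraction (mean over replicates). A ratio > 1
#' means nuclear-enriched.
#'
#' @param ct a [ct_table] with a `fraction` column.
#' @param gene target gene id.
#' @param nuclear_label,cytoplasmic_label values of `fraction` naming the
#'   two fractions.
#' @param reference reference gene id.
#' @return the enrichment ratio (numeric scalar).
#' @export
fraction_enrichment <- function(ct, gene, nuclear_label = "nuclear",
                                cytoplasmic_label = "cytoplasmic",
                                reference = "HPRT") {
  if (!"fraction" %in% names(ct)) stop("ct table has no 'fraction' column")
  mean_dct <- function(fr) {
    d <- ct[ct$fraction == fr, , drop = FALSE]
    if (!nrow(d)) stop(sprintf("missing fraction '%s'", fr))
    mean(delta_ct(d, gene, reference)$dct)
  }
  2^(-(mean_dct(nuclear_label) - mean_dct(cytoplasmic_label)))
}
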