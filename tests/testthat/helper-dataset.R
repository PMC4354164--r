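# One frozen synthetic dataset (seed 1 defaults), generated once per test run
# and shared by the pipeline, characterization, conservation and acceptance
# tests.
default_dataset <- local({
  ds <- NULL
  function() {
    if (is.null(ds)) ds <<- simulate_dataset(synthetic_config())
    ds
  }
})

dataset_lincrnas <- function(ds) {
  subset_transcripts(ds$transcripts, ds$truth$transcript_id[ds$truth$class == "lincRNA"])
}

run_default_pipeline <- function(ds) {
  run_pipeline(
    ds$transcripts, ds$genome, gene_loci(ds$protein_annotation),
    ds$utr_intervals, ds$hits$protein, ds$hits$domain, ds$hits$rna_family
  )
}
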