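---
title: "Identifying multi-exon lincRNAs: methods and design notes"
author: "lincseek authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying multi-exon lincRNAs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lincseek)
```

## The problem

Long intergenic non-coding RNAs (lincRNAs) are spliced transcripts of at
least 200 nt that lie between protein-coding genes and have no appreciable
protein-coding capacity. When a transcriptome is assembled from RNA-seq
(e.g. with Cufflinks/StringTie), the assembly mixes genuine lincRNAs with
protein-coding transcripts, assembly fragments, UTR pieces of neighboring
mRNAs, and small structural RNAs. `lincseek` implements the stringent filter
cascade commonly used to purify a multi-exon lincRNA catalog from such an
assembly, plus the downstream characterization and validation arithmetic.

## The filter cascade

`run_pipeline()` applies seven stages in a fixed order; each stage returns
its survivors and an auditable report entry (`n_input = n_removed +
n_surviving` holds at every stage, and stage *k+1*'s input is stage *k*'s
survivor set):

1. **Size/exon selection.** Single-exon transcripts and transcripts with
   mature (spliced) length < 200 nt are removed. "Length" everywhere in this
   package means mature length, not genomic span; the removal rule is
   strict, so a 200-nt transcript survives.
2. **Protein-coding gene overlap.** Any transcript whose genomic span
   overlaps an annotated protein-coding gene locus by ≥ 1 base is removed,
   strand-agnostically. We read "overlap (>1 bp)" as *any overlap of at
   least one base*: the stricter reading (≥ 2 bases) would let one-base
   overlaps with coding genes through, which contradicts the intent of a
   stringent intergenic filter. Overlap is evaluated on locus spans, because
   the rule names *genes*; an exon-level mode is available via
   `exon_level = TRUE`.
3. **Coding potential.** Each transcript is scored on both strands and
   removed when either strand scores strictly above 0. The built-in score is
   an ORF-feature stand-in for CPC-style classifiers:
   `s = min(L, 300)/300 + C − 1`, with `L` the longest ATG-initiated ORF
   (codons, excluding the stop; truncated ORFs running off the end count)
   and `C = 3L / mature length` its coverage. It is calibrated so that a
   full-length ORF of ≥ 300 codons scores ≈ +1 and an ATG-free sequence
   scores −1. External score tables (e.g. real CPC output) drop in via
   `cpc_scores`; the sign convention (coding ⇔ score > 0) is the contract.
4. **Protein similarity.** Transcripts with a protein-database hit at
   E ≤ 1e−5 are removed (threshold inclusive).
5. **Protein domains.** Transcripts whose six-frame translations have a
   domain hit at E ≤ 1e−5 in any frame are removed. The significance
   threshold for domain hits is not independently standardized, so we default
   to the same 1e−5 as stage 4; it is configurable.
6. **Small-RNA families.** Transcripts with an RNA-family hit in
   {snRNA, snoRNA, tRNA, miRNA, rRNA} are removed; the class set is
   configurable.
7. **UTR fragments.** Incomplete assemblies often leave fragments of mRNA
   UTRs that pass the span-overlap stage. A transcript whose mature length
   is covered > 90% by annotated UTR intervals of curated (`NM_`) reference
   mRNAs is discarded; exactly 90% survives ("more than 90%" is strict).
   Coverage is computed on genomic coordinates against annotated UTR
   intervals, which is deterministic and needs no re-alignment; a hit-table
   route is possible by restricting nucleotide alignments to UTR intervals
   upstream.

Surviving transcripts are grouped into lincRNA gene loci by their assembler
`gene_id`; isoforms per locus is the transcript/locus ratio.

Separately, `classify_protein_coding()` labels multi-exon transcripts as
protein-coding when a nucleotide alignment to a reference mRNA reaches
≥ 96% identity and covers ≥ 90% of that mRNA (both inclusive).

## The synthetic data generator

No public accession provides the original assembly this kind of pipeline is
run on, and the pipeline's correctness claims are about *decisions*, not
about any particular genome. The generator therefore plants a fully labelled
toy dataset; its defaults are frozen as the package's study conditions:

* genome: 2 chromosomes × 200 kb, i.i.d. uniform A/C/G/T, seed 1;
* 30 lincRNA transcripts over 25 loci (five loci carry a second isoform,
  giving the 1.2 isoforms/locus typical of lincRNA catalogs). Exon counts
  follow P(2,3,4) = (0.66, 0.25, 0.09) and mature lengths are uniform on
  600–1500 nt, emulating the ~1 kb / ~2.5-exon / ~66% two-exon structure
  reported for mammalian muscle lincRNA catalogs;
* 30 coding transcripts with a planted ORF covering ≥ 80% of the mature
  length and annotated 5′/3′ UTRs. One third are planted at loci *absent*
  from the protein annotation, emulating incomplete annotation: these must
  fall at the coding-potential stage, the rest at the overlap stage;
* 10 decoys each: single-exon, short (< 200 nt), UTR fragments and
  small-RNA-like transcripts (70–150 nt, with Rfam-style family hits).

Design choices worth recording:

* **ORF suppression.** Planted lincRNAs must be non-coding *by
  construction*. All six frames of every lincRNA mature sequence are
  scanned, and any open stretch (ATG-initiated, no stop yet) is cut by
  overwriting a codon with TAA before it reaches the suppression threshold;
  the scan iterates (isoforms share exonic bases) until all frames of all
  isoforms are clean. The threshold is `min(99, floor(L/7))` codons: the cap
  of 99 codons alone would allow an ORF covering up to 98% of a minimal
  300-nt transcript and hence a *positive* coding score, so the threshold
  adapts to short transcripts, guaranteeing ORF coverage ≤ 3/7 and a
  strictly negative score at every length. At the default lengths (≥ 600 nt)
  the 99-codon cap is the active constraint for most transcripts.
* **UTR fragments and stage order.** UTR-fragment decoys are planted inside
  the 3′ UTR of dedicated *host* genes that appear in the UTR annotation but
  not in the protein annotation used by stage 2 (annotation sets from
  different sources rarely coincide; RefSeq-only genes are common). This
  makes stage 7 the only stage that can remove them, so the fixture
  exercises the cascade's last line of defense.
* **Repeats.** 65% of lincRNAs carry one planted repeat; the covered
  fraction among bearers is Beta(1, 2.56) — mean 0.28 and P(≥ 0.5) ≈ 0.19,
  matching the 65% / 28% / ~13% repeat statistics typical of mammalian
  lincRNA catalogs. Family labels are drawn from a categorical distribution
  with SINE+LINE ≈ 58% and LTR ≈ 15.5% of features. Repeats are annotation
  only; the sequence is untouched.
* **Ortholog genome.** A copy of the genome with 5% i.i.d. substitutions and
  an identity chain split into blocks; the blocks under 20% of the lincRNA
  loci are deleted so those loci must fail the lift, while every mappable
  locus lifts with ratio ≈ 1. No indels are simulated, so the built-in
  ungapped homology search is expected to recover every planted pair — the
  fixture tests threshold behavior, not gapped-alignment sensitivity.
* **Ct tables.** `Ct(target) = 25 − log2(fold) + ε`, reference fixed at 20,
  `ε ~ N(0, 0.2²)` cycles, six replicates — the usual scale of qPCR
  validation panels. With `noise_sd = 0` the planted fold is recovered
  exactly, which pins the ΔΔCt arithmetic.

What passing on this fixture does **not** show: robustness to indels and
rearrangements, to fuzzy gene boundaries, to assembly artifacts other than
the planted decoy classes, to GC/repeat sequence composition bias, or to
real CPC/BLAST/HMMER score distributions. The generator's purpose is
decision-level correctness with planted truth, not realism of sequence
composition.

## Conservation analysis

* `homology_search()` is a deliberately small seed-and-extend nucleotide
  searcher: exact 11-mer seeds, ungapped X-drop extension (+1/−2, X-drop
  20), Karlin–Altschul expectation `E = K·m·n·e^(−λS)` with fixed λ = 1.28,
  K = 0.46 (the standard values for +1/−2 scoring) over the concatenated
  subject length. Matching NCBI BLASTN E-values digit-for-digit is a
  non-goal; the contract is behavior at the E ≤ 1e−5 threshold, and real
  BLAST outfmt-6 tables can be substituted anywhere.
* `liftover_map()` maps every base through its containing chain block and
  succeeds when the mapped-base ratio is ≥ `min_ratio` (inclusive, matching
  liftOver's `-minMatch` semantics) and all images share one target
  chromosome and orientation; split lifts are failures. The default
  `min_ratio = 0.5` mirrors common usage for noncoding loci.
* `boundary_conservation()` flags a conserved segment end as `at_boundary`
  when it coincides with an internal exon junction in mature coordinates
  (tolerance 0 by default); transcript ends do not count as junctions.
* Overlap counting between lifted loci and target loci again uses the ≥ 1
  base rule, consistent with stage 2.

## Expression assay arithmetic

* `ddct_quantify()` implements the standard 2^−ΔΔCt method with positional
  replicate pairing and the arithmetic mean of calibrator ΔCt. Figure-style
  summaries report both SD and SEM, labelled, since conventions differ
  between methods sections (SD) and figure legends (SEM).
* `percent_input()` adjusts the input Ct by `log2(1/input_fraction)` before
  comparing with the IP Ct. The input fraction is a required argument with
  no default — it is an experimental parameter that must be reported, not
  assumed.
* `two_sample_t()` is the classical equal-variance two-tailed test ("
  Student's"); Welch's correction is available behind `var_equal = FALSE`.
* `fraction_enrichment()` compares reference-normalized ΔCt between nuclear
  and cytoplasmic fractions; ratios above 1 mean nuclear enrichment.

## Numerical conventions and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; GTF and
  RepeatMasker tables (1-based inclusive) convert at the I/O boundary, and
  `IRanges`/`GRanges` (1-based closed) wherever they are built. Half-open
  adjacency means adjacent spans overlap by zero bases.
* Strand "." is treated as "+" for sequence extraction and as
  strand-agnostic in all overlap filters (assemblers emit unstranded
  transcripts; the overlap rules are positional).
* A single-exon transcript has an empty splice-site list (not an error); an
  intron shorter than 4 nt cannot yield donor and acceptor dinucleotides and
  is an error.
* Neighbor distances are gaps between half-open spans, strictly positive
  and strictly below the 10 kb window; overlapping and directly abutting
  protein genes are excluded. Upstream/downstream are genomic left/right,
  ignoring strand, since assembled lincRNA strand is often unknown.
* RepeatMasker family strings collapse on the text before `/` into the
  closed set {SINE, LINE, LTR, DNA, Simple_repeat, Low_complexity, Other};
  per-transcript repeat coverage unions overlapping features, while family
  percentages count features.
* Per-transcript repeat-fraction histograms use the ten bins
  [0,10), …, [90,100], with repeat-free transcripts in the first bin.

## Problem sizes

The frozen fixture (100 transcripts on 400 kb) runs the full cascade in a
few seconds and the complete test suite, including the brute-force oracle
comparisons (≥ 500 randomized instances per interval operation), in about
two minutes on one CPU. These sizes were chosen so that every claim is
re-checked from scratch on every run; all statistics scale linearly if a
larger fixture is configured.

## Known limitations

* The homology searcher is ungapped; diverged orthologs with indels need an
  external aligner (its tabular output is accepted as a drop-in).
* The built-in coding score is a two-feature stand-in, not a trained
  classifier; borderline transcripts (short ORF, high coverage) are best
  re-scored with a dedicated tool via the score-table route.
* GO enrichment of neighbor genes is out of scope: the package produces the
  deduplicated neighbor gene list that enrichment services consume.
* The generator plants substitutions only (no indels, no rearrangements)
  and uniform base composition.
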