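# txbench

Benchmarking toolkit for **full-length transcript reconstruction from
RNA-Seq**. Assemblers such as Cufflinks and StringTie infer transcript
models (GTF) and abundances (FPKM) from short reads; judging their accuracy
needs data where the full-length truth is known and a scoring rule that
separates what is recoverable (internal splice junctions) from what is not
(transcription start/end). txbench builds that benchmark end to end, for
anyone developing or evaluating transcript assembly and quantification
methods:

* **Fixture generator** — synthetic genome (FASTA) and non-overlapping
  single-isoform gene annotation (GTF), so nothing needs downloading.
* **Truth designer** — controlled alternative splicing on top of the base
  annotation: exon skipping, truncation (alternate transcription
  start/end) and splice-site shifts (mostly in-frame, by multiples of 3),
  never mixed within a gene; the canonical design is 1,000 single-form
  genes plus 1,000 genes per category for each of 2–5 forms per gene —
  13,000 genes, 43,000 splice forms.
* **Read simulator** — strand-specific paired-end reads (FASTQ) with
  configurable polymorphism (substitutions + indels on one haplotype),
  sequencing error and pre-mRNA intron signal; plus a *perfect* truth
  alignment (SAM, against the reference through an indel coordinate map),
  a per-fragment truth table and true FPKM from actual exonic fragment
  counts.
* **Annotation corruptor** — the deliberately imperfect gene-model file
  used for annotation-guided assembly: hide a fraction of expressed
  transcripts, optionally replacing each with an unexpressed decoy of the
  same gene, under a ledger.
* **Evaluator** — junction-chain precision/recall with comfort-zone flags
  (recall ≥ 25% and precision ≥ 66.6%), stratified by annotation status,
  event category, forms per gene and coverage bin; FPKM agreement via
  Pearson correlation after separating on/off errors; base-level alignment
  accuracy of any SAM against the truth SAM.

The matching rule: a predicted transcript is a **true positive** iff its
ordered chain of internal junction coordinates
((end(e₁),start(e₂)), …, (end(e₍ₙ₋₁₎),start(eₙ))) is identical to a truth
transcript's chain on the same chromosome and strand — terminal coordinates
are ignored. One wrong junction ⇒ false positive; an expressed truth form
never matched ⇒ false negative. Single-exon forms match by ≥ 50% reciprocal
overlap.

## Worked example

```r
library(txbench)

## 1. fixture genome + 30 single-isoform genes
cfg    <- fixture_config(n_genes = 30, chromosome_length = 1e6, seed = 1)
genome <- generate_genome(cfg)
base   <- generate_annotation(genome, cfg)

## 2. truth set: 3 single-form genes + 2x2 genes per splicing category
truth <- build_t1_truth(base, t1_design(n_single_form_genes = 3,
  per_category_counts = c(`2` = 2L, `3` = 2L), seed = 1))
truth
#> <truth_annotation> 15 genes, 33 transcripts
#>         category     N
#> 1:   SINGLE_FORM     3
#> 2: EXON_SKIPPING     4
#> 3:    TRUNCATION     4
#> 4:  SPLICE_SHIFT     4

## 3. simulate 100-base paired-end reads at uniform 40x coverage
profile <- assign_expression(truth, uniform_coverage(40))
attr(profile, "model") <- uniform_coverage(40)
sim <- simulate_dataset(genome, truth, profile, simulation_config(seed = 1))
head(sim$true_quant, 3)
#>    transcript_id fragments     fpkm coverage
#> 1:     G00001.T1       369 24285.26 37.84615
#> 2:     G00002.T1       370 24991.89 38.94737
#> 3:     G00003.T1       381 25075.03 39.07692

## 4. corrupt the annotation (hide 40% of expressed forms, plant decoys)
##    and score it as if an assembler had just echoed the provided models
cor <- corrupt_annotation(truth, profile, hide_fraction = 0.4,
                          replace = TRUE, seed = 1)
cls <- classify_predictions(cor$annotation, truth, sim$true_quant, cor$ledger)
cls
#> <tx_classification> TP 18, FP 13, FN 13 | precision 0.581, recall 0.581
```

Reading the numbers: each transcript's `coverage` is its realised per-base
exonic depth (target 40×; 369 fragments × 200 sequenced bases / spliced
length), and `fpkm` the true abundance computed from the fragments the
simulator actually emitted. In step 4 the "call everything provided"
predictor recovers the 18 retained expressed forms (TP), wrongly reports
the 13 planted unexpressed decoys (FP), and misses the 13 hidden expressed
forms (FN) — precision and recall 0.581, outside nothing yet, but any real
assembler is scored the same way from its GTF via `read_gtf()`.

A shell front-end wraps the same pipeline
(`txbench make-fixture | design-t1 | simulate | corrupt | evaluate`); see
`exec/txbench --help`. Every run writes a JSON manifest with its config and
seed, and all outputs are byte-reproducible from the seed.

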