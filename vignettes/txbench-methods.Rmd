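---
title: "Benchmarking transcript reconstruction with txbench: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking transcript reconstruction with txbench: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Reconstructing full-length mRNA splice forms from short-read RNA-Seq is hard:
short reads rarely span more than one junction, so assemblers must stitch
local evidence into global transcript models, and they make many mistakes
doing it. Judging *how many* mistakes requires data where the full-length
truth is known — which in practice means simulation with a controlled truth
set, plus a scoring rule that separates the recoverable part of a transcript
(its internal junctions) from the part nobody can recover reliably (its
transcription start and end).

txbench provides that benchmark scaffolding end to end: a synthetic genome
and annotation fixture, a truth designer with controlled alternative
splicing, a strand-specific paired-end read simulator that also emits a
*perfect* truth alignment, an annotation corruptor that models imperfect
gene-model files, and an evaluator implementing junction-chain
precision/recall with coverage and event-category stratification. The
package never runs an assembler or aligner itself; it produces their inputs
and scores their outputs (GTF, SAM, FPKM tables).

## Matching identity: the junction chain

A transcript with exons $e_1, \dots, e_n$ (disjoint, in genomic order)
determines the *junction chain*

$$ J = \big( (\mathrm{end}(e_1), \mathrm{start}(e_2)), \dots,
             (\mathrm{end}(e_{n-1}), \mathrm{start}(e_n)) \big), $$

the ordered internal exon/exon boundary pairs. A predicted multi-exon
transcript is a **true positive** iff some truth transcript on the same
chromosome and strand has an identical chain — the first exon's start and
the last exon's end are deliberately ignored, because transcription
boundaries are notoriously hard to infer and penalising them would swamp the
signal. One wrong junction makes a **false positive**. An expressed truth
transcript never matched is a **false negative**. From these,
$\mathrm{precision} = TP/(TP+FP)$ and $\mathrm{recall} = TP/(TP+FN)$, and
results with recall < 25% or precision < 66.6% are flagged as outside the
"comfort zone" where error rates are usable in practice.

Three choices here were genuinely open and are worth recording:

* **Single-exon transcripts** have an empty chain, so junction matching is
  vacuous. They are matched by ≥ 50% reciprocal exon overlap — the weakest
  criterion still consistent with "right number of exons"; the threshold is
  exposed in `evaluation_config()`.
* **Duplicate predictions** of one truth form count as one TP; the surplus
  counts neither as TP nor FP. This keeps precision invariant under an
  assembler emitting the same model twice.
* **Expression gating of FN**: only truth transcripts with at least
  `fn_expression_threshold` true exonic fragments (default 1) can be false
  negatives — a form that contributed no reads cannot reasonably be demanded
  of any algorithm.

Unstranded predictions (strand `"."`) match either strand, with a log note.

## The truth designer

`build_t1_truth()` turns a single-isoform base annotation into a truth set
with a controlled layout: a block of single-form genes (required to have at
least 5 exons), then, for each of three alternative-processing categories,
blocks of genes carrying 2–5 forms. The canonical design is 1,000
single-form genes plus 1,000 genes per category per form count — 13,000
genes, 43,000 transcripts. Categories are never mixed within a gene, so
accuracy can be isolated per event type:

* **exon skipping** — remove k internal exons, k uniform on
  {1, …, min(2, n internal)}; terminals kept;
* **truncation** (alternate transcription start/end) — drop a prefix and/or
  suffix of exons, uniform over admissible pairs, possibly down to a single
  exon;
* **splice shift** — move one junction-adjacent exon boundary by δ, with
  δ a multiple of three ({±3, ±6, ±9}) with probability 0.9 and ±1/±2
  otherwise, reflecting the in-frame bias of real alternate splice sites;
  shifts breaking exon or intron positivity are redrawn.

Each variant carries 1 + Poisson(0.5) events of its gene's category (capped
by admissibility): most variants are a single event, occasional variants are
compound. Forms within a gene must be pairwise distinct on (junction chain,
terminal coordinates) — two forms may share all junctions if their
transcription boundaries differ. A gene that cannot yield enough distinct
forms within the retry budget is substituted by the next candidate, with a
log count. Splice-site sequence motifs are *not* maintained (or created):
nothing downstream of alignment reads the genome sequence, and txbench
scores coordinates only.

## The read simulator

Expression is assigned by one of two models. `uniform_coverage(40)` gives
every transcript a molecule weight proportional to its spliced length, so
expected per-base depth is flat; the fragment count that realises the target
is `ceiling(target * total_length / (2 * read_length))`, since each fragment
contributes two mates of `read_length` sequenced bases.
`exponential_expression(rate = 0.01, expressed_fraction = 2/3)` expresses
each transcript independently with probability 2/3 and draws expressed
weights from Exponential(0.01) — a long-tailed spectrum typical of quality
bulk data.

Fragments are drawn with replacement, transcript chosen with probability
proportional to weight. Fragment length follows a truncated normal —
Normal(300, 1000/3) rounded and rejected outside [200, 500] by default; for
molecules shorter than the maximum the upper truncation tightens to the
molecule length, and molecules shorter than the *minimum* fragment length
contribute no fragments at all (short genes are under-represented, which is
why gene sets are pre-filtered at 200 bases). Mate 1 is the first
`read_length` bases of the fragment on the transcript strand and mate 2 the
reverse complement of the last `read_length` bases (forward-stranded
protocol; `orientation = "RF"` swaps the roles).

Three noise processes are configurable and all default to zero:

* **polymorphism** — the reads are sequenced from one polymorphic haplotype:
  substitutions at `substitution_frequency` per base, indels seeded at
  `indel_frequency` per base (insertion/deletion with equal odds, lengths
  uniform on {1,2,3} — small indels dominate real polymorphism). A
  per-chromosome coordinate map records the alignment between haplotype and
  reference;
* **sequencing error** — each sequenced base is substituted with probability
  `basewise_error` (quality strings are a constant Phred 40: the error model
  is a rate, not a quality profile);
* **intron signal** — with probability `intron_frequency` a fragment is
  drawn from the source gene's *unspliced* pre-mRNA instead of the mature
  transcript. Because introns are typically much longer than exons, a
  sizeable intron-signal rate still yields very low per-base intronic
  coverage; a property test asserts intronic coverage stays below exonic
  coverage on a fixture with 10:1 intron:exon length.

The truth alignment (SAM text, coordinate-sorted, `@SQ` from the reference)
is expressed against the **reference** genome, not the haplotype, so aligner
outputs are directly comparable: transcript coordinates are lifted through
the coordinate map, producing `N` operations across spliced-out introns and
`I`/`D` operations at indel polymorphisms; reads starting or ending inside
an insertion are soft-clipped. The truth table records, per fragment, the
source transcript (or intron-signal flag), the per-mate reference blocks and
the fragment length; per-transcript *true FPKM* is computed from the actual
exonic fragment counts,

$$ \mathrm{FPKM}_t = \frac{C_t}{(L_t/10^3)\,(N/10^6)}, $$

never from theoretical intensities, and intron-signal fragments are never
counted as exonic. Mean coverage is $2\,C_t\,\ell / L_t$ with $\ell$ the
read length.

## Annotation corruption

Real gene-model files miss expressed transcripts and contain unexpressed
ones. `corrupt_annotation()` reproduces both defects: it hides
`round(hide_fraction * n_expressed)` expressed transcripts uniformly at
random (rounding half-up) and, when `replace = TRUE`, plants for each hidden
transcript a freshly generated *unexpressed* decoy variant of the same gene,
keeping the provided annotation's size constant. With a realistic expression
spectrum about a third of the annotation is already unexpressed, so
`replace = FALSE` (removal only) is the natural mode there.

Decoys are generated with the gene's own event category when known, starting
from the gene's most exon-rich form, and are required to be **junction-chain
distinct** from every form of their gene (or, for single-exon decoys, below
50% reciprocal overlap). This is deliberately stricter than the
(chain, terminals) distinctness used inside a truth gene: a decoy differing
from an expressed form only at its terminals would be matched by the
junction-chain criterion and could never be scored a false positive, which
would defeat the decoy's purpose. A gene where no such decoy is
constructible is hidden without replacement, with a log count. The ledger
(retained / hidden_expressed / planted_decoy) is what the evaluator uses to
stratify results into annotated vs hidden.

## What the fixtures emulate — and what they do not

`generate_genome()` draws i.i.d. bases at a configurable GC fraction and
`generate_annotation()` places non-overlapping single-isoform genes
left-to-right with uniform gaps in [gap, 2·gap], exon counts and exon/intron
lengths from configurable discrete laws. This is enough for everything the
toolkit measures, because all scoring is coordinate-based. It does **not**
emulate: isochore or repeat structure, splice-site motifs, overlapping or
nested genes, pseudogenes, positional library-preparation bias (the severe
within-transcript coverage distortion of ribosomal-depletion protocols
cannot be meaningfully simulated and is deliberately out of scope), PCR
duplicates, or quality-score profiles. Passing tests therefore demonstrate
correctness of the benchmark machinery and of the scoring definitions — not
that any assembler's accuracy on real tissue data will match its accuracy
here. That gap is the reason the clean configuration is best read as an
*upper bound* on accuracy.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; GTF I/O converts
  (1-based inclusive) at exactly one boundary. Junction coordinates are
  stored in ascending genomic order on either strand.
* All randomness flows from per-module seed substreams derived from one
  master seed, so enlarging the fragment count does not perturb variant
  design, and every artefact is byte-reproducible from its config + seed
  (the CLI writes a manifest per run).
* Coverage strata are half-open — low [1, 10), medium [10, 100),
  high [100, ∞) — with below-1 transcripts left unbinned and excluded from
  binned strata.
* Quantification agreement removes *on/off errors* (true zero with positive
  inference, or the reverse) before correlating, reports their counts
  separately, and additionally removes extreme outliers at
  |log10(inferred/true)| > 2 (count always reported, so the filter's effect
  is visible). Pearson r is marked undefined below 3 surviving pairs.
* An empty stratum yields NA precision/recall and an absent comfort-zone
  flag rather than a silent 0; empty predicted sets give recall 0 and NA
  precision.
* Overlapping indel seeds are dropped left-to-right; substituted bases are
  always different from the reference base.

## Problem sizes used by the test-suite

The package's own checks run the canonical 13,000-gene design once on a
62 Mb synthetic chromosome (exon counts 5–8, exons 100–200 b, introns
100–300 b, sized by the worst-case footprint formula so placement cannot
fail), the distributional checks at 10^5 fragment-length draws and 30,000
transcripts, the classification oracle on 1,000 randomized instances
against an exhaustive pairwise matcher, and end-to-end closure on a 40-gene
fixture at 40× uniform coverage. The headline coverage quantity is
recomputed by `scripts/acceptance.R` on a 100-gene fixture. These sizes keep
every property statistically sharp (binomial 99% intervals well inside the
asserted tolerances) while remaining desk-scale.

## Known limitations

* The simulator produces one polymorphic haplotype, not a diploid pair.
* Intron-signal fragments are attributed to the sampled transcript's gene;
  genes overlapping on opposite strands (not produced by the fixture
  generator) would share pre-mRNA signal in reality.
* The GTF writer emits exon features only (no CDS/UTR), which is all the
  benchmarked task consumes.
* `alignment_base_accuracy()` scores aligned *coordinates* only; it does not
  penalise base-call mismatches, which are the aligner's input, not its
  output.
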