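---
title: "Private-variant prioritization: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Private-variant prioritization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privar)
```

## The analysis model

`privar` implements case-versus-cohort variant prioritization for rare
monogenic disorders. The underlying genetic model is that a rare,
fully or incompletely penetrant variant of large effect segregates in
one or a few affected individuals and is absent from a large catalog
of population controls. The analysis therefore reduces each case
genome to its *private* variants — alternate alleles carried by zero
catalog genomes — and ranks them by predicted functional consequence.
The approach assumes (i) the causal variant is detectable as an SNV or
short indel in short-read data, (ii) controls are unaffected carriers
of at most benign alleles, and (iii) gene annotation is good enough
that consequence classes are meaningful. All three assumptions fail in
characteristic ways (structural variants, incompletely penetrant
alleles segregating in controls, mis-annotated UTRs), which is why the
package reports classes and carrier counts rather than verdicts.

### Allele matching

Variants are compared across files by a canonical key: the
left-aligned, minimal, anchored representation of the allele
(`left_align()`), the convention used by VCF-based toolchains. The
complementary HGVS convention — the 3′ rule, which places ambiguous
indels at their most 3′ position *in the reading direction* — is
applied only at rendering time (`shift_3prime()`), and flips to
genomic-leftward for minus-strand transcripts. Both representations
are validated against each other by apply-and-compare tests: applying
either spelling to the reference yields byte-identical sequences.

### Consequence classification

Each variant is classified once per overlapping transcript and the
most severe call is reported. The severity order is a strict total
order: splice_donor > splice_acceptor > frameshift > nonsense >
start_lost > stop_lost > missense > inframe_indel > synonymous >
intronic > intergenic, with ties between transcripts broken
alphabetically by transcript id so multi-transcript resolution is
deterministic. The canonical splice region is intronic positions ±1
and ±2 — exactly the GT/AG dinucleotides; deeper intronic positions
near junctions are reported as intronic, while *exonic* variants
within `splice_window` (default 3 bp) of a junction carry a separate
escalation flag, because synonymous changes at exon ends are a known
splicing-pathogenic class.

Report classes partition the effect classes into the four summary
columns (protein-changing, synonymous, intronic, intergenic), so class
counts always sum to the total. Two buckets required a decision the
annotation itself does not force: UTR and non-coding-exon variants are
counted as intronic (they are transcribed but not protein-changing),
and variants in the gene-proximal flank (default 5 kb) outside the
exon span are counted as intergenic. Both choices are configurable in
spirit — the mapping lives in one function (`report_class_of()`) — and
documented here because a different bucketing changes the
intronic/intergenic split, though never the protein-changing column.

### Mutant protein prediction

`translate_mutant()` edits the spliced CDS and translates with the
standard genetic code until the first stop. When a frameshift or
stop-loss runs past the original stop codon, translation continues
into 3′ sequence — first the remainder of the exon chain, then
contiguous genomic sequence — up to `extension` nt (default 300). The
default bounds run time and memory on pathological inputs; if no stop
appears within the window the result is flagged `no_stop` rather than
raising an error, since that outcome is biologically meaningful
(non-stop decay candidates). Frameshift notation follows HGVS: in
`p.(Ser341ArgfsTer22)` the `Ter22` is the stop position in the new
reading frame counted from the first changed residue, i.e. 21 novel
residues then a stop. A description such as "a novel 22 amino acid
C-terminus" in prose usually counts the same peptide inclusively of
the changed residue but not the stop; the renderer always uses the
HGVS convention.

### Donor-site model

The donor model is a 9-mer position-weight matrix over −3..+6 (three
exonic, six intronic bases) of U2-type GT-AG introns. The packaged
default anchors +1 G and +2 T at 100%, their near-invariant values in
large human donor compilations; the remaining seven positions carry
representative human donor frequencies and are explicitly
user-replaceable (`load_consensus()` accepts any table of the same
shape). Scores are log-odds in bits against a uniform background,
`sum(log2(freq/25))`, with frequencies floored at `pseudo` (default
0.1%) so zero-frequency bases stay finite. The verdict logic keeps the
biology and the score separate: any change removing the +1 G or +2 T
is `canonical_broken` regardless of score, because GT-AG recognition
is essentially obligatory; otherwise `weakened` when the score drop is
at or below `threshold` bits (default −3, an arbitrary but stated
cutoff roughly equal to losing one well-conserved position) and
`neutral` above it.

### Gly-X-Y classification

Collagen triple-helix substitutions are interpreted through the repeat
frame: `classify_gxy(residue, helix_start, gly_phase)` with the frame
anchor passed explicitly. The phase is a parameter rather than an
inference because repeat frames in real annotations are
accession-specific and silently inferring one from sequence invites
off-by-one errors in exactly the situation (Gly vs X/Y) where the
clinical interpretation flips.

## The synthetic study

`simulate_study()` generates the testing universe. Its defaults are
the package's study conditions:

- 2 contigs × 500 kb; 20 cohort genomes; 3 cases; ~300 background
  variants per genome. This desk scale keeps a full simulated study
  around ten seconds; the logic under test (matching, filtering,
  annotation) is scale-free, and the tests exercise it across ten
  seeds rather than at WGS scale (millions of variants per genome
  against 584 controls), which no test suite should attempt.
- Background class proportions 50.7% intergenic / 48.3% intronic /
  0.7% protein-changing / 0.3% synonymous — the split observed for
  private variants in canine WGS case series, so summary tables look
  like their real counterparts.
- Background variants are 95% SNVs with ≤4 bp indels, reflecting
  small-variant calling; background indels are placed in non-coding
  classes only, so each background variant's report class is known at
  generation time without running the annotator (the annotator is
  exercised on coding indels separately, via planted variants and
  randomized oracle tests).
- 70% of each genome's expected count is drawn from a shared pool
  (per-variant carriage probabilities uniform on 0.1–0.5), 30% is
  genome-specific; carried alleles are homozygous with probability
  0.3. The pool induces realistic sharing between cases and cohort so
  the privacy filter has real work to do.

Three genes are *designed*, not random: a minus-strand collagen-like
gene whose helix region is an exact (Gly-X-Y)~n~ repeat with a GTC
valine at the X-position residue 596; a minus-strand 17-exon splice
gene whose first 16 coding exons total 1446 nt, placing the intron-16
donor at c.1446+1; and a plus-strand 12-exon gene encoding a
355-residue protein whose last exon carries a TCAGTCAG context at
c.1017–1024, so a TCAG deletion is ambiguous, left-aligns upstream and
3′-shifts to c.1021_1024delTCAG with frameshift Ser341Arg, 21 novel
residues, and a stop at new-frame position 22 — the three exemplar
candidate types, heterozygous by default. Planted sites are reserved
before background sampling, and no cohort genome ever draws them, so
truth sets are exact.

What the generator does **not** emulate: linkage disequilibrium, breed
or population structure, sequencing error, genotyping uncertainty,
multi-allelic sites beyond VCF splitting, structural variants, and
annotation error. Passing tests therefore demonstrate correctness of
the *pipeline logic* under clean inputs, not robustness to the failure
modes of real WGS callsets.

## Numerical and degenerate-input choices

- Genomic coordinates are 1-based inclusive at every interface (VCF,
  GFF3, HGVS); no half-open representation leaks out.
- Normalization at a contig edge (an indel at position 1) anchors on
  the following base instead of the preceding one.
- Missing genotypes (`./.`) are treated as non-carriage and counted;
  for privacy filtering this is the conservative direction (a missing
  cohort genotype cannot rescue a case variant into privacy).
- Summary fractions round to one decimal; per-class rounding can move
  their sum by up to ±0.2 from 100.
- `summarize_cases()` derives statistics from the table cells rather
  than re-tallying calls, so a rendered-then-parsed table reproduces
  its statistics exactly.
- Degenerate inputs fail loudly with the offending record named:
  duplicate contigs, non-nucleotide bases, CDS lengths not divisible
  by 3, REF/reference mismatches, carrier tables whose rows do not
  reconcile.

## Known limitations

- Recessive filtering defaults to strict privacy (no cohort carriers
  at all); `allow_cohort_hets = TRUE` relaxes this for incompletely
  penetrant or common-carrier recessives, and `max_carriers` relaxes
  dominant filtering, but no frequency model is provided.
- One consequence per variant per transcript; compound effects
  (an indel that both disrupts a splice region and shifts frame) take
  the most severe single label.
- `translate_mutant()` requires the edit to lie within the CDS of a
  single exon; junction-spanning indels are classified but not
  protein-predicted.
- The donor model covers U2-type GT-AG donors only — no acceptor,
  branch-point or U12 models; non-GT-AG introns in user annotation
  would score as heavily disrupted rather than being recognized as a
  different splicing class.
- UTRs are supported by the coordinate machinery but the generated
  fixtures are UTR-less, so UTR paths see lighter testing than coding
  paths.
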