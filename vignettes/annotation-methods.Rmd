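---
title: "Methods: transcript-aware variant consequence annotation"
author: "vcanno"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcript-aware variant consequence annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
design is the way it is: the annotation model and its assumptions, the
tunable parameters, what the synthetic fixtures emulate (and do not), the
numerical and tie-break choices, and known limitations. Nothing stated here
goes beyond what the test suite and `scripts/acceptance.R` themselves compute.

## The annotation unit

The engine's output unit is one row per **(alternative allele, overlapped
genomic feature)** pair. A variant with two alternative alleles overlapping
two transcripts yields four rows; a variant overlapping nothing yields a
single `intergenic_variant` row against a pseudo-feature. This cardinality is
asserted directly in the tests and is the invariant every writer (tab, VCF
`CSQ`, JSON) preserves.

Variants are held internally in 1-based, fully-closed coordinates with
anchor bases stripped: a deletion keeps only the deleted bases
(`ref = "AC"`, `alt = "-"`), and an insertion has `ref = "-"` with the
convention `start = end + 1`, so the insertion point sits between two
genomic bases. The VCF anchor base is removed only for unbalanced records;
balanced substitutions keep their input representation. Optional allele
minimisation (5′ shared bases first, then 3′, adjusting the start by the
count of 5′-stripped bases) is off by default because it changes input
coordinates; likewise indels are deliberately **not** left-aligned — HGVS
requires right-normalisation relative to the transcript, and silently
rewriting input coordinates would make input and output disagree. Users who
want normalised input should pre-process with a dedicated normaliser.

## Consequence terms and the registry

Consequence classes live in a data file
(`inst/extdata/consequence_registry.tsv`): 33 Sequence Ontology classes with
accession, parent links, a unique severity rank (1 = most severe) and an
impact class (HIGH/MODERATE/LOW/MODIFIER). Membership is data, not code — a
user may supply a replacement file — and the tests pin the count and
spot-check the ordering rather than re-deriving it. The parent links give the
"most specific term" rule its meaning: after predicate evaluation, any term
that is an ancestor of another assigned term is dropped, so
`{coding_sequence_variant, missense_variant}` collapses to
`missense_variant` while terms on distinct branches
(`splice_region_variant` + `synonymous_variant`) co-exist.

The impact mapping is deliberately coarse and conventional: HIGH for
ablations, amplifications, frameshift, stop gain/loss, start loss and the
donor/acceptor splice sites; MODERATE for missense and in-frame indels; LOW
for synonymous-class and splice-region changes; MODIFIER otherwise.

## Predicates and pre-predicate gates

One predicate function per class. Each predicate is *total* — safe to
evaluate on any allele/feature context — which is what makes the gating
design testable: with gates disabled every predicate runs and the result set
must be identical, only the evaluation counter differs. The gates themselves
are cheap location checks computed once per pair: a span wholly inside an
intron skips all coding predicates; a span outside the transcript skips
everything except the flank predicates; coding transcripts skip the
non-coding branch and vice versa. The run statistics object counts
evaluations and skips so the `n·f·p` bound (alleles × features × predicates)
is a checkable inequality, not a slogan.

Positional definitions, fixed here because they must be identical in the
engine and the oracle:

- splice donor/acceptor: first/last 2 intronic bases in transcript
  orientation;
- splice region: exonic bases 1–3 adjacent to a junction, or intronic bases
  3–8;
- a wholly-donor/acceptor span is *not* additionally `intron_variant`;
  intronic splice-region positions are (`splice_region_variant` +
  `intron_variant`, distinct branches);
- an insertion "overlaps" a feature only when the feature contains the
  insertion point strictly (both neighbouring bases inside), so an insertion
  immediately after a transcript's last base is downstream, and an insertion
  at an exon/intron junction is splice-relevant, not coding. This is the
  deterministic tie-break for a case the coordinate conventions leave open.

Coding calls are codon-local: the affected codons are cut from the cached
CDS, the allele substituted (reverse-complemented for minus-strand
transcripts), and both sides translated. Changed bases are upper-cased
inside lower-case codon context (`gCc/gTc`). Start-codon changes are
`start_lost`; a change inside the trailing partial codon of a CDS whose
length is not a multiple of 3 is `incomplete_terminal_codon_variant` (the
translator drops and flags the partial codon). Indel frame calls use the
length of the *coding* part of the change modulo 3 — a deletion straddling a
splice boundary counts only its CDS-exonic bases. Complex in-frame changes
that defeat codon-local analysis fall back to `coding_sequence_variant`.

Translation uses the standard code, the vertebrate mitochondrial code for
chromosomes named in a configurable set ({MT, chrM, M} by default), and
renders annotated selenocysteine TGA codons as `U`. Selenocysteine positions
arrive via a sidecar file at cache build because GTF dialects have no agreed
attribute for them. Note the mitochondrial table's actual content: AGA/AGG
are stops but TGA codes tryptophan, so e.g. `ATGAGATGA` translates to
`M*W`.

Structural variants (spans or insertions > 50 bp, or symbolic
`SVTYPE`/`END` records) use containment rules per feature: DEL containing a
transcript → `transcript_ablation`, partial → `feature_truncation` (plus
`coding_sequence_variant` when the CDS is touched); DUP → amplification /
elongation; regulatory and motif features take the analogous
`regulatory_region_*` / `TFBS_*` terms. Copy-number records follow the
duplication rules and large insertions elongate — a documented
simplification, since a bare CNV record does not say whether copies were
gained or lost.

## The annotation store

Features are compiled into one serialized file per (chromosome, megabase
bin), JSON-lines with a schema-versioned manifest recording source checksums
and build parameters. The portable text format is a deliberate choice over
any language-specific serialization. A feature spanning a bin boundary is
written into every bin it overlaps and deduplicated by identifier at query
time. Bin loads are memoized per store handle, and the memoization is
behaviourally invisible (asserted by test). Derived sequences — spliced
cDNA, CDS, translation, and the per-transcript coordinate maps — are
memoized the same way.

Sequence access reads whole chromosomes once into memory via the indexed
FASTA and caches them per store handle. That is the right trade-off for the
megabase-scale genomes this package targets in its tests and for typical
microbial or targeted-region use; for a full mammalian genome a windowed
`FaFile` accessor would be the first thing to swap in, and the store
isolates that decision in one function.

The transcript flank defaults to 5,000 bp and applies only to transcripts —
regulatory features and motifs match on their own span. The canonical
transcript is marked by a configurable GFF attribute
(`Ensembl_canonical`/`canonical` accepted by default) since annotation
sources disagree on its name.

## HGVS

Descriptions carry versioned accessions always (unversioned transcripts get
version 1 at cache build). Indels are right-shifted by rotation: a deletion
shifts while the base entering the window equals the base leaving it; an
insertion rotates its allele while its first base matches the next reference
base; an insertion equal to the immediately 5′ adjacent sequence becomes
`dup`. `del`/`dup` descriptions are position-only (no sequence suffix), the
stable-under-genome-edits modern form, and predicted protein changes are
written without parentheses. Transcript-level shifting happens in cDNA
space, so on minus-strand transcripts "3′" correctly means lower genomic
coordinates — asserted on a dedicated minus-strand homopolymer fixture.
Genomic (`g.`) descriptions are also 3′-shifted: transcript-relative
shifting alone would let `g.` and `c.` name different bases of the same
repeat run, which we judged worse than extending the rule to the genomic
level; this is the package's choice where the convention is genuinely open.
Protein frameshifts re-translate the mutant CDS through the transcript end
to find the new stop (`fsTer<n>`, `fsTer?` if none before the transcript
runs out); stop-loss extensions are computed the same way.

HGVS *input* resolves `g.` and `c.`/`n.` (including intronic offsets and UTR
positions projected through the exon structure); protein-level input is
rejected as unsupported because codon-level ambiguity makes it ill-posed
without extra conventions. A version mismatch against the cache warns and
resolves on the accession.

## Motifs and regulatory features

The motif score is a min–max normalised log-probability with pseudocount
10⁻² applied when the JASPAR-style matrix is read: the consensus scores
exactly 1, the anti-consensus exactly 0, and substituting any base for a
higher-probability base can never lower the score (a tested monotonicity
property). Scores are clamped to [0, 1] so floating-point round-off cannot
leak outside the documented range. The informative-position flag is column
information content ≥ 1 bit (of 2): a simple, testable proxy for "important
in the consensus". Both the formula and the threshold are package design
decisions isolated behind this module, chosen because no standard formula
exists for "closeness to consensus"; swapping either changes nothing
outside `scoreMotif()`/`motifConsequence()`. Strand handling is symmetric: a
minus-strand motif scores identically to its reverse-complemented
plus-strand counterpart with complemented alleles. Cell-type restriction
keeps regulatory features whose annotated cell types intersect the user's
list; features without cell-type annotation are retained.

## Co-located variants, filters, prioritisation

Known variants are stored in the same bins as a third feature class and
matched by identical coordinates with an allele-compatibility check after
minimisation; position-only matches carry an `ALLELE_MISMATCH` flag. The
common-variant filter removes all results of a variant whose any co-located
record has global minor allele frequency **strictly greater** than the
threshold (default 1 %); strictness is our reading of "greater than" where
the boundary case is unstated, and the boundary is pinned by test.

The filter language is `field op value` clauses joined by AND/OR, AND
binding tighter, no parentheses (matching the complexity of the documented
examples). `in` accepts a file of values; `matches` is case-insensitive
substring; numeric comparators coerce and evaluate false on non-numeric
fields; unknown fields evaluate false with a warning rather than erroring,
so a filter written for one annotation configuration degrades gracefully on
another. Prediction-style values (`deleterious(0.02)`) match their bare term
under `is`.

Prioritisation (`pick`) orders by: canonical flag, protein-coding biotype,
severity rank, CDS length (longer first), transcript identifier
(lexicographic) — the last two being deterministic tie-breaks; `per_gene`
applies the same ordering within each gene.

## Buffering and parallelism

Input streams in contiguous blocks (default 5,000 variants). Each block may
be divided among forked workers; each chunk carries private statistics and
warning collectors that are merged back, and results are re-sorted into
input order, so the primary output is byte-identical for any worker count —
asserted on a 12,000-variant fixture, which also makes the buffer flushes
(5,000 + 5,000 + 2,000) observable. Plugins run after consequence
calculation: a plugin is any function receiving the finished result row plus
the store handle and returning key–value pairs merged into the row's extras;
the shipped demo re-thresholds the flank distance.

## The synthetic fixtures and what passing means

`makeFixture()` writes a deterministic genome (identical seed → byte-identical
files), a GFF3 transcript set, variant panels, a known-variant VCF, a
JASPAR-style PWM and a truth table. The transcript set is *designed*, not
sampled: a single-exon coding transcript with hand-chosen codons (so codon
arithmetic is checkable by eye), a 3-exon coding transcript and a
skipped-exon isoform sharing its gene, a minus-strand coding transcript with
an engineered cDNA homopolymer, a long non-coding transcript, a miRNA with a
mature region, a transcript with an incomplete terminal codon, a
selenoprotein, and a mitochondrial transcript. Designed coding regions draw
filler codons from a T-free alphabet, which guarantees no stop codon can
arise in any reading frame without post-hoc checks. Random background
sequence fills the rest; every designed landmark (homopolymer runs, splice
dinucleotides, the motif consensus site) is overlaid at fixed coordinates so
expectations are seed-independent.

The truth table is constructed from two independent routes: the
first-principles oracle (`naiveAnnotate()`) for sequence variants —
re-splicing and re-translating the full mutant cDNA with no gates and no
caches — and the containment rules for structural/regulatory cases. The
headline test annotates every possible SNV at every position of the 3-exon
and the minus-strand transcripts (three alleles each, ~3,600 cases) and
demands exact agreement between engine and oracle.

What this does **not** show about real data: fixtures have clean,
non-overlapping exons, complete codons except where designed otherwise, no
N bases, no assembly gaps, VCF records that always match the reference, and
variant spectra chosen for class coverage rather than realism. Real
annotation sets contain malformed records, biotype vocabularies beyond the
one tested, and transcripts whose CDS annotations are inconsistent — the
build step validates what it can (CDS inside exons, spliced CDS ≥ 3,
exons within chromosome bounds) and fails loudly, but the package has not
been exercised against the full zoo of public GTF dialects.

## Numerical and degenerate-input choices

- Scores and frequencies are plain doubles; the only clamping is the motif
  score's [0, 1] bound.
- Identical ref/alt pairs minimise to a zero-length no-op flagged for QC.
- QC failures (reference mismatch, length mismatch, bad characters,
  coordinate order) skip the variant and write a warnings-file line; the run
  continues. Partial annotation of a failing variant is never attempted —
  the failure modes (wrong reference) poison every downstream computation,
  so skipping whole variants is the only defensible reading.
- Empty inputs produce valid, headered, empty outputs and zeroed statistics.
- An intron too short for the full splice-region window truncates the
  window; a chromosome missing from the cache yields an empty result plus a
  warning rather than an error.

## Problem sizes

The shipped tests and the acceptance script run on megabase-scale synthetic
chromosomes: a 20 kb main chromosome, ~3,600-case exhaustive oracle
comparisons, and a 12,000-variant bulk set annotated twice for the
worker-invariance check. These sizes were chosen so the full suite exercises
every code path, including two complete bulk runs, in a few minutes on a
single core while still producing tens of thousands of result rows.

## Known limitations

- No NMD assessment, no pathogenicity score computation, no left-alignment,
  no GVF output, no bigWig tracks (extension point documented), no
  LRG/ALT-haplotype coordinates, and no compound (phased multi-variant)
  effects — each variant allele is annotated independently.
- Whole-chromosome sequence caching (above) bounds the practical genome
  size.
- The upstream/downstream distance is measured to the transcript, not the
  gene.
- CNV structural records are treated as copy-gain; a loss-typed CNV should
  be encoded as `<DEL>`.
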