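# vcanno

**vcanno** is a self-contained, offline variant consequence annotation engine
for R. Given sequence or structural variants (VCF, variant identifiers, or
HGVS notations), a transcript annotation set (GFF3/GTF plus a genome FASTA)
and optional regulatory, motif and known-variant tracks, it produces **one
annotation unit per alternative allele per overlapped genomic feature**:

- a set of [Sequence Ontology](http://sequenceontology.org) consequence terms
  (`missense_variant`, `splice_donor_variant`, `intron_variant`, ...) drawn
  from a severity-ranked registry of 33 classes with parent links, so that
  only the most specific term under any parent chain is reported;
- transcript-relative coordinates (cDNA, CDS, protein), exon/intron numbers
  and distances for flanking variants;
- HGVS descriptions at the genomic (`g.`), transcript (`c.`/`n.`) and protein
  (`p.`) levels, with indels right-shifted to the most 3′ position in
  repetitive context relative to the transcript orientation;
- position weight matrix (PWM) score changes and an informative-position flag
  for variants inside transcription factor binding motifs;
- co-located known variants with allele frequencies, clinical significance
  and citation attributes, plus overlaps with user-supplied BED/GFF/VCF
  tracks;
- result prioritisation (`pick`/`per-gene`), a 1 % common-variant filter, and
  a field–operator–value filter language
  (`"AFR >0.1 AND EUR <0.05"`).

Annotation sources are compiled once into a **megabase-binned on-disk cache**
(JSON-lines per bin plus a manifest with checksums); region loads and derived
sequences (spliced cDNA, CDS, translations) are memoized so consecutive input
buffers touching the same region never re-read from disk. Input streams
through buffers of 5,000 variants and can be divided among parallel workers;
results are rejoined into input order, so output is identical for any worker
count.

## The model in brief

For each variant allele *a* and overlapped feature *f* (transcripts are
extended by a configurable flank, default 5,000 bp), the engine evaluates a
suite of predicate functions, one per consequence class. Cheap
*pre-predicate* location checks (is the span wholly intronic? outside the
transcript? in a non-coding biotype?) let whole predicate groups be skipped
without changing the result; without them, runtime is proportional to
*n·f·p* for *n* alleles, *f* features and *p* predicates, and the package
counts both evaluated and skipped predicates so this bound is testable.
Coding predicates compare the reference and mutant codons (standard or
vertebrate-mitochondrial code, with annotated selenocysteine positions
rendered as `U`); frameshift/in-frame calls use the length of the coding
change modulo 3; splice calls use the positional definitions (donor/acceptor
= first/last 2 intronic bases; splice region = exonic bases 1–3 or intronic
bases 3–8 from a junction). Structural variants (> 50 bp) use containment
rules: a deletion containing a transcript ablates it, a duplication
amplifies it, partial overlaps truncate or elongate.

Motif scores are min–max normalised log-probabilities
(score = (Σ log p − Σ log p_min) / (Σ log p_max − Σ log p_min), pseudocount
10⁻²), so the consensus sequence scores 1 and the anti-consensus 0; a motif
position is *informative* when its column carries ≥ 1 bit of information
content.

## Worked example

The package ships a synthetic fixture generator with known ground truth
(`makeFixture()`), which is also how the test suite exercises every
consequence class:

```r
library(vcanno)
fx    <- makeFixture(fixtureSpec(seed = 1), "fixture")
store <- buildFixtureCache("fixture", "cache")
runAnnotation(list(input = "fixture/variants.vcf", cache = "cache",
                   fasta = "fixture/genome.fa",
                   output = "results.tab", format = "tab"))
```

`results.tab` begins:

```
## vcanno 0.1.0
## cache: cache (schema 1)
## command: annotate --input fixture/variants.vcf --cache cache --format tab
#Uploaded_variation  Location  Allele  Gene  Feature  Feature_type  Consequence  cDNA_position  CDS_position  Protein_position  Amino_acids  Codons  Existing_variation  Extra
v01  chrT:25  T  G1  TX1.1  Transcript  missense_variant  15  5  2  A/V  gCc/gTc  rsK1  IMPACT=MODERATE;GMAF=0.02;...;HGVSc=TX1.1:c.5C>T;HGVSp=TX1.1:p.Ala2Val;FLAGS=canonical
v01  chrT:25  T  G2  TX2.1  Transcript  upstream_gene_variant  -  -  -  -  -  rsK1  IMPACT=MODIFIER;GMAF=0.02;DISTANCE=176;...
```

Reading the first data row: the `C>T` allele of variant `v01` falls at cDNA
position 15 / CDS position 5 / protein position 2 of transcript `TX1.1`,
changing codon `gCc` to `gTc` (Ala→Val, hence `missense_variant`, impact
MODERATE, `p.Ala2Val`); it is co-located with the known variant `rsK1`
(global minor allele frequency 0.02, so `--filter-common` would drop it).
The same allele is also reported once per other transcript within the 5 kb
flank (`upstream_gene_variant` at distance 176, and so on) — one row per
allele per feature. The run's summary JSON reports 42 variants, 288
annotation rows and `transcript_ablation` as the most severe consequence
seen.

VCF output echoes the input records with a `CSQ` INFO field (field order
declared in the header); JSON output emits one object per input variant with
nested per-feature consequence arrays.

### Command line

A thin CLI over the same functions is installed with the package:

```sh
vcanno annotate --input in.vcf --cache cache --fasta genome.fa \
       --output out.tab --format tab --pick --filter-common 0.01
vcanno build-cache --gff annotation.gff3 --fasta genome.fa --out cache
vcanno filter --input out.tab --expr "Consequence is missense_variant"
vcanno make-fixture --seed 1 --out fixture
```

Custom tracks are declared as `--custom name=path=format[,exact]`; a
known-variant VCF may carry the reserved INFO keys `GMAF`, `GMAF_ALLELE`,
`AF_<POP>`, `CLNSIG`, `SOMATIC`, `PMID`.

## Scope notes

Pathogenicity scores (SIFT/PolyPhen/CADD) are pass-through attributes of
known-variant or custom tracks, never computed; phenotype databases are
modeled as generic attributes; GVF output, bigWig tracks, protein-level HGVS
*input* and live database connectivity are out of scope. See the methods
vignette (`vignettes/annotation-methods.Rmd`) for the full model description,
parameter defaults and limitations.
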