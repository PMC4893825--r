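Package: vcanno
Title: Transcript-Aware Variant Consequence Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained variant annotation engine. Given variants (VCF,
    identifiers, or HGVS notations), a transcript annotation set (GFF3/GTF plus
    genome FASTA) and optional regulatory, motif and known-variant tracks, it
    produces one annotation unit per alternative allele per overlapped genomic
    feature: Sequence Ontology consequence terms resolved through a severity-ranked
    registry, transcript/CDS/protein coordinates, HGVS g./c./n./p. notations with
    3'-normalisation, position weight matrix score changes in transcription factor
    binding motifs, co-located known variant data, result prioritisation and a
    field-operator-value filter language. Annotation sources are compiled into a
    megabase-binned on-disk cache with memoized region loads. Includes a synthetic
    fixture generator with known ground truth and a naive re-translation oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
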