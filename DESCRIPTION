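Package: MitoSoma
Title: Somatic Variant Filtering, Noncoding Burden, and Mitochondrial
    Heteroplasmy Lineage Analysis for Tumour/Normal Genomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for paired tumour/normal whole-genome analysis of
    lymphocyte-rich tumours with few coding mutations. Implements
    threshold-based somatic filtering for nuclear and mitochondrial
    variants, coding consequence and noncoding functional-region
    annotation, partitioning of noncoding burden into cis-regulatory and
    nonfunctional space, known-hotspot lookup and cohort recurrence
    tallies, 96-channel trinucleotide mutation spectra with non-negative
    least-squares signature refitting, mitochondrial heteroplasmy and
    heteroplasmic-shift quantification, per-region mtDNA mutation
    statistics, Nei-Gojobori dN/dS under nuclear and vertebrate
    mitochondrial genetic codes, and a rule-based reconstruction of
    mitochondrial clone lineage trees from variant allele frequencies.
    A fully deterministic synthetic-cohort generator provides paired
    VCFs, references and annotations with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    VariantAnnotation,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SomaticMutation, VariantAnnotation, Phylogenetics, Software
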