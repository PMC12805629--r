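---
title: "MitoSoma: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MitoSoma: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MitoSoma)
```

MitoSoma analyses paired tumour/normal whole-genome variant calls from
tumours whose nuclear coding genomes are nearly silent — the situation in
lymphocyte-rich thymomas, where most of the somatic signal sits in
noncoding space and in the mitochondrial genome. This vignette explains
the statistical machinery, the tunable parameters, and the choices made
where the design was genuinely open. Nothing here states an empirical
result that the test suite or the acceptance script does not itself
compute.

## Somatic filtering

Variants arrive as paired tumour/normal VCF records
(`readPairedVcf()`); samples are identified by name, never by column
order, because multi-sample VCF column order is caller-dependent. Each
ALT allele becomes one row of a `SomaticVariantSet`.

`filterNuclear()` applies seven criteria in a fixed order: FILTER is
`PASS`; somatic quality score ≥ 18; tumour coverage ≥ 21×; normal
coverage ≥ 21×; tumour allele frequency > 0.25; at least 6
alt-supporting tumour reads; normal allele frequency < 0.02.
`filterMito()` applies five: `PASS`, quality ≥ 18, tumour frequency
> 0.05, ≥ 5 supporting reads, normal frequency < 0.05 — deliberately
with *no* coverage minima, mirroring the shorter mitochondrial criteria
list. Two conventions are worth making explicit:

* **Strictness.** Frequency thresholds are strict inequalities and
  count/coverage thresholds are inclusive, read literally off the
  criteria. A tumour VAF of exactly 0.25 fails; exactly 6 alt reads
  passes.
* **Attribution.** Each rejected variant is charged to the *first*
  failing criterion in the listed order, which makes the
  `FilterReport` conserve counts exactly:
  `passed + sum(rejected) = input`. Any attribution rule is arbitrary;
  first-fail is deterministic and auditable.

A site with zero depth cannot be assessed for a frequency criterion and
is rejected there (nuclear zero-depth sites already fail the coverage
criteria); no division by zero can occur. Note one shadowing effect of
the nuclear criteria: with coverage ≥ 21 and VAF > 0.25 the alt-read
count is necessarily ≥ 6, so the alt-read criterion can never be the
first to fail — it is retained for completeness and for configurations
with other thresholds.

Manual review steps (inspection of variant-rich regions, read-end
artefacts) are not reproducible from a VCF. The package provides one
automatable proxy, `densityFilter()` (reject clusters of > 3 passing
variants per 100 bp window), which is off by default; read-end artefact
exclusion needs alignment-level data and is explicitly out of scope.
NUMT contamination of chrM alignments is handled upstream of
variant-level work by `numtReadPairFilter()`: only read pairs with both
mates mapped to the mitochondrial contig count toward mtDNA evidence.

## Consequence and region annotation

`classifyCoding()` decodes codons against the reference CDS — standard
genetic code on nuclear contigs, vertebrate mitochondrial code on the
circular contig (so TGA is tryptophan there: a TGG→TGA change on chrM
is synonymous, not stop-causing) — and returns exactly one of six
categories with precedence splice > stop-causing > stop-loss >
nonsynonymous > synonymous. The categories are single-label on purpose,
like "most severe consequence" summaries; the published category list
comes without a precedence rule, so one is fixed and documented here.
Splice windows are the 2 bp of intron beyond each internal exon
boundary. CDS indels, which have no codon-level category, are labelled
`coding_indel`.

`classifyNoncoding()` uses the fixed precedence UTR > ncRNA > intron >
upstream/downstream > intergenic, with 2 kb flank windows (a common
convention; configurable). Intergenic is the fallback, so every variant
receives exactly one label and label counts conserve input size —
a property the tests check against interval-arithmetic footprints.

`partitionCre()` splits noncoding variants by positional overlap with
candidate cis-regulatory element intervals; `lookupKnownHotspots()`
reports overlaps with a user-supplied table of previously reported
recurrently mutated regions; `cohortRecurrenceTally()` tallies exact
positions and merged 21-bp windows mutated in ≥ 2 patients. Strand is
ignored in all interval intersections, since the regulatory-region and
hotspot usage is purely positional.

Intervals are held as `GRanges` (1-based, closed) throughout — the
Bioconductor convention — and converted only at the I/O boundary: BED
is read and written as 0-based half-open, VCF positions as 1-based.
One internal convention plus boundary conversion is what prevents
off-by-one drift.

Mitochondrial variants are assigned to regions from a packaged
rCRS-coordinate map in which the D-loop wraps the origin
(16024–16569 ∪ 1–576). The D-loop takes precedence over any
overlapping feature; hypervariable region I (16024–16383) is reported
as a sub-tally of the D-loop rather than a competing region, matching
how HVR I is normally displayed as a zoom of the control region.
Region rates are `count / (size_Mb × n_patients)`.

## Spectra and signature refitting

`buildSpectrum()` counts SNVs over the 96 pyrimidine-centred
trinucleotide channels, reverse-complementing purine-reference
substitutions; contexts containing N are excluded from the channels but
counted. `collapseClasses()` folds these to the six substitution
classes, with an optional seventh *indel* category for side-by-side
nuclear/mitochondrial displays — the data model offers no other
unambiguous seventh class, and the choice is recorded in the output.

`refitSignatures()` solves the non-negative least-squares problem
min‖v − Wᵀx‖₂, x ≥ 0 (via `pracma::lsqnonneg`) against a
row-stochastic signature matrix, L1-normalises the exposures and
reports the reconstruction cosine. The packaged 30 × 96 reference is
**synthetic**: it reproduces the layout of a legacy 30-signature
catalogue and shapes two rows after well-known processes (a CpG-C>T
deamination-like SBS1 and a T>C-transition-dominated SBS12) but is not
the COSMIC data; any row-stochastic matrix can be substituted. Refits
can be run per case or on pooled spectra; per-case is the default
interface since pooling is a trivial sum of spectra.

## Heteroplasmy, density and dN/dS

Heteroplasmy is the mutant-read fraction at a site. A shift is
*tumour-specific* when the normal level is below 0.05 and
*tumour-enriched* when the mutation is present in the normal but at a
higher level in the tumour; the 0.05 presence threshold deliberately
reuses the mitochondrial filter's normal-frequency bound so one
constant governs "absent in normal". Group comparisons (by region or
consequence class) use the two-sided Mann–Whitney U test. The five
region groups used for display are {D-loop, complex I genes, complex
III/IV genes, rRNA/tRNA, other} — a display choice, not a modelling
one.

Mutation density is `n / (kb × patients)`; the nuclear comparator uses
a documented genome-size constant (`NUCLEAR_GENOME_KB`, the hg38
primary assembly, 3,099,734 kb), configurable.

dN/dS uses Nei–Gojobori (1986) unweighted pathway counting: each codon
position contributes to the expected nonsynonymous (N) and synonymous
(S) site totals the fraction of its three possible changes in each
class, so N + S = 3 × codons exactly — an invariant the tests exploit
with an exhaustive 9-changes-per-codon oracle under both genetic
codes. ω = (N_d/N)/(S_d/S) on raw counts: at per-gene counts of a few
mutations, multiple-hit (Jukes–Cantor-type) correction is undefined
and is not applied. S_d = 0 with N_d > 0 reports ω = ∞ with a
`divergent` flag rather than failing.

## Lineage trees from heteroplasmy VAFs

Because a cell carries many mitochondrial genome copies, ordinary
single-cell phylogenetics does not apply; the package reconstructs
clone lineages directly from VAFs with three rules:

1. order variants by descending VAF beneath the unmutated root A0 at
   100% (ties broken by position then allele, for determinism);
2. insert clones one at a time in that order;
3. never let a node's children sum to more than its own VAF
   (enforced incrementally as residual-capacity checking).

Adjacent variants closer than δ = 0.02 in VAF are first merged into
multi-mutation clones (`mergeCoclonal()`; δ is a first-class parameter
and δ = 0 disables merging). The rules constrain but do not uniquely
determine where a clone attaches. The default preference attaches each
clone to the *deepest* feasible node. On a descending sequence the
deepest node's residual equals its own VAF, which is at least the next
clone's VAF — so the deepest-feasible rule always admits, and always
produces, a chain: it is the maximal-linearity reading of the rules,
and the tests verify by exhaustive enumeration (n ≤ 6) that the greedy
tree is always feasible and of maximal depth. Since a chain is always
feasible, branching can only arise from a different attachment
preference; the alternative `parentRule = "residual"` (attach to the
largest residual capacity) is provided for exactly that reason and is
reported side by side rather than hidden.

Clone proportions are the stick-breaking differences
p(node) = VAF − Σ(children VAFs) with the root at 1.0; they are
non-negative by rule 3 and sum to exactly 1. The first hit of a case
is clone A1; `firstHitStats()` reports its VAF, mutations and regions,
and the cohort fraction with first-hit VAF ≥ 0.5. Heteroplasmy VAFs
are used raw — mtDNA is polyploid per cell, so the VAF itself
approximates the clone's share of genome copies and no diploid
doubling is appropriate.

## The synthetic cohort generator

No patient-level data accompany the study conditions this package
targets, so `simulateCohort()` generates complete cohorts with known
ground truth. The defaults *are* the study conditions: 10 patients;
nuclear coverage 115× (tumour) / 129× (normal) and mitochondrial 368×;
per-case means of 21.1 coding and 1,671.3 noncoding mutations, of
which 405.0/1,671.3 fall on cis-regulatory elements; an SBS12-dominant
signature mixture (weights 0.75 SBS12 / 0.25 SBS1 — the dominant and
secondary processes of a transition-heavy spectrum; the exact split is
the package's choice since only dominance is specified); mitochondrial
chains of mean length 4.3 (truncated Poisson ≥ 1) with D-loop weight
17/43 and first-hit VAFs drawn in 0.45–0.96 so heteroplasmies span
roughly 5–96%.

Per-case counts are negative binomial (dispersion `size = 3`) rather
than Poisson, to reproduce the wide per-case ranges such cohorts show;
normal samples carry a 0.5% cross-contamination alt-read rate so the
normal-frequency criteria are exercised against realistic rather than
perfectly clean normals. Substitutions are drawn channel-first from
the signature mixture and positions second from
context-matched pools, so the planted spectrum matches the configured
mixture exactly in expectation (the uniform-position alternative would
distort the context marginal). A configurable decoy fraction (default
25%) plants sub-threshold records — non-PASS, low quality, thin
coverage, low VAF, germline-like — one family per filter criterion.
The nuclear toy genome is 1 Mb over two contigs with 18 multi-exon
genes; mutation densities per case are therefore orders of magnitude
higher than in a real genome, which is immaterial for the
counting/rate statistics but means absolute per-Mb rates from the toy
cohort are not comparable to published per-Mb figures. Everything is
deterministic under one master seed, byte-for-byte in the emitted
FASTA/VCF/BED/TSV/JSON files.

What passing tests on this cohort do **not** show about real data: the
generator has no alignment artefacts, no NUMT mis-mappings (the
read-pair rule is tested on simulated pair descriptors, not
alignments), no copy-number or structural variation, binomial rather
than overdispersed read counts at a site, and an idealised annotation.

## Numerical choices and problem sizes

* VAF comparisons in tree construction use an absolute tolerance of
  1e-9; proportions are exact stick-breaking differences.
* NNLS is deterministic; exposures below ~1e-12 are clipped by the
  solver itself.
* The co-clonal merge compares *adjacent* VAFs (transitive along the
  run), so a long gentle ramp can merge; δ = 0.02 keeps that risk
  negligible at the coverages simulated.
* The topology-recovery study uses linear chains with inter-clone gaps
  ≥ 0.08 at 3000× coverage (binomial s.e. of a VAF ≈ 0.009 there, so
  erroneous merges at δ = 0.02 are ~5σ events). At 368× with gaps near
  2δ the VAF noise (s.e. ≈ 0.025) makes adjacent-clone merges common,
  and clone-count recovery is not a meaningful target; the high-coverage
  setting is chosen a priori from that standard-error argument.
* Test and acceptance problem sizes (500-variant filter fixtures,
  200 enumeration draws at n ≤ 6, 20 refit seeds at 20,000 draws,
  100-seed recovery studies, 10,000-variant annotation nulls) are the
  package's chosen trade-off between statistical resolution and a
  suite that runs in a few minutes.

## Known limitations

Indels are consumed as called (no re-normalisation or left-alignment);
the somatic quality score is read from `QUAL` or a configurable INFO
key, since callers differ in where they put it; the six coding
categories do not include frameshift/inframe subtypes; recurrence
detection is a positional tally, not a covariate-adjusted hotspot
model; and mtDNA copy-number estimation, haplogroup assignment and
multi-region phylogenetics are out of scope.
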