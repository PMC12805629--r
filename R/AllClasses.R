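#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

VARIANT_COLUMNS <- c("chrom", "pos", "ref", "alt", "qscore", "filter",
                     "t_depth", "t_alt", "n_depth", "n_alt", "kind")

#' Container for paired tumour/normal somatic variant calls
#'
#' One row per ALT allele of a paired tumour/normal variant call, carrying
#' the site quality score, the raw VCF FILTER string, and per-sample total
#' and alt-supporting read depths. Multi-allelic records are split upstream
#' so that every row describes a single substitution or indel.
#'
#' The \code{kind} column is \code{"SNV"} exactly when both alleles have
#' length 1, \code{"insertion"} when the alternate allele is longer than the
#' reference, and \code{"deletion"} otherwise.
#'
#' @slot data a \code{DataFrame} with columns \code{chrom}, \code{pos}
#'   (1-based), \code{ref}, \code{alt}, \code{qscore}, \code{filter},
#'   \code{t_depth}, \code{t_alt}, \code{n_depth}, \code{n_alt},
#'   \code{kind}. Additional annotation columns (region labels,
#'   heteroplasmy levels, shift classes) may be appended by downstream
#'   steps and are preserved by subsetting.
#'
#' @seealso [SomaticVariantSet()] for the constructor,
#'   [readPairedVcf()] to build one from a VCF file.
#' @export
setClass("SomaticVariantSet", representation(data = "DataFrame"))

setValidity("SomaticVariantSet", function(object) {
    d <- object@data
    missing_cols <- setdiff(VARIANT_COLUMNS, colnames(d))
    if (length(missing_cols))
        return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
    if (nrow(d) == 0L)
        return(TRUE)
    if (any(d$pos < 1L))
        return("pos must be >= 1")
    if (any(d$t_alt < 0L | d$t_alt > d$t_depth))
        return("t_alt must satisfy 0 <= t_alt <= t_depth")
    if (any(d$n_alt < 0L | d$n_alt > d$n_depth))
        return("n_alt must satisfy 0 <= n_alt <= n_depth")
    if (any(d$ref == d$alt))
        return("ref and alt alleles must differ")
    snv <- nchar(d$ref) == 1L & nchar(d$alt) == 1L
    if (any(snv != (d$kind == "SNV")))
        return("kind must be 'SNV' exactly when both alleles have length 1")
    TRUE
})

#' Reference genome with optional circular contigs
#'
#' A named set of uppercase DNA sequences plus the subset of contig names
#' that are treated as circular (the mitochondrial contig in practice).
#' Trinucleotide context extraction wraps around on circular contigs and
#' N-pads at the edges of linear ones.
#'
#' @slot sequences a [Biostrings::DNAStringSet] of contigs.
#' @slot circular character vector of circular contig names.
#'
#' @seealso [ReferenceGenome()], [trinucleotideContext()]
#' @export
setClass("ReferenceGenome",
         representation(sequences = "DNAStringSet", circular = "character"))

setValidity("ReferenceGenome", function(object) {
    nm <- names(object@sequences)
    if (is.null(nm) || anyDuplicated(nm))
        return("sequences must have unique names")
    if (!all(object@circular %in% nm))
        return("circular contig names must name sequences")
    freq <- Biostrings::alphabetFrequency(object@sequences)
    if (any(rowSums(freq[, c("A", "C", "G", "T", "N"), drop = FALSE]) !=
            Biostrings::width(object@sequences)))
        return("sequence alphabet must be within {A,C,G,T,N}")
    TRUE
})

#' Transcript annotation for consequence classification
#'
#' Per-gene feature intervals used to classify variants into the six coding
#' consequence categories and the noncoding functional-region labels. All
#' intervals are \code{GRanges} with a \code{gene} metadata column; CDS
#' ranges additionally know their strand through the \code{GRanges} strand.
#' Splice windows (2 bp of intron beyond each CDS-adjacent exon boundary)
#' are derived at construction time.
#'
#' @slot genes gene-body ranges; mcols \code{gene}, \code{type}
#'   (\code{"coding"} or \code{"ncRNA"}).
#' @slot exons exon ranges; mcols \code{gene}.
#' @slot cds CDS ranges; mcols \code{gene}. Per gene the CDS length is a
#'   multiple of 3.
#' @slot utr5,utr3 untranslated-region ranges; mcols \code{gene}.
#' @slot splice 2-bp intronic splice windows; mcols \code{gene},
#'   \code{site} (\code{"acceptor"} or \code{"donor"}).
#'
#' @seealso [TranscriptAnnotation()], [classifyCoding()], [classifyNoncoding()]
#' @export
setClass("TranscriptAnnotation",
         representation(genes = "GRanges", exons = "GRanges", cds = "GRanges",
                        utr5 = "GRanges", utr3 = "GRanges", splice = "GRanges"))

#' Rejection accounting for a filtering pass
#'
#' Tallies, for one call to [filterNuclear()] or [filterMito()], how many
#' variants were rejected by each criterion. Rejections are attributed to
#' the FIRST failing criterion in the published order, so the counts are
#' conserved: \code{passed + sum(rejected) == input}.
#'
#' @slot input number of variants examined.
#' @slot passed number passing every criterion.
#' @slot rejected named integer vector of first-failing-criterion counts.
#' @export
setClass("FilterReport",
         representation(input = "integer", passed = "integer",
                        rejected = "integer"))

setValidity("FilterReport", function(object) {
    if (object@passed + sum(object@rejected) != object@input)
        return("passed + sum(rejected) must equal input")
    if (object@passed < 0L || any(object@rejected < 0L))
        return("counts must be non-negative")
    TRUE
})

#' Trinucleotide mutation spectrum
#'
#' Counts of single-base substitutions over the 96 pyrimidine-centred
#' trinucleotide channels (6 substitution classes x 16 flanking contexts).
#' Substitutions observed with a purine reference base are
#' reverse-complemented into the corresponding pyrimidine channel.
#' Substitutions whose context contains N are excluded from the channels
#' but kept in \code{nExcluded}.
#'
#' @slot counts named numeric vector over the 96 channels in conventional
#'   order (classes C>A, C>G, C>T, T>A, T>C, T>G; within each class the 16
#'   contexts in A/C/G/T-major order).
#' @slot nExcluded substitutions dropped for ambiguous (N) context.
#' @seealso [buildSpectrum()], [collapseClasses()], [refitSignatures()]
#' @export
setClass("MutationSpectrum",
         representation(counts = "numeric", nExcluded = "integer"))

setValidity("MutationSpectrum", function(object) {
    if (length(object@counts) != 96L)
        return("counts must have 96 channels")
    if (!identical(names(object@counts), sbsChannels()))
        return("counts must be named by the conventional 96 channels")
    if (any(object@counts < 0))
        return("counts must be non-negative")
    TRUE
})

#' Signature refit result
#'
#' Non-negative per-signature weights obtained by least squares against a
#' row-stochastic signature reference, L1-normalised to sum to one, with
#' the cosine similarity between the reconstructed and observed spectra.
#'
#' @slot weights named non-negative numeric vector summing to 1.
#' @slot cosine reconstruction cosine similarity in [0, 1].
#' @slot residual the NNLS residual norm (unnormalised scale).
#' @seealso [refitSignatures()]
#' @export
setClass("SignatureExposure",
         representation(weights = "numeric", cosine = "numeric",
                        residual = "numeric"))

setValidity("SignatureExposure", function(object) {
    if (any(object@weights < -1e-12))
        return("weights must be non-negative")
    if (sum(object@weights) > 0 && abs(sum(object@weights) - 1) > 1e-6)
        return("weights must sum to 1")
    TRUE
})

#' Mitochondrial clone lineage tree
#'
#' A rooted clone tree built from heteroplasmy VAFs by the three ordering /
#' extension / feasibility rules (see [buildLineageTree()]). The root is the
#' unmutated state A0 at VAF 1. Each non-root node is a clone carrying one
#' or more mutations; its clone proportion is its VAF minus the summed VAFs
#' of its children, so proportions are non-negative and sum to one.
#'
#' @slot nodes a \code{data.frame} with one row per node: \code{id}
#'   (0 = root), \code{parent} (NA for root), \code{depth}, \code{vaf},
#'   \code{nMut}, \code{proportion}.
#' @slot variants list (parallel to \code{nodes}) of character vectors of
#'   the mutation identifiers carried by each clone.
#' @slot topology \code{"linear"} if no node has more than one child,
#'   otherwise \code{"branching"}.
#' @slot delta the co-clonal VAF merge tolerance used.
#' @slot parentRule \code{"deepest"} or \code{"residual"}.
#' @seealso [buildLineageTree()], [cloneProportions()], [firstHitStats()]
#' @export
setClass("LineageTree",
         representation(nodes = "data.frame", variants = "list",
                        topology = "character", delta = "numeric",
                        parentRule = "character"))

setValidity("LineageTree", function(object) {
    nd <- object@nodes
    need <- c("id", "parent", "depth", "vaf", "nMut", "proportion")
    if (!all(need %in% colnames(nd)))
        return(paste("nodes must have columns:", paste(need, collapse = ", ")))
    if (length(object@variants) != nrow(nd))
        return("variants list must parallel nodes")
    if (any(nd$proportion < -1e-9))
        return("clone proportions must be non-negative")
    for (i in seq_len(nrow(nd))) {
        kid_vaf <- sum(nd$vaf[!is.na(nd$parent) & nd$parent == nd$id[i]])
        if (nd$vaf[i] < kid_vaf - 1e-9)
            return("node VAF must be >= sum of children VAFs (rule 3)")
    }
    TRUE
})
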