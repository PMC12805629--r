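#' Default somatic filter thresholds
#'
#' The published criteria for paired tumour/normal calls. Nuclear
#' variants must satisfy, in order: (1) FILTER is PASS; (2) somatic
#' quality score >= 18; (3) tumour coverage >= 21x; (4) normal coverage
#' >= 21x; (5) tumour allele frequency > 0.25 (strict); (6) >= 6 distinct
#' tumour reads supporting the mutation; (7) normal allele frequency
#' < 0.02 (strict). Mitochondrial variants must satisfy: PASS; quality
#' >= 18; tumour frequency > 0.05; >= 5 supporting reads; normal
#' frequency < 0.05 — with no coverage minima, matching the published
#' list. Frequency thresholds are strict inequalities exactly as printed;
#' count thresholds are inclusive.
#'
#' @return a list with elements \code{nuclear} and \code{mito}, each a
#'   named numeric vector of thresholds.
#' @export
filterDefaults <- function() {
    list(nuclear = c(qscoreMin = 18, tCovMin = 21, nCovMin = 21,
                     tVafMin = 0.25, tAltMin = 6, nVafMax = 0.02),
         mito = c(qscoreMin = 18, tVafMin = 0.05, tAltMin = 5,
                  nVafMax = 0.05))
}

makeFilterReport <- function(input, passed, rejected) {
    new("FilterReport", input = as.integer(input),
        passed = as.integer(passed),
        rejected = stats::setNames(as.integer(rejected), names(rejected)))
}

# Shared criterion engine: `criteria` is an ordered named list of logical
# "pass" vectors; rejection is attributed to the first failing criterion.
applyCriteria <- function(x, criteria) {
    n <- length(x)
    state <- rep(NA_character_, n)
    pass <- rep(TRUE, n)
    for (nm in names(criteria)) {
        ok <- criteria[[nm]]
        ok[is.na(ok)] <- FALSE
        newly <- pass & !ok
        state[newly] <- nm
        pass <- pass & ok
    }
    rejected <- vapply(names(criteria),
                       function(nm) sum(state == nm, na.rm = TRUE),
                       integer(1))
    list(pass = x[pass],
         report = makeFilterReport(n, sum(pass), rejected))
}

#' Filter nuclear somatic variants
#'
#' Applies the seven nuclear criteria (see [filterDefaults()]) in their
#' published order. A variant with zero tumour (normal) depth fails the
#' tumour (normal) coverage criterion; no division by zero can occur.
#'
#' @param x a [SomaticVariantSet-class]
#' @param qscoreMin minimum somatic quality score (inclusive).
#' @param tCovMin,nCovMin minimum tumour/normal total depth (inclusive).
#' @param tVafMin tumour allele-frequency threshold (strict \code{>}).
#' @param tAltMin minimum tumour alt-supporting reads (inclusive).
#' @param nVafMax normal allele-frequency ceiling (strict \code{<}).
#' @return a list with \code{pass} (the passing
#'   [SomaticVariantSet-class]) and \code{report} (a
#'   [FilterReport-class] attributing each rejection to the first failing
#'   criterion).
#' @examples
#' v <- SomaticVariantSet(data.frame(
#'   chrom = "chr1", pos = 1:2, ref = "A", alt = "G",
#'   qscore = c(30, 10), filter = "PASS",
#'   t_depth = 40L, t_alt = 16L, n_depth = 40L, n_alt = 0L))
#' filterNuclear(v)$report
#' @export
filterNuclear <- function(x, qscoreMin = 18, tCovMin = 21, nCovMin = 21,
                          tVafMin = 0.25, tAltMin = 6, nVafMax = 0.02) {
    d <- x@data
    tvaf <- tumourVAF(x)
    nvaf <- normalVAF(x)
    applyCriteria(x, list(
        pass_flag = d$filter == "PASS",
        qscore = d$qscore >= qscoreMin,
        tumour_coverage = d$t_depth >= tCovMin,
        normal_coverage = d$n_depth >= nCovMin,
        tumour_frequency = !is.nan(tvaf) & tvaf > tVafMin,
        tumour_alt_reads = d$t_alt >= tAltMin,
        normal_frequency = !is.nan(nvaf) & nvaf < nVafMax))
}

#' Filter mitochondrial somatic variants
#'
#' Applies the five mitochondrial criteria (see [filterDefaults()]):
#' PASS, quality >= 18, tumour frequency > 0.05, >= 5 supporting reads,
#' normal frequency < 0.05. No coverage minima are applied, matching the
#' published list. Zero-depth sites fail the corresponding frequency
#' criterion.
#'
#' @inheritParams filterNuclear
#' @return as [filterNuclear()].
#' @export
filterMito <- function(x, qscoreMin = 18, tVafMin = 0.05, tAltMin = 5,
                       nVafMax = 0.05) {
    d <- x@data
    tvaf <- tumourVAF(x)
    nvaf <- normalVAF(x)
    applyCriteria(x, list(
        pass_flag = d$filter == "PASS",
        qscore = d$qscore >= qscoreMin,
        tumour_frequency = !is.nan(tvaf) & tvaf > tVafMin,
        tumour_alt_reads = d$t_alt >= tAltMin,
        normal_frequency = !is.nan(nvaf) & nvaf < nVafMax))
}

#' NUMT read-pair filter
#'
#' Nuclear-embedded mitochondrial segments (NUMTs) contaminate chrM
#' alignments with reads whose mates map elsewhere. Following the
#' published rule, only read pairs in which BOTH mates are mapped and both
#' map to the mitochondrial contig are retained for mtDNA analysis.
#'
#' @param pairs a \code{data.frame} with columns \code{mate1_chrom},
#'   \code{mate2_chrom} (contig of each mate; \code{NA} for an absent
#'   mate, i.e. single-end), \code{mate1_mapped}, \code{mate2_mapped}
#'   (logical).
#' @param mitoChrom name of the mitochondrial contig.
#' @return a list: \code{retained} (the subset of \code{pairs} kept),
#'   \code{nDropped} (pairs failing the rule), \code{nSingleEnd}
#'   (single-end records, dropped and counted separately).
#' @export
numtReadPairFilter <- function(pairs, mitoChrom = "chrM") {
    single <- is.na(pairs$mate1_chrom) | is.na(pairs$mate2_chrom)
    keep <- !single &
        pairs$mate1_mapped & pairs$mate2_mapped &
        pairs$mate1_chrom == mitoChrom & pairs$mate2_chrom == mitoChrom
    keep[is.na(keep)] <- FALSE
    list(retained = pairs[keep, , drop = FALSE],
         nDropped = sum(!keep & !single),
         nSingleEnd = sum(single))
}

#' Tumour mutational burden
#'
#' TMB is the number of somatic coding base substitutions and indels
#' (including synonymous changes) per megabase of coding sequence
#' examined. The caller is responsible for restricting the variants to
#' the coding footprint; noncoding variants are not part of TMB.
#'
#' @param nCoding number of passing coding mutations (or a
#'   [SomaticVariantSet-class], whose length is used).
#' @param codingRegionSize size of the examined coding footprint in bases
#'   (> 0).
#' @return mutations per megabase.
#' @examples
#' computeTmb(12, 30e6)   # 0.4 mutations/Mb
#' @export
computeTmb <- function(nCoding, codingRegionSize) {
    if (is(nCoding, "SomaticVariantSet"))
        nCoding <- length(nCoding)
    if (!is.finite(codingRegionSize) || codingRegionSize <= 0)
        stop("codingRegionSize must be > 0")
    nCoding / (codingRegionSize / 1e6)
}

#' Variant-density cluster filter
#'
#' Automatable stand-in for manual review of variant-rich regions: if
#' more than \code{maxPerWindow} passing variants fall within any window
#' of \code{windowSize} bases on one contig, the whole cluster is
#' rejected. Off by default in the pipeline; read-end artefact review has
#' no VCF-level counterpart and is not attempted.
#'
#' @param x a [SomaticVariantSet-class]
#' @param maxPerWindow maximum variants tolerated per window.
#' @param windowSize window width in bases.
#' @return a list with \code{pass} and \code{rejected} variant sets.
#' @export
densityFilter <- function(x, maxPerWindow = 3L, windowSize = 100L) {
    d <- x@data
    drop <- rep(FALSE, nrow(d))
    for (chrom in unique(d$chrom)) {
        idx <- which(d$chrom == chrom)
        p <- d$pos[idx]
        for (i in seq_along(idx)) {
            inWin <- abs(p - p[i]) < windowSize
            if (sum(inWin) > maxPerWindow)
                drop[idx[inWin]] <- TRUE
        }
    }
    list(pass = x[!drop], rejected = x[drop])
}
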