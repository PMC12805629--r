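#' Heteroplasmy level of a mitochondrial variant
#'
#' The heteroplasmy level is the proportion of mutant reads among the
#' total reads at the mutation site.
#'
#' @param alt alt-supporting read count(s).
#' @param depth total read depth(s); a zero depth is an error, since the
#'   level is undefined there.
#' @return numeric fraction(s) in [0, 1].
#' @examples
#' heteroplasmy(18, 360)    # 0.05
#' heteroplasmy(360, 360)   # 1 (homoplasmy)
#' @export
heteroplasmy <- function(alt, depth) {
    if (any(depth <= 0))
        stop("heteroplasmy is undefined at zero depth")
    if (any(alt < 0 | alt > depth))
        stop("alt reads must lie in [0, depth]")
    alt / depth
}

#' Classify a tumour/normal heteroplasmic shift
#'
#' A mutation is \code{tumour-specific} when it is effectively absent in
#' the matched normal (normal heteroplasmy below \code{threshold}) and
#' \code{tumour-enriched} when it is present in the normal but at a
#' higher level in the tumour. Anything else is \code{no-shift}; the
#' mitochondrial filter removes such variants upstream.
#'
#' @param hTumour,hNormal heteroplasmy levels in tumour and normal
#'   (vectors recycle).
#' @param threshold the presence threshold (default 0.05, the same value
#'   the mitochondrial filter uses for the normal-frequency criterion).
#' @return character vector of shift classes.
#' @examples
#' classifyShift(0.40, 0.00)  # tumour-specific
#' classifyShift(0.40, 0.06)  # tumour-enriched
#' @export
classifyShift <- function(hTumour, hNormal, threshold = 0.05) {
    ifelse(hNormal < threshold, "tumour-specific",
           ifelse(hTumour > hNormal, "tumour-enriched", "no-shift"))
}

#' Annotate a mitochondrial variant set with heteroplasmy columns
#'
#' Adds \code{h_tumour}, \code{h_normal}, \code{shift_class} and
#' \code{region} columns to a filtered mitochondrial variant set.
#'
#' @param x a [SomaticVariantSet-class] on the mitochondrial contig.
#' @param map mitochondrial region map (see [readMitoRegionMap()]).
#' @param threshold shift-classification threshold.
#' @return the annotated [SomaticVariantSet-class].
#' @export
annotateMitoVariants <- function(x, map = readMitoRegionMap(),
                                 threshold = 0.05) {
    d <- x@data
    if (!nrow(d))
        return(x)
    d$h_tumour <- heteroplasmy(d$t_alt, d$t_depth)
    d$h_normal <- ifelse(d$n_depth > 0L, d$n_alt / d$n_depth, 0)
    d$shift_class <- classifyShift(d$h_tumour, d$h_normal, threshold)
    x@data <- d
    d$region <- assignMitoRegion(x, map)
    x@data <- d
    x
}

#' Mutation density per kilobase per patient
#'
#' \code{n / (contigKb * nPatients)}: the statistic used to compare the
#' mutation load of the 16.6 kb mitochondrial genome with the nuclear
#' genome, where it differs by orders of magnitude.
#'
#' @param nMutations mutation count.
#' @param contigKb contig (or genome) length in kilobases, > 0.
#' @param nPatients number of patients, > 0.
#' @return mutations per kb per patient.
#' @examples
#' mutationDensity(43, 16.569, 10)   # ~0.26/kbp
#' @export
mutationDensity <- function(nMutations, contigKb, nPatients) {
    if (!is.finite(contigKb) || contigKb <= 0)
        stop("contigKb must be > 0")
    if (!is.finite(nPatients) || nPatients <= 0)
        stop("nPatients must be > 0")
    nMutations / (contigKb * nPatients)
}

#' Nuclear genome size constant for density comparisons
#'
#' Total length of the hg38 primary assembly in kilobases, used as the
#' default denominator when contrasting mitochondrial and nuclear
#' mutation densities.
#' @export
NUCLEAR_GENOME_KB <- 3099734

#' Compare heteroplasmy levels between groups
#'
#' Splits heteroplasmy levels by a grouping label (functional region or
#' consequence class) and, for exactly two non-empty groups, performs a
#' two-sided Mann-Whitney U (Wilcoxon rank-sum) test. With more than two
#' groups only the per-group values are returned; empty groups are
#' dropped with a message.
#'
#' @param levels numeric heteroplasmy levels.
#' @param groups grouping labels, parallel to \code{levels}.
#' @return a list: \code{values} (named list of per-group levels),
#'   \code{pValue} (two-group comparisons only, else \code{NA}),
#'   \code{statistic} (the U statistic, else \code{NA}).
#' @export
heteroplasmyByGroup <- function(levels, groups) {
    stopifnot(length(levels) == length(groups))
    values <- split(levels, groups)
    empty <- lengths(values) == 0L
    if (any(empty)) {
        message("dropping empty group(s): ",
                paste(names(values)[empty], collapse = ", "))
        values <- values[!empty]
    }
    p <- NA_real_
    u <- NA_real_
    if (length(values) == 2L) {
        wt <- stats::wilcox.test(values[[1]], values[[2]],
                                 alternative = "two.sided", exact = FALSE,
                                 correct = FALSE)
        p <- wt$p.value
        u <- unname(wt$statistic)
    } else if (length(values) < 2L) {
        message("fewer than two non-empty groups; comparison skipped")
    }
    list(values = values, pValue = p, statistic = u)
}
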