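#' Construct a SomaticVariantSet
#'
#' @param data a \code{data.frame} or \code{DataFrame} with at least the
#'   columns \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#'   \code{qscore}, \code{filter}, \code{t_depth}, \code{t_alt},
#'   \code{n_depth}, \code{n_alt}. The \code{kind} column is derived from
#'   the alleles if absent.
#' @return a [SomaticVariantSet-class] object.
#' @examples
#' v <- SomaticVariantSet(data.frame(
#'   chrom = "chr1", pos = 100L, ref = "A", alt = "G",
#'   qscore = 30, filter = "PASS",
#'   t_depth = 100L, t_alt = 40L, n_depth = 90L, n_alt = 0L))
#' tumourVAF(v)
#' @export
SomaticVariantSet <- function(data = data.frame()) {
    d <- DataFrame(data)
    if (nrow(d) == 0L && !all(VARIANT_COLUMNS %in% colnames(d))) {
        d <- DataFrame(chrom = character(), pos = integer(),
                       ref = character(), alt = character(),
                       qscore = numeric(), filter = character(),
                       t_depth = integer(), t_alt = integer(),
                       n_depth = integer(), n_alt = integer(),
                       kind = character())
    }
    if (!"kind" %in% colnames(d) && nrow(d) > 0L)
        d$kind <- variantKindFromAlleles(d$ref, d$alt)
    rownames(d) <- NULL
    new("SomaticVariantSet", data = d)
}

variantKindFromAlleles <- function(ref, alt) {
    ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
           ifelse(nchar(alt) > nchar(ref), "insertion", "deletion"))
}

#' @describeIn SomaticVariantSet number of variants
#' @param x a \code{SomaticVariantSet}
#' @export
setMethod("length", "SomaticVariantSet", function(x) nrow(x@data))

#' Extract the variant table
#'
#' @param x a [SomaticVariantSet-class]
#' @return the underlying \code{DataFrame}.
#' @export
setGeneric("variantData", function(x) standardGeneric("variantData"))

#' @rdname variantData
#' @export
setMethod("variantData", "SomaticVariantSet", function(x) x@data)

#' @export
setMethod("[", "SomaticVariantSet", function(x, i, j, ..., drop = FALSE) {
    initialize(x, data = x@data[i, , drop = FALSE])
})

#' Tumour and normal variant allele frequencies
#'
#' VAF is alt-supporting reads over total reads at the site. A zero total
#' depth yields \code{NaN} rather than an error; the filters treat that as
#' a failed frequency criterion.
#'
#' @param x a [SomaticVariantSet-class]
#' @return numeric vector of allele frequencies.
#' @export
setGeneric("tumourVAF", function(x) standardGeneric("tumourVAF"))

#' @rdname tumourVAF
#' @export
setMethod("tumourVAF", "SomaticVariantSet", function(x)
    ifelse(x@data$t_depth > 0L, x@data$t_alt / x@data$t_depth, NaN))

#' @rdname tumourVAF
#' @export
setGeneric("normalVAF", function(x) standardGeneric("normalVAF"))

#' @rdname tumourVAF
#' @export
setMethod("normalVAF", "SomaticVariantSet", function(x)
    ifelse(x@data$n_depth > 0L, x@data$n_alt / x@data$n_depth, NaN))

#' @export
setMethod("show", "SomaticVariantSet", function(object) {
    d <- object@data
    cat("SomaticVariantSet with", nrow(d), "variants\n")
    if (nrow(d)) {
        kinds <- table(d$kind)
        cat("  kinds:", paste(names(kinds), kinds, sep = "=", collapse = ", "),
            "\n")
        cat("  contigs:", paste(unique(d$chrom), collapse = ", "), "\n")
        extra <- setdiff(colnames(d), VARIANT_COLUMNS)
        if (length(extra))
            cat("  annotation columns:", paste(extra, collapse = ", "), "\n")
    }
    invisible(object)
})

#' Coerce a SomaticVariantSet to data.frame
#'
#' @param x a [SomaticVariantSet-class]
#' @param row.names,optional,... passed on to the DataFrame method
#' @exportS3Method base::as.data.frame
#' @export
as.data.frame.SomaticVariantSet <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
    as.data.frame(x@data, row.names = row.names, optional = optional, ...)
}

setMethod("as.data.frame", "SomaticVariantSet",
          as.data.frame.SomaticVariantSet)

#' Combine variant sets
#'
#' @param x,... \code{SomaticVariantSet} objects with compatible columns.
#' @export
setMethod("c", "SomaticVariantSet", function(x, ...) {
    sets <- list(x, ...)
    tabs <- lapply(sets, function(s) s@data)
    initialize(x, data = do.call(rbind, tabs))
})

#' Show method for filter reports
#' @param object a [FilterReport-class]
#' @export
setMethod("show", "FilterReport", function(object) {
    cat("FilterReport:", object@passed, "of", object@input,
        "variants passed\n")
    rej <- object@rejected[object@rejected > 0L]
    for (nm in names(rej))
        cat(sprintf("  rejected by %s: %d\n", nm, rej[[nm]]))
    invisible(object)
})

#' Accessors for FilterReport tallies
#'
#' @param x a [FilterReport-class]
#' @return \code{nPassed}/\code{nInput}: integer counts;
#'   \code{rejections}: named integer vector of first-failing-criterion
#'   rejection counts.
#' @export
setGeneric("nPassed", function(x) standardGeneric("nPassed"))
#' @rdname nPassed
#' @export
setMethod("nPassed", "FilterReport", function(x) x@passed)
#' @rdname nPassed
#' @export
setGeneric("nInput", function(x) standardGeneric("nInput"))
#' @rdname nPassed
#' @export
setMethod("nInput", "FilterReport", function(x) x@input)
#' @rdname nPassed
#' @export
setGeneric("rejections", function(x) standardGeneric("rejections"))
#' @rdname nPassed
#' @export
setMethod("rejections", "FilterReport", function(x) x@rejected)
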