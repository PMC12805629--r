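#' Read a mitochondrial region map
#'
#' Tab-separated table describing the functional regions of the circular
#' mitochondrial contig with columns \code{region}, \code{start},
#' \code{end} (1-based closed) and \code{class} (one of \code{gene},
#' \code{rRNA}, \code{tRNA}, \code{dloop}, \code{sub}). The D-loop wraps
#' the origin and is stored as two rows (16024-16569 and 1-576 on the
#' rCRS); hypervariable region I is a \code{sub} row reported as a
#' sub-tally of the D-loop, not a competing region.
#'
#' @param path TSV path; defaults to the packaged rCRS-coordinate map.
#' @return a \code{GRanges} on \code{chrM} with \code{name} and
#'   \code{class} metadata columns.
#' @seealso [mitoRegionTally()]
#' @export
readMitoRegionMap <- function(path = system.file("extdata",
                                                 "mito_regions_rcrs.tsv",
                                                 package = "MitoSoma")) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("region", "start", "end", "class")
    if (!all(need %in% colnames(tab)))
        stop("mito region map must have columns: ",
             paste(need, collapse = ", "))
    GenomicRanges::GRanges("chrM", IRanges::IRanges(tab$start, tab$end),
                           name = tab$region, class = tab$class)
}

#' Assign mitochondrial variants to functional regions
#'
#' Each variant is assigned to exactly one region: the D-loop takes
#' precedence over any overlapping feature, then the first overlapping
#' gene/rRNA/tRNA row of the map, and \code{other} is the catch-all, so
#' region counts always sum to the number of variants.
#'
#' @param x a [SomaticVariantSet-class] on the mitochondrial contig.
#' @param map region map \code{GRanges} from [readMitoRegionMap()].
#' @param contigLength mitochondrial contig length (rCRS 16,569 bp); a
#'   variant position beyond it is an error.
#' @return character vector of region names, one per variant.
#' @export
assignMitoRegion <- function(x, map = readMitoRegionMap(),
                             contigLength = 16569L) {
    d <- x@data
    if (!nrow(d))
        return(character())
    if (any(d$pos > contigLength))
        stop("variant position beyond mitochondrial contig length")
    cls <- S4Vectors::mcols(map)$class
    nm <- S4Vectors::mcols(map)$name
    pos_gr <- GenomicRanges::GRanges("chrM", IRanges::IRanges(d$pos, d$pos))
    out <- rep("other", nrow(d))
    dl <- map[cls == "dloop"]
    hit <- !is.na(GenomicRanges::findOverlaps(pos_gr, dl, select = "first"))
    out[hit] <- S4Vectors::mcols(dl)$name[1]
    main <- map[cls %in% c("gene", "rRNA", "tRNA")]
    first <- GenomicRanges::findOverlaps(pos_gr, main, select = "first")
    todo <- !hit & !is.na(first)
    out[todo] <- S4Vectors::mcols(main)$name[first[todo]]
    out
}

#' Per-region mtDNA mutation tally with rates
#'
#' Region-level counts, sizes and per-Mb per-patient rates for
#' mitochondrial variants, with hypervariable region I reported as a
#' sub-tally of the D-loop (attribute \code{hvr1Count}). Region sizes are
#' summed interval widths from the map; \code{other} is the remainder of
#' the contig not covered by D-loop/gene/rRNA/tRNA rows.
#'
#' @inheritParams assignMitoRegion
#' @param nPatients number of patients contributing the variants.
#' @return a \code{data.frame} as from [regionTally()] (one row per
#'   region that the map names, plus \code{other}), with attributes
#'   \code{hvr1Count} and \code{nPatients}.
#' @export
mitoRegionTally <- function(x, map = readMitoRegionMap(), nPatients = 1L,
                            contigLength = 16569L) {
    labels <- assignMitoRegion(x, map, contigLength)
    cls <- S4Vectors::mcols(map)$class
    nm <- S4Vectors::mcols(map)$name
    keep <- cls %in% c("dloop", "gene", "rRNA", "tRNA")
    sizes <- tapply(GenomicRanges::width(map)[keep], nm[keep], sum)
    # D-loop first, then map order, then the catch-all remainder
    region_order <- unique(nm[keep][order(cls[keep] != "dloop")])
    sizes <- sizes[region_order]
    covered <- sum(GenomicRanges::width(GenomicRanges::reduce(map[keep])))
    sizes <- c(sizes, other = max(1, contigLength - covered))
    out <- regionTally(labels, sizes, nPatients)
    hvr <- map[cls == "sub"]
    hvr1 <- 0L
    if (length(hvr) && nrow(x@data)) {
        pos_gr <- GenomicRanges::GRanges("chrM",
                                         IRanges::IRanges(x@data$pos,
                                                          x@data$pos))
        dlname <- S4Vectors::mcols(map)$name[cls == "dloop"][1]
        inhvr <- !is.na(GenomicRanges::findOverlaps(pos_gr, hvr,
                                                    select = "first"))
        hvr1 <- sum(inhvr & labels == dlname)
    }
    attr(out, "hvr1Count") <- hvr1
    attr(out, "nPatients") <- nPatients
    out
}
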