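#' Read a paired tumour/normal VCF
#'
#' Parses a VCF 4.2 file containing both the tumour and the normal sample
#' and returns one [SomaticVariantSet-class] row per ALT allele
#' (multi-allelic records are split). Per-sample total depth is taken from
#' \code{FORMAT/DP} and alt-supporting reads from \code{FORMAT/AD}; the
#' somatic quality score is taken from \code{QUAL} by default or from a
#' named \code{INFO} key. Samples are identified strictly by name, never
#' by column order.
#'
#' Records missing depth or allelic-depth values for either sample are
#' skipped with a single summarising warning; the number skipped is
#' available as \code{attr(result, "nSkipped")}.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param tumourSample,normalSample sample names as given in the VCF
#'   header. A missing sample name is an error.
#' @param qscoreKey where to read the somatic quality score:
#'   \code{"QUAL"} (default) or the name of an INFO field.
#' @return a [SomaticVariantSet-class]; attribute \code{nSkipped} counts
#'   records dropped for missing depth fields.
#' @export
readPairedVcf <- function(path, tumourSample, normalSample,
                          qscoreKey = "QUAL") {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
    samples <- colnames(vcf)
    for (s in c(tumourSample, normalSample))
        if (!s %in% samples)
            stop("sample '", s, "' not present in ", path,
                 " (samples: ", paste(samples, collapse = ", "), ")")
    g <- VariantAnnotation::geno(vcf)
    if (!all(c("DP", "AD") %in% names(g)))
        stop("VCF must carry per-sample FORMAT/DP and FORMAT/AD")
    rr <- SummarizedExperiment::rowRanges(vcf)
    chrom <- as.character(GenomicRanges::seqnames(rr))
    pos <- GenomicRanges::start(rr)
    ref <- as.character(rr$REF)
    alts <- rr$ALT                       # DNAStringSetList, one set per record
    qual <- rr$QUAL
    filt <- VariantAnnotation::fixed(vcf)$FILTER
    if (!identical(qscoreKey, "QUAL")) {
        info <- VariantAnnotation::info(vcf)
        if (!qscoreKey %in% colnames(info))
            stop("INFO key '", qscoreKey, "' not present in ", path)
        qual <- as.numeric(info[[qscoreKey]])
    }
    dp <- g$DP
    ad <- g$AD
    n <- length(rr)
    rows <- vector("list", n)
    skipped <- 0L
    for (i in seq_len(n)) {
        alt_i <- as.character(alts[[i]])
        t_dp <- dp[i, tumourSample][[1]]
        n_dp <- dp[i, normalSample][[1]]
        t_ad <- ad[i, tumourSample][[1]]
        n_ad <- ad[i, normalSample][[1]]
        if (is.na(t_dp) || is.na(n_dp) ||
            length(t_ad) < 1L + length(alt_i) || anyNA(t_ad) ||
            length(n_ad) < 1L + length(alt_i) || anyNA(n_ad)) {
            skipped <- skipped + 1L
            next
        }
        j <- seq_along(alt_i)
        rows[[i]] <- data.frame(
            chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alt_i,
            qscore = as.numeric(qual[i]), filter = filt[i],
            t_depth = as.integer(t_dp), t_alt = as.integer(t_ad[1L + j]),
            n_depth = as.integer(n_dp), n_alt = as.integer(n_ad[1L + j]),
            stringsAsFactors = FALSE)
    }
    if (skipped > 0L)
        warning(skipped, " record(s) lacking depth fields were skipped")
    out <- SomaticVariantSet(do.call(rbind,
                                     c(rows[!vapply(rows, is.null, logical(1))],
                                       list(make.row.names = FALSE))))
    attr(out, "nSkipped") <- skipped
    out
}

#' Write a paired tumour/normal VCF
#'
#' Emits a minimal VCF 4.2 with \code{QUAL} carrying the somatic quality
#' score, the stored \code{FILTER} string, and a \code{GT:DP:AD} FORMAT
#' block for the two samples. Reading the file back with [readPairedVcf()]
#' reproduces the variant table field for field.
#'
#' @param x a [SomaticVariantSet-class]
#' @param path output path.
#' @param tumourSample,normalSample sample column names to write.
#' @param contigLengths optional named integer vector used to emit
#'   \code{##contig} header lines.
#' @return \code{path}, invisibly.
#' @export
writePairedVcf <- function(x, path, tumourSample = "TUMOUR",
                           normalSample = "NORMAL",
                           contigLengths = NULL) {
    d <- as.data.frame(x)
    hdr <- c("##fileformat=VCFv4.2",
             "##source=MitoSoma",
             '##FILTER=<ID=PASS,Description="All filters passed">',
             '##FILTER=<ID=base_quality,Description="Failed caller quality model">',
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
             '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')
    if (!is.null(contigLengths))
        hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                              names(contigLengths), contigLengths))
    hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", tumourSample,
                        normalSample, sep = "\t"))
    body <- character(0)
    if (nrow(d)) {
        ord <- order(d$chrom, d$pos)
        d <- d[ord, , drop = FALSE]
        t_fmt <- sprintf("0/1:%d:%d,%d", d$t_depth, d$t_depth - d$t_alt,
                         d$t_alt)
        n_fmt <- sprintf("0/0:%d:%d,%d", d$n_depth, d$n_depth - d$n_alt,
                         d$n_alt)
        body <- paste(d$chrom, d$pos, ".", d$ref, d$alt,
                      format(d$qscore, trim = TRUE, scientific = FALSE),
                      d$filter, ".", "GT:DP:AD", t_fmt, n_fmt, sep = "\t")
    }
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read a BED file of intervals
#'
#' Accepts BED3 or wider; the fourth column, when present, becomes the
#' interval label (\code{name} metadata column). BED's 0-based half-open
#' coordinates are converted at this boundary to the 1-based closed
#' convention used internally (\code{GRanges}).
#'
#' @param path BED file path. An empty file yields an empty
#'   \code{GRanges}.
#' @return a [GenomicRanges::GRanges] with a \code{name} metadata column.
#' @export
readBedFile <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
    if (!length(lines))
        return(GenomicRanges::GRanges(name = character()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop("BED line ", which(nf < 3L)[1], ": fewer than 3 columns")
    chrom <- vapply(fields, `[[`, "", 1L)
    start0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end0 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    if (anyNA(start0) || anyNA(end0))
        stop("BED line ", which(is.na(start0) | is.na(end0))[1],
             ": non-numeric coordinates")
    bad <- start0 >= end0
    if (any(bad))
        stop("BED line ", which(bad)[1], ": start >= end")
    name <- ifelse(nf >= 4L, vapply(fields, function(f)
        if (length(f) >= 4L) f[[4L]] else "", ""), "")
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(start0 + 1L, end0),
                           name = name)
}

#' Write intervals to a BED file
#'
#' The inverse of [readBedFile()]: internal 1-based closed ranges are
#' written as 0-based half-open BED records, with the \code{name} metadata
#' column as the fourth field when present.
#'
#' @param gr a \code{GRanges}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBedFile <- function(gr, path) {
    if (!length(gr)) {
        writeLines(character(0), path)
        return(invisible(path))
    }
    chrom <- as.character(GenomicRanges::seqnames(gr))
    start0 <- GenomicRanges::start(gr) - 1L
    end0 <- GenomicRanges::end(gr)
    if ("name" %in% colnames(S4Vectors::mcols(gr)))
        writeLines(paste(chrom, start0, end0, S4Vectors::mcols(gr)$name,
                         sep = "\t"), path)
    else
        writeLines(paste(chrom, start0, end0, sep = "\t"), path)
    invisible(path)
}

#' Read a known-hotspot region table
#'
#' Tab-separated table with columns \code{chrom}, \code{start},
#' \code{end}, \code{name}, \code{source} describing previously reported
#' recurrently mutated noncoding regions (1-based closed coordinates).
#'
#' @param path TSV path with a header line.
#' @return a \code{GRanges} with \code{name} and \code{source} metadata.
#' @export
readHotspotTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "name", "source")
    if (!all(need %in% colnames(tab)))
        stop("hotspot table must have columns: ",
             paste(need, collapse = ", "))
    bad <- !is.finite(tab$start) | !is.finite(tab$end) | tab$start > tab$end
    if (any(bad))
        stop("hotspot table row ", which(bad)[1], ": malformed interval")
    GenomicRanges::GRanges(tab$chrom, IRanges::IRanges(tab$start, tab$end),
                           name = tab$name, source = tab$source)
}
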