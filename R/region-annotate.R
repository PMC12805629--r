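#' Construct a TranscriptAnnotation
#'
#' Assembles the per-gene feature intervals used for consequence
#' classification. Splice windows — the 2 bp of intron immediately beyond
#' each internal exon boundary — are derived here from the exon ranges:
#' on the plus strand the two intronic bases after an exon end form a
#' donor window and the two before the next exon start an acceptor
#' window; on the minus strand the roles are swapped.
#'
#' @param genes \code{GRanges} of gene bodies with metadata columns
#'   \code{gene} (identifier) and \code{type} (\code{"coding"} or
#'   \code{"ncRNA"}); strand is taken from the \code{GRanges} strand.
#' @param exons,cds,utr5,utr3 \code{GRanges} with a \code{gene} metadata
#'   column. Per gene, the total CDS length must be a multiple of 3.
#' @return a [TranscriptAnnotation-class].
#' @export
TranscriptAnnotation <- function(genes = GenomicRanges::GRanges(),
                                 exons = GenomicRanges::GRanges(),
                                 cds = GenomicRanges::GRanges(),
                                 utr5 = GenomicRanges::GRanges(),
                                 utr3 = GenomicRanges::GRanges()) {
    if (length(genes) && !all(c("gene", "type") %in%
                              colnames(S4Vectors::mcols(genes))))
        stop("genes must carry 'gene' and 'type' metadata columns")
    for (gr in list(exons, cds, utr5, utr3))
        if (length(gr) && !"gene" %in% colnames(S4Vectors::mcols(gr)))
            stop("feature ranges must carry a 'gene' metadata column")
    if (length(cds)) {
        persum <- tapply(GenomicRanges::width(cds),
                         S4Vectors::mcols(cds)$gene, sum)
        if (any(persum %% 3L != 0L))
            stop("CDS length not divisible by 3 for gene(s): ",
                 paste(names(persum)[persum %% 3L != 0L], collapse = ", "))
    }
    new("TranscriptAnnotation", genes = genes, exons = exons, cds = cds,
        utr5 = utr5, utr3 = utr3, splice = spliceWindows(exons))
}

# 2-bp intronic windows flanking internal exon boundaries
spliceWindows <- function(exons) {
    if (!length(exons))
        return(GenomicRanges::GRanges(gene = character(),
                                      site = character()))
    out <- list()
    for (g in unique(S4Vectors::mcols(exons)$gene)) {
        ex <- exons[S4Vectors::mcols(exons)$gene == g]
        if (length(ex) < 2L) next
        ex <- ex[order(GenomicRanges::start(ex))]
        minus <- as.character(GenomicRanges::strand(ex)[1]) == "-"
        chrom <- as.character(GenomicRanges::seqnames(ex)[1])
        ends <- GenomicRanges::end(ex)[-length(ex)]
        starts <- GenomicRanges::start(ex)[-1]
        # plus strand: after exon end = donor, before next exon = acceptor
        out[[g]] <- GenomicRanges::GRanges(
            chrom,
            IRanges::IRanges(c(ends + 1L, starts - 2L),
                             c(ends + 2L, starts - 1L)),
            gene = g,
            site = c(rep(if (minus) "acceptor" else "donor", length(ends)),
                     rep(if (minus) "donor" else "acceptor", length(starts))))
    }
    if (!length(out))
        return(GenomicRanges::GRanges(gene = character(),
                                      site = character()))
    suppressWarnings(unname(do.call(c, unname(out))))
}

#' @export
setMethod("show", "TranscriptAnnotation", function(object) {
    cat("TranscriptAnnotation:", length(object@genes), "genes,",
        length(object@exons), "exons,", length(object@cds), "CDS ranges,",
        length(object@splice), "splice windows\n")
    invisible(object)
})

#' Feature accessors for TranscriptAnnotation
#'
#' @param x a [TranscriptAnnotation-class]
#' @return the requested feature \code{GRanges}.
#' @export
setGeneric("geneRanges", function(x) standardGeneric("geneRanges"))
#' @rdname geneRanges
#' @export
setMethod("geneRanges", "TranscriptAnnotation", function(x) x@genes)
#' @rdname geneRanges
#' @export
setGeneric("cdsRanges", function(x) standardGeneric("cdsRanges"))
#' @rdname geneRanges
#' @export
setMethod("cdsRanges", "TranscriptAnnotation", function(x) x@cds)
#' @rdname geneRanges
#' @export
setGeneric("spliceRanges", function(x) standardGeneric("spliceRanges"))
#' @rdname geneRanges
#' @export
setMethod("spliceRanges", "TranscriptAnnotation", function(x) x@splice)

variantPositions <- function(x) {
    d <- x@data
    GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$pos, d$pos))
}

# CDS-relative coordinate (1-based along the spliced, strand-oriented CDS)
# and the spliced CDS sequence for one gene.
cdsModel <- function(annotation, genome, gene) {
    cr <- annotation@cds[S4Vectors::mcols(annotation@cds)$gene == gene]
    cr <- cr[order(GenomicRanges::start(cr))]
    chrom <- as.character(GenomicRanges::seqnames(cr)[1])
    minus <- as.character(GenomicRanges::strand(cr)[1]) == "-"
    seq <- paste(vapply(seq_along(cr), function(i)
        substring(genomeSequence(genome, chrom),
                  GenomicRanges::start(cr)[i], GenomicRanges::end(cr)[i]),
        ""), collapse = "")
    if (minus)
        seq <- revComp(seq)
    list(ranges = cr, chrom = chrom, minus = minus, seq = seq)
}

cdsOffset <- function(model, pos) {
    st <- GenomicRanges::start(model$ranges)
    en <- GenomicRanges::end(model$ranges)
    w <- en - st + 1L
    hit <- which(pos >= st & pos <= en)
    if (!length(hit))
        return(NA_integer_)
    fwd <- sum(w[seq_len(hit[1] - 1L)]) + (pos - st[hit[1]]) + 1L
    if (model$minus) sum(w) - fwd + 1L else fwd
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revComp <- function(s) {
    vapply(s, function(x) paste(rev(COMPLEMENT[strsplit(x, "")[[1]]]),
                                collapse = ""), "", USE.NAMES = FALSE)
}

geneticCodeFor <- function(genome, chrom) {
    if (chrom %in% circularContigs(genome))
        Biostrings::getGeneticCode("2")   # vertebrate mitochondrial
    else
        Biostrings::getGeneticCode("1")
}

#' Classify coding variants into six consequence categories
#'
#' Assigns each variant overlapping a CDS or splice window to exactly one
#' of: \code{splice_acceptor}, \code{splice_donor}, \code{stop_causing},
#' \code{stop_loss}, \code{nonsynonymous}, \code{synonymous}, with
#' precedence splice > stop-causing > stop-loss > nonsynonymous >
#' synonymous. Codons are decoded with the standard genetic code for
#' nuclear contigs and the vertebrate mitochondrial code for the circular
#' (mitochondrial) contig — under which TGA encodes tryptophan, so a
#' TGG>TGA change on chrM is synonymous rather than stop-causing.
#' CDS indels, which have no codon-level category, are labelled
#' \code{coding_indel}.
#'
#' @param x a [SomaticVariantSet-class]
#' @param annotation a [TranscriptAnnotation-class]
#' @param genome a [ReferenceGenome-class] (its circular set decides the
#'   genetic code per contig).
#' @return character vector, one label per variant; \code{NA} for
#'   variants outside all CDS and splice windows (the caller routes these
#'   to the noncoding path).
#' @export
classifyCoding <- function(x, annotation, genome) {
    d <- x@data
    out <- rep(NA_character_, nrow(d))
    if (!nrow(d))
        return(out)
    pos_gr <- variantPositions(x)
    sp <- annotation@splice
    if (length(sp)) {
        hits <- GenomicRanges::findOverlaps(pos_gr, sp, select = "first")
        hit <- !is.na(hits)
        out[hit] <- paste0("splice_",
                           S4Vectors::mcols(sp)$site[hits[hit]])
    }
    cds <- annotation@cds
    if (length(cds)) {
        hits <- GenomicRanges::findOverlaps(pos_gr, cds, select = "first")
        todo <- which(is.na(out) & !is.na(hits))
        models <- list()
        for (i in todo) {
            if (d$kind[i] != "SNV") {
                out[i] <- "coding_indel"
                next
            }
            gene <- S4Vectors::mcols(cds)$gene[hits[i]]
            if (is.null(models[[gene]]))
                models[[gene]] <- cdsModel(annotation, genome, gene)
            m <- models[[gene]]
            cp <- cdsOffset(m, d$pos[i])
            codon_i <- (cp - 1L) %/% 3L
            within <- (cp - 1L) %% 3L + 1L
            ref_codon <- substring(m$seq, codon_i * 3L + 1L,
                                   codon_i * 3L + 3L)
            alt_base <- if (m$minus) COMPLEMENT[[d$alt[i]]] else d$alt[i]
            alt_codon <- ref_codon
            substring(alt_codon, within, within) <- alt_base
            code <- geneticCodeFor(genome, d$chrom[i])
            ref_aa <- code[[ref_codon]]
            alt_aa <- code[[alt_codon]]
            out[i] <- if (alt_aa == "*" && ref_aa != "*") "stop_causing"
                      else if (ref_aa == "*" && alt_aa != "*") "stop_loss"
                      else if (ref_aa != alt_aa) "nonsynonymous"
                      else "synonymous"
        }
    }
    out
}

#' Classify noncoding variants into functional-region labels
#'
#' One label per variant from \{\code{5'UTR}, \code{3'UTR}, \code{ncRNA},
#' \code{intron}, \code{upstream}, \code{downstream}, \code{intergenic}\}
#' with fixed precedence UTR > ncRNA > intron > upstream/downstream >
#' intergenic. "Upstream" and "downstream" are strand-aware windows of
#' \code{flankWindow} bases beyond the gene body; intergenic is the
#' fallback, so every variant receives exactly one label.
#'
#' @param x a [SomaticVariantSet-class] of non-coding variants.
#' @param annotation a [TranscriptAnnotation-class]
#' @param flankWindow width in bases of the upstream/downstream windows.
#' @return character vector of labels, one per variant.
#' @export
classifyNoncoding <- function(x, annotation, flankWindow = 2000L) {
    d <- x@data
    n <- nrow(d)
    out <- rep(NA_character_, n)
    if (!n)
        return(out)
    pos_gr <- variantPositions(x)
    assign <- function(gr, label) {
        if (!length(gr) || all(!is.na(out)))
            return(invisible())
        hit <- !is.na(GenomicRanges::findOverlaps(pos_gr, gr,
                                                  select = "first"))
        out[is.na(out) & hit] <<- label
    }
    assign(annotation@utr5, "5'UTR")
    assign(annotation@utr3, "3'UTR")
    genes <- annotation@genes
    nc <- genes[S4Vectors::mcols(genes)$type == "ncRNA"]
    assign(nc, "ncRNA")
    coding <- genes[S4Vectors::mcols(genes)$type == "coding"]
    assign(coding, "intron")   # in gene body, past UTR/CDS/splice routing
    if (length(genes)) {
        minus <- as.character(GenomicRanges::strand(genes)) == "-"
        up <- GenomicRanges::GRanges(
            GenomicRanges::seqnames(genes),
            IRanges::IRanges(
                ifelse(minus, GenomicRanges::end(genes) + 1L,
                       pmax(1L, GenomicRanges::start(genes) - flankWindow)),
                ifelse(minus, GenomicRanges::end(genes) + flankWindow,
                       pmax(1L, GenomicRanges::start(genes) - 1L))))
        dn <- GenomicRanges::GRanges(
            GenomicRanges::seqnames(genes),
            IRanges::IRanges(
                ifelse(minus, pmax(1L, GenomicRanges::start(genes) - flankWindow),
                       GenomicRanges::end(genes) + 1L),
                ifelse(minus, pmax(1L, GenomicRanges::start(genes) - 1L),
                       GenomicRanges::end(genes) + flankWindow)))
        assign(up, "upstream")
        assign(dn, "downstream")
    }
    out[is.na(out)] <- "intergenic"
    out
}

#' Partition noncoding variants into cis-regulatory vs nonfunctional
#'
#' A variant is cis-regulatory if its position overlaps at least one
#' candidate cis-regulatory element (cCRE) interval; every other variant
#' is "nonfunctional". Counts are conserved:
#' \code{length(cre) + length(nonfunctional) == length(x)}.
#'
#' @param x a [SomaticVariantSet-class] of noncoding variants.
#' @param ccre a \code{GRanges} of cCRE intervals (e.g. from
#'   [readBedFile()]).
#' @return a list with elements \code{cre} and \code{nonfunctional},
#'   both [SomaticVariantSet-class] objects.
#' @export
partitionCre <- function(x, ccre) {
    if (!length(x))
        return(list(cre = x, nonfunctional = x))
    hit <- !is.na(GenomicRanges::findOverlaps(variantPositions(x), ccre,
                                              select = "first"))
    list(cre = x[hit], nonfunctional = x[!hit])
}

#' Look up variants in known noncoding hotspot regions
#'
#' Reports every overlap between a variant position and a region from a
#' table of previously reported recurrently mutated noncoding regions
#' (see [readHotspotTable()]); a variant inside two listed regions yields
#' two rows.
#'
#' @param x a [SomaticVariantSet-class]
#' @param hotspots a \code{GRanges} with \code{name} and \code{source}
#'   metadata columns.
#' @return a \code{data.frame} with columns \code{variant} (row index in
#'   \code{x}), \code{chrom}, \code{pos}, \code{region}, \code{source};
#'   zero rows when nothing overlaps.
#' @export
lookupKnownHotspots <- function(x, hotspots) {
    empty <- data.frame(variant = integer(), chrom = character(),
                        pos = integer(), region = character(),
                        source = character(), stringsAsFactors = FALSE)
    if (!length(x) || !length(hotspots))
        return(empty)
    ov <- GenomicRanges::findOverlaps(variantPositions(x), hotspots)
    if (!length(ov))
        return(empty)
    i <- S4Vectors::queryHits(ov)
    j <- S4Vectors::subjectHits(ov)
    data.frame(variant = i,
               chrom = x@data$chrom[i], pos = x@data$pos[i],
               region = S4Vectors::mcols(hotspots)$name[j],
               source = S4Vectors::mcols(hotspots)$source[j],
               stringsAsFactors = FALSE)
}

#' Tally positions and windows recurrently mutated across a cohort
#'
#' Reports exact positions mutated in two or more patients, and windowed
#' recurrences: each variant position is extended to a window of
#' \code{window} bases, overlapping windows are merged, and merged
#' regions carrying variants from two or more distinct patients are
#' reported.
#'
#' @param variantSets a named list of [SomaticVariantSet-class], one per
#'   patient (at least two).
#' @param window window width in bases for windowed recurrence (odd;
#'   default 21).
#' @return a list with \code{positions} (\code{chrom}, \code{pos},
#'   \code{nPatients}) and \code{windows} (\code{chrom}, \code{start},
#'   \code{end}, \code{nPatients}).
#' @export
cohortRecurrenceTally <- function(variantSets, window = 21L) {
    stopifnot(length(variantSets) >= 2L)
    if (is.null(names(variantSets)))
        names(variantSets) <- paste0("case", seq_along(variantSets))
    tabs <- lapply(names(variantSets), function(nm) {
        d <- variantSets[[nm]]@data
        if (!nrow(d))
            return(NULL)
        unique(data.frame(patient = nm, chrom = d$chrom, pos = d$pos,
                          stringsAsFactors = FALSE))
    })
    all_pos <- do.call(rbind, tabs)
    empty_pos <- data.frame(chrom = character(), pos = integer(),
                            nPatients = integer(), stringsAsFactors = FALSE)
    empty_win <- data.frame(chrom = character(), start = integer(),
                            end = integer(), nPatients = integer(),
                            stringsAsFactors = FALSE)
    if (is.null(all_pos) || !nrow(all_pos))
        return(list(positions = empty_pos, windows = empty_win))
    key <- paste(all_pos$chrom, all_pos$pos)
    counts <- tapply(all_pos$patient, key, function(p) length(unique(p)))
    rec <- counts[counts >= 2L]
    positions <- empty_pos
    if (length(rec)) {
        parts <- strsplit(names(rec), " ", fixed = TRUE)
        positions <- data.frame(
            chrom = vapply(parts, `[[`, "", 1L),
            pos = as.integer(vapply(parts, `[[`, "", 2L)),
            nPatients = as.integer(rec), stringsAsFactors = FALSE)
        positions <- positions[order(positions$chrom, positions$pos), ,
                               drop = FALSE]
        rownames(positions) <- NULL
    }
    half <- (window - 1L) %/% 2L
    gr <- GenomicRanges::GRanges(
        all_pos$chrom,
        IRanges::IRanges(pmax(1L, all_pos$pos - half), all_pos$pos + half),
        patient = all_pos$patient)
    merged <- GenomicRanges::reduce(gr)
    ov <- GenomicRanges::findOverlaps(merged, gr)
    npat <- tapply(all_pos$patient[S4Vectors::subjectHits(ov)],
                   S4Vectors::queryHits(ov),
                   function(p) length(unique(p)))
    keep <- as.integer(names(npat)[npat >= 2L])
    windows <- empty_win
    if (length(keep)) {
        m <- merged[keep]
        windows <- data.frame(
            chrom = as.character(GenomicRanges::seqnames(m)),
            start = GenomicRanges::start(m), end = GenomicRanges::end(m),
            nPatients = as.integer(npat[npat >= 2L]),
            stringsAsFactors = FALSE)
        rownames(windows) <- NULL
    }
    list(positions = positions, windows = windows)
}

#' Per-region mutation counts and rates
#'
#' Generic region tally: counts variants per region label and computes
#' the per-megabase, per-patient mutation rate
#' \code{count / (size_Mb * nPatients)}.
#'
#' @param labels character vector of region labels, one per variant.
#' @param regionSizes named numeric vector of region sizes in bases.
#' @param nPatients number of patients in the cohort.
#' @return a \code{data.frame} with columns \code{region}, \code{count},
#'   \code{size_bp}, \code{ratePerMbPerPatient}.
#' @export
regionTally <- function(labels, regionSizes, nPatients) {
    stopifnot(nPatients > 0, all(regionSizes > 0))
    counts <- table(factor(labels, levels = names(regionSizes)))
    data.frame(region = names(regionSizes),
               count = as.integer(counts),
               size_bp = as.numeric(regionSizes),
               ratePerMbPerPatient =
                   as.integer(counts) / (regionSizes / 1e6) / nPatients,
               row.names = NULL, stringsAsFactors = FALSE)
}
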