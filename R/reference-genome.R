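#' Construct a ReferenceGenome
#'
#' @param sequences a named [Biostrings::DNAStringSet], or a named
#'   character vector of DNA strings (converted and upper-cased).
#' @param circular character vector of contig names to treat as circular
#'   (typically the mitochondrial contig).
#' @return a [ReferenceGenome-class].
#' @examples
#' g <- ReferenceGenome(c(chr1 = "ACGTACGT", chrM = "ACGT"),
#'                      circular = "chrM")
#' trinucleotideContext(g, "chrM", 1)  # wraps: "TAC"
#' @export
ReferenceGenome <- function(sequences, circular = character()) {
    if (is.character(sequences))
        sequences <- Biostrings::DNAStringSet(toupper(sequences))
    new("ReferenceGenome", sequences = sequences,
        circular = as.character(circular))
}

#' Read a reference FASTA into a ReferenceGenome
#'
#' @param path FASTA file path.
#' @param circular contig names to mark circular.
#' @return a [ReferenceGenome-class].
#' @export
readReferenceFasta <- function(path, circular = character()) {
    seqs <- Biostrings::readDNAStringSet(path)
    # keep only the first word of FASTA headers, as aligners do
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    ReferenceGenome(seqs, circular = circular)
}

#' Write a ReferenceGenome to FASTA
#'
#' @param genome a [ReferenceGenome-class]
#' @param path output file path.
#' @export
writeReferenceFasta <- function(genome, path) {
    Biostrings::writeXStringSet(genome@sequences, path)
    invisible(path)
}

#' Contig lengths and circularity
#'
#' @param x a [ReferenceGenome-class]
#' @return \code{contigLengths}: named integer vector;
#'   \code{circularContigs}: character vector of circular contig names.
#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))

#' @rdname contigLengths
#' @export
setMethod("contigLengths", "ReferenceGenome", function(x) {
    stats::setNames(Biostrings::width(x@sequences), names(x@sequences))
})

#' @rdname contigLengths
#' @export
setGeneric("circularContigs", function(x) standardGeneric("circularContigs"))

#' @rdname contigLengths
#' @export
setMethod("circularContigs", "ReferenceGenome", function(x) x@circular)

#' @export
setMethod("show", "ReferenceGenome", function(object) {
    len <- contigLengths(object)
    cat("ReferenceGenome with", length(len), "contigs (",
        sum(len), "bp )\n")
    for (nm in names(len))
        cat(sprintf("  %s: %d bp%s\n", nm, len[[nm]],
                    if (nm %in% object@circular) " (circular)" else ""))
    invisible(object)
})

#' Extract reference bases
#'
#' Positions are 1-based. On circular contigs, positions outside
#' \code{1..length} wrap modulo the contig length; on linear contigs they
#' yield \code{"N"}.
#'
#' @param genome a [ReferenceGenome-class]
#' @param chrom contig name.
#' @param pos integer vector of 1-based positions.
#' @return character vector of single bases.
#' @export
referenceBase <- function(genome, chrom, pos) {
    seq <- genomeSequence(genome, chrom)
    len <- nchar(seq)
    circ <- chrom %in% genome@circular
    if (circ)
        pos <- ((pos - 1L) %% len) + 1L
    out <- rep("N", length(pos))
    ok <- pos >= 1L & pos <= len
    if (any(ok))
        out[ok] <- substring(seq, pos[ok], pos[ok])
    out
}

genomeSequence <- function(genome, chrom) {
    if (!chrom %in% names(genome@sequences))
        stop("unknown contig: ", chrom)
    as.character(genome@sequences[[chrom]])
}

#' Trinucleotide context at a position
#'
#' Returns the reference bases at \code{pos - 1 .. pos + 1}. On a circular
#' contig positions wrap modulo the contig length, so position 1 of a
#' circular "ACGT" has context "TAC". On a linear contig, contexts that
#' fall off an edge are N-padded.
#'
#' @param genome a [ReferenceGenome-class]
#' @param chrom contig name (unknown contig is an error).
#' @param pos integer vector of 1-based positions within the contig.
#' @return character vector of 3-mers.
#' @export
trinucleotideContext <- function(genome, chrom, pos) {
    if (!chrom %in% names(genome@sequences))
        stop("unknown contig: ", chrom)
    len <- contigLengths(genome)[[chrom]]
    if (any(pos < 1L | pos > len))
        stop("position outside contig ", chrom)
    paste0(referenceBase(genome, chrom, pos - 1L),
           referenceBase(genome, chrom, pos),
           referenceBase(genome, chrom, pos + 1L))
}
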