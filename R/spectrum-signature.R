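BASES <- c("A", "C", "G", "T")
SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide substitution channels
#'
#' Conventional channel order: the six pyrimidine-centred substitution
#' classes C>A, C>G, C>T, T>A, T>C, T>G; within each class the 16
#' flanking contexts with the 5' base varying slowest, e.g.
#' \code{A[C>A]A}, \code{A[C>A]C}, ..., \code{T[T>G]T}.
#'
#' @return character vector of 96 channel names.
#' @export
sbsChannels <- function() {
    unlist(lapply(SBS_CLASSES, function(cl) {
        ref <- substr(cl, 1, 1)
        alt <- substr(cl, 3, 3)
        as.vector(t(outer(BASES, BASES, function(f, t)
            paste0(f, "[", ref, ">", alt, "]", t))))
    }))
}

#' Construct a MutationSpectrum
#'
#' @param counts named numeric vector over [sbsChannels()] (missing
#'   channels are zero-filled).
#' @param nExcluded substitutions excluded for ambiguous context.
#' @return a [MutationSpectrum-class].
#' @export
MutationSpectrum <- function(counts = numeric(), nExcluded = 0L) {
    full <- stats::setNames(numeric(96), sbsChannels())
    if (length(counts)) {
        bad <- setdiff(names(counts), names(full))
        if (length(bad))
            stop("unknown channels: ", paste(bad, collapse = ", "))
        full[names(counts)] <- counts
    }
    new("MutationSpectrum", counts = full, nExcluded = as.integer(nExcluded))
}

#' @export
setMethod("show", "MutationSpectrum", function(object) {
    cat("MutationSpectrum:", sum(object@counts), "SNVs over 96 channels")
    if (object@nExcluded)
        cat(" (+", object@nExcluded, "excluded for N context)")
    cat("\n")
    cl <- collapseClasses(object)
    cat(" ", paste(names(cl), cl, sep = "=", collapse = "  "), "\n")
    invisible(object)
})

#' Channel counts of a spectrum
#'
#' @param x a [MutationSpectrum-class]
#' @return named numeric vector over the 96 channels.
#' @export
setGeneric("spectrumCounts", function(x) standardGeneric("spectrumCounts"))

#' @rdname spectrumCounts
#' @export
setMethod("spectrumCounts", "MutationSpectrum", function(x) x@counts)

#' Build the 96-channel spectrum of a set of SNVs
#'
#' Every single-base substitution is placed in its pyrimidine-centred
#' trinucleotide channel: substitutions with a purine reference base are
#' reverse-complemented first (a G>A change in context \code{C[G]T}
#' counts in channel \code{A[C>T]G}). Substitutions whose context
#' contains N are excluded from the channels but counted in
#' \code{nExcluded}. Non-SNV rows of \code{x} are ignored.
#'
#' @param x a [SomaticVariantSet-class] (only \code{kind == "SNV"} rows
#'   are used).
#' @param genome a [ReferenceGenome-class] supplying trinucleotide
#'   context (circular contigs wrap).
#' @return a [MutationSpectrum-class].
#' @export
buildSpectrum <- function(x, genome) {
    d <- x@data[x@data$kind == "SNV", , drop = FALSE]
    if (!nrow(d))
        return(MutationSpectrum())
    ctx <- character(nrow(d))
    for (chrom in unique(d$chrom)) {
        i <- d$chrom == chrom
        ctx[i] <- trinucleotideContext(genome, chrom, d$pos[i])
    }
    ref <- substr(ctx, 2, 2)
    alt <- d$alt
    purine <- ref %in% c("A", "G")
    ctx[purine] <- revComp(ctx[purine])
    alt[purine] <- COMPLEMENT[alt[purine]]
    ok <- !grepl("N", ctx, fixed = TRUE) & alt %in% BASES
    channel <- paste0(substr(ctx, 1, 1), "[", substr(ctx, 2, 2), ">",
                      alt, "]", substr(ctx, 3, 3))
    counts <- table(factor(channel[ok], levels = sbsChannels()))
    MutationSpectrum(stats::setNames(as.numeric(counts), names(counts)),
                     nExcluded = sum(!ok))
}

#' Collapse a spectrum to 6 substitution classes (plus optional indels)
#'
#' Sums the 96 channels into the six pyrimidine-centred substitution
#' classes. With \code{includeIndelCategory = TRUE} a seventh
#' \code{indel} entry is appended from \code{indelCount}, for side-by-side
#' display of nuclear and mitochondrial mutation patterns where indels
#' form their own category.
#'
#' @param spectrum a [MutationSpectrum-class]
#' @param includeIndelCategory append an \code{indel} category?
#' @param indelCount number of indels for the seventh category.
#' @return named numeric vector of 6 (or 7) class counts.
#' @export
collapseClasses <- function(spectrum, includeIndelCategory = FALSE,
                            indelCount = 0L) {
    cls <- sub("^.\\[([ACGT]>[ACGT])\\].$", "\\1", names(spectrum@counts))
    out <- vapply(SBS_CLASSES, function(k) sum(spectrum@counts[cls == k]),
                  numeric(1))
    if (includeIndelCategory)
        out <- c(out, indel = as.numeric(indelCount))
    out
}

cosineSimilarity <- function(a, b) {
    na <- sqrt(sum(a^2))
    nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0)
        return(NA_real_)
    sum(a * b) / (na * nb)
}

#' Refit a spectrum against a signature reference by NNLS
#'
#' Solves \eqn{\min_x \|v - W^T x\|_2} subject to \eqn{x \ge 0}, where
#' \eqn{v} is the observed 96-channel spectrum and \eqn{W} the
#' (signatures x 96) reference with L1-normalised rows, then
#' L1-normalises the weights and reports the cosine similarity between
#' the reconstruction and the observed spectrum.
#'
#' @param spectrum a [MutationSpectrum-class] with a positive total.
#' @param reference numeric matrix, signatures in rows and the 96
#'   channels in columns (column names must match [sbsChannels()]); rows
#'   are L1-normalised internally.
#' @return a [SignatureExposure-class].
#' @export
refitSignatures <- function(spectrum, reference) {
    v <- spectrum@counts
    if (sum(v) <= 0)
        stop("cannot refit an all-zero spectrum")
    if (!identical(colnames(reference), sbsChannels()))
        reference <- reference[, sbsChannels(), drop = FALSE]
    W <- reference / rowSums(reference)
    fit <- pracma::lsqnonneg(t(W), as.numeric(v))
    x <- fit$x
    recon <- as.numeric(t(W) %*% x)
    names(x) <- rownames(reference)
    new("SignatureExposure",
        weights = if (sum(x) > 0) x / sum(x) else x,
        cosine = cosineSimilarity(recon, as.numeric(v)),
        residual = sqrt(max(0, fit$resid.norm)))
}

#' @export
setMethod("show", "SignatureExposure", function(object) {
    cat("SignatureExposure: cosine =", round(object@cosine, 4), "\n")
    w <- sort(object@weights[object@weights > 0.005], decreasing = TRUE)
    cat("  top weights:",
        paste(names(w), round(w, 3), sep = "=", collapse = ", "), "\n")
    invisible(object)
})

#' Exposure weights of a refit
#'
#' @param x a [SignatureExposure-class]
#' @return \code{exposureWeights}: named numeric weights summing to 1;
#'   \code{reconstructionCosine}: cosine similarity of the NNLS
#'   reconstruction to the observed spectrum.
#' @export
setGeneric("exposureWeights", function(x) standardGeneric("exposureWeights"))
#' @rdname exposureWeights
#' @export
setMethod("exposureWeights", "SignatureExposure", function(x) x@weights)
#' @rdname exposureWeights
#' @export
setGeneric("reconstructionCosine",
           function(x) standardGeneric("reconstructionCosine"))
#' @rdname exposureWeights
#' @export
setMethod("reconstructionCosine", "SignatureExposure", function(x) x@cosine)

#' Read a signature reference matrix
#'
#' Tab-separated matrix with signatures in rows (first column
#' \code{signature}) and the 96 channels in columns. The packaged default
#' is a SYNTHETIC 30-signature reference built by
#' [syntheticSignatureMatrix()] — it mimics the layout and two salient
#' rows (a CpG C>T deamination-like SBS1 and a T>C-dominated SBS12) of
#' the legacy COSMIC catalogue but is not the COSMIC data; substitute any
#' row-stochastic matrix for real analyses.
#'
#' @param path TSV path; default the packaged synthetic reference.
#' @return numeric matrix, rows L1-normalised, columns in
#'   [sbsChannels()] order.
#' @export
readSignatureMatrix <- function(path = system.file(
        "extdata", "signatures_synthetic_sbs30.tsv",
        package = "MitoSoma")) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    m <- m[, sbsChannels(), drop = FALSE]
    m / rowSums(m)
}

#' Deterministic synthetic signature reference
#'
#' Builds a 30-signature x 96-channel row-stochastic matrix for testing
#' and demonstration. Two rows are shaped after well-known processes:
#' \code{SBS1} concentrates C>T mass at NpCpG contexts (deamination-like)
#' and \code{SBS12} is dominated by T>C transitions with a secondary C>T
#' component, matching the transition-heavy spectra this package targets.
#' The remaining rows are sparse random profiles drawn from a fixed
#' internal seed, so the matrix is reproducible and does not disturb the
#' caller's RNG state.
#'
#' @param nSignatures number of signature rows (>= 2).
#' @return numeric matrix with rows \code{SBS1..SBSn} summing to 1.
#' @export
syntheticSignatureMatrix <- function(nSignatures = 30L) {
    stopifnot(nSignatures >= 2L)
    channels <- sbsChannels()
    withLocalSeed(191919L, {
        m <- matrix(stats::rgamma(nSignatures * 96, shape = 0.15),
                    nrow = nSignatures, dimnames =
                        list(paste0("SBS", seq_len(nSignatures)), channels))
        cls <- sub("^.\\[([ACGT]>[ACGT])\\].$", "\\1", channels)
        cpg <- cls == "C>T" & substr(channels, 7, 7) == "G"
        m["SBS1", ] <- 0.02
        m["SBS1", cpg] <- 3
        if (nSignatures >= 12L) {
            m["SBS12", ] <- 0.05
            m["SBS12", cls == "T>C"] <-
                2 + stats::runif(sum(cls == "T>C"))
            m["SBS12", cls == "C>T"] <-
                0.6 + 0.3 * stats::runif(sum(cls == "C>T"))
        }
        m / rowSums(m)
    })
}
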