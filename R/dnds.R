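#' Nei-Gojobori expected site counts for a CDS
#'
#' Unweighted pathway counting: at each codon position, each of the three
#' possible single-nucleotide changes is classified as synonymous or
#' nonsynonymous under the given genetic code (changes to or from a stop
#' codon count as nonsynonymous), and the position contributes the
#' nonsynonymous fraction of 1 site to N and the rest to S. Site counts
#' are therefore conserved exactly: \code{N + S = 3 * nCodons}.
#'
#' @param cds a DNA string (character) whose length is a multiple of 3,
#'   or a character vector of several CDS (summed).
#' @param code a genetic code as returned by
#'   [Biostrings::getGeneticCode()] ("1" standard, "2" vertebrate
#'   mitochondrial).
#' @return named numeric vector \code{c(N = ..., S = ...)}.
#' @export
ngSiteCounts <- function(cds, code = Biostrings::getGeneticCode("1")) {
    N <- 0
    S <- 0
    for (seq in cds) {
        seq <- toupper(seq)
        stopifnot(nchar(seq) %% 3L == 0L)
        for (start in seq(1L, nchar(seq), by = 3L)) {
            codon <- substring(seq, start, start + 2L)
            if (grepl("N", codon, fixed = TRUE))
                next
            aa <- code[[codon]]
            for (p in 1:3) {
                base <- substring(codon, p, p)
                for (b in setdiff(BASES, base)) {
                    mut <- codon
                    substring(mut, p, p) <- b
                    if (code[[mut]] == aa && aa != "*")
                        S <- S + 1 / 3
                    else
                        N <- N + 1 / 3
                }
            }
        }
    }
    c(N = N, S = S)
}

#' dN/dS for observed coding mutations
#'
#' Computes the ratio of nonsynonymous changes per nonsynonymous site to
#' synonymous changes per synonymous site,
#' \eqn{\omega = (N_d/N) / (S_d/S)}, with Nei-Gojobori (unweighted
#' pathway) site counting over the supplied CDS sequences and observed
#' counts classified under the same genetic code. Counts are used raw: at
#' the per-gene mutation counts this package deals in, multiple-hit
#' correction is undefined and is deliberately not applied.
#'
#' @param mutations a \code{data.frame} with columns \code{cds} (index or
#'   name of the CDS in \code{cdsSeqs}), \code{cdsPos} (1-based position
#'   within the spliced CDS) and \code{alt} (alternate base on the coding
#'   strand); or \code{NULL} with explicit \code{Nd}/\code{Sd}.
#' @param cdsSeqs character vector of CDS sequences (coding strand, each
#'   length a multiple of 3).
#' @param code genetic code (see [ngSiteCounts()]).
#' @param Nd,Sd observed nonsynonymous/synonymous counts, computed from
#'   \code{mutations} when omitted.
#' @return a list with \code{Nd}, \code{Sd}, \code{N}, \code{S},
#'   \code{omega} (Inf with \code{divergent = TRUE} when \code{Sd} is 0
#'   and \code{Nd} > 0).
#' @examples
#' # single-codon gene TTT (Phe): 9 possible changes, of which TTC is
#' # the only synonymous one -> N = 8/3 + ..., see ngSiteCounts()
#' dnds(data.frame(cds = 1, cdsPos = 3, alt = "C"), "TTT")
#' @export
dnds <- function(mutations = NULL, cdsSeqs,
                 code = Biostrings::getGeneticCode("1"),
                 Nd = NULL, Sd = NULL) {
    cdsSeqs <- toupper(cdsSeqs)
    sites <- ngSiteCounts(cdsSeqs, code)
    if (is.null(Nd) || is.null(Sd)) {
        stopifnot(is.data.frame(mutations),
                  all(c("cds", "cdsPos", "alt") %in% colnames(mutations)))
        Nd <- 0L
        Sd <- 0L
        for (i in seq_len(nrow(mutations))) {
            seq <- cdsSeqs[[mutations$cds[i]]]
            cp <- mutations$cdsPos[i]
            codon_start <- ((cp - 1L) %/% 3L) * 3L + 1L
            codon <- substring(seq, codon_start, codon_start + 2L)
            mut <- codon
            substring(mut, (cp - 1L) %% 3L + 1L,
                      (cp - 1L) %% 3L + 1L) <- toupper(mutations$alt[i])
            if (code[[mut]] == code[[codon]] && code[[codon]] != "*")
                Sd <- Sd + 1L
            else
                Nd <- Nd + 1L
        }
    }
    pn <- Nd / sites[["N"]]
    ps <- if (sites[["S"]] > 0) Sd / sites[["S"]] else NA_real_
    divergent <- FALSE
    omega <- if (!is.na(ps) && ps > 0) {
        pn / ps
    } else if (Nd > 0) {
        divergent <- TRUE
        Inf
    } else 0
    list(Nd = Nd, Sd = Sd, N = sites[["N"]], S = sites[["S"]],
         omega = omega, divergent = divergent)
}
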