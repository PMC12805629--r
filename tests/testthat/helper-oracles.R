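# Independent oracles and fixture builders shared across the suite.

# Plain if-chain re-check of the nuclear criteria, one line per
# criterion, deliberately independent of the vectorised filter engine.
bruteNuclearPass <- function(d) {
    vapply(seq_len(nrow(d)), function(i) {
        if (d$filter[i] != "PASS") return(FALSE)
        if (d$qscore[i] < 18) return(FALSE)
        if (d$t_depth[i] < 21) return(FALSE)
        if (d$n_depth[i] < 21) return(FALSE)
        if (!(d$t_alt[i] / d$t_depth[i] > 0.25)) return(FALSE)
        if (d$t_alt[i] < 6) return(FALSE)
        if (!(d$n_alt[i] / d$n_depth[i] < 0.02)) return(FALSE)
        TRUE
    }, logical(1))
}

bruteMitoPass <- function(d) {
    vapply(seq_len(nrow(d)), function(i) {
        if (d$filter[i] != "PASS") return(FALSE)
        if (d$qscore[i] < 18) return(FALSE)
        if (d$t_depth[i] == 0) return(FALSE)
        if (!(d$t_alt[i] / d$t_depth[i] > 0.05)) return(FALSE)
        if (d$t_alt[i] < 5) return(FALSE)
        if (d$n_depth[i] == 0) return(FALSE)
        if (!(d$n_alt[i] / d$n_depth[i] < 0.05)) return(FALSE)
        TRUE
    }, logical(1))
}

# Random variant table exercising every criterion's neighbourhood.
randomVariantTable <- function(n, seed) {
    withr::with_seed(seed, {
        t_depth <- sample(0:60, n, replace = TRUE)
        n_depth <- sample(0:60, n, replace = TRUE)
        data.frame(
            chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
            pos = sample(1e6, n),
            ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
            alt = "X",    # placeholder, fixed below
            qscore = round(runif(n, 10, 30), 1),
            filter = sample(c("PASS", "base_quality"), n, replace = TRUE,
                            prob = c(0.8, 0.2)),
            t_depth = t_depth,
            t_alt = vapply(t_depth, function(d) sample(0:d, 1), integer(1)),
            n_depth = n_depth,
            n_alt = vapply(n_depth, function(d)
                sample(0:min(d, 3), 1), integer(1)),
            stringsAsFactors = FALSE)
    }) -> d
    d$alt <- vapply(d$ref, function(r)
        sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    d
}

# Exhaustive enumeration of all rule-3-feasible trees over descending
# clone VAFs: every clone's parent is the root or an earlier clone, and
# each node's VAF must cover the sum of its children's VAFs.
enumerateFeasibleTrees <- function(vafs, eps = 1e-9) {
    n <- length(vafs)
    v <- c(1.0, vafs)                   # index 1 = root
    grids <- lapply(seq_len(n), function(i) seq_len(i))
    combos <- expand.grid(grids)
    feasible <- list()
    for (r in seq_len(nrow(combos))) {
        parent <- as.integer(combos[r, ])   # parent index in 1..i
        childSum <- numeric(n + 1L)
        ok <- TRUE
        for (i in seq_len(n)) {
            p <- parent[i]
            childSum[p] <- childSum[p] + vafs[i]
            if (childSum[p] > v[p] + eps) { ok <- FALSE; break }
        }
        if (ok)
            feasible[[length(feasible) + 1L]] <- parent
    }
    depths <- vapply(feasible, function(parent) {
        depth <- c(0L, integer(n))
        for (i in seq_len(n))
            depth[i + 1L] <- depth[parent[i]] + 1L
        max(depth)
    }, integer(1))
    list(parents = feasible, depths = depths)
}

# Nei-Gojobori per-codon oracle via Biostrings translation, independent
# of the package's string-table walk.
ngOracle <- function(seq, codeId) {
    code <- Biostrings::getGeneticCode(codeId)
    n_codons <- nchar(seq) / 3
    N <- 0; S <- 0
    for (k in seq_len(n_codons)) {
        codon <- substr(seq, 3 * k - 2, 3 * k)
        if (grepl("N", codon)) next
        aa <- code[[codon]]
        for (p in 1:3) for (b in c("A", "C", "G", "T")) {
            if (b == substr(codon, p, p)) next
            mut <- codon
            substr(mut, p, p) <- b
            if (code[[mut]] == aa && aa != "*") S <- S + 1/3 else N <- N + 1/3
        }
    }
    c(N = N, S = S)
}

# Minimal variant set builder with sensible read-count defaults.
makeVariants <- function(chrom, pos, ref, alt, qscore = 30,
                         filter = "PASS", t_depth = 100L, t_alt = 40L,
                         n_depth = 100L, n_alt = 0L) {
    SomaticVariantSet(data.frame(
        chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
        qscore = qscore, filter = filter, t_depth = as.integer(t_depth),
        t_alt = as.integer(t_alt), n_depth = as.integer(n_depth),
        n_alt = as.integer(n_alt), stringsAsFactors = FALSE))
}

# Mito variant fixture carrying the published per-region counts:
# D-loop 17, MT-CYB 5, MT-ND4 5, MT-ND1 3, MT-ND5 3, MT-CO2 3, other 7.
publishedRegionFixture <- function(seed = 1L) {
    withr::with_seed(seed, {
        pick <- function(lo, hi, n) sample(lo:hi, n)
        pos <- c(c(pick(16024, 16569, 9), pick(1, 576, 8)),  # D-loop 17
                 pick(14747, 15887, 5),                      # MT-CYB
                 pick(10767, 12137, 5),                      # MT-ND4
                 pick(3307, 4262, 3),                        # MT-ND1
                 pick(12337, 14148, 3),                      # MT-ND5
                 pick(7586, 8269, 3),                        # MT-CO2
                 c(5580, 5581, 5582, 5730, 5731, 8270, 8271)) # unmapped
    })
    makeVariants("chrM", pos, "A", "G", t_depth = 368L, t_alt = 150L,
                 n_depth = 368L, n_alt = 0L)
}
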