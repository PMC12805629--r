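test_that("heteroplasmy is the mutant-read fraction and is unbiased", {
    expect_equal(heteroplasmy(18, 360), 0.05)
    expect_equal(heteroplasmy(360, 360), 1)
    expect_error(heteroplasmy(1, 0), "zero depth")
    expect_error(heteroplasmy(10, 5), "alt reads")

    # binomial simulation at the study's mito coverage
    h <- 0.3; c <- 368; reps <- 1000
    est <- withr::with_seed(3, heteroplasmy(rbinom(reps, c, h), c))
    se <- sqrt(h * (1 - h) / c) / sqrt(reps)
    expect_lt(abs(mean(est) - h), 3 * se)
})

test_that("shift classes split tumour-specific from tumour-enriched", {
    expect_equal(classifyShift(0.40, 0.00), "tumour-specific")
    expect_equal(classifyShift(0.40, 0.06), "tumour-enriched")
    expect_equal(classifyShift(0.05, 0.06), "no-shift")
    # 500 simulated pairs against the direct conditional
    withr::with_seed(19, {
        ht <- runif(500)
        hn <- runif(500, 0, 0.2)
    })
    got <- classifyShift(ht, hn)
    oracle <- ifelse(hn < 0.05, "tumour-specific",
                     ifelse(ht > hn, "tumour-enriched", "no-shift"))
    expect_equal(got, oracle)
})

test_that("mutation density reproduces the mtDNA-vs-nuclear contrast", {
    expect_equal(round(mutationDensity(43, 16.569, 10), 2), 0.26)
    expect_equal(mutationDensity(0, 16.569, 10), 0)
    expect_error(mutationDensity(1, 0, 10), "> 0")
    # linear in count, inverse-linear in patients
    expect_equal(mutationDensity(86, 16.569, 10),
                 2 * mutationDensity(43, 16.569, 10))
    expect_equal(mutationDensity(43, 16.569, 20),
                 mutationDensity(43, 16.569, 10) / 2)
    # cohort-scale contrast: 43 mito mutations vs ~1,692 nuclear
    # mutations per case over the whole genome gives a ratio of
    # several hundred
    mito <- mutationDensity(43, 16.569, 10)
    nuc <- mutationDensity(16924, NUCLEAR_GENOME_KB, 10)
    expect_equal(round(nuc, 4), 5e-04)
    expect_gt(mito / nuc, 300)
    expect_lt(mito / nuc, 700)
})

test_that("Nei-Gojobori site counts match exhaustive enumeration", {
    # single codon TTT (Phe): of its 9 changes only TTC is synonymous
    got <- ngSiteCounts("TTT")
    expect_equal(got[["S"]], 1 / 3)
    expect_equal(got[["N"]], 8 / 3)
    # site conservation and agreement with the translation oracle on
    # random 30-codon genes, under both genetic codes
    for (codeId in c("1", "2")) {
        code <- Biostrings::getGeneticCode(codeId)
        for (seed in 1:5) {
            seq <- withr::with_seed(seed, paste(
                sample(c("A", "C", "G", "T"), 90, TRUE), collapse = ""))
            got <- ngSiteCounts(seq, code)
            expect_equal(got, ngOracle(seq, codeId))
            expect_equal(got[["N"]] + got[["S"]], 90)
        }
    }
    # the codes genuinely differ: TGA codons count differently
    expect_false(isTRUE(all.equal(
        ngSiteCounts("TGA", Biostrings::getGeneticCode("1")),
        ngSiteCounts("TGA", Biostrings::getGeneticCode("2")))))
})

test_that("dN/dS classifies observed mutations and handles degenerate counts", {
    # TTT gene, position 3 T>C: TTC is synonymous -> omega = 0
    res <- dnds(data.frame(cds = 1, cdsPos = 3, alt = "C"), "TTT")
    expect_equal(res$Sd, 1L)
    expect_equal(res$omega, 0)
    # position 1 T>C (CTT, Leu) is nonsynonymous, no synonymous -> Inf
    res <- dnds(data.frame(cds = 1, cdsPos = 1, alt = "C"), "TTT")
    expect_equal(res$Nd, 1L)
    expect_true(is.infinite(res$omega))
    expect_true(res$divergent)
    # explicit counts path
    res <- dnds(cdsSeqs = "TTTAAA", Nd = 2, Sd = 1)
    expect_equal(res$N + res$S, 6)
    expect_gt(res$omega, 0)
})

test_that("a planted nonsynonymous excess yields omega > 1 almost always", {
    # random 30-codon mito gene; draw mutations with nonsynonymous
    # changes 3x more likely than neutral expectation
    code <- Biostrings::getGeneticCode("2")
    hits <- 0L
    for (seed in 1:100) {
        withr::with_seed(seed, {
            seq <- paste(sample(c("A", "C", "G", "T"), 90, TRUE),
                         collapse = "")
            # enumerate all possible single-nt changes and their class
            muts <- do.call(rbind, lapply(1:90, function(p) {
                codon_start <- ((p - 1) %/% 3) * 3 + 1
                codon <- substr(seq, codon_start, codon_start + 2)
                do.call(rbind, lapply(
                    setdiff(c("A", "C", "G", "T"),
                            substr(seq, p, p)), function(b) {
                    mut <- codon
                    substr(mut, (p - 1) %% 3 + 1, (p - 1) %% 3 + 1) <- b
                    data.frame(cds = 1, cdsPos = p, alt = b,
                               syn = code[[mut]] == code[[codon]] &&
                                   code[[codon]] != "*")
                }))
            }))
            w <- ifelse(muts$syn, 1, 3)
            pick <- sample(nrow(muts), 20, prob = w)
        })
        res <- dnds(muts[pick, c("cds", "cdsPos", "alt")], seq, code)
        if (is.infinite(res$omega) || res$omega > 1)
            hits <- hits + 1L
    }
    expect_gte(hits, 95L)
})

test_that("heteroplasmy group comparison uses a two-sided rank-sum test", {
    # identical distributions -> p of 1
    res <- heteroplasmyByGroup(rep(c(0.1, 0.2, 0.3, 0.4), 2),
                               rep(c("a", "b"), each = 4))
    expect_equal(res$pValue, 1, tolerance = 1e-9)

    # U statistic on a 5-vs-5 toy set equals exhaustive pair counting
    x <- c(0.9, 0.8, 0.7, 0.35, 0.3)
    y <- c(0.6, 0.5, 0.4, 0.2, 0.1)
    res <- heteroplasmyByGroup(c(x, y), rep(c("g1", "g2"), each = 5))
    u_oracle <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(res$statistic, u_oracle)

    # power: shifted groups (delta 0.3, n 20) detected in >= 80% of seeds
    sig <- 0L
    for (seed in 1:100) {
        withr::with_seed(seed, {
            a <- runif(20, 0.1, 0.5)
            b <- a + 0.3
        })
        p <- heteroplasmyByGroup(c(a, b),
                                 rep(c("a", "b"), each = 20))$pValue
        if (p < 0.05) sig <- sig + 1L
    }
    expect_gte(sig, 80L)

    # empty group -> comparison skipped with a notice
    expect_message(
        res <- heteroplasmyByGroup(c(0.1, 0.2),
                                   factor(c("a", "a"),
                                          levels = c("a", "b"))),
        "empty")
    expect_true(is.na(res$pValue))
})

test_that("mito annotation adds levels, shift classes and regions", {
    v <- makeVariants("chrM", c(200, 16100), "A", "G",
                      t_depth = 368L, t_alt = c(37L, 350L),
                      n_depth = 368L, n_alt = c(0L, 30L))
    a <- annotateMitoVariants(v)
    d <- as.data.frame(a)
    expect_equal(d$h_tumour, c(37, 350) / 368)
    expect_equal(d$shift_class, c("tumour-specific", "tumour-enriched"))
    expect_equal(d$region, c("D-loop", "D-loop"))
    expect_true(all(d$h_tumour >= 0 & d$h_tumour <= 1))
})
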