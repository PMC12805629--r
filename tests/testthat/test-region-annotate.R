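# Hand-built two-contig genome with known codons at known places.
buildToyAnnotation <- function() {
    withr::with_seed(21, {
        chrN <- sample(c("A", "C", "G", "T"), 12000, TRUE)
        chrM <- sample(c("A", "C", "G", "T"), 600, TRUE)
    })
    # gene A (+): CDS exon1 2001-2099, exon2 2201-2302
    chrN[2001:2003] <- c("C", "G", "A")   # codon 1 Arg (CGA)
    chrN[2004:2006] <- c("T", "G", "G")   # codon 2 Trp
    chrN[2007:2009] <- c("T", "G", "A")   # codon 3 stop (standard code)
    # gene B (-): genomic 5001-5009 TTTCATCCC -> coding GGGATGAAA
    chrN[5001:5009] <- strsplit("TTTCATCCC", "")[[1]]
    # mito gene M: CDS 101-109, codon 1 Trp (TGG)
    chrM[101:103] <- c("T", "G", "G")
    genome <- ReferenceGenome(c(chrN = paste(chrN, collapse = ""),
                                chrM = paste(chrM, collapse = "")),
                              circular = "chrM")
    genes <- GenomicRanges::GRanges(
        c("chrN", "chrN", "chrN", "chrM"),
        IRanges::IRanges(c(2001, 5001, 8001, 101),
                         c(2302, 5009, 8400, 109)),
        strand = c("+", "-", "+", "+"),
        gene = c("A", "B", "C", "M"),
        type = c("coding", "coding", "ncRNA", "coding"))
    exons <- GenomicRanges::GRanges(
        c("chrN", "chrN", "chrN", "chrN", "chrM"),
        IRanges::IRanges(c(2001, 2201, 5001, 8001, 101),
                         c(2099, 2302, 5009, 8400, 109)),
        strand = c("+", "+", "-", "+", "+"),
        gene = c("A", "A", "B", "C", "M"))
    cds <- exons[c(1, 2, 3, 5)]
    utr5 <- GenomicRanges::GRanges("chrN", IRanges::IRanges(1951, 2000),
                                   strand = "+", gene = "A")
    TranscriptAnnotation(genes = genes, exons = exons, cds = cds,
                         utr5 = utr5) -> ann
    list(genome = genome, annotation = ann)
}

test_that("coding consequences decode codons under the right genetic code", {
    toy <- buildToyAnnotation()
    v <- makeVariants(
        c("chrN", "chrN", "chrN", "chrN", "chrN", "chrN", "chrM"),
        c(2003, 2006, 2009, 2100, 2199, 5006, 103),
        c("A", "G", "A", "N", "N", "T", "G"),
        c("G", "A", "G", "A", "A", "C", "A"))
    got <- classifyCoding(v, toy$annotation, toy$genome)
    expect_equal(got, c(
        "synonymous",        # CGA>CGG, Arg>Arg
        "stop_causing",      # TGG>TGA under the standard code
        "stop_loss",         # TGA>TGG
        "splice_donor",      # first intronic base after a + strand exon
        "splice_acceptor",   # intronic base before the next exon
        "nonsynonymous",     # minus-strand ATG>GTG
        "synonymous"))       # chrM TGG>TGA: TGA is Trp in the mito
                             # code, so NOT stop-causing
    # outside all transcripts -> NA for the noncoding path
    out <- makeVariants("chrN", 11000, "A", "G")
    expect_true(is.na(classifyCoding(out, toy$annotation, toy$genome)))
    # a CDS indel has no codon category
    indel <- makeVariants("chrN", 2050, "AC", "A")
    expect_equal(classifyCoding(indel, toy$annotation, toy$genome),
                 "coding_indel")
})

test_that("noncoding labels follow the documented precedence", {
    toy <- buildToyAnnotation()
    v <- makeVariants("chrN", c(1960, 2150, 8100, 1500, 3000, 11500),
                      "A", "G")
    expect_equal(classifyNoncoding(v, toy$annotation),
                 c("5'UTR",       # beats upstream
                   "intron",      # inside gene A body, not exonic
                   "ncRNA",
                   "upstream",    # within 2 kb of gene A start (+)
                   "downstream",
                   "intergenic")) # far from everything
})

test_that("noncoding label fractions match footprint fractions on uniform variants", {
    cfg <- cohortConfig(nPatients = 1L)
    ref <- generateReference(cfg, seed = 31L)
    ann <- ref$annotation
    lens <- cohortConfig()$contigLengths
    n <- 10000L
    withr::with_seed(13, {
        chrom <- sample(names(lens), n, TRUE, prob = lens / sum(lens))
        pos <- vapply(chrom, function(ch)
            sample(3:(lens[[ch]] - 2L), 1), integer(1))
    })
    v <- makeVariants(chrom, pos, "A", "G")
    coding <- classifyCoding(v, ann, ref$genome)
    labels <- classifyNoncoding(v[is.na(coding)], ann)

    # footprint oracle by interval set arithmetic, same precedence
    total <- sum(lens)
    taken <- suppressWarnings(GenomicRanges::reduce(
        c(ann@cds, ann@splice), ignore.strand = TRUE))
    footprint <- function(gr) {
        x <- suppressWarnings(GenomicRanges::setdiff(
            GenomicRanges::reduce(gr, ignore.strand = TRUE), taken,
            ignore.strand = TRUE))
        taken <<- suppressWarnings(
            GenomicRanges::reduce(c(taken, x), ignore.strand = TRUE))
        sum(GenomicRanges::width(x))
    }
    genes <- ann@genes
    minus <- as.character(GenomicRanges::strand(genes)) == "-"
    flank <- function(up) GenomicRanges::GRanges(
        GenomicRanges::seqnames(genes),
        IRanges::IRanges(
            ifelse(xor(minus, up), GenomicRanges::end(genes) + 1L,
                   pmax(1L, GenomicRanges::start(genes) - 2000L)),
            ifelse(xor(minus, up), GenomicRanges::end(genes) + 2000L,
                   pmax(1L, GenomicRanges::start(genes) - 1L))))
    exp_bp <- c(
        "5'UTR" = footprint(ann@utr5),
        "3'UTR" = footprint(ann@utr3),
        ncRNA = footprint(genes[S4Vectors::mcols(genes)$type == "ncRNA"]),
        intron = footprint(genes[S4Vectors::mcols(genes)$type == "coding"]),
        upstream = footprint(flank(TRUE)),
        downstream = footprint(flank(FALSE)))
    coding_bp <- sum(GenomicRanges::width(suppressWarnings(
        GenomicRanges::reduce(c(ann@cds, ann@splice),
                              ignore.strand = TRUE))))
    exp_p <- exp_bp / total
    exp_p <- c(exp_p,
               intergenic = 1 - coding_bp / total - sum(exp_p))
    m <- length(labels)
    for (lab in names(exp_p)) {
        obs <- mean(labels == lab) * m / n   # fraction of ALL variants
        tol <- max(0.012, 4 * sqrt(exp_p[[lab]] * (1 - exp_p[[lab]]) / n))
        expect_lt(abs(obs - exp_p[[lab]]), tol, label = lab)
    }
})

test_that("CRE partition matches a naive overlap oracle and conserves counts", {
    toyccre <- GenomicRanges::GRanges("chr1",
                                      IRanges::IRanges(100, 200))
    v <- makeVariants("chr1", 150, "A", "G")
    res <- partitionCre(v, toyccre)
    expect_equal(length(res$cre), 1L)

    expect_equal(length(partitionCre(v, GenomicRanges::GRanges())$cre), 0L)

    withr::with_seed(41, {
        pos <- sample(1e5, 1000)
        st <- sample(1e5, 200)
        w <- sample(50:500, 200, replace = TRUE)
    })
    v <- makeVariants("chr1", pos, "A", "G")
    ccre <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, st + w))
    res <- partitionCre(v, ccre)
    oracle <- vapply(pos, function(p)
        any(p >= st & p <= st + w), logical(1))
    expect_equal(length(res$cre), sum(oracle))
    expect_equal(length(res$cre) + length(res$nonfunctional), 1000L)
    expect_equal(sort(as.data.frame(res$cre)$pos), sort(pos[oracle]))
})

test_that("known-hotspot lookup reports planted overlaps by name", {
    hs <- GenomicRanges::GRanges(
        c("chr1", "chr2"), IRanges::IRanges(c(500, 900), c(600, 950)),
        name = c("IRF8_promoter", "hs2"), source = c("proj1", "proj2"))
    v <- makeVariants(c("chr1", "chr1"), c(550, 5000), "A", "G")
    hits <- lookupKnownHotspots(v, hs)
    expect_equal(nrow(hits), 1L)
    expect_equal(hits$region, "IRF8_promoter")
    expect_equal(hits$source, "proj1")
    expect_equal(nrow(lookupKnownHotspots(
        makeVariants("chr1", 10, "A", "G"), hs)), 0L)
})

test_that("cohort recurrence reports positions and windows seen in >= 2 patients", {
    sets <- list(p1 = makeVariants("chr1", c(100, 5000), "A", "G"),
                 p2 = makeVariants("chr1", c(100, 9000), "A", "G"),
                 p3 = makeVariants("chr1", c(105, 20000), "A", "G"))
    res <- cohortRecurrenceTally(sets, window = 21L)
    expect_equal(res$positions$pos, 100L)
    expect_equal(res$positions$nPatients, 2L)
    # 100 and 105 fall in one merged 21-bp window -> 3 patients
    expect_equal(res$windows$nPatients[1], 3L)

    uniq <- list(p1 = makeVariants("chr1", 1, "A", "G"),
                 p2 = makeVariants("chr1", 1000, "A", "G"))
    res <- cohortRecurrenceTally(uniq)
    expect_equal(nrow(res$positions), 0L)
    expect_equal(nrow(res$windows), 0L)
})

test_that("mito region assignment honours D-loop precedence and wrap-around", {
    v <- makeVariants("chrM", c(16258, 16527, 300, 15000, 11000, 5585),
                      "A", "G")
    reg <- assignMitoRegion(v)
    expect_equal(reg, c("D-loop", "D-loop", "D-loop", "MT-CYB",
                        "MT-ND4", "other"))
    tal <- mitoRegionTally(v, nPatients = 2L)
    expect_equal(sum(tal$count), length(v))
    # m.16258 and m.16527 lie in/near HVR I; only 16258 is inside it
    expect_equal(attr(tal, "hvr1Count"), 1L)
    expect_error(assignMitoRegion(makeVariants("chrM", 17000, "A", "G")),
                 "beyond")
})

test_that("region rates scale inverse-linearly with size and patient count", {
    labels <- c(rep("a", 10), rep("b", 5))
    sizes <- c(a = 1e6, b = 5e5)
    t1 <- regionTally(labels, sizes, nPatients = 1)
    t2 <- regionTally(labels, sizes * 2, nPatients = 1)
    t4 <- regionTally(labels, sizes, nPatients = 4)
    expect_equal(t1$ratePerMbPerPatient, c(10, 10))
    expect_equal(t2$ratePerMbPerPatient, t1$ratePerMbPerPatient / 2)
    expect_equal(t4$ratePerMbPerPatient, t1$ratePerMbPerPatient / 4)
    expect_equal(sum(t1$count), length(labels))
})
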