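smallConfig <- function(...) {
    cohortConfig(nPatients = 3L, codingMean = 15, noncodingMean = 250,
                 contigLengths = c(chr1 = 300000L, chr2 = 200000L),
                 nGenes = 10L, nCre = 80L, ...)
}

test_that("one master seed reproduces the cohort byte for byte", {
    cfg <- smallConfig()
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    suppressWarnings(simulateCohort(cfg, seed = 7L, dir = d1))
    suppressWarnings(simulateCohort(cfg, seed = 7L, dir = d2))
    files <- list.files(d1)
    expect_setequal(files, list.files(d2))
    for (f in files)
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), label = f)
    # and a different seed changes the data
    d3 <- withr::local_tempdir()
    suppressWarnings(simulateCohort(cfg, seed = 8L, dir = d3))
    expect_false(identical(
        readLines(file.path(d1, "case01_nuclear.vcf")),
        readLines(file.path(d3, "case01_nuclear.vcf"))))
})

test_that("generated annotation is internally consistent", {
    ref <- generateReference(smallConfig(), seed = 3L)
    ann <- ref$annotation
    # no overlapping CDS within one gene, total length divisible by 3
    for (g in unique(S4Vectors::mcols(ann@cds)$gene)) {
        cr <- ann@cds[S4Vectors::mcols(ann@cds)$gene == g]
        expect_equal(sum(GenomicRanges::width(cr)) %% 3L, 0L)
        expect_equal(length(GenomicRanges::reduce(cr)), length(cr))
    }
    # genes do not overlap each other
    expect_equal(length(GenomicRanges::reduce(ann@genes,
                                              ignore.strand = TRUE)),
                 length(ann@genes))
    # mito contig has the rCRS length and is circular
    expect_equal(contigLengths(ref$genome)[["chrM"]], 16569L)
    expect_true("chrM" %in% circularContigs(ref$genome))
    # hotspot table has the expected size and the planted promoter
    expect_equal(length(ref$hotspots), 159L)
    expect_true("IRF8_promoter" %in%
                S4Vectors::mcols(ref$hotspots)$name)
})

test_that("a gene-free genome yields a purely noncoding cohort", {
    cfg <- smallConfig(nGenes = 0L, noncodingMean = 60)
    ref <- generateReference(cfg, seed = 5L)
    expect_equal(length(ref$annotation@genes), 0L)
    sim <- plantNuclearMutations(ref, cfg, seed = 5L)
    expect_true(all(sim$truth$class == "noncoding"))
    v <- sim$variants[[1]]
    expect_true(all(is.na(classifyCoding(v, ref$annotation,
                                         ref$genome))))
    expect_true(all(classifyNoncoding(v, ref$annotation) == "intergenic"))
})

test_that("planted decoys are rejected by the nuclear filter", {
    cfg <- smallConfig(decoyFraction = 1)
    ref <- generateReference(cfg, seed = 9L)
    sim <- plantNuclearMutations(ref, cfg, seed = 9L)
    for (case in names(sim$variants)) {
        res <- filterNuclear(sim$variants[[case]])
        expect_equal(nPassed(res$report), 0L)
    }
})

test_that("the pipeline recovers the planted coding:noncoding split", {
    cfg <- smallConfig(nPatients = 4L, codingMean = 21.1,
                       noncodingMean = 400, decoyFraction = 0)
    ref <- generateReference(cfg, seed = 13L)
    sim <- plantNuclearMutations(ref, cfg, seed = 13L)
    truth_coding <- sum(sim$truth$class == "coding")
    truth_noncoding <- sum(sim$truth$class == "noncoding")
    got_coding <- 0L
    got_noncoding <- 0L
    for (case in names(sim$variants)) {
        lab <- classifyCoding(sim$variants[[case]], ref$annotation,
                              ref$genome)
        got_coding <- got_coding + sum(!is.na(lab))
        got_noncoding <- got_noncoding + sum(is.na(lab))
    }
    expect_lt(abs(got_coding / got_noncoding -
                  truth_coding / truth_noncoding) /
              (truth_coding / truth_noncoding), 0.10)
    # CRE split recovered against ground truth
    all_v <- do.call(c, unname(sim$variants))
    lab <- classifyCoding(all_v, ref$annotation, ref$genome)
    parts <- partitionCre(all_v[is.na(lab)], ref$ccre)
    expect_equal(length(parts$cre) + length(parts$nonfunctional),
                 sum(is.na(lab)))
    truth_cre <- sum(sim$truth$cre)
    expect_lt(abs(length(parts$cre) - truth_cre) / truth_cre, 0.10)
})

test_that("expected filter outcomes in the ground truth match the filter", {
    cfg <- smallConfig()
    ref <- generateReference(cfg, seed = 23L)
    sim <- plantNuclearMutations(ref, cfg, seed = 23L)
    for (case in names(sim$variants)) {
        res <- filterNuclear(sim$variants[[case]])
        truth <- sim$truth[sim$truth$patient == case, ]
        expect_equal(nPassed(res$report), sum(truth$expectedPass))
    }
})

test_that("high-coverage mito chains are reconstructed exactly from the spec", {
    cfg <- smallConfig(nPatients = 1L,
                       coverage = c(tumour = 115, normal = 129,
                                    mito = 10000))
    ref <- generateReference(cfg, seed = 2L)
    sim <- plantMitoLineage(ref, cfg, seed = 2L,
                            chainSpecs = list(c(0.9, 0.6, 0.3)))
    v <- annotateMitoVariants(filterMito(sim$variants[[1]])$pass,
                              ref$mitoMap)
    d <- as.data.frame(v)
    tr <- lineageFromVariants(data.frame(
        id = seq_len(nrow(d)), vaf = d$h_tumour, pos = d$pos,
        alt = d$alt))
    expect_equal(topologyClass(tr), "linear")
    expect_equal(nrow(tr@nodes) - 1L,
                 length(sim$truth[[1]]$cloneVafs))
    expect_equal(tr@nodes$vaf[-1], c(0.9, 0.6, 0.3), tolerance = 0.02)

    # a single clone at VAF 1 is homoplasmic and trivially linear
    sim <- plantMitoLineage(ref, cfg, seed = 4L,
                            chainSpecs = list(1.0))
    d <- as.data.frame(sim$variants[[1]])
    expect_true(all(d$t_alt / d$t_depth > 0.99))

    expect_error(plantMitoLineage(ref, cfg, seed = 5L,
                                  chainSpecs = list(c(0.3, 0.9))),
                 "infeasible")
})

test_that("D-loop enrichment is recovered in region proportions", {
    cfg <- cohortConfig(nPatients = 50L)
    ref <- generateReference(smallConfig(), seed = 6L)
    sim <- plantMitoLineage(ref, cfg, seed = 6L)
    regions <- unlist(lapply(sim$truth, `[[`, "regions"))
    n <- length(regions)
    # positions are drawn inside the D-loop with prob dloopWeight and
    # outside it otherwise, so the expected D-loop fraction is the weight
    p <- cfg$dloopWeight
    expect_lt(abs(mean(regions == "D-loop") - p),
              4 * sqrt(p * (1 - p) / n))
})
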