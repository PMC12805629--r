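#' Configuration for a synthetic tumour/normal cohort
#'
#' Defaults encode the study conditions the generator emulates: a
#' 10-patient cohort with ~115x tumour / ~129x normal nuclear and ~368x
#' mitochondrial coverage; 21.1 coding and 1,671.3 noncoding somatic
#' mutations per case on average, of which 405.0/1,671.3 fall on
#' candidate cis-regulatory elements; a T>C/C>T-dominated (SBS12-like)
#' substitution spectrum; and per-patient mitochondrial clone chains of
#' mean length 4.3 with D-loop-enriched positions (17 of 43 region
#' counts) and heteroplasmies spanning roughly 5-96%. Per-case mutation
#' counts are negative binomial (overdispersed) rather than Poisson to
#' reproduce wide per-case ranges.
#'
#' @param ... named overrides of any default listed below.
#' @return a list with elements \code{nPatients}, \code{contigLengths},
#'   \code{nGenes}, \code{ncRnaFraction}, \code{codingMean},
#'   \code{noncodingMean}, \code{dispersion}, \code{creFraction},
#'   \code{nCre}, \code{nHotspots}, \code{signatureWeights},
#'   \code{coverage} (tumour/normal/mito), \code{contamination},
#'   \code{decoyFraction}, \code{tumourVafRange},
#'   \code{mitoChainMean}, \code{mitoExtraMutationProb},
#'   \code{dloopWeight}, \code{mitoContigLength}, \code{mitoChrom}.
#' @export
cohortConfig <- function(...) {
    cfg <- list(
        nPatients = 10L,
        contigLengths = c(chr1 = 600000L, chr2 = 400000L),
        nGenes = 18L,
        ncRnaFraction = 0.15,
        codingMean = 21.1,
        noncodingMean = 1671.3,
        dispersion = 3,
        creFraction = 405.0 / 1671.3,
        nCre = 200L,
        nHotspots = 159L,
        signatureWeights = c(SBS12 = 0.75, SBS1 = 0.25),
        coverage = c(tumour = 115, normal = 129, mito = 368),
        contamination = 0.005,
        decoyFraction = 0.25,
        tumourVafRange = c(0.30, 0.60),
        mitoChainMean = 4.3,
        mitoExtraMutationProb = 0.2,
        dloopWeight = 17 / 43,
        mitoContigLength = 16569L,
        mitoChrom = "chrM")
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
        stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
    stopifnot(cfg$nPatients >= 1L, cfg$codingMean > 0,
              cfg$noncodingMean > 0, cfg$creFraction >= 0,
              cfg$creFraction <= 1, cfg$decoyFraction >= 0,
              cfg$decoyFraction <= 1)
    cfg
}

randomDna <- function(n) paste(sample(BASES, n, replace = TRUE),
                               collapse = "")

# Lay out one coding gene: exon ranges, and role assignment (5'UTR /
# CDS / 3'UTR) walked along the coding strand.
layoutGene <- function(chrom, start, minus, nExons) {
    exon_w <- sample(180:420, nExons, replace = TRUE)
    intron_w <- if (nExons > 1L) sample(300:1500, nExons - 1L,
                                        replace = TRUE) else integer()
    ex_start <- start + c(0L, cumsum(exon_w[-nExons] + intron_w))
    ex_end <- ex_start + exon_w - 1L
    total <- sum(exon_w)
    utr5 <- 30L
    utr3 <- 30L + (total - 60L) %% 3L
    # exonic positions in coding order
    pos <- unlist(lapply(seq_len(nExons), function(i)
        ex_start[i]:ex_end[i]))
    if (minus)
        pos <- rev(pos)
    role <- rep("cds", total)
    role[seq_len(utr5)] <- "utr5"
    role[(total - utr3 + 1L):total] <- "utr3"
    list(exons = IRanges::IRanges(ex_start, ex_end),
         end = ex_end[nExons], pos = pos, role = role)
}

rolesToRanges <- function(chrom, strand, pos, role, gene, want) {
    p <- sort(pos[role == want])
    if (!length(p))
        return(GenomicRanges::GRanges())
    brk <- cumsum(c(1L, diff(p) != 1L))
    st <- tapply(p, brk, min)
    en <- tapply(p, brk, max)
    GenomicRanges::GRanges(chrom, IRanges::IRanges(as.integer(st),
                                                   as.integer(en)),
                           strand = strand, gene = gene)
}

#' Generate a synthetic reference, annotation and region files
#'
#' Builds a toy nuclear genome (two linear contigs by default) with
#' non-overlapping multi-exon protein-coding genes and a few noncoding
#' RNA genes, a 16,569 bp circular mitochondrial contig annotated with
#' the packaged rCRS-coordinate region map, a set of candidate
#' cis-regulatory element intervals in non-CDS space, and a table of
#' known noncoding hotspot regions (one of which is named
#' \code{IRF8_promoter}, the known-hotspot hit the lookup stage should
#' recover). Deterministic: the same seed reproduces every object
#' exactly.
#'
#' @param config a [cohortConfig()] list.
#' @param seed integer seed.
#' @return a list with \code{genome} ([ReferenceGenome-class]),
#'   \code{annotation} ([TranscriptAnnotation-class]), \code{ccre}
#'   (\code{GRanges}), \code{hotspots} (\code{GRanges}), \code{mitoMap}
#'   (\code{GRanges}).
#' @export
generateReference <- function(config = cohortConfig(), seed = 1L) {
    withLocalSeed(seed, {
        seqs <- vapply(config$contigLengths, randomDna, "")
        names(seqs) <- names(config$contigLengths)
        seqs[[config$mitoChrom]] <- randomDna(config$mitoContigLength)
        genome <- ReferenceGenome(seqs, circular = config$mitoChrom)

        nGenes <- config$nGenes
        nNc <- max(0L, round(config$ncRnaFraction * nGenes))
        chroms <- names(config$contigLengths)
        per_chrom <- table(factor(
            sample(chroms, nGenes, replace = TRUE,
                   prob = config$contigLengths / sum(config$contigLengths)),
            levels = chroms))
        genes <- list(); exons <- list(); cds <- list()
        utr5 <- list(); utr3 <- list()
        gi <- 0L
        nc_ids <- sample(nGenes, nNc)
        for (chrom in chroms) {
            k <- per_chrom[[chrom]]
            if (k == 0L) next
            cursor <- 5000L
            for (j in seq_len(k)) {
                gi <- gi + 1L
                gene <- sprintf("GENE%02d", gi)
                minus <- runif(1) < 0.5
                strand <- if (minus) "-" else "+"
                is_nc <- gi %in% nc_ids
                if (is_nc) {
                    w <- sample(400:1200, 1)
                    if (cursor + w > config$contigLengths[[chrom]] - 5000L)
                        break
                    gr <- GenomicRanges::GRanges(
                        chrom, IRanges::IRanges(cursor, cursor + w - 1L),
                        strand = strand)
                    genes[[gene]] <- gr
                    S4Vectors::mcols(genes[[gene]]) <-
                        S4Vectors::DataFrame(gene = gene, type = "ncRNA")
                    exons[[gene]] <- gr
                    S4Vectors::mcols(exons[[gene]]) <-
                        S4Vectors::DataFrame(gene = gene)
                    cursor <- cursor + w + sample(8000:20000, 1)
                    next
                }
                lay <- layoutGene(chrom, cursor, minus,
                                  nExons = sample(2:4, 1))
                if (lay$end > config$contigLengths[[chrom]] - 5000L)
                    break
                genes[[gene]] <- GenomicRanges::GRanges(
                    chrom, IRanges::IRanges(cursor, lay$end),
                    strand = strand, gene = gene, type = "coding")
                exons[[gene]] <- GenomicRanges::GRanges(
                    chrom, lay$exons, strand = strand, gene = gene)
                cds[[gene]] <- rolesToRanges(chrom, strand, lay$pos,
                                             lay$role, gene, "cds")
                utr5[[gene]] <- rolesToRanges(chrom, strand, lay$pos,
                                              lay$role, gene, "utr5")
                utr3[[gene]] <- rolesToRanges(chrom, strand, lay$pos,
                                              lay$role, gene, "utr3")
                cursor <- lay$end + sample(8000:20000, 1)
            }
        }
        cat_gr <- function(lst) if (length(lst))
            suppressWarnings(unname(do.call(c, unname(lst))))
            else GenomicRanges::GRanges()
        annotation <- TranscriptAnnotation(
            genes = cat_gr(genes), exons = cat_gr(exons),
            cds = cat_gr(cds), utr5 = cat_gr(utr5), utr3 = cat_gr(utr3))

        cds_all <- annotation@cds
        ccre <- list()
        for (i in seq_len(config$nCre)) {
            chrom <- sample(chroms, 1,
                            prob = config$contigLengths / sum(config$contigLengths))
            w <- sample(300:1500, 1)
            st <- sample(config$contigLengths[[chrom]] - w, 1)
            cand <- GenomicRanges::GRanges(chrom,
                                           IRanges::IRanges(st, st + w - 1L))
            if (length(cds_all) &&
                !is.na(GenomicRanges::findOverlaps(cand, cds_all,
                                                   select = "first")))
                next
            S4Vectors::mcols(cand)$name <- sprintf("cCRE_%04d", i)
            ccre[[length(ccre) + 1L]] <- cand
        }
        ccre <- sort(cat_gr(ccre))

        sources <- paste0("project_", sprintf("%02d", 1:10))
        hs_chrom <- sample(chroms, config$nHotspots, replace = TRUE)
        hs_w <- sample(200:1000, config$nHotspots, replace = TRUE)
        hs_start <- vapply(seq_len(config$nHotspots), function(i)
            sample(config$contigLengths[[hs_chrom[i]]] - hs_w[i], 1),
            integer(1))
        hotspots <- GenomicRanges::GRanges(
            hs_chrom, IRanges::IRanges(hs_start, hs_start + hs_w - 1L),
            name = c("IRF8_promoter",
                     sprintf("hotspot_%03d", seq_len(config$nHotspots - 1L))),
            source = sample(sources, config$nHotspots, replace = TRUE))

        list(genome = genome, annotation = annotation, ccre = ccre,
             hotspots = hotspots, mitoMap = readMitoRegionMap())
    })
}

# Position pools for mutation placement on the nuclear contigs, keyed by
# pyrimidine-collapsed trinucleotide context so substitution channels can
# be drawn from the signature mixture FIRST and positions second.
positionPools <- function(reference, config) {
    chroms <- names(config$contigLengths)
    cds <- reference$annotation@cds
    chrom_v <- character(0); pos_v <- integer(0)
    ctx_v <- character(0); pool_v <- character(0)
    for (chrom in chroms) {
        len <- config$contigLengths[[chrom]]
        seq <- genomeSequence(reference$genome, chrom)
        p <- 2:(len - 1L)                       # edge contexts excluded
        ctx <- substring(seq, p - 1L, p + 1L)
        central <- substring(seq, p, p)
        pur <- central %in% c("A", "G")
        ctx[pur] <- revComp(ctx[pur])
        in_cds <- rep(FALSE, len)
        sub <- cds[as.character(GenomicRanges::seqnames(cds)) == chrom]
        for (i in seq_along(sub))
            in_cds[GenomicRanges::start(sub)[i]:
                   GenomicRanges::end(sub)[i]] <- TRUE
        in_cre <- rep(FALSE, len)
        sub <- reference$ccre[
            as.character(GenomicRanges::seqnames(reference$ccre)) == chrom]
        for (i in seq_along(sub))
            in_cre[GenomicRanges::start(sub)[i]:
                   GenomicRanges::end(sub)[i]] <- TRUE
        pool <- ifelse(in_cds[p], "cds",
                       ifelse(in_cre[p], "cre", "rest"))
        chrom_v <- c(chrom_v, rep(chrom, length(p)))
        pos_v <- c(pos_v, p)
        ctx_v <- c(ctx_v, ctx)
        pool_v <- c(pool_v, pool)
    }
    list(chrom = chrom_v, pos = pos_v,
         index = split(seq_along(pos_v), paste(pool_v, ctx_v)))
}

# Mixture channel probabilities (length 96, named).
mixtureChannelProbs <- function(signatureWeights,
                                reference = readSignatureMatrix()) {
    w <- signatureWeights / sum(signatureWeights)
    missing_sig <- setdiff(names(w), rownames(reference))
    if (length(missing_sig))
        stop("unknown signature(s): ", paste(missing_sig, collapse = ", "))
    p96 <- as.numeric(t(reference[names(w), , drop = FALSE]) %*% w)
    stats::setNames(p96 / sum(p96), colnames(reference))
}

# Draw n sites from one pool: channel from the mixture, then a position
# whose (collapsed) context matches, without replacement. Returns chrom,
# pos, ref (actual reference base) and alt (strand-corrected).
sampleSites <- function(pools, genome, pool, n, channelProbs) {
    if (n == 0L)
        return(data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          stringsAsFactors = FALSE))
    channels <- sample(names(channelProbs), n, replace = TRUE,
                       prob = channelProbs)
    ctx <- paste0(substr(channels, 1, 1), substr(channels, 3, 3),
                  substr(channels, 7, 7))
    alt_pyr <- substr(channels, 5, 5)
    idx <- integer(n)
    for (k in unique(ctx)) {
        i <- which(ctx == k)
        avail <- pools$index[[paste(pool, k)]]
        if (length(avail) < length(i))
            stop("context pool exhausted for ", pool, "/", k)
        idx[i] <- sample(avail, length(i))
    }
    chrom <- pools$chrom[idx]
    pos <- pools$pos[idx]
    ref <- character(n)
    for (ch in unique(chrom)) {
        i <- chrom == ch
        ref[i] <- referenceBase(genome, ch, pos[i])
    }
    pur <- ref %in% c("A", "G")
    alt <- ifelse(pur, COMPLEMENT[alt_pyr], alt_pyr)
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
               stringsAsFactors = FALSE)
}

#' Plant nuclear somatic mutations and emit paired read counts
#'
#' Draws per-case coding and noncoding mutation counts from negative
#' binomial distributions around the configured means, places coding
#' mutations uniformly in the CDS footprint and noncoding mutations in
#' cis-regulatory vs remaining space with the configured CRE fraction,
#' samples substitution types from the configured signature mixture, and
#' draws tumour/normal read counts binomially at the configured
#' coverages. A configurable fraction of sub-threshold decoys (non-PASS,
#' low quality, thin coverage, low VAF, germline-like normals) is added
#' to exercise every filter criterion.
#'
#' @param reference output of [generateReference()].
#' @param config a [cohortConfig()] list.
#' @param seed integer seed.
#' @param signatureReference signature matrix for the mixture sampler.
#' @return a list with \code{variants} (named list of
#'   [SomaticVariantSet-class], one per patient) and \code{truth}
#'   (\code{data.frame}: \code{patient}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{class} coding/noncoding, \code{cre},
#'   \code{decoy} type or "somatic", \code{trueVaf},
#'   \code{expectedPass}).
#' @export
plantNuclearMutations <- function(reference, config = cohortConfig(),
                                  seed = 1L,
                                  signatureReference = readSignatureMatrix()) {
    withLocalSeed(seed + 104729L, {
        pools <- positionPools(reference, config)
        channelProbs <- mixtureChannelProbs(config$signatureWeights,
                                            signatureReference)
        genome <- reference$genome
        variants <- list()
        truth <- list()
        decoy_types <- c("not_pass", "low_qscore", "low_t_cov",
                         "low_n_cov", "low_vaf", "germline_like")
        for (p in seq_len(config$nPatients)) {
            case <- sprintf("case%02d", p)
            nCod <- max(1L, rnbinom(1, size = config$dispersion,
                                    mu = config$codingMean))
            if (!any(startsWith(names(pools$index), "cds ")))
                nCod <- 0L              # no genes: nothing coding to plant
            nNon <- max(1L, rnbinom(1, size = config$dispersion,
                                    mu = config$noncodingMean))
            nCre <- rbinom(1, nNon, config$creFraction)
            tag <- function(df, cls, cre) {
                df$class <- rep(cls, nrow(df))
                df$cre <- rep(cre, nrow(df))
                df
            }
            site <- rbind(tag(sampleSites(pools, genome, "cds", nCod,
                                          channelProbs),
                              "coding", FALSE),
                          tag(sampleSites(pools, genome, "cre", nCre,
                                          channelProbs),
                              "noncoding", TRUE),
                          tag(sampleSites(pools, genome, "rest",
                                          nNon - nCre, channelProbs),
                              "noncoding", FALSE))
            n <- nrow(site)
            refb <- site$ref
            alt <- site$alt
            nDecoy <- round(config$decoyFraction * n)
            decoy <- rep("somatic", n)
            if (nDecoy > 0L)
                decoy[sample(n, nDecoy)] <-
                    sample(decoy_types, nDecoy, replace = TRUE)
            vaf <- runif(n, config$tumourVafRange[1],
                         config$tumourVafRange[2])
            t_depth <- pmax(1L, rpois(n, config$coverage[["tumour"]]))
            n_depth <- pmax(1L, rpois(n, config$coverage[["normal"]]))
            qscore <- round(runif(n, 25, 60), 1)
            filter <- rep("PASS", n)
            filter[decoy == "not_pass"] <- "base_quality"
            qscore[decoy == "low_qscore"] <- round(runif(
                sum(decoy == "low_qscore"), 2, 17.5), 1)
            i <- decoy == "low_t_cov"
            t_depth[i] <- sample(3:20, sum(i), replace = TRUE)
            i <- decoy == "low_n_cov"
            n_depth[i] <- sample(3:20, sum(i), replace = TRUE)
            i <- decoy == "low_vaf"
            vaf[i] <- runif(sum(i), 0.03, 0.15)
            t_alt <- rbinom(n, t_depth, vaf)
            n_alt <- rbinom(n, n_depth, config$contamination)
            i <- decoy == "germline_like"
            n_alt[i] <- rbinom(sum(i), n_depth[i], 0.45)
            d <- data.frame(chrom = site$chrom, pos = site$pos,
                            ref = refb, alt = alt, qscore = qscore,
                            filter = filter, t_depth = t_depth,
                            t_alt = t_alt, n_depth = n_depth,
                            n_alt = n_alt, stringsAsFactors = FALSE)
            ord <- order(d$chrom, d$pos)
            d <- d[ord, , drop = FALSE]
            variants[[case]] <- SomaticVariantSet(d)
            tvaf <- ifelse(d$t_depth > 0, d$t_alt / d$t_depth, 0)
            nvaf <- ifelse(d$n_depth > 0, d$n_alt / d$n_depth, 0)
            truth[[case]] <- data.frame(
                patient = case, chrom = d$chrom, pos = d$pos,
                ref = d$ref, alt = d$alt,
                class = site$class[ord], cre = site$cre[ord],
                decoy = decoy[ord], trueVaf = vaf[ord],
                expectedPass = d$filter == "PASS" & d$qscore >= 18 &
                    d$t_depth >= 21 & d$n_depth >= 21 & tvaf > 0.25 &
                    d$t_alt >= 6 & nvaf < 0.02,
                stringsAsFactors = FALSE)
        }
        list(variants = variants,
             truth = do.call(rbind, c(truth,
                                      list(make.row.names = FALSE))))
    })
}

#' Plant mitochondrial clone lineages and emit read counts
#'
#' Per patient, draws a linear clone chain of length ~Poisson(mean 4.3,
#' truncated at 1), assigns descending clone VAFs by stick-breaking so
#' rule-3 feasibility holds by construction, places mutations with the
#' configured D-loop enrichment and a transition-biased substitution
#' model, and draws tumour alt reads Binomial(coverage, clone VAF) with
#' low-level cross-contamination in the normal.
#'
#' @param reference output of [generateReference()] (for the
#'   mitochondrial contig sequence and region map).
#' @param config a [cohortConfig()] list.
#' @param seed integer seed.
#' @param chainSpecs optional list of numeric VAF vectors (descending),
#'   one per patient, overriding the random chains; an infeasible spec
#'   (ascending or outside (0, 1]) is an error before any sampling.
#' @return a list with \code{variants} (named list of
#'   [SomaticVariantSet-class]) and \code{truth} (per-patient list:
#'   \code{cloneVafs}, \code{cloneOfMutation}, \code{positions},
#'   \code{regions}, \code{ids}).
#' @export
plantMitoLineage <- function(reference, config = cohortConfig(),
                             seed = 1L, chainSpecs = NULL) {
    if (!is.null(chainSpecs)) {
        for (sp in chainSpecs)
            if (any(diff(sp) > 0) || any(sp <= 0 | sp > 1))
                stop("infeasible chain spec: VAFs must be descending in (0,1]")
    }
    withLocalSeed(seed + 224737L, {
        genome <- reference$genome
        map <- reference$mitoMap
        mchrom <- config$mitoChrom
        cls <- S4Vectors::mcols(map)$class
        dloop <- map[cls == "dloop"]
        dloop_pos <- unlist(lapply(seq_along(dloop), function(i)
            GenomicRanges::start(dloop)[i]:GenomicRanges::end(dloop)[i]))
        other_pos <- setdiff(seq_len(config$mitoContigLength), dloop_pos)
        variants <- list()
        truth <- list()
        for (p in seq_len(config$nPatients)) {
            case <- sprintf("case%02d", p)
            if (!is.null(chainSpecs)) {
                vafs <- chainSpecs[[p]]
            } else {
                L <- 0L
                while (L < 1L)
                    L <- rpois(1, config$mitoChainMean)
                vafs <- numeric(L)
                vafs[1] <- runif(1, 0.45, 0.96)
                if (L > 1L)
                    for (i in 2:L)
                        vafs[i] <- max(0.06, vafs[i - 1] *
                                       runif(1, 0.45, 0.85))
                vafs <- sort(vafs, decreasing = TRUE)
            }
            L <- length(vafs)
            nmut <- 1L + rbinom(L, 1L, config$mitoExtraMutationProb)
            clone_of <- rep(seq_len(L), nmut)
            n <- length(clone_of)
            use_dloop <- runif(n) < config$dloopWeight
            pos <- integer(n)
            pos[use_dloop] <- sample(dloop_pos, sum(use_dloop))
            pos[!use_dloop] <- sample(other_pos, sum(!use_dloop))
            refb <- referenceBase(genome, mchrom, pos)
            transition <- c(A = "G", G = "A", C = "T", T = "C")
            alt <- vapply(refb, function(b)
                if (runif(1) < 0.8) transition[[b]]
                else sample(setdiff(BASES, c(b, transition[[b]])), 1),
                "", USE.NAMES = FALSE)
            true_vaf <- vafs[clone_of]
            t_depth <- pmax(1L, rpois(n, config$coverage[["mito"]]))
            n_depth <- pmax(1L, rpois(n, config$coverage[["mito"]]))
            t_alt <- rbinom(n, t_depth, true_vaf)
            n_alt <- rbinom(n, n_depth, config$contamination)
            d <- data.frame(chrom = mchrom, pos = pos, ref = refb,
                            alt = alt,
                            qscore = round(runif(n, 25, 60), 1),
                            filter = "PASS", t_depth = t_depth,
                            t_alt = t_alt, n_depth = n_depth,
                            n_alt = n_alt, stringsAsFactors = FALSE)
            ord <- order(d$pos)
            vs <- SomaticVariantSet(d[ord, , drop = FALSE])
            ids <- sprintf("%s_m%02d", case, seq_len(n))
            variants[[case]] <- vs
            truth[[case]] <- list(
                cloneVafs = vafs,
                cloneOfMutation = clone_of[ord],
                positions = pos[ord],
                regions = assignMitoRegion(vs, map,
                                           config$mitoContigLength),
                ids = ids[ord], trueVaf = true_vaf[ord])
        }
        list(variants = variants, truth = truth)
    })
}

#' Generate a complete synthetic cohort, optionally writing files
#'
#' Chains [generateReference()], [plantNuclearMutations()] and
#' [plantMitoLineage()] under one master seed. With \code{dir} set, the
#' cohort is written out as text files: reference FASTA, per-case paired
#' tumour/normal VCFs (nuclear and mitochondrial), cCRE BED, hotspot and
#' mitochondrial region TSVs, and a ground-truth JSON — the same seed
#' reproduces every file byte for byte.
#'
#' @param config a [cohortConfig()] list.
#' @param seed master integer seed.
#' @param dir output directory (created if needed), or \code{NULL} to
#'   skip writing.
#' @return a list: \code{reference}, \code{nuclear}, \code{mito} (as
#'   returned by the three generators), and \code{dir}.
#' @export
simulateCohort <- function(config = cohortConfig(), seed = 1L,
                           dir = NULL) {
    reference <- generateReference(config, seed)
    nuclear <- plantNuclearMutations(reference, config, seed)
    mito <- plantMitoLineage(reference, config, seed)
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        writeReferenceFasta(reference$genome,
                            file.path(dir, "reference.fa"))
        writeBedFile(reference$ccre, file.path(dir, "ccre.bed"))
        hs <- reference$hotspots
        utils::write.table(
            data.frame(chrom = as.character(GenomicRanges::seqnames(hs)),
                       start = GenomicRanges::start(hs),
                       end = GenomicRanges::end(hs),
                       name = S4Vectors::mcols(hs)$name,
                       source = S4Vectors::mcols(hs)$source),
            file.path(dir, "hotspots.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
        file.copy(system.file("extdata", "mito_regions_rcrs.tsv",
                              package = "MitoSoma"),
                  file.path(dir, "mito_regions.tsv"), overwrite = TRUE)
        lens <- contigLengths(reference$genome)
        for (case in names(nuclear$variants)) {
            writePairedVcf(nuclear$variants[[case]],
                           file.path(dir, paste0(case, "_nuclear.vcf")),
                           tumourSample = paste0(case, "_T"),
                           normalSample = paste0(case, "_N"),
                           contigLengths = lens)
            writePairedVcf(mito$variants[[case]],
                           file.path(dir, paste0(case, "_chrM.vcf")),
                           tumourSample = paste0(case, "_T"),
                           normalSample = paste0(case, "_N"),
                           contigLengths = lens)
        }
        jsonlite::write_json(
            list(seed = seed,
                 nuclearTruth = nuclear$truth,
                 mitoTruth = mito$truth),
            file.path(dir, "ground_truth.json"),
            auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    list(reference = reference, nuclear = nuclear, mito = mito,
         dir = dir)
}
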