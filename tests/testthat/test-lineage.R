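toyVariants <- function(vafs, pos = seq_along(vafs)) {
    data.frame(id = paste0("m", seq_along(vafs)), vaf = vafs,
               pos = pos, alt = "G", stringsAsFactors = FALSE)
}

test_that("variants order by descending VAF with deterministic ties", {
    v <- toyVariants(c(0.3, 0.9, 0.6))
    expect_equal(orderVariants(v)$vaf, c(0.9, 0.6, 0.3))
    # equal VAFs: position order
    v <- toyVariants(c(0.5, 0.5, 0.5), pos = c(30, 10, 20))
    expect_equal(orderVariants(v)$pos, c(10, 20, 30))
    # random sets agree with a plain sort
    for (seed in 1:5) {
        vafs <- withr::with_seed(seed, runif(50, 0.05, 1))
        expect_equal(orderVariants(toyVariants(vafs))$vaf,
                     sort(vafs, decreasing = TRUE))
    }
})

test_that("co-clonal merging is transitive along the ordered run", {
    ord <- orderVariants(toyVariants(c(0.50, 0.49)))
    cl <- mergeCoclonal(ord, delta = 0.02)
    expect_equal(cl$vaf, 0.495)
    expect_equal(lengths(cl$variants), 2L)

    # delta 0 never merges
    cl <- mergeCoclonal(ord, delta = 0)
    expect_equal(length(cl$vaf), 2L)

    # transitive: consecutive gaps below delta chain into one clone
    ord <- orderVariants(toyVariants(c(0.50, 0.49, 0.485, 0.30)))
    cl <- mergeCoclonal(ord, delta = 0.02)
    expect_equal(length(cl$vaf), 2L)
    expect_equal(cl$vaf[1], mean(c(0.50, 0.49, 0.485)))
})

test_that("the deepest-feasible rule builds the published chain example", {
    tr <- buildLineageTree(c(0.9, 0.6, 0.3))
    expect_equal(topologyClass(tr), "linear")
    expect_equal(unname(cloneProportions(tr)), c(0.1, 0.3, 0.3, 0.3))
    expect_equal(tr@nodes$parent, c(NA, 0L, 1L, 2L))

    # unsorted VAFs reorder first, then chain: (0.9, 0.45, 0.50)
    tr <- lineageFromVariants(toyVariants(c(0.9, 0.45, 0.50)), delta = 0)
    expect_equal(tr@nodes$vaf[-1], c(0.9, 0.50, 0.45))
    expect_equal(topologyClass(tr), "linear")

    # n = 0: root-only tree
    tr <- buildLineageTree(numeric(0))
    expect_equal(nrow(tr@nodes), 1L)
    expect_equal(sum(cloneProportions(tr)), 1)

    expect_error(buildLineageTree(c(0.3, 0.9)), "descending")
})

test_that("greedy trees are feasible and of maximal depth among all rule-3 trees", {
    for (draw in 1:200) {
        vafs <- withr::with_seed(draw, {
            n <- sample(1:6, 1)
            sort(runif(n, 0.05, 0.95), decreasing = TRUE)
        })
        tr <- buildLineageTree(vafs, delta = 0)
        oracle <- enumerateFeasibleTrees(vafs)
        # greedy parents in oracle's encoding: parent id + 1
        greedy <- tr@nodes$parent[-1] + 1L
        matched <- any(vapply(oracle$parents, identical, logical(1),
                              y = greedy))
        expect_true(matched)
        expect_equal(max(tr@nodes$depth), max(oracle$depths))
        # rule 3 at every node
        nd <- tr@nodes
        for (i in seq_len(nrow(nd))) {
            kid_sum <- sum(nd$vaf[!is.na(nd$parent) &
                                  nd$parent == nd$id[i]])
            expect_gte(nd$vaf[i] + 1e-9, kid_sum)
        }
    }
})

test_that("clone proportions are a stick-breaking of the root mass", {
    for (seed in 1:100) {
        vafs <- withr::with_seed(seed, {
            n <- sample(1:8, 1)
            sort(runif(n, 0.05, 1), decreasing = TRUE)
        })
        rule <- if (seed %% 2) "deepest" else "residual"
        tr <- buildLineageTree(vafs, parentRule = rule, delta = 0)
        p <- cloneProportions(tr)
        expect_true(all(p >= -1e-12))
        expect_equal(sum(p), 1)
    }
})

test_that("the residual parent rule can branch where the default chains", {
    vafs <- c(0.4, 0.35, 0.2)
    expect_equal(topologyClass(buildLineageTree(vafs)), "linear")
    tr <- buildLineageTree(vafs, parentRule = "residual")
    expect_equal(topologyClass(tr), "branching")
    expect_equal(sum(cloneProportions(tr)), 1)
})

test_that("tree construction is invariant under input permutation", {
    vafs <- c(0.82, 0.55, 0.54, 0.31, 0.12)
    v <- toyVariants(vafs)
    base <- lineageFromVariants(v)
    for (seed in 1:5) {
        perm <- withr::with_seed(seed, sample(nrow(v)))
        tr <- lineageFromVariants(v[perm, ])
        expect_equal(tr@nodes, base@nodes)
        expect_equal(tr@variants, base@variants)
    }
})

test_that("first-hit statistics report clone A1 per case", {
    t1 <- lineageFromVariants(toyVariants(0.8))
    res <- firstHitStats(list(only = t1))
    expect_equal(res$perCase$vaf, 0.8)
    expect_equal(res$fractionVafGE50, 1)

    # a merged top clone is the first hit with all its mutations
    tr <- lineageFromVariants(toyVariants(c(0.70, 0.69, 0.3)),
                              delta = 0.02)
    res <- firstHitStats(list(a = tr),
                         regions = c(m1 = "D-loop", m2 = "MT-ND1",
                                     m3 = "MT-CO1"))
    expect_equal(res$perCase$nMut, 2L)
    expect_equal(res$perCase$vaf, 0.695)
    expect_match(res$perCase$regions, "D-loop")

    # planted cohort first hits recovered exactly
    planted <- withr::with_seed(8, runif(10, 0.3, 0.95))
    trees <- lapply(planted, function(a1)
        lineageFromVariants(toyVariants(c(a1, a1 * 0.5)), delta = 0))
    names(trees) <- paste0("case", 1:10)
    res <- firstHitStats(trees)
    expect_equal(res$perCase$vaf, planted)
    expect_equal(res$fractionVafGE50, mean(planted >= 0.5))

    expect_message(firstHitStats(list(e = buildLineageTree(numeric(0)))),
                   "skipped")
})

test_that("trees render as indented text and Newick", {
    tr <- buildLineageTree(c(0.9, 0.6))
    txt <- formatLineageTree(tr)
    expect_length(txt, 3L)
    expect_match(txt[1], "A0")
    nwk <- lineageNewick(tr)
    expect_match(nwk, "^\\(\\(A2:0.6\\)A1:0.3\\)A0:0.1;$")
    s <- lineageSummary(list(x = tr))
    expect_equal(s$nClones, 2L)
    expect_equal(s$firstHitVaf, 0.9)
})
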