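#' Order mitochondrial variants by descending VAF
#'
#' Rule 1 of the lineage construction: the variant allele frequencies
#' A1, A2, ..., An are ordered from highest to lowest below the unmutated
#' root state A0 at 100%. Ties are broken by (position, alt allele)
#' lexicographic order so the sequence is deterministic under input
#' permutation.
#'
#' @param variants a \code{data.frame} with columns \code{id},
#'   \code{vaf}, \code{pos}, \code{alt}.
#' @return the rows of \code{variants}, reordered.
#' @export
orderVariants <- function(variants) {
    stopifnot(all(c("id", "vaf", "pos", "alt") %in% colnames(variants)))
    stopifnot(all(variants$vaf > 0 & variants$vaf <= 1))
    out <- variants[order(-variants$vaf, variants$pos, variants$alt), ,
                    drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Merge co-clonal variants along the ordered VAF sequence
#'
#' Adjacent variants in the descending VAF sequence whose VAF difference
#' is strictly below \code{delta} are taken to mark the same clone;
#' merging is transitive along the run, and the merged clone's VAF is the
#' mean of its members. \code{delta = 0} disables merging.
#'
#' @param ordered a \code{data.frame} as returned by [orderVariants()].
#' @param delta VAF tolerance (default 0.02).
#' @return a list with \code{vaf} (numeric vector, one per clone,
#'   descending) and \code{variants} (list of member id vectors).
#' @export
mergeCoclonal <- function(ordered, delta = 0.02) {
    n <- nrow(ordered)
    if (n == 0L)
        return(list(vaf = numeric(), variants = list()))
    grp <- cumsum(c(TRUE, diff(ordered$vaf) <= -delta | delta == 0))
    if (delta == 0)
        grp <- seq_len(n)
    vaf <- as.numeric(tapply(ordered$vaf, grp, mean))
    ids <- split(as.character(ordered$id), grp)
    list(vaf = unname(vaf), variants = unname(ids))
}

#' Build a mitochondrial clone lineage tree from ordered clone VAFs
#'
#' Rules 2 and 3 of the construction: clones are inserted one by one in
#' descending VAF order, and a clone may only become a child of a node
#' whose VAF can still accommodate it — a parent's VAF must remain at
#' least the sum of its children's VAFs (the subset condition is enforced
#' incrementally as residual-capacity checking). Among feasible parents,
#' the default \code{"deepest"} preference attaches the clone to the
#' deepest already-placed node, which maximises linearity; on a
#' descending sequence the deepest node's residual is always at least the
#' next VAF, so this rule yields a chain. The alternative
#' \code{"residual"} preference attaches to the node with the largest
#' residual capacity and can produce branching trees; both are exposed
#' because the rules themselves do not determine the attachment uniquely.
#'
#' @param cloneVafs numeric vector of clone VAFs in (0, 1], descending
#'   (e.g. from [mergeCoclonal()]).
#' @param cloneVariants optional list of member mutation ids per clone.
#' @param parentRule \code{"deepest"} (default) or \code{"residual"}.
#' @param delta the merge tolerance used upstream (recorded only).
#' @return a [LineageTree-class].
#' @examples
#' tr <- buildLineageTree(c(0.9, 0.6, 0.3))
#' cloneProportions(tr)      # 0.1, 0.3, 0.3, 0.3
#' topologyClass(tr)         # "linear"
#' @export
buildLineageTree <- function(cloneVafs, cloneVariants = NULL,
                             parentRule = c("deepest", "residual"),
                             delta = 0.02) {
    parentRule <- match.arg(parentRule)
    eps <- 1e-9
    stopifnot(all(cloneVafs > 0 & cloneVafs <= 1 + eps))
    if (is.unsorted(rev(cloneVafs), strictly = FALSE) &&
        any(diff(cloneVafs) > eps))
        stop("cloneVafs must be in descending order")
    n <- length(cloneVafs)
    if (is.null(cloneVariants))
        cloneVariants <- lapply(seq_len(n), function(i) paste0("m", i))
    stopifnot(length(cloneVariants) == n)
    id <- 0:n
    parent <- c(NA_integer_, integer(n))
    depth <- c(0L, integer(n))
    vaf <- c(1.0, cloneVafs)
    childSum <- numeric(n + 1L)
    for (i in seq_len(n)) {
        v <- cloneVafs[i]
        placed <- seq_len(i)               # node indices 1..i = ids 0..i-1
        residual <- vaf[placed] - childSum[placed]
        feasible <- which(residual + eps >= v)
        if (!length(feasible))
            stop("no feasible parent for clone ", i, " (VAF ",
                 format(v), "): summed VAFs exceed capacity")
        cand <- placed[feasible]
        pick <- if (parentRule == "deepest") {
            best <- cand[depth[cand] == max(depth[cand])]
            best[which.max(residual[feasible][depth[cand] ==
                                              max(depth[cand])])]
        } else {
            best <- cand[residual[feasible] == max(residual[feasible])]
            best[which.max(depth[best])]
        }
        parent[i + 1L] <- id[pick]
        depth[i + 1L] <- depth[pick] + 1L
        childSum[pick] <- childSum[pick] + v
    }
    proportion <- vaf - childSum
    nodes <- data.frame(id = id, parent = parent, depth = depth,
                        vaf = vaf,
                        nMut = c(0L, lengths(cloneVariants)),
                        proportion = proportion)
    nchildren <- table(factor(parent, levels = id))
    topology <- if (all(nchildren <= 1L)) "linear" else "branching"
    new("LineageTree", nodes = nodes,
        variants = c(list(character()), lapply(cloneVariants, as.character)),
        topology = topology, delta = delta, parentRule = parentRule)
}

#' Build a lineage tree directly from a mitochondrial variant table
#'
#' Convenience wrapper chaining [orderVariants()], [mergeCoclonal()] and
#' [buildLineageTree()].
#'
#' @param variants a \code{data.frame} with columns \code{id},
#'   \code{vaf}, \code{pos}, \code{alt}.
#' @inheritParams buildLineageTree
#' @return a [LineageTree-class].
#' @export
lineageFromVariants <- function(variants, delta = 0.02,
                                parentRule = c("deepest", "residual")) {
    parentRule <- match.arg(parentRule)
    ord <- orderVariants(variants)
    clones <- mergeCoclonal(ord, delta)
    buildLineageTree(clones$vaf, clones$variants, parentRule = parentRule,
                     delta = delta)
}

#' Clone proportions of a lineage tree
#'
#' The proportion of mitochondrial genome copies belonging exclusively to
#' each clone: its VAF minus the summed VAFs of its children, with the
#' root counted at VAF 1. Proportions are non-negative by rule-3
#' feasibility and sum to exactly 1.
#'
#' @param tree a [LineageTree-class]
#' @return named numeric vector (names \code{A0}, \code{A1}, ...).
#' @export
cloneProportions <- function(tree) {
    stats::setNames(tree@nodes$proportion, paste0("A", tree@nodes$id))
}

#' Topology class of a lineage tree
#'
#' @param tree a [LineageTree-class]
#' @return \code{"linear"} if no node has more than one child, otherwise
#'   \code{"branching"}.
#' @export
topologyClass <- function(tree) tree@topology

#' First-hit statistics across a cohort of lineage trees
#'
#' The putative first hit of each case is clone A1, the clone with the
#' largest VAF (after co-clonal merging a first hit can carry several
#' mutations). Reports per-case first-hit VAF, mutation ids and region
#' labels, plus the cohort fraction of first hits at VAF >= 0.5.
#'
#' @param trees a named list of [LineageTree-class] objects; cases whose
#'   tree has no mutated clone are skipped with a message.
#' @param regions optional named character vector mapping mutation ids to
#'   region labels.
#' @return a list: \code{perCase} (\code{data.frame} with \code{case},
#'   \code{vaf}, \code{nMut}, \code{ids}, \code{regions}) and
#'   \code{fractionVafGE50} (fraction of reported cases with first-hit
#'   VAF >= 0.5).
#' @export
firstHitStats <- function(trees, regions = NULL) {
    if (is.null(names(trees)))
        names(trees) <- paste0("case", seq_along(trees))
    rows <- list()
    for (nm in names(trees)) {
        tr <- trees[[nm]]
        if (nrow(tr@nodes) < 2L) {
            message("case ", nm, " has no mutated clone; skipped")
            next
        }
        ids <- tr@variants[[2L]]
        reg <- if (is.null(regions)) NA_character_ else
            paste(unique(regions[ids]), collapse = ",")
        rows[[nm]] <- data.frame(
            case = nm, vaf = tr@nodes$vaf[2L], nMut = length(ids),
            ids = paste(ids, collapse = ","), regions = reg,
            stringsAsFactors = FALSE)
    }
    perCase <- if (length(rows))
        do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else
        data.frame(case = character(), vaf = numeric(),
                   nMut = integer(), ids = character(),
                   regions = character(), stringsAsFactors = FALSE)
    list(perCase = perCase,
         fractionVafGE50 = if (nrow(perCase)) mean(perCase$vaf >= 0.5)
                           else NA_real_)
}

#' @export
setMethod("show", "LineageTree", function(object) {
    cat("LineageTree (", object@topology, ", parent rule ",
        object@parentRule, ", delta ", object@delta, ")\n", sep = "")
    cat(formatLineageTree(object), sep = "\n")
    invisible(object)
})

#' Render a lineage tree as indented text
#'
#' @param tree a [LineageTree-class]
#' @return character vector, one line per node.
#' @export
formatLineageTree <- function(tree) {
    nd <- tree@nodes
    out <- character(0)
    recurse <- function(i, indent) {
        row <- which(nd$id == i)
        out <<- c(out, sprintf(
            "%sA%d: VAF %.3f, %d mutation(s), proportion %.1f%%",
            strrep("  ", indent), i, nd$vaf[row], nd$nMut[row],
            100 * nd$proportion[row]))
        for (k in nd$id[!is.na(nd$parent) & nd$parent == i])
            recurse(k, indent + 1L)
    }
    recurse(0L, 0L)
    out
}

#' Newick string for a lineage tree
#'
#' Node labels are \code{A0..An}; branch lengths carry each clone's
#' proportion, so the string round-trips the stick-breaking of the VAFs.
#'
#' @param tree a [LineageTree-class]
#' @return a single Newick string terminated by ";".
#' @export
lineageNewick <- function(tree) {
    nd <- tree@nodes
    recurse <- function(i) {
        row <- which(nd$id == i)
        kids <- nd$id[!is.na(nd$parent) & nd$parent == i]
        label <- sprintf("A%d:%.6g", i, nd$proportion[row])
        if (!length(kids))
            return(label)
        paste0("(", paste(vapply(kids, recurse, ""), collapse = ","),
               ")", label)
    }
    paste0(recurse(0L), ";")
}

#' Cohort lineage summary table
#'
#' @param trees a named list of [LineageTree-class] objects.
#' @return a \code{data.frame} with one row per case: topology class,
#'   number of clones, first-hit VAF, and total mutations.
#' @export
lineageSummary <- function(trees) {
    if (is.null(names(trees)))
        names(trees) <- paste0("case", seq_along(trees))
    do.call(rbind, c(lapply(names(trees), function(nm) {
        tr <- trees[[nm]]
        data.frame(case = nm, topology = tr@topology,
                   nClones = nrow(tr@nodes) - 1L,
                   firstHitVaf = if (nrow(tr@nodes) > 1L)
                       tr@nodes$vaf[2L] else NA_real_,
                   nMutations = sum(tr@nodes$nMut),
                   stringsAsFactors = FALSE)
    }), list(make.row.names = FALSE)))
}
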