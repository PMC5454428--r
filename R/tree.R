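#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei neighbor joining (via [ape::nj()], the implementation
#' the reference analyses of this field use). Negative branch lengths, which
#' NJ can produce on non-additive matrices, are clamped to zero; the total
#' clamped deficit is recorded in the `"clampedDeficit"` attribute of the
#' returned tree.
#'
#' @param d labeled symmetric distance matrix with zero diagonal, >= 3
#'   labels.
#' @return an unrooted `phylo` tree.
#' @export
neighborJoining <- function(d) {
    .checkDistanceMatrix(d)
    if (nrow(d) < 3L) stop("need at least 3 labels")
    tr <- ape::nj(d)
    deficit <- -sum(tr$edge.length[tr$edge.length < 0])
    tr$edge.length[tr$edge.length < 0] <- 0
    attr(tr, "clampedDeficit") <- deficit
    tr
}

#' Resample gene clusters in a presence-absence matrix
#' @noRd
.resampleColumns <- function(inc, mode) {
    p <- ncol(inc)
    cols <- if (mode == "bootstrap") sample.int(p, p, replace = TRUE)
            else sample.int(p, max(1L, round(0.8 * p)), replace = FALSE)
    sub <- inc[, cols, drop = FALSE]
    colnames(sub) <- paste0("b", seq_len(ncol(sub)))  # resampled copies
    sub
}

#' Gene-cluster resampling support for the gene-content NJ tree
#'
#' Builds the reference NJ tree from the full presence-absence matrix, then
#' resamples gene-cluster columns `iterations` times (bootstrap: with
#' replacement at full column count, the default; jackknife: 80% of columns
#' without replacement), recomputes the distance matrix and NJ tree each
#' time, and attaches the fraction of replicate trees containing each
#' internal bipartition as node labels of the reference tree.
#'
#' Replicates in which a genome loses its entire repertoire (all-zero row)
#' are redrawn, since the gene-content distance is undefined there.
#'
#' @param pa a [PresenceAbsenceMatrix-class].
#' @param iterations number of resampling iterations (>= 1; 1000 in the
#'   reference analysis).
#' @param mode `"bootstrap"` (default) or `"jackknife"`.
#' @param seed RNG seed for reproducible resampling.
#' @return the reference `phylo` tree with supports in \[0, 1\] as
#'   `node.label` (NA for the root).
#' @export
bootstrapSupport <- function(pa, iterations = 1000L,
                             mode = c("bootstrap", "jackknife"),
                             seed = NULL) {
    stopifnot(is(pa, "PresenceAbsenceMatrix"))
    mode <- match.arg(mode)
    iterations <- as.integer(iterations)
    if (is.na(iterations) || iterations < 1L) stop("iterations must be >= 1")
    ref <- neighborJoining(paDistanceMatrix(pa))
    inc <- pa@incidence
    trees <- .withSeed(seed, {
        lapply(seq_len(iterations), function(i) {
            repeat {
                sub <- .resampleColumns(inc, mode)
                if (all(rowSums(sub) > 0)) break
            }
            neighborJoining(paDistanceMatrix(
                new("PresenceAbsenceMatrix", incidence = sub)))
        })
    })
    class(trees) <- "multiPhylo"
    counts <- ape::prop.clades(ref, trees, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    support <- counts / iterations
    # first internal node is the (arbitrary) root of the unrooted tree
    support[1L] <- NA_real_
    ref$node.label <- support
    ref
}

#' Robinson-Foulds distance between two trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' unrooted trees (symmetric difference), computed with
#' [phangorn::RF.dist()]. Identical topologies give 0.
#'
#' @param t1,t2 `phylo` trees over the same leaf label set.
#' @return integer bipartition count.
#' @export
robinsonFoulds <- function(t1, t2) {
    if (!inherits(t1, "phylo") || !inherits(t2, "phylo"))
        stop("expected two phylo trees")
    if (!setequal(t1$tip.label, t2$tip.label))
        stop("trees must share the same leaf label set")
    as.integer(phangorn::RF.dist(t1, t2, check.labels = TRUE))
}

#' Do the given leaves form a clade (bipartition) of an unrooted tree?
#'
#' TRUE when some edge of the tree splits exactly `leaves` from the rest.
#'
#' @param tree a `phylo` tree.
#' @param leaves character vector of tip labels.
#' @return logical.
#' @export
isClade <- function(tree, leaves) {
    if (!all(leaves %in% tree$tip.label)) stop("unknown leaf label(s)")
    parts <- ape::prop.part(tree)
    labs <- attr(parts, "labels")
    target <- sort(match(leaves, labs))
    comp <- sort(setdiff(seq_along(labs), target))
    any(vapply(parts, function(p) identical(sort(p), target) ||
                                   identical(sort(p), comp), logical(1)))
}
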