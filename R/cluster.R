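#' Greedy centroid engine shared by protein and OTU clustering.
#'
#' `ids` are processed in the given order; each joins the first existing
#' centroid (creation order) whose identity reaches the threshold, else
#' founds a new cluster. `identityFun(id, centroidIds)` must return the
#' identity of record `id` to each centroid.
#' @noRd
.greedyEngine <- function(ids, identityFun, threshold,
                          seedCentroids = character(0)) {
    centroids <- seedCentroids
    membership <- setNames(seedCentroids, seedCentroids)
    for (id in ids) {
        sims <- identityFun(id, centroids)
        hit <- which(sims >= threshold)
        if (length(hit)) {
            membership[[id]] <- centroids[hit[1L]]
        } else {
            centroids <- c(centroids, id)
            membership[[id]] <- id
        }
    }
    list(centroids = centroids, membership = membership)
}

#' Length-descending, id-lexicographic processing order (C collation).
#' @noRd
.greedyOrder <- function(seqs) {
    ids <- names(seqs)
    ids[order(-Biostrings::width(seqs), ids, method = "radix")]
}

#' Greedy centroid clustering at a fractional identity threshold
#'
#' Clusters protein records across genomes into gene clusters, emulating
#' centroid-led clustering a la USEARCH/UCLUST: records are processed in
#' decreasing length order (ties broken by id, lexicographically); each
#' record joins the first existing centroid (in creation order) reaching
#' [pairwiseIdentity()] `>= threshold`, otherwise it becomes a new centroid.
#' The outcome is deterministic for a given input.
#'
#' @param seqs an [Biostrings::AAStringSet] with unique names (record ids).
#' @param groups optional character vector parallel to `seqs` (or named by
#'   record id) giving the genome of origin of each record; defaults to the
#'   part of the id before the first `"|"`.
#' @param threshold fractional identity in (0, 1]; default 0.5, the
#'   amino-acid identity used to delineate homologues across
#'   phycodnavirus genomes.
#' @return a [GeneClusterSet-class].
#' @seealso [buildPresenceAbsence()], [otuCluster()]
#' @export
greedyCluster <- function(seqs, groups = NULL, threshold = 0.5) {
    seqs <- Biostrings::AAStringSet(seqs)
    if (length(seqs) == 0L) stop("no records to cluster")
    ids <- names(seqs)
    if (is.null(ids) || anyDuplicated(ids)) stop("record ids must be unique")
    if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
    if (is.null(groups)) groups <- sub("\\|.*$", "", ids)
    if (!is.null(names(groups))) groups <- groups[ids]
    groups <- setNames(as.character(groups), ids)

    idFun <- function(id, centroids) .identityToSet(seqs[[id]], seqs[centroids])
    res <- .greedyEngine(.greedyOrder(seqs), idFun, threshold)
    new("GeneClusterSet", sequences = seqs, groups = groups,
        membership = res$membership[ids], centroids = res$centroids,
        threshold = threshold, referenceIds = character(0))
}

#' Build a genome-by-cluster presence-absence matrix
#'
#' A cluster is present in a genome when it contains at least one record
#' from that genome; multi-copy genes collapse to a single presence.
#'
#' @param clusters a [GeneClusterSet-class].
#' @return a [PresenceAbsenceMatrix-class] with genomes as rows (order of
#'   first appearance) and clusters as columns (creation order).
#' @export
buildPresenceAbsence <- function(clusters) {
    stopifnot(is(clusters, "GeneClusterSet"))
    genomes <- unique(clusters@groups)
    cl <- clusters@centroids
    inc <- matrix(FALSE, length(genomes), length(cl),
                  dimnames = list(genomes, cl))
    idx <- cbind(match(clusters@groups, genomes),
                 match(clusters@membership[names(clusters@groups)], cl))
    inc[idx] <- TRUE
    new("PresenceAbsenceMatrix", incidence = inc)
}

#' Venn-style shared cluster counts
#'
#' For a chosen set of genomes, counts the clusters present in all of them
#' (core of the subset), in at least two, and in exactly one (unique), plus
#' the pairwise shared counts Sij. Clusters absent from every chosen genome
#' are ignored.
#'
#' @param pa a [PresenceAbsenceMatrix-class].
#' @param subset genome labels to restrict to (default: all genomes).
#' @return list with elements `all`, `atLeastTwo`, `unique` (integers) and
#'   `pairwise` (symmetric matrix of shared counts, diagonal = Ni).
#' @export
sharedCounts <- function(pa, subset = NULL) {
    stopifnot(is(pa, "PresenceAbsenceMatrix"))
    inc <- pa@incidence
    if (is.null(subset)) subset <- rownames(inc)
    if (!all(subset %in% rownames(inc)))
        stop("unknown genome label(s): ",
             paste(setdiff(subset, rownames(inc)), collapse = ", "))
    sub <- inc[subset, , drop = FALSE]
    npres <- colSums(sub)
    pair <- sub %*% t(sub)
    storage.mode(pair) <- "integer"
    list(all = sum(npres == nrow(sub)),
         atLeastTwo = sum(npres >= 2L),
         unique = sum(npres == 1L),
         pairwise = pair)
}

#' Core / pan partition of gene clusters
#'
#' Core clusters are present in every genome of the matrix; all remaining
#' clusters (present in some but not all genomes) form the flexible
#' pan-genome. No annotation-based augmentation of the core is applied.
#'
#' @param pa a [PresenceAbsenceMatrix-class] with at least two genomes.
#' @return list with character vectors `core` and `pan` of cluster ids.
#' @export
corePanPartition <- function(pa) {
    stopifnot(is(pa, "PresenceAbsenceMatrix"))
    inc <- pa@incidence
    if (nrow(inc) < 2L) stop("need at least two genomes")
    core <- colnames(inc)[colSums(inc) == nrow(inc)]
    list(core = core, pan = setdiff(colnames(inc), core))
}
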