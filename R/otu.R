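#' Collapse identical sequences, keeping one representative id each
#' @noRd
.dereplicate <- function(seqs) {
    key <- as.character(seqs)
    rep <- !duplicated(key)
    list(reps = seqs[rep],
         repOf = setNames(names(seqs)[rep][match(key, key[rep])],
                          names(seqs)))
}

#' Cluster amplicon reads with reference sequences into OTUs
#'
#' Pools reference sequences and environmental reads and clusters them at a
#' fractional amino-acid identity threshold (default 0.97). References are
#' seeded as the first centroids in their input order, so reference-anchored
#' OTUs keep stable ids; reads are then processed by the greedy rule of
#' [greedyCluster()] (length-descending, first centroid reaching the
#' threshold). Reads are dereplicated before clustering, with duplicates
#' re-expanded into the membership afterwards.
#'
#' @param reads an [Biostrings::AAStringSet] of amino-acid reads with unique
#'   names, or a named list of such sets (one per sample).
#' @param references an [Biostrings::AAStringSet] of reference amplicon
#'   sequences with unique names (may be empty).
#' @param threshold fractional identity in (0, 1]; default 0.97.
#' @param samples optional character vector (parallel to `reads` or named
#'   by read id) of sample labels; defaults to the part of the read id
#'   before the first `"|"`, and is taken from list names when `reads` is a
#'   per-sample list. References get the label `"reference"`.
#' @return a [GeneClusterSet-class] whose `referenceIds` slot flags the
#'   reference-seeded centroids.
#' @export
otuCluster <- function(reads, references = NULL, threshold = 0.97,
                       samples = NULL) {
    if (is.list(reads) && !is(reads, "AAStringSet")) {
        if (is.null(names(reads))) stop("per-sample read list must be named")
        samples <- rep(names(reads), vapply(reads, length, integer(1)))
        reads <- do.call(c, unname(lapply(reads, Biostrings::AAStringSet)))
    } else {
        reads <- Biostrings::AAStringSet(reads)
    }
    if (is.null(references)) references <- Biostrings::AAStringSet()
    references <- Biostrings::AAStringSet(references)
    if (length(reads) + length(references) == 0L) stop("nothing to cluster")
    if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
    if (is.null(samples)) samples <- sub("\\|.*$", "", names(reads))
    if (!is.null(names(samples))) samples <- samples[names(reads)]

    seqs <- c(references, reads)
    ids <- names(seqs)
    if (is.null(ids) || anyDuplicated(ids))
        stop("read/reference ids must be unique")
    groups <- setNames(c(rep("reference", length(references)),
                         as.character(samples)), ids)

    der <- .dereplicate(reads)
    # representatives already equal to a reference sequence still go through
    # the greedy pass; identity 1 assigns them to that reference centroid
    idFun <- function(id, cents) .identityToSet(seqs[[id]], seqs[cents])
    res <- .greedyEngine(.greedyOrder(der$reps), idFun, threshold,
                         seedCentroids = names(references))
    membership <- res$membership[c(names(references),
                                   der$repOf[names(reads)])]
    names(membership) <- ids
    new("GeneClusterSet", sequences = seqs, groups = groups,
        membership = membership, centroids = res$centroids,
        threshold = threshold, referenceIds = names(references))
}

#' Discard singleton clusters
#'
#' Removes clusters with a single member. A reference seeded as a centroid
#' that attracted no reads counts as a singleton and is retained only with
#' `keepReferences = TRUE`.
#'
#' @param clusters a [GeneClusterSet-class].
#' @param keepReferences keep read-less reference clusters (default FALSE).
#' @return a [GeneClusterSet-class] restricted to the surviving clusters.
#' @export
discardSingletons <- function(clusters, keepReferences = FALSE) {
    stopifnot(is(clusters, "GeneClusterSet"))
    sz <- clusterSizes(clusters)
    keep <- names(sz)[sz >= 2L]
    if (keepReferences)
        keep <- union(keep, intersect(clusters@centroids,
                                      clusters@referenceIds))
    keep <- clusters@centroids[clusters@centroids %in% keep]
    mem <- clusters@membership[clusters@membership %in% keep]
    ids <- names(mem)
    new("GeneClusterSet", sequences = clusters@sequences[ids],
        groups = clusters@groups[ids], membership = mem,
        centroids = keep, threshold = clusters@threshold,
        referenceIds = intersect(clusters@referenceIds, ids))
}

#' Assign reads to OTU centroids and tabulate per-sample counts
#'
#' Each read is assigned to the best-identity centroid with identity at
#' least `threshold` (ties broken by centroid creation order); reads below
#' the threshold for every centroid are tallied as unassigned. Reads are
#' dereplicated internally, so identical reads share one alignment pass.
#'
#' @param reads an [Biostrings::AAStringSet] of reads, or a named
#'   per-sample list of such sets.
#' @param centroids an [Biostrings::AAStringSet] of OTU centroid sequences
#'   (e.g. `centroidSeqs(clusters)`), or a [GeneClusterSet-class] from
#'   [otuCluster()] whose centroids and reference flags are then used.
#' @param threshold fractional identity (default 0.97).
#' @param samples optional sample labels, as in [otuCluster()].
#' @return an [OTUTable-class] of raw counts.
#' @export
assignReads <- function(reads, centroids, threshold = 0.97, samples = NULL) {
    refOtus <- character(0)
    if (is(centroids, "GeneClusterSet")) {
        refOtus <- centroids@centroids[
            vapply(centroids@centroids, function(cc)
                any(clusterMembers(centroids, cc) %in%
                        centroids@referenceIds), logical(1))]
        centroids <- centroidSeqs(centroids)
    }
    centroids <- Biostrings::AAStringSet(centroids)
    if (length(centroids) == 0L) stop("no centroids")
    if (is.list(reads) && !is(reads, "AAStringSet")) {
        if (is.null(names(reads))) stop("per-sample read list must be named")
        samples <- rep(names(reads), vapply(reads, length, integer(1)))
        reads <- do.call(c, unname(lapply(reads, Biostrings::AAStringSet)))
    } else {
        reads <- Biostrings::AAStringSet(reads)
    }
    if (is.null(samples)) samples <- sub("\\|.*$", "", names(reads))
    if (!is.null(names(samples))) samples <- samples[names(reads)]
    samples <- as.character(samples)

    der <- .dereplicate(reads)
    best <- vapply(names(der$reps), function(id) {
        sims <- .identityToSet(der$reps[[id]], centroids)
        top <- max(sims)
        if (top >= threshold) which(sims == top)[1L] else NA_integer_
    }, integer(1))
    otuOfRead <- best[match(der$repOf[names(reads)], names(der$reps))]

    sampleLevels <- unique(samples)
    otuIds <- names(centroids)
    counts <- matrix(0L, length(sampleLevels), length(otuIds),
                     dimnames = list(sampleLevels, otuIds))
    assigned <- !is.na(otuOfRead)
    tab <- table(factor(samples[assigned], levels = sampleLevels),
                 factor(otuIds[otuOfRead[assigned]], levels = otuIds))
    counts[] <- as.integer(tab)
    unassigned <- as.integer(table(factor(samples[!assigned],
                                          levels = sampleLevels)))
    new("OTUTable", counts = counts, rarefied = FALSE, depth = NA_integer_,
        referenceOtus = intersect(refOtus, otuIds),
        unassigned = setNames(unassigned, sampleLevels))
}

#' Rarefy an OTU table to the minimum sample depth
#'
#' Subsamples every sample's counts without replacement to the smallest
#' cumulative read count over samples (hypergeometric rarefaction, via
#' [vegan::rrarefy()]); deterministic for a given seed.
#'
#' @param table an [OTUTable-class] with every row sum >= 1.
#' @param seed RNG seed.
#' @return the rarefied [OTUTable-class] (every row sums to the depth).
#' @export
rarefyTable <- function(table, seed = NULL) {
    stopifnot(is(table, "OTUTable"))
    cnt <- table@counts
    if (any(rowSums(cnt) < 1))
        stop("sample(s) with zero reads cannot be rarefied: ",
             paste(rownames(cnt)[rowSums(cnt) < 1], collapse = ", "))
    depth <- min(rowSums(cnt))
    rar <- .withSeed(seed, vegan::rrarefy(cnt, depth))
    storage.mode(rar) <- "integer"
    dimnames(rar) <- dimnames(cnt)
    new("OTUTable", counts = rar, rarefied = TRUE,
        depth = as.integer(depth), referenceOtus = table@referenceOtus,
        unassigned = table@unassigned)
}

#' Top-abundance OTUs per sample
#'
#' The `topK` highest-count OTUs in each sample among those with nonzero
#' counts; ties are broken by OTU column order.
#'
#' @param table an [OTUTable-class].
#' @param topK number of OTUs per sample (>= 1).
#' @return named list (one character vector of OTU ids per sample).
#' @export
dominantOtus <- function(table, topK = 1L) {
    stopifnot(is(table, "OTUTable"))
    topK <- as.integer(topK)
    if (is.na(topK) || topK < 1L) stop("topK must be >= 1")
    cnt <- table@counts
    out <- lapply(rownames(cnt), function(s) {
        v <- cnt[s, ]
        nz <- which(v > 0)
        nz <- nz[order(-v[nz], nz)]
        colnames(cnt)[utils::head(nz, topK)]
    })
    setNames(out, rownames(cnt))
}
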