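#' @include PanPhylo-package.R
NULL

setOldClass("phylo")

#' Empirical amino-acid substitution model
#'
#' Holds the symmetric exchangeabilities and stationary frequencies of an
#' empirical amino-acid replacement model, together with the rate matrix Q
#' normalized to one expected substitution per unit time and the
#' eigendecomposition used to compute transition probabilities.
#'
#' @slot name model name, e.g. `"WAG"`.
#' @slot rates symmetric 20 x 20 exchangeability matrix (zero diagonal).
#' @slot freqs stationary amino-acid frequencies, summing to 1.
#' @slot Q normalized rate matrix; rows sum to 0 and
#'   `-sum(freqs * diag(Q)) == 1`.
#' @slot eigenValues,eigenVectors eigendecomposition of the symmetrized rate
#'   matrix `diag(sqrt(freqs)) Q diag(1/sqrt(freqs))`; `eigenVectors` is
#'   orthogonal.
#'
#' @seealso [wagModel()], [probMatrix()]
#' @export
setClass("SubstitutionModel",
    representation(name = "character", rates = "matrix", freqs = "numeric",
                   Q = "matrix", eigenValues = "numeric",
                   eigenVectors = "matrix"))

setValidity("SubstitutionModel", function(object) {
    msg <- character()
    if (!isTRUE(all.equal(sum(object@freqs), 1, tolerance = 1e-8)))
        msg <- c(msg, "stationary frequencies must sum to 1")
    if (max(abs(rowSums(object@Q))) > 1e-8)
        msg <- c(msg, "rows of Q must sum to 0")
    if (abs(sum(object@freqs * diag(object@Q)) + 1) > 1e-8)
        msg <- c(msg, "Q must be normalized to 1 expected substitution/unit")
    if (max(abs(object@rates - t(object@rates))) > 1e-10)
        msg <- c(msg, "exchangeabilities must be symmetric")
    if (length(msg)) msg else TRUE
})

#' Centroid-led protein sequence clusters
#'
#' Result of greedy centroid clustering at a fractional amino-acid identity
#' threshold ([greedyCluster()], [otuCluster()]). Every input record belongs
#' to exactly one cluster; each cluster is identified by the id of its
#' centroid record. Members reach at least `threshold` identity to their
#' centroid; a record became a new centroid only after failing the threshold
#' against every earlier centroid (greedy property).
#'
#' @slot sequences all clustered records, an [Biostrings::AAStringSet] named
#'   by record id.
#' @slot groups grouping label per record (genome of origin, or sample for
#'   amplicon reads), parallel to `sequences`.
#' @slot membership cluster id for every record id (named character).
#' @slot centroids centroid record ids in creation order; cluster ids equal
#'   centroid ids.
#' @slot threshold fractional identity threshold in (0, 1].
#' @slot referenceIds record ids that were seeded as reference centroids
#'   (empty outside OTU analysis).
#'
#' @export
setClass("GeneClusterSet",
    representation(sequences = "AAStringSet", groups = "character",
                   membership = "character", centroids = "character",
                   threshold = "numeric", referenceIds = "character"))

setValidity("GeneClusterSet", function(object) {
    ids <- names(object@sequences)
    msg <- character()
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "record ids must be unique and non-NULL")
    if (!setequal(names(object@membership), ids))
        msg <- c(msg, "membership must cover exactly the input records")
    if (!all(object@membership %in% object@centroids))
        msg <- c(msg, "every cluster id must be a centroid id")
    if (anyDuplicated(object@centroids))
        msg <- c(msg, "duplicated centroid ids")
    if (!all(object@membership[object@centroids] == object@centroids))
        msg <- c(msg, "each centroid must belong to its own cluster")
    if (length(object@threshold) != 1L || object@threshold <= 0 ||
        object@threshold > 1)
        msg <- c(msg, "threshold must be a single value in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Genome-by-cluster incidence matrix
#'
#' Boolean incidence of gene clusters across genomes. Row sums are the
#' per-genome cluster counts Ni; the inner product of two rows is the shared
#' count Sij entering the gene-content distance.
#'
#' @slot incidence logical matrix, genomes as rows, cluster ids as columns.
#'
#' @seealso [buildPresenceAbsence()], [paDistanceMatrix()], [sharedCounts()]
#' @export
setClass("PresenceAbsenceMatrix",
    representation(incidence = "matrix"))

setValidity("PresenceAbsenceMatrix", function(object) {
    inc <- object@incidence
    msg <- character()
    if (!is.logical(inc)) msg <- c(msg, "incidence must be logical")
    if (is.null(rownames(inc)) || is.null(colnames(inc)))
        msg <- c(msg, "incidence must have genome and cluster dimnames")
    if (anyDuplicated(rownames(inc)) || anyDuplicated(colnames(inc)))
        msg <- c(msg, "duplicated genome or cluster labels")
    if (length(msg)) msg else TRUE
})

#' Sample-by-OTU count table
#'
#' Counts of amplicon reads per sample and OTU (97% amino-acid identity
#' clusters by default). After [rarefyTable()] every row sums exactly to the
#' common depth. Reads failing the assignment threshold are tallied per
#' sample in `unassigned`.
#'
#' @slot counts integer matrix, samples as rows, OTU ids as columns.
#' @slot rarefied whether rows have been rarefied to even depth.
#' @slot depth rarefaction depth (NA when not rarefied).
#' @slot referenceOtus OTU ids whose cluster contains a reference sequence.
#' @slot unassigned per-sample count of reads not assigned to any OTU.
#'
#' @seealso [assignReads()], [rarefyTable()], [dominantOtus()]
#' @export
setClass("OTUTable",
    representation(counts = "matrix", rarefied = "logical",
                   depth = "integer", referenceOtus = "character",
                   unassigned = "integer"))

setValidity("OTUTable", function(object) {
    cnt <- object@counts
    msg <- character()
    if (!is.numeric(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
        msg <- c(msg, "counts must be nonnegative integers")
    if (is.null(rownames(cnt)) || is.null(colnames(cnt)))
        msg <- c(msg, "counts must have sample and OTU dimnames")
    if (isTRUE(object@rarefied)) {
        if (is.na(object@depth))
            msg <- c(msg, "rarefied table must record its depth")
        else if (any(rowSums(cnt) != object@depth))
            msg <- c(msg, "rarefied rows must all sum to the depth")
    }
    if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @describeIn GeneClusterSet-class number of clusters.
#' @param x,object a `GeneClusterSet`.
#' @export
setMethod("length", "GeneClusterSet", function(x) length(x@centroids))

#' Cluster ids (equal to centroid record ids), in creation order
#' @param x a [GeneClusterSet-class].
#' @return character vector of cluster ids.
#' @export
clusterIds <- function(x) {
    stopifnot(is(x, "GeneClusterSet"))
    x@centroids
}

#' Cluster sizes in creation order
#' @param x a [GeneClusterSet-class].
#' @return named integer vector, one entry per cluster.
#' @export
clusterSizes <- function(x) {
    stopifnot(is(x, "GeneClusterSet"))
    tab <- table(factor(x@membership, levels = x@centroids))
    setNames(as.integer(tab), x@centroids)
}

#' Member record ids of one cluster
#' @param x a [GeneClusterSet-class].
#' @param cluster a cluster id.
#' @return character vector of record ids (centroid first).
#' @export
clusterMembers <- function(x, cluster) {
    stopifnot(is(x, "GeneClusterSet"))
    if (!cluster %in% x@centroids) stop("unknown cluster id: ", cluster)
    ids <- names(x@membership)[x@membership == cluster]
    c(cluster, setdiff(ids, cluster))
}

#' Cluster membership of every record
#' @param x a [GeneClusterSet-class].
#' @return named character vector mapping record id to cluster id.
#' @export
memberMap <- function(x) {
    stopifnot(is(x, "GeneClusterSet"))
    x@membership
}

#' Centroid sequences in creation order
#' @param x a [GeneClusterSet-class].
#' @return an [Biostrings::AAStringSet] of centroid sequences.
#' @export
centroidSeqs <- function(x) {
    stopifnot(is(x, "GeneClusterSet"))
    x@sequences[x@centroids]
}

#' Genome (or sample) labels of a `PresenceAbsenceMatrix` or `OTUTable`
#' @param x a [PresenceAbsenceMatrix-class] or [OTUTable-class].
#' @return character vector of row labels.
#' @export
sampleIds <- function(x) {
    if (is(x, "PresenceAbsenceMatrix")) return(rownames(x@incidence))
    if (is(x, "OTUTable")) return(rownames(x@counts))
    stop("unsupported object")
}

#' Incidence matrix of a `PresenceAbsenceMatrix`
#' @param x a [PresenceAbsenceMatrix-class].
#' @return logical genome-by-cluster matrix.
#' @export
incidence <- function(x) {
    stopifnot(is(x, "PresenceAbsenceMatrix"))
    x@incidence
}

#' Per-genome gene cluster counts (Ni)
#' @param x a [PresenceAbsenceMatrix-class].
#' @return named integer vector of row sums.
#' @export
geneCounts <- function(x) {
    stopifnot(is(x, "PresenceAbsenceMatrix"))
    rowSums(x@incidence)
}

#' Count matrix of an `OTUTable`
#' @param x an [OTUTable-class].
#' @return integer sample-by-OTU matrix.
#' @export
otuCounts <- function(x) {
    stopifnot(is(x, "OTUTable"))
    x@counts
}

#' Is an `OTUTable` rarefied, and to what depth?
#' @param x an [OTUTable-class].
#' @return `isRarefied`: logical; `rarefactionDepth`: integer (NA if not
#'   rarefied).
#' @export
isRarefied <- function(x) {
    stopifnot(is(x, "OTUTable"))
    x@rarefied
}

#' @rdname isRarefied
#' @export
rarefactionDepth <- function(x) {
    stopifnot(is(x, "OTUTable"))
    x@depth
}

## ---- show methods ----

setMethod("show", "SubstitutionModel", function(object) {
    cat("SubstitutionModel:", object@name, "\n")
    cat("  20 states, Q normalized to 1 expected substitution per unit time\n")
})

setMethod("show", "GeneClusterSet", function(object) {
    sz <- clusterSizes(object)
    cat("GeneClusterSet:", length(object@centroids), "clusters,",
        length(object@sequences), "records, identity threshold",
        object@threshold, "\n")
    cat("  cluster sizes: ", paste(utils::head(sz, 8L), collapse = " "),
        if (length(sz) > 8L) "..." else "", "\n", sep = "")
    if (length(object@referenceIds))
        cat("  reference-seeded centroids:", length(object@referenceIds), "\n")
})

setMethod("show", "PresenceAbsenceMatrix", function(object) {
    cat("PresenceAbsenceMatrix:", nrow(object@incidence), "genomes x",
        ncol(object@incidence), "gene clusters\n")
    cat("  per-genome counts:",
        paste(rownames(object@incidence), rowSums(object@incidence),
              sep = "=", collapse = " "), "\n")
})

setMethod("show", "OTUTable", function(object) {
    cat("OTUTable:", nrow(object@counts), "samples x", ncol(object@counts),
        "OTUs", if (object@rarefied)
            paste0("(rarefied to depth ", object@depth, ")") else
            "(raw counts)", "\n")
    if (any(object@unassigned > 0))
        cat("  unassigned reads:",
            paste(names(object@unassigned), object@unassigned,
                  sep = "=", collapse = " "), "\n")
})
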