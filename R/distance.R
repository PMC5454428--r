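#' Gene-content phylogenetic distance
#'
#' Distance between two genomes from shared gene-cluster counts:
#' `D = -ln(S / sqrt(Ni * Nj))`, where `S` is the number of clusters shared
#' by the pair and `Ni`, `Nj` are the cluster counts of the two genomes.
#' Identical repertoires give 0. When `S = 0` the distance is undefined;
#' a pseudo-count of 0.5 shared clusters is substituted so downstream tree
#' building stays finite, and the value is flagged via the `"capped"`
#' attribute.
#'
#' @param s shared cluster count(s) Sij (vectorized).
#' @param ni,nj per-genome cluster counts, each >= 1.
#' @return numeric distance(s); attribute `"capped"` marks entries where
#'   the `S = 0` pseudo-count was applied.
#' @examples
#' geneContentDistance(125, 271, 260) # 0.7531
#' @export
geneContentDistance <- function(s, ni, nj) {
    if (any(ni < 1) || any(nj < 1)) stop("ni and nj must be >= 1")
    if (any(s < 0) || any(s > pmin(ni, nj)))
        stop("s must satisfy 0 <= s <= min(ni, nj)")
    capped <- s == 0
    s <- ifelse(capped, 0.5, s)
    d <- -log(s / sqrt(ni * nj))
    attr(d, "capped") <- capped
    d
}

#' Pairwise gene-content distance matrix from a presence-absence matrix
#'
#' All pairwise [geneContentDistance()] values over the rows of the
#' incidence matrix. Pairs with no shared clusters are capped (0.5
#' pseudo-count) and listed in the `"cappedPairs"` attribute.
#'
#' @param pa a [PresenceAbsenceMatrix-class]; every genome must carry at
#'   least one cluster.
#' @return symmetric numeric matrix with zero diagonal, labeled by genome.
#' @export
paDistanceMatrix <- function(pa) {
    stopifnot(is(pa, "PresenceAbsenceMatrix"))
    inc <- pa@incidence
    ni <- rowSums(inc)
    if (any(ni == 0))
        stop("genome(s) with empty repertoire: ",
             paste(rownames(inc)[ni == 0], collapse = ", "))
    s <- inc %*% t(inc)
    d <- -log(pmax(s, 0.5) / sqrt(outer(ni, ni)))
    diag(d) <- 0
    capped <- which(s == 0 & upper.tri(s), arr.ind = TRUE)
    attr(d, "cappedPairs") <- if (nrow(capped))
        cbind(rownames(inc)[capped[, 1L]], rownames(inc)[capped[, 2L]])
    else NULL
    d
}

#' Validate a labeled square distance matrix
#' @noRd
.checkDistanceMatrix <- function(d, tol = 1e-8) {
    if (!is.matrix(d) || nrow(d) != ncol(d))
        stop("expected a square matrix")
    if (is.null(rownames(d)) || !identical(rownames(d), colnames(d)))
        stop("row and column labels must be present and identical")
    if (max(abs(d - t(d))) > tol) stop("matrix is not symmetric")
    if (max(abs(diag(d))) > tol) stop("diagonal must be zero")
    if (any(!is.finite(d))) stop("all distances must be finite")
    invisible(d)
}

#' Restrict a distance matrix to a subset of labels
#'
#' @param d labeled symmetric distance matrix.
#' @param keep labels to retain (at least 3); output preserves the order of
#'   `keep`.
#' @return the restricted matrix.
#' @export
subsetDistanceMatrix <- function(d, keep) {
    .checkDistanceMatrix(d)
    if (!all(keep %in% rownames(d)))
        stop("unknown label(s): ",
             paste(setdiff(keep, rownames(d)), collapse = ", "))
    if (length(keep) < 3L) stop("need at least 3 labels")
    d[keep, keep]
}

#' Read / write a labeled square distance matrix as TSV
#'
#' The dialect is a header row and header column of labels with `%.4f`
#' values; [readDistanceMatrix()] validates symmetry and zero diagonal.
#'
#' @param path file path.
#' @return `readDistanceMatrix`: labeled numeric matrix.
#' @export
readDistanceMatrix <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                            check.names = FALSE)
    d <- as.matrix(df)
    storage.mode(d) <- "double"
    .checkDistanceMatrix(d)
    d
}

#' @rdname readDistanceMatrix
#' @param d labeled symmetric distance matrix.
#' @export
writeDistanceMatrix <- function(d, path) {
    .checkDistanceMatrix(d)
    out <- matrix(sprintf("%.4f", d), nrow(d), dimnames = dimnames(d))
    utils::write.table(out, path, sep = "\t", quote = FALSE, col.names = NA)
    invisible(path)
}

#' Reference distance matrices for sequenced phycodnaviruses
#'
#' Published pairwise phylogenetic distances among 13 sequenced
#' prasinovirus and chlorovirus reference genomes (MpV1, MPV-12T, MpV-PL1,
#' MpV-SP1, BpV1, BpV2, OtV1, OtV2, OtV5, OtV6, OlV1, PBCV1, AR158):
#' gene presence-absence distances at the 50% amino-acid identity
#' clustering level, full-length DNApol maximum-likelihood (WAG) distances,
#' and the per-genome CDS counts, transcribed from the primary literature
#' for these isolates and shipped as plain-text fixtures.
#'
#' @return list with elements `geneContent` and `dnapol` (13 x 13 labeled
#'   distance matrices) and `cdsCounts` (named integer vector).
#' @examples
#' ref <- referenceDistanceMatrices()
#' mantelTest(ref$geneContent, ref$dnapol, permutations = 99, seed = 1)
#' @export
referenceDistanceMatrices <- function() {
    ext <- function(f) system.file("extdata", f, package = "PanPhylo",
                                   mustWork = TRUE)
    cds <- utils::read.table(ext("prasinovirus_cds_counts.tsv"),
                             sep = "\t", header = TRUE)
    list(geneContent =
             readDistanceMatrix(ext("prasinovirus_gene_content_distances.tsv")),
         dnapol = readDistanceMatrix(ext("prasinovirus_dnapol_distances.tsv")),
         cdsCounts = setNames(as.integer(cds$cds), cds$genome))
}
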