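#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation of the vectorized strict lower triangles after
#' aligning the second matrix to the label order of the first; significance
#' from permuting the label order of the second matrix. The permutation
#' p-value is `(#{r_perm >= r_obs} + 1) / (permutations + 1)` for the
#' upper tail (or with `|r|` for the two-sided variant), so it is never
#' smaller than `1 / (permutations + 1)`.
#'
#' @param d1,d2 labeled symmetric distance matrices over the same label
#'   set (order may differ), at least 4 labels.
#' @param permutations number of label permutations (default 999).
#' @param seed RNG seed for reproducible permutations.
#' @param tail `"upper"` (default) or `"two-sided"`.
#' @return object of class `"MantelResult"`: list with `r`, `p`,
#'   `permutations`, `tail`.
#' @examples
#' ref <- referenceDistanceMatrices()
#' mantelTest(ref$geneContent, ref$dnapol, permutations = 99, seed = 1)
#' @export
mantelTest <- function(d1, d2, permutations = 999L, seed = NULL,
                       tail = c("upper", "two-sided")) {
    tail <- match.arg(tail)
    .checkDistanceMatrix(d1)
    .checkDistanceMatrix(d2)
    if (!setequal(rownames(d1), rownames(d2)))
        stop("matrices must share the same label set")
    n <- nrow(d1)
    if (n < 4L) stop("need at least 4 labels")
    permutations <- as.integer(permutations)
    if (is.na(permutations) || permutations < 1L)
        stop("permutations must be >= 1")
    d2 <- d2[rownames(d1), rownames(d1)]
    lt <- lower.tri(d1)
    v1 <- d1[lt]
    robs <- stats::cor(v1, d2[lt])
    rperm <- .withSeed(seed, {
        vapply(seq_len(permutations), function(i) {
            p <- sample.int(n)
            stats::cor(v1, d2[p, p][lt])
        }, numeric(1))
    })
    p <- if (tail == "upper") (sum(rperm >= robs) + 1) / (permutations + 1)
         else (sum(abs(rperm) >= abs(robs)) + 1) / (permutations + 1)
    structure(list(r = robs, p = p, permutations = permutations,
                   tail = tail),
              class = "MantelResult")
}

#' @export
print.MantelResult <- function(x, ...) {
    cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s tail, %d permutations)\n",
                x$r, x$p, x$tail, x$permutations))
    invisible(x)
}

#' Calibrate the amplicon clustering threshold against full-length
#' divergence
#'
#' For each candidate identity threshold, clusters the amplicon sequences
#' greedily ([greedyCluster()] semantics on a precomputed identity matrix),
#' pools the full-length pairwise distances among co-clustered labels over
#' all clusters with at least two members, and reports the sample standard
#' deviation of the pooled values. Decreasing spread with increasing
#' stringency indicates the threshold at which amplicon clusters become
#' specific to full-length marker divergence.
#'
#' @param fullDist labeled distance matrix of full-length marker distances.
#' @param amplicons an [Biostrings::AAStringSet] of amplicon sequences whose
#'   names are a subset of the `fullDist` labels.
#' @param thresholds increasing identity thresholds in (0, 1]; default a
#'   0.70-1.00 grid in steps of 0.01.
#' @return data frame of class `"CalibrationCurve"` with columns
#'   `threshold`, `stdv` (NA when fewer than two co-clustered pairs
#'   contribute) and `nPairs`.
#' @seealso [selectThreshold()]
#' @export
calibrationCurve <- function(fullDist, amplicons,
                             thresholds = seq(0.70, 1.00, by = 0.01)) {
    .checkDistanceMatrix(fullDist)
    amplicons <- Biostrings::AAStringSet(amplicons)
    if (length(amplicons) == 0L) stop("no amplicon sequences")
    ids <- names(amplicons)
    if (is.null(ids) || anyDuplicated(ids))
        stop("amplicon names must be unique")
    if (!all(ids %in% rownames(fullDist)))
        stop("amplicon labels missing from the distance matrix")
    if (any(thresholds <= 0 | thresholds > 1) ||
        is.unsorted(thresholds, strictly = TRUE))
        stop("thresholds must be strictly increasing values in (0, 1]")

    # precompute the identity matrix once; greedy passes then just look up
    idm <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_len(length(ids) - 1L))
        for (j in seq.int(i + 1L, length(ids)))
            idm[i, j] <- idm[j, i] <-
                pairwiseIdentity(amplicons[[i]], amplicons[[j]])

    ord <- .greedyOrder(amplicons)
    res <- lapply(thresholds, function(g) {
        cl <- .greedyEngine(ord, function(id, cents) idm[id, cents], g)
        pooled <- numeric(0)
        for (cent in cl$centroids) {
            mem <- names(cl$membership)[cl$membership == cent]
            if (length(mem) >= 2L) {
                sub <- fullDist[mem, mem]
                pooled <- c(pooled, sub[lower.tri(sub)])
            }
        }
        c(stdv = if (length(pooled) >= 2L) stats::sd(pooled) else NA_real_,
          nPairs = length(pooled))
    })
    out <- data.frame(threshold = thresholds,
                      stdv = vapply(res, `[[`, numeric(1), "stdv"),
                      nPairs = as.integer(vapply(res, `[[`, numeric(1),
                                                 "nPairs")))
    class(out) <- c("CalibrationCurve", class(out))
    out
}

#' Select the amplicon clustering threshold from a calibration curve
#'
#' Smallest threshold whose within-cluster full-length distance spread is
#' at most `epsilon`. When no threshold qualifies, the threshold with the
#' minimal spread is returned with attribute `"flagged" = TRUE`.
#'
#' @param curve a [calibrationCurve()] result.
#' @param epsilon tolerated standard deviation (default 0.05).
#' @return selected threshold (numeric scalar).
#' @export
selectThreshold <- function(curve, epsilon = 0.05) {
    stopifnot(inherits(curve, "CalibrationCurve") || is.data.frame(curve))
    ok <- !is.na(curve$stdv)
    if (!any(ok)) stop("spread undefined at every threshold")
    qual <- ok & curve$stdv <= epsilon
    if (any(qual)) return(curve$threshold[which(qual)[1L]])
    best <- which.min(ifelse(ok, curve$stdv, Inf))
    structure(curve$threshold[best], flagged = TRUE)
}
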