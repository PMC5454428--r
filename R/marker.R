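#' Site-pattern counts of an aligned sequence pair, pairwise deletion
#'
#' Drops columns where either sequence has a gap (`-` or `.`) or an
#' ambiguous residue (`X`); returns the 20 x 20 table of aligned residue
#' pairs.
#' @noRd
.pairCounts <- function(a, b) {
    ca <- strsplit(as.character(a), "", fixed = TRUE)[[1L]]
    cb <- strsplit(as.character(b), "", fixed = TRUE)[[1L]]
    if (length(ca) != length(cb))
        stop("aligned sequences must have equal length")
    ia <- match(ca, .AA20)
    ib <- match(cb, .AA20)
    keep <- !is.na(ia) & !is.na(ib)
    table(factor(.AA20[ia[keep]], levels = .AA20),
          factor(.AA20[ib[keep]], levels = .AA20))
}

#' Log-likelihood of an aligned pair at divergence t
#' @noRd
.pairLogLik <- function(counts, model, t) {
    P <- probMatrix(model, t)
    L <- model@freqs * P  # pi_x * P_xy(t)
    sum(counts * log(pmax(L, 1e-300)))
}

#' Pairwise maximum-likelihood protein distance
#'
#' ML estimate of the evolutionary distance between two aligned amino-acid
#' sequences under a reversible empirical model: columns gapped in either
#' sequence are dropped (pairwise deletion), and the per-site likelihood
#' `sum(log(pi_x * P_xy(t)))` is maximized over `t` in \[1e-6, 20\] by
#' bracketed one-dimensional optimization (tolerance 1e-8). No among-site
#' rate variation is modeled.
#'
#' @param a,b aligned sequences of equal length (character or
#'   [Biostrings::AAString]); gaps `-`/`.` and `X` allowed.
#' @param model a [SubstitutionModel-class]; default WAG.
#' @return estimated distance in expected substitutions per site.
#' @export
pairwiseMLDistance <- function(a, b, model = wagModel()) {
    counts <- .pairCounts(a, b)
    if (sum(counts) == 0L)
        stop("no shared residue columns; distance undefined")
    opt <- stats::optimize(function(t) .pairLogLik(counts, model, t),
                           interval = c(1e-6, 20), maximum = TRUE,
                           tol = 1e-8)
    opt$maximum
}

#' Simple corrected distances between aligned protein sequences
#'
#' `kind = "p"`: mismatch fraction over shared-residue columns.
#' `kind = "poisson"`: Poisson correction `-ln(1 - p)`; undefined at
#' `p = 1`.
#'
#' @inheritParams pairwiseMLDistance
#' @param kind `"p"` or `"poisson"`.
#' @return distance.
#' @export
correctedDistance <- function(a, b, kind = c("p", "poisson")) {
    kind <- match.arg(kind)
    counts <- .pairCounts(a, b)
    n <- sum(counts)
    if (n == 0L) stop("no shared residue columns; distance undefined")
    p <- 1 - sum(diag(counts)) / n
    if (kind == "p") return(p)
    if (p >= 1) stop("p distance is 1; Poisson correction undefined")
    -log(1 - p)
}

#' Pairwise ML distance matrix for a marker alignment
#'
#' All [pairwiseMLDistance()] values among the sequences of a gap-aware
#' protein alignment; the role mirrors a full-length marker (DNApol)
#' distance matrix.
#'
#' @param msa an [Biostrings::AAStringSet] of aligned sequences (equal
#'   widths, unique names), >= 3 sequences.
#' @param model a [SubstitutionModel-class]; default WAG.
#' @return symmetric labeled distance matrix with zero diagonal.
#' @export
markerDistanceMatrix <- function(msa, model = wagModel()) {
    msa <- Biostrings::AAStringSet(msa)
    n <- length(msa)
    if (n < 3L) stop("need at least 3 sequences")
    if (length(unique(Biostrings::width(msa))) != 1L)
        stop("sequences must be aligned to equal length")
    labs <- names(msa)
    if (is.null(labs) || anyDuplicated(labs))
        stop("sequence names must be unique")
    d <- matrix(0, n, n, dimnames = list(labs, labs))
    chars <- as.character(msa)
    for (i in seq_len(n - 1L))
        for (j in seq.int(i + 1L, n))
            d[i, j] <- d[j, i] <- pairwiseMLDistance(chars[i], chars[j],
                                                     model)
    d
}

#' Extract an amplicon window from a marker alignment
#'
#' Column slice of the alignment emulating the region amplified by marker
#' primers; the default window spans 140 alignment columns.
#'
#' @param msa an [Biostrings::AAStringSet] of aligned sequences.
#' @param start first column (1-based, default 301).
#' @param end last column (inclusive, default 440).
#' @return the sliced [Biostrings::AAStringSet], labels preserved.
#' @export
extractAmplicon <- function(msa, start = 301L, end = 440L) {
    msa <- Biostrings::AAStringSet(msa)
    w <- unique(Biostrings::width(msa))
    if (length(w) != 1L) stop("sequences must be aligned to equal length")
    if (start < 1L || end > w || start > end)
        stop("window [", start, ", ", end, "] out of range for length ", w)
    Biostrings::subseq(msa, start, end)
}
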