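# Independent oracles and small fixture builders used across the suite.

suppressPackageStartupMessages({
    library(Biostrings)
    library(ape)
})

.B62 <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
})

randAASeq <- function(len) {
    aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
    paste(sample(aa, len, replace = TRUE), collapse = "")
}

# Exhaustive global alignment score under affine gaps (gap of length k
# costs open + k * ext, terminal gaps included), by enumerating every
# alignment of two short sequences.
bruteForceScore <- function(a, b, open = 11, ext = 1) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    best <- -Inf
    rec <- function(i, j, cols) {
        if (i > length(ca) && j > length(cb)) {
            sc <- 0
            inGapA <- FALSE; inGapB <- FALSE
            for (cl in cols) {
                if (cl[1] == "-") {
                    sc <- sc - ext - if (!inGapA) open else 0
                    inGapA <- TRUE; inGapB <- FALSE
                } else if (cl[2] == "-") {
                    sc <- sc - ext - if (!inGapB) open else 0
                    inGapB <- TRUE; inGapA <- FALSE
                } else {
                    sc <- sc + .B62[cl[1], cl[2]]
                    inGapA <- FALSE; inGapB <- FALSE
                }
            }
            best <<- max(best, sc)
            return(invisible())
        }
        if (i <= length(ca) && j <= length(cb))
            rec(i + 1, j + 1, c(cols, list(c(ca[i], cb[j]))))
        if (i <= length(ca))
            rec(i + 1, j, c(cols, list(c(ca[i], "-"))))
        if (j <= length(cb))
            rec(i, j + 1, c(cols, list(c("-", cb[j]))))
    }
    rec(1, 1, list())
    best
}

# Column recount of identity from a returned alignment, written against the
# stated definition rather than sharing code with the package.
recountIdentity <- function(sa, sb) {
    ca <- strsplit(sa, "")[[1]]
    cb <- strsplit(sb, "")[[1]]
    gap <- ca == "-" | cb == "-"
    n <- length(ca)
    first <- 1
    while (first <= n && gap[first]) first <- first + 1
    last <- n
    while (last >= first && gap[last]) last <- last - 1
    cols <- seq(first, last)
    sum(ca[cols] == cb[cols] & ca[cols] != "-" & ca[cols] != "X") /
        length(cols)
}

# Independent greedy clustering re-trace from a full identity matrix.
greedyRetrace <- function(seqs, threshold) {
    ids <- names(seqs)
    idm <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_along(ids))
        for (j in seq_along(ids))
            if (i < j)
                idm[i, j] <- idm[j, i] <-
                    PanPhylo::pairwiseIdentity(seqs[[i]], seqs[[j]])
    ord <- ids[order(-width(seqs), ids, method = "radix")]
    centroids <- character(0)
    memb <- character(0)
    for (id in ord) {
        hit <- NA
        for (cen in centroids)
            if (idm[id, cen] >= threshold) { hit <- cen; break }
        if (is.na(hit)) { centroids <- c(centroids, id); hit <- id }
        memb[id] <- hit
    }
    memb
}

adjRandIndex <- function(x, y) mclust::adjustedRandIndex(x, y)

# Additive distance matrix from a random tree (patristic distances).
randomAdditiveMatrix <- function(n) {
    tr <- ape::rtree(n)
    tr$edge.length <- tr$edge.length + 0.05  # keep edges well positive
    list(tree = tr, d = cophenetic(tr))
}

# Two-tip tree with given branch lengths, for single-branch evolution.
twoTipTree <- function(lenA, lenB, labels = c("A", "B")) {
    structure(list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                   edge.length = c(lenA, lenB), Nnode = 1L,
                   tip.label = labels),
              class = "phylo")
}

# Log-likelihood of an aligned pair at distance t, written directly from
# the model definition (used to cross-check the ML optimizer).
pairLogLikOracle <- function(a, b, t, model) {
    ca <- strsplit(as.character(a), "")[[1]]
    cb <- strsplit(as.character(b), "")[[1]]
    P <- probMatrix(model, t)
    pi <- stationaryFreqs(model)
    keep <- ca %in% names(pi) & cb %in% names(pi)
    sum(log(pi[ca[keep]] * P[cbind(ca[keep], cb[keep])]))
}

# Reference panel with strain structure for threshold calibration: a set of
# divergent lineages, each accompanied by two close strains generated by
# short-branch WAG evolution, so amplicon clusters at high stringency pool
# only near-identical full-length sequences.
strainPanel <- function(nLineages = 10, strainTimes = c(0.01, 0.03),
                        seed = 5) {
    cfg <- PanPhylo::simulationConfig(nTaxa = nLineages, seed = seed)
    base <- PanPhylo::simulateTree(nLineages, seed = seed)
    base$edge.length <- base$edge.length * 0.7
    mk <- PanPhylo::evolveMarker(base, cfg, seed = seed)
    model <- PanPhylo::wagModel()
    evolveOne <- function(seq, t) {
        P <- PanPhylo::probMatrix(model, t)
        ch <- strsplit(as.character(seq), "")[[1]]
        idx <- match(ch, rownames(P))
        out <- vapply(idx, function(a)
            sample.int(20, 1, prob = pmax(P[a, ], 0)), integer(1))
        paste(rownames(P)[out], collapse = "")
    }
    set.seed(seed)
    seqs <- as.character(mk)
    for (tip in names(mk))
        for (k in seq_along(strainTimes))
            seqs[paste0(tip, "_s", k)] <- evolveOne(mk[[tip]],
                                                    strainTimes[k])
    refs <- Biostrings::AAStringSet(seqs)
    list(full = PanPhylo::markerDistanceMatrix(refs),
         amplicons = PanPhylo::extractAmplicon(refs))
}
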