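#' Optimal global protein alignment with affine gap costs
#'
#' Needleman-Wunsch/Gotoh global alignment of two amino-acid sequences under
#' BLOSUM62 with affine gap costs (a gap of length k costs
#' `gapOpen + k * gapExtend`). The dynamic programming is delegated to
#' [Biostrings::pairwiseAlignment()]; this wrapper fixes the scoring
#' defaults and returns the aligned strings.
#'
#' @param a,b amino-acid sequences (character or [Biostrings::AAString]);
#'   alphabet: the 20 standard residues plus `X`.
#' @param gapOpen,gapExtend positive gap costs (defaults 11 and 1, the
#'   BLAST protein defaults).
#' @param matrix substitution score matrix (default BLOSUM62).
#' @return list with elements `a`, `b` (gapped aligned strings of equal
#'   length) and `score`.
#' @examples
#' globalAlign("ACDE", "ACE")
#' @export
globalAlign <- function(a, b, gapOpen = 11, gapExtend = 1, matrix = NULL) {
    a <- as.character(a); b <- as.character(b)
    if (length(a) != 1L || length(b) != 1L || nchar(a) < 1L || nchar(b) < 1L)
        stop("both sequences must be single nonempty strings")
    if (is.null(matrix)) matrix <- .blosum62()
    aln <- Biostrings::pairwiseAlignment(
        a, b, type = "global", substitutionMatrix = matrix,
        gapOpening = gapOpen, gapExtension = gapExtend)
    list(a = as.character(Biostrings::alignedPattern(aln)),
         b = as.character(Biostrings::alignedSubject(aln)),
         score = Biostrings::score(aln))
}

#' Count identity over the columns of a gapped aligned pair
#'
#' Identity = identical residue pairs / alignment columns, where columns
#' inside a terminal gap run (a gap run touching either end of the
#' alignment in either sequence) are excluded from the denominator and
#' internal gap columns are included. `X` matches nothing, not even
#' another `X`.
#' @noRd
.identityFromAlignment <- function(sa, sb) {
    ca <- strsplit(sa, "", fixed = TRUE)[[1L]]
    cb <- strsplit(sb, "", fixed = TRUE)[[1L]]
    n <- length(ca)
    gap <- ca == "-" | cb == "-"
    lead <- 0L
    while (lead < n && gap[lead + 1L]) lead <- lead + 1L
    trail <- 0L
    while (trail < n - lead && gap[n - trail]) trail <- trail + 1L
    keep <- seq.int(lead + 1L, n - trail)
    if (length(keep) == 0L) return(NA_real_)
    ident <- sum(ca[keep] == cb[keep] & ca[keep] != "-" & ca[keep] != "X")
    ident / length(keep)
}

#' Fractional amino-acid identity of two sequences
#'
#' Globally aligns the two sequences ([globalAlign()]) and reports the
#' fraction of identical residue pairs over the alignment columns, with
#' terminal-gap columns excluded from the denominator and internal gap
#' columns included (the BLAST-style identity used for gene clustering).
#' `X` never counts as a match.
#'
#' @inheritParams globalAlign
#' @return identity fraction in \[0, 1\].
#' @examples
#' pairwiseIdentity("AAAA", "AAAC") # 0.75
#' @export
pairwiseIdentity <- function(a, b, gapOpen = 11, gapExtend = 1) {
    aln <- globalAlign(a, b, gapOpen = gapOpen, gapExtend = gapExtend)
    .identityFromAlignment(aln$a, aln$b)
}

#' Identities of one query against many subjects in a single call
#' @noRd
.identityToSet <- function(query, subjects) {
    if (length(subjects) == 0L) return(numeric(0))
    aln <- Biostrings::pairwiseAlignment(
        subjects, as.character(query), type = "global",
        substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1)
    pa <- as.character(Biostrings::alignedPattern(aln))
    sa <- as.character(Biostrings::alignedSubject(aln))
    vapply(seq_along(pa), function(i) .identityFromAlignment(pa[i], sa[i]),
           numeric(1))
}
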