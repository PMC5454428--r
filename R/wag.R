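#' Load the WAG substitution model
#'
#' Builds a [SubstitutionModel-class] from the packaged plain-text file of
#' WAG exchangeabilities and stationary frequencies (Whelan & Goldman 2001,
#' PAML layout). The rate matrix `Q[i, j] = s[i, j] * pi[j]` is normalized
#' to one expected substitution per unit time, and its eigendecomposition
#' (via the similarity transform that makes the reversible Q symmetric) is
#' cached for fast transition probabilities.
#'
#' @return a [SubstitutionModel-class].
#' @examples
#' m <- wagModel()
#' rowSums(probMatrix(m, 0.5)) # all 1
#' @export
wagModel <- local({
    cache <- NULL
    function() {
        if (!is.null(cache)) return(cache)
        path <- system.file("extdata", "wag.dat", package = "PanPhylo",
                            mustWork = TRUE)
        ln <- readLines(path)
        ln <- ln[!grepl("^#", ln) & nzchar(trimws(ln))]
        num <- lapply(strsplit(trimws(ln), "[ \t]+"), as.numeric)
        rates <- matrix(0, 20, 20, dimnames = list(.AA20, .AA20))
        for (i in 2:20) rates[i, seq_len(i - 1L)] <- num[[i - 1L]]
        rates <- rates + t(rates)
        freqs <- setNames(num[[20L]], .AA20)
        freqs <- freqs / sum(freqs)
        cache <<- .buildModel("WAG", rates, freqs)
        cache
    }
})

#' Assemble a normalized reversible model and its eigendecomposition
#' @noRd
.buildModel <- function(name, rates, freqs) {
    Q <- rates * rep(freqs, each = nrow(rates))
    diag(Q) <- -rowSums(Q)
    scale <- -sum(freqs * diag(Q))
    Q <- Q / scale
    sq <- sqrt(freqs)
    B <- diag(sq) %*% Q %*% diag(1 / sq)
    B <- (B + t(B)) / 2  # enforce exact symmetry before eigen()
    e <- eigen(B, symmetric = TRUE)
    new("SubstitutionModel", name = name, rates = rates, freqs = freqs,
        Q = Q, eigenValues = e$values, eigenVectors = e$vectors)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param model a [SubstitutionModel-class].
#' @param t nonnegative evolutionary time (expected substitutions per
#'   site).
#' @return 20 x 20 stochastic matrix; `probMatrix(model, 0)` is the
#'   identity.
#' @export
probMatrix <- function(model, t) {
    stopifnot(is(model, "SubstitutionModel"), t >= 0)
    sq <- sqrt(model@freqs)
    U <- model@eigenVectors
    P <- diag(1 / sq) %*% (U %*% (exp(model@eigenValues * t) * t(U))) %*%
        diag(sq)
    dimnames(P) <- dimnames(model@Q)
    P
}

#' Stationary frequencies of a substitution model
#' @param model a [SubstitutionModel-class].
#' @return named numeric vector of 20 frequencies.
#' @export
stationaryFreqs <- function(model) {
    stopifnot(is(model, "SubstitutionModel"))
    model@freqs
}
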