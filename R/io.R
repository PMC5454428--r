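#' Read per-genome protein FASTA files
#'
#' Reads one multi-FASTA of predicted proteins per genome and pools the
#' records, prefixing each record id with its genome label
#' (`"<genome>|<record>"`) so downstream clustering can recover the genome
#' of origin. The genome label defaults to the file stem.
#'
#' @param paths FASTA file paths, one per genome.
#' @param genomeLabels optional labels parallel to `paths`.
#' @return list with `seqs` (pooled [Biostrings::AAStringSet]) and `genome`
#'   (named character vector, record id to genome label).
#' @export
readGenomeFasta <- function(paths, genomeLabels = NULL) {
    if (is.null(genomeLabels))
        genomeLabels <- sub("\\.[^.]*$", "", basename(paths))
    if (length(genomeLabels) != length(paths) ||
        anyDuplicated(genomeLabels))
        stop("genome labels must be unique and match the number of files")
    sets <- lapply(seq_along(paths), function(i) {
        s <- Biostrings::readAAStringSet(paths[i])
        names(s) <- paste0(genomeLabels[i], "|",
                           sub("\\s.*$", "", names(s)))
        s
    })
    seqs <- do.call(c, sets)
    if (anyDuplicated(names(seqs)))
        stop("duplicated record ids after labeling")
    genome <- setNames(rep(genomeLabels,
                           vapply(sets, length, integer(1))), names(seqs))
    list(seqs = seqs, genome = genome)
}
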