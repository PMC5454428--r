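#' Configuration for the genome / marker / amplicon simulator
#'
#' Bundles the parameters of the synthetic study system: the number of
#' taxa, the ancestral gene-family count, per-unit-branch-length loss and
#' gain rates, the fraction of gains that are horizontal transfers from a
#' contemporaneous lineage, the marker gene length and amplicon window,
#' and the sequence identity structure of gene families.
#'
#' @param nTaxa number of genomes (>= 3).
#' @param rootFamilyCount ancestral gene-family count G0 at the root.
#' @param lossRate per-unit-branch-length loss rate mu (>= 0).
#' @param gainRate per-unit-branch-length gain rate lambda (>= 0).
#' @param hgtFraction proportion of gains copied from another extant
#'   lineage, in \[0, 1\]; the rest are novel families.
#' @param markerLength marker gene length in residues (default 900).
#' @param ampliconWindow 1-based inclusive column interval of the amplicon
#'   within the marker (default `c(301, 440)`, 140 residues).
#' @param withinFamilyIdentity target fractional identity among orthologs
#'   of one family (default 0.8).
#' @param betweenFamilyIdentityMax upper bound on identity between
#'   distinct families (default 0.3); must stay below the clustering
#'   threshold while `withinFamilyIdentity` stays above it.
#' @param seed default RNG seed used by the simulator operations.
#' @return a validated list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(nTaxa = 12L, rootFamilyCount = 150L,
                             lossRate = 0.3, gainRate = 0.3,
                             hgtFraction = 0.2, markerLength = 900L,
                             ampliconWindow = c(301L, 440L),
                             withinFamilyIdentity = 0.8,
                             betweenFamilyIdentityMax = 0.3,
                             seed = 1L) {
    cfg <- list(nTaxa = as.integer(nTaxa),
                rootFamilyCount = as.integer(rootFamilyCount),
                lossRate = lossRate, gainRate = gainRate,
                hgtFraction = hgtFraction,
                markerLength = as.integer(markerLength),
                ampliconWindow = as.integer(ampliconWindow),
                withinFamilyIdentity = withinFamilyIdentity,
                betweenFamilyIdentityMax = betweenFamilyIdentityMax,
                seed = as.integer(seed))
    if (cfg$nTaxa < 3L) stop("nTaxa must be >= 3")
    if (cfg$rootFamilyCount < 1L) stop("rootFamilyCount must be >= 1")
    if (cfg$lossRate < 0 || cfg$gainRate < 0) stop("rates must be >= 0")
    if (cfg$hgtFraction < 0 || cfg$hgtFraction > 1)
        stop("hgtFraction must be in [0, 1]")
    if (cfg$markerLength < 1L) stop("markerLength must be >= 1")
    if (length(cfg$ampliconWindow) != 2L ||
        cfg$ampliconWindow[1L] < 1L ||
        cfg$ampliconWindow[2L] > cfg$markerLength ||
        cfg$ampliconWindow[1L] > cfg$ampliconWindow[2L])
        stop("ampliconWindow must lie within [1, markerLength]")
    if (!(cfg$withinFamilyIdentity > 0.5 &&
          0.5 > cfg$betweenFamilyIdentityMax))
        stop("need withinFamilyIdentity > 0.5 > betweenFamilyIdentityMax")
    class(cfg) <- "SimulationConfig"
    cfg
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat("SimulationConfig:", x$nTaxa, "taxa, G0 =", x$rootFamilyCount,
        sprintf("; loss %.3g, gain %.3g, hgt %.3g", x$lossRate, x$gainRate,
                x$hgtFraction), "\n")
    cat("  marker", x$markerLength, "aa, amplicon columns",
        x$ampliconWindow[1L], "-", x$ampliconWindow[2L],
        sprintf("; identity within %.2f / between <= %.2f\n",
                x$withinFamilyIdentity, x$betweenFamilyIdentityMax))
    invisible(x)
}

#' Simulate an ultrametric species tree
#'
#' Pure-birth (Yule) tree with unit birth rate, branch lengths rescaled so
#' the tree height (root-to-leaf distance) is exactly 1. Deterministic for
#' a given seed.
#'
#' @param nTaxa number of leaves (>= 3).
#' @param seed RNG seed.
#' @return an ultrametric `phylo` tree of height 1 with tip labels
#'   `t1..tn`.
#' @export
simulateTree <- function(nTaxa, seed = NULL) {
    nTaxa <- as.integer(nTaxa)
    if (is.na(nTaxa) || nTaxa < 3L) stop("nTaxa must be >= 3")
    tr <- .withSeed(seed, ape::rphylo(nTaxa, birth = 1, death = 0))
    h <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / h
    tr
}

#' Substitute a fraction of residues, drawing replacements from the
#' model's stationary frequencies excluding the current residue.
#' @noRd
.mutateToIdentity <- function(chars, targetIdentity, freqs) {
    hit <- runif(length(chars)) > targetIdentity
    for (i in which(hit)) {
        p <- freqs
        p[chars[i]] <- 0
        chars[i] <- sample(names(p), 1L, prob = p)
    }
    chars
}

#' Evolve gene content along a tree by loss, gain, and transfer
#'
#' The root lineage carries `rootFamilyCount` ancestral families. Along
#' each branch of length `t`, every present family is lost independently
#' with probability `1 - exp(-lossRate * t)`, and `Poisson(gainRate * t)`
#' families are gained; each gain is a novel family with probability
#' `1 - hgtFraction`, otherwise it is copied from a uniformly chosen other
#' branch spanning the (uniform) event time, taking that donor branch's
#' starting repertoire. Leaf repertoires are returned as an incidence
#' matrix over the families observed in at least one leaf.
#'
#' @param tree a `phylo` tree, typically from [simulateTree()].
#' @param cfg a [simulationConfig()].
#' @param seed RNG seed (default `cfg$seed`).
#' @return list with `pa` (a [PresenceAbsenceMatrix-class]) and `truth`, a
#'   list of class `"TruthBundle"` with the tree, per-leaf family sets,
#'   family origins (`ancestral` / `gain` / `hgt`), HGT donors, and the
#'   per-node family sets needed to replay the history.
#' @export
evolveGeneContent <- function(tree, cfg, seed = cfg$seed) {
    stopifnot(inherits(tree, "phylo"), inherits(cfg, "SimulationConfig"))
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    tree <- stats::reorder(tree, "cladewise")  # parents before children
    depth <- ape::node.depth.edgelength(tree)

    .withSeed(seed, {
        fam <- vector("list", ntip + tree$Nnode)
        fam[[root]] <- paste0("F", seq_len(cfg$rootFamilyCount))
        origin <- setNames(rep("ancestral", cfg$rootFamilyCount),
                           fam[[root]])
        donorOf <- character(0)
        hgtEvents <- list()
        counter <- cfg$rootFamilyCount
        edges <- tree$edge
        for (k in seq_len(nrow(edges))) {
            par <- edges[k, 1L]; child <- edges[k, 2L]
            t <- tree$edge.length[k]
            inherited <- fam[[par]]
            kept <- inherited[runif(length(inherited)) < exp(-cfg$lossRate * t)]
            gained <- character(0)
            nGain <- rpois(1L, cfg$gainRate * t)
            for (g in seq_len(nGain)) {
                u <- runif(1L, depth[par], depth[child])
                asHgt <- runif(1L) < cfg$hgtFraction
                newFam <- NULL
                if (asHgt) {
                    # branches spanning the event time, other than this one
                    live <- setdiff(which(depth[edges[, 1L]] <= u &
                                          depth[edges[, 2L]] > u), k)
                    if (length(live)) {
                        dk <- live[sample.int(length(live), 1L)]
                        pool <- fam[[edges[dk, 1L]]]
                        if (length(pool)) {
                            newFam <- pool[sample.int(length(pool), 1L)]
                            if (!newFam %in% names(donorOf))
                                donorOf[newFam] <-
                                    as.character(edges[dk, 2L])
                            hgtEvents[[length(hgtEvents) + 1L]] <-
                                data.frame(family = newFam,
                                           donor = edges[dk, 2L],
                                           recipient = child, time = u)
                        }
                    }
                }
                if (is.null(newFam)) {
                    # novel family (also the fallback when no donor carries
                    # any family at the event time)
                    counter <- counter + 1L
                    newFam <- paste0("F", counter)
                    origin[newFam] <- "gain"
                }
                gained <- c(gained, newFam)
            }
            fam[[child]] <- union(kept, gained)
        }
        leafFam <- setNames(fam[seq_len(ntip)], tree$tip.label)
        observed <- sort(unique(unlist(leafFam)))
        inc <- matrix(FALSE, ntip, length(observed),
                      dimnames = list(tree$tip.label, observed))
        for (g in tree$tip.label) inc[g, leafFam[[g]]] <- TRUE
        truth <- structure(list(tree = tree, familyMembership = leafFam,
                                familyOrigin = origin, hgtDonor = donorOf,
                                hgtEvents = if (length(hgtEvents))
                                    do.call(rbind, hgtEvents)
                                else data.frame(family = character(0),
                                                donor = integer(0),
                                                recipient = integer(0),
                                                time = numeric(0)),
                                nodeFamilies = fam),
                           class = "TruthBundle")
        list(pa = new("PresenceAbsenceMatrix", incidence = inc),
             truth = truth)
    })
}

#' Evolve a gap-free marker-gene protein alignment along a tree
#'
#' The root sequence is drawn from the model's stationary frequencies and
#' every site evolves independently along each branch by sampling from the
#' transition matrix `P(t) = exp(Qt)`. No indels, so the leaves form a
#' gap-free alignment of `cfg$markerLength` columns.
#'
#' @inheritParams evolveGeneContent
#' @param model a [SubstitutionModel-class]; default WAG.
#' @return an [Biostrings::AAStringSet] of aligned leaf sequences, named by
#'   tip label.
#' @export
evolveMarker <- function(tree, cfg, model = wagModel(), seed = cfg$seed) {
    stopifnot(inherits(tree, "phylo"), inherits(cfg, "SimulationConfig"))
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    tree <- stats::reorder(tree, "cladewise")
    L <- cfg$markerLength
    freqs <- model@freqs
    .withSeed(seed, {
        states <- matrix(NA_integer_, ntip + tree$Nnode, L)
        states[root, ] <- sample.int(20L, L, replace = TRUE, prob = freqs)
        for (k in seq_len(nrow(tree$edge))) {
            par <- tree$edge[k, 1L]; child <- tree$edge[k, 2L]
            P <- probMatrix(model, tree$edge.length[k])
            parent <- states[par, ]
            out <- integer(L)
            for (a in unique(parent)) {
                idx <- which(parent == a)
                out[idx] <- sample.int(20L, length(idx), replace = TRUE,
                                       prob = pmax(P[a, ], 0))
            }
            states[child, ] <- out
        }
        seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1L,
                      function(s) paste(.AA20[s], collapse = ""))
        Biostrings::AAStringSet(setNames(seqs, tree$tip.label))
    })
}

#' Emit mutated protein sequences for simulated gene families
#'
#' Every family receives a random prototype sequence (length uniform in
#' \[65, 800\] residues, residues drawn from the model's stationary
#' frequencies); each genome carrying the family receives an independently
#' mutated copy at approximately `withinFamilyIdentity` fractional identity
#' to the prototype. Distinct families are unrelated random sequences, so
#' their pairwise identity stays far below the clustering threshold.
#'
#' @param pa a [PresenceAbsenceMatrix-class] from [evolveGeneContent()].
#' @param cfg a [simulationConfig()].
#' @param seed RNG seed (default `cfg$seed`).
#' @param lengthRange inclusive range of prototype lengths (default
#'   `c(65, 800)`, honoring the 65-residue minimum ORF length of the
#'   annotation pipeline being emulated).
#' @param model a [SubstitutionModel-class] supplying residue frequencies.
#' @return list with `seqs` (an [Biostrings::AAStringSet]; record ids are
#'   `"<genome>|<family>"`), `genome` and `family` (named character vectors
#'   mapping record id to its genome and true family).
#' @export
emitFamilySequences <- function(pa, cfg, seed = cfg$seed,
                                lengthRange = c(65L, 800L),
                                model = wagModel()) {
    stopifnot(is(pa, "PresenceAbsenceMatrix"),
              inherits(cfg, "SimulationConfig"))
    inc <- pa@incidence
    freqs <- model@freqs
    .withSeed(seed, {
        ids <- character(0); seqs <- character(0)
        genome <- character(0); family <- character(0)
        for (f in colnames(inc)) {
            len <- sample(seq.int(lengthRange[1L], lengthRange[2L]), 1L)
            proto <- sample(names(freqs), len, replace = TRUE, prob = freqs)
            for (g in rownames(inc)[inc[, f]]) {
                copy <- .mutateToIdentity(proto, cfg$withinFamilyIdentity,
                                          freqs)
                id <- paste0(g, "|", f)
                ids <- c(ids, id)
                seqs <- c(seqs, paste(copy, collapse = ""))
                genome <- c(genome, g)
                family <- c(family, f)
            }
        }
        list(seqs = Biostrings::AAStringSet(setNames(seqs, ids)),
             genome = setNames(genome, ids),
             family = setNames(family, ids))
    })
}

#' Simulate environmental amplicon samples with known OTU truth
#'
#' Builds a lineage pool from the reference marker sequences plus
#' `nNovel` novel lineages (a reference mutated to a uniform 85-95%
#' identity). Each sample draws lineage abundances from a log-normal
#' distribution, allocates `readsPerSample` reads multinomially, and emits
#' each read as the amplicon window of its lineage with independent
#' per-residue substitution noise.
#'
#' @param references an [Biostrings::AAStringSet] of full-length marker
#'   sequences (e.g. from [evolveMarker()]), nonempty, named.
#' @param cfg a [simulationConfig()] (supplies the amplicon window).
#' @param nSamples number of samples.
#' @param readsPerSample reads per sample (>= 1).
#' @param nNovel number of novel lineages (default: half the references).
#' @param noiseRate per-residue substitution probability of a read
#'   (default 0.005; keep <= 0.01).
#' @param seed RNG seed (default `cfg$seed`).
#' @param model a [SubstitutionModel-class] supplying residue frequencies.
#' @return list with `samples` (named list of per-sample read
#'   [Biostrings::AAStringSet]s; read ids are `"<sample>|r<k>"`),
#'   `lineages` (amplicon sequences of all lineages; novel lineages named
#'   `"novel<i>|<source>"`), and `truth` (an [OTUTable-class] of true
#'   per-sample lineage counts).
#' @export
simulateEnvironmentalSamples <- function(references, cfg, nSamples,
                                         readsPerSample,
                                         nNovel = NULL, noiseRate = 0.005,
                                         seed = cfg$seed,
                                         model = wagModel()) {
    references <- Biostrings::AAStringSet(references)
    if (length(references) == 0L) stop("references must be nonempty")
    readsPerSample <- as.integer(readsPerSample)
    if (is.na(readsPerSample) || readsPerSample < 1L)
        stop("readsPerSample must be >= 1")
    nSamples <- as.integer(nSamples)
    if (is.na(nSamples) || nSamples < 1L) stop("nSamples must be >= 1")
    if (is.null(nNovel)) nNovel <- length(references) %/% 2L
    freqs <- model@freqs
    win <- cfg$ampliconWindow

    .withSeed(seed, {
        lineages <- as.character(references)
        names(lineages) <- names(references)
        for (i in seq_len(nNovel)) {
            src <- sample(names(references), 1L)
            chars <- strsplit(lineages[[src]], "", fixed = TRUE)[[1L]]
            target <- runif(1L, 0.85, 0.95)
            chars <- .mutateToIdentity(chars, target, freqs)
            lineages[paste0("novel", i, "|", src)] <-
                paste(chars, collapse = "")
        }
        amp <- substr(lineages, win[1L], win[2L])
        nl <- length(amp)
        counts <- matrix(0L, nSamples, nl,
                         dimnames = list(paste0("S", seq_len(nSamples)),
                                         names(amp)))
        samples <- vector("list", nSamples)
        names(samples) <- rownames(counts)
        for (s in seq_len(nSamples)) {
            ab <- rlnorm(nl, meanlog = 0, sdlog = 1)
            cnt <- as.integer(rmultinom(1L, readsPerSample, prob = ab))
            counts[s, ] <- cnt
            lineageOfRead <- rep(seq_len(nl), cnt)
            reads <- vapply(lineageOfRead, function(li) {
                chars <- strsplit(amp[[li]], "", fixed = TRUE)[[1L]]
                if (noiseRate > 0)
                    chars <- .mutateToIdentity(chars, 1 - noiseRate, freqs)
                paste(chars, collapse = "")
            }, character(1))
            ids <- paste0(rownames(counts)[s], "|r", seq_along(reads))
            samples[[s]] <- Biostrings::AAStringSet(setNames(reads, ids))
        }
        truth <- new("OTUTable", counts = counts, rarefied = FALSE,
                     depth = NA_integer_,
                     referenceOtus = names(references),
                     unassigned = setNames(integer(nSamples),
                                           rownames(counts)))
        list(samples = samples,
             lineages = Biostrings::AAStringSet(amp),
             truth = truth)
    })
}

#' Write simulated genomes, marker, amplicons, and truth tables to disk
#'
#' Convenience exporter for the simulator outputs: per-genome protein
#' FASTA, the marker alignment, per-sample amplicon FASTA, the true tree
#' (Newick), and tab-separated truth tables.
#'
#' @param dir output directory (created if needed).
#' @param famSeqs result of [emitFamilySequences()].
#' @param marker result of [evolveMarker()] (optional).
#' @param env result of [simulateEnvironmentalSamples()] (optional).
#' @param truth a `TruthBundle` from [evolveGeneContent()] (optional).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(dir, famSeqs, marker = NULL, env = NULL,
                            truth = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (g in unique(famSeqs$genome)) {
        sel <- famSeqs$genome == g
        Biostrings::writeXStringSet(famSeqs$seqs[names(which(sel))],
                                    file.path(dir, paste0(g, ".faa")))
    }
    utils::write.table(
        data.frame(genome = famSeqs$genome, family = famSeqs$family),
        file.path(dir, "family_membership.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(marker))
        Biostrings::writeXStringSet(marker, file.path(dir, "marker.faa"))
    if (!is.null(env)) {
        dir.create(file.path(dir, "samples"), showWarnings = FALSE)
        for (s in names(env$samples))
            Biostrings::writeXStringSet(
                env$samples[[s]],
                file.path(dir, "samples", paste0(s, ".faa")))
        cnt <- otuCounts(env$truth)
        long <- data.frame(sample = rep(rownames(cnt), ncol(cnt)),
                           otu = rep(colnames(cnt), each = nrow(cnt)),
                           count = as.vector(cnt))
        utils::write.table(long[long$count > 0, ],
                           file.path(dir, "otu_truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(truth))
        ape::write.tree(truth$tree, file.path(dir, "true_tree.nwk"))
    invisible(dir)
}
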