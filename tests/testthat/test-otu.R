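# small deterministic lineage panel for OTU tests
otuFixture <- function(nRefs = 4, nSamples = 3, readsPerSample = 40,
                       noiseRate = 0, nNovel = 2, seed = 14) {
    cfg <- simulationConfig(nTaxa = nRefs, markerLength = 500,
                            ampliconWindow = c(101L, 240L), seed = seed)
    tr <- simulateTree(nRefs, seed = seed)
    mk <- evolveMarker(tr, cfg)
    env <- simulateEnvironmentalSamples(mk, cfg, nSamples, readsPerSample,
                                        nNovel = nNovel,
                                        noiseRate = noiseRate, seed = seed)
    list(cfg = cfg, refs = extractAmplicon(mk, 101, 240), env = env)
}

test_that("references seed the first centroids and capture matching reads", {
    fx <- otuFixture()
    oc <- otuCluster(fx$env$samples, references = fx$refs)
    expect_s4_class(oc, "GeneClusterSet")
    expect_identical(clusterIds(oc)[seq_along(fx$refs)], names(fx$refs))
    # noise-free reads from reference lineages join reference clusters
    truth <- otuCounts(fx$env$truth)
    refCols <- intersect(colnames(truth), names(fx$refs))
    sz <- clusterSizes(oc)
    for (r in refCols)
        expect_equal(unname(sz[r]), sum(truth[, r]) + 1L)  # + the ref itself
})

test_that("single lineage with zero noise collapses to one OTU", {
    fx <- otuFixture(nRefs = 3, nNovel = 0, readsPerSample = 15)
    oneRef <- fx$refs[1]
    reads <- Biostrings::AAStringSet(
        setNames(rep(as.character(oneRef), 20), paste0("S1|r", 1:20)))
    oc <- otuCluster(reads, references = oneRef)
    expect_equal(length(oc), 1L)
    # a near-zero threshold pools every read with a single seeded reference
    ocAll <- otuCluster(fx$env$samples, references = fx$refs[1],
                        threshold = 0.01)
    expect_equal(length(ocAll), 1L)
})

test_that("singleton discard removes exactly the size-1 clusters", {
    fx <- otuFixture(readsPerSample = 30)
    oc <- otuCluster(fx$env$samples, references = fx$refs)
    sz <- clusterSizes(oc)
    surv <- discardSingletons(oc)
    expect_setequal(clusterIds(surv), names(sz)[sz >= 2])
    expect_true(all(clusterSizes(surv) >= 2))
    withRefs <- discardSingletons(oc, keepReferences = TRUE)
    expect_true(all(names(fx$refs) %in% clusterIds(withRefs)))
    # planted singleton: a read unlike anything else vanishes downstream
    set.seed(99)
    lone <- Biostrings::AAStringSet(setNames(randAASeq(140), "S1|lone"))
    reads2 <- c(fx$env$samples$S1, lone)
    oc2 <- otuCluster(reads2, references = fx$refs)
    expect_true("S1|lone" %in% clusterIds(oc2))
    expect_false("S1|lone" %in% clusterIds(discardSingletons(oc2)))
})

test_that("read assignment honors threshold, ties, and truth", {
    fx <- otuFixture()
    oc <- otuCluster(fx$env$samples, references = fx$refs)
    tab <- assignReads(fx$env$samples, oc)
    expect_s4_class(tab, "OTUTable")
    truth <- otuCounts(fx$env$truth)
    shared <- intersect(colnames(truth), colnames(otuCounts(tab)))
    expect_gt(length(shared), 0)
    expect_equal(otuCounts(tab)[rownames(truth), names(fx$refs)],
                 truth[, names(fx$refs)])
    expect_true(all(tab@unassigned == 0L))
    # reads below the threshold to every centroid stay unassigned
    set.seed(77)
    junk <- Biostrings::AAStringSet(setNames(
        vapply(1:3, function(i) randAASeq(140), character(1)),
        paste0("S9|j", 1:3)))
    tab2 <- assignReads(junk, centroidSeqs(oc), samples = rep("S9", 3))
    expect_equal(unname(tab2@unassigned["S9"]), 3L)
    expect_equal(sum(otuCounts(tab2)), 0L)
})

test_that("reads trimmed to 129 residues still assign to their source", {
    fx <- otuFixture(readsPerSample = 20, noiseRate = 0)
    trimmed <- lapply(fx$env$samples, function(s)
        Biostrings::subseq(s, 1, 129))
    tab <- assignReads(trimmed, fx$refs, threshold = 0.97)
    truth <- otuCounts(fx$env$truth)
    expect_equal(otuCounts(tab)[rownames(truth), names(fx$refs)],
                 truth[, names(fx$refs)])
})

test_that("rarefaction conserves row sums and the hypergeometric mean", {
    cnt <- matrix(c(30L, 10L, 0L,
                    5L, 4L, 1L,
                    12L, 0L, 8L), 3, 3, byrow = TRUE,
                  dimnames = list(paste0("S", 1:3), paste0("o", 1:3)))
    tab <- new("OTUTable", counts = cnt, rarefied = FALSE,
               depth = NA_integer_, referenceOtus = character(0),
               unassigned = setNames(integer(3), rownames(cnt)))
    r <- rarefyTable(tab, seed = 1)
    expect_true(isRarefied(r))
    expect_equal(rarefactionDepth(r), 10L)
    expect_equal(unname(rowSums(otuCounts(r))), rep(10, 3))
    # already-even depths pass through unchanged
    even <- new("OTUTable", counts = matrix(c(3L, 7L, 6L, 4L), 2, 2,
                    byrow = TRUE,
                    dimnames = list(c("a", "b"), c("x", "y"))),
                rarefied = FALSE, depth = NA_integer_,
                referenceOtus = character(0),
                unassigned = setNames(integer(2), c("a", "b")))
    re <- rarefyTable(even, seed = 5)
    expect_identical(otuCounts(re), otuCounts(even))
    # determinism and expectation depth * count / total
    expect_identical(otuCounts(rarefyTable(tab, seed = 3)),
                     otuCounts(rarefyTable(tab, seed = 3)))
    draws <- vapply(1:400, function(s)
        otuCounts(rarefyTable(tab, seed = s))["S1", "o1"], numeric(1))
    expZ <- 10 * 30 / 40
    # hypergeometric variance n*p*(1-p)*(N-n)/(N-1)
    v <- 10 * 0.75 * 0.25 * (40 - 10) / 39
    expect_lt(abs(mean(draws) - expZ), 3 * sqrt(v / 400))
    zero <- new("OTUTable", counts = matrix(c(0L, 0L, 3L, 2L), 2, 2,
                    byrow = TRUE,
                    dimnames = list(c("a", "b"), c("x", "y"))),
                rarefied = FALSE, depth = NA_integer_,
                referenceOtus = character(0),
                unassigned = setNames(integer(2), c("a", "b")))
    expect_error(rarefyTable(zero), "zero reads")
})

test_that("dominant OTU extraction matches a full-sort oracle", {
    set.seed(44)
    cnt <- matrix(as.integer(rpois(15, 4)), 3, 5,
                  dimnames = list(paste0("S", 1:3), paste0("o", 1:5)))
    tab <- new("OTUTable", counts = cnt, rarefied = FALSE,
               depth = NA_integer_, referenceOtus = character(0),
               unassigned = setNames(integer(3), rownames(cnt)))
    for (k in c(1, 3, 10)) {
        got <- dominantOtus(tab, k)
        for (s in rownames(cnt)) {
            v <- cnt[s, ]
            nz <- names(v)[v > 0]
            oracle <- nz[order(-v[nz], match(nz, colnames(cnt)))]
            expect_identical(got[[s]], utils::head(oracle, k))
        }
    }
    expect_error(dominantOtus(tab, 0), "topK")
})

test_that("known mixture richness is recovered after singleton discard", {
    fx <- otuFixture(nRefs = 6, nSamples = 2, readsPerSample = 250,
                     nNovel = 4, noiseRate = 0.005, seed = 23)
    trueRich <- sum(colSums(otuCounts(fx$env$truth)) >= 2)
    oc <- otuCluster(fx$env$samples, references = fx$refs)
    surv <- discardSingletons(oc)
    expect_equal(length(surv), trueRich)
})
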