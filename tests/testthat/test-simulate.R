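test_that("simulation config validates its invariants", {
    cfg <- simulationConfig()
    expect_s3_class(cfg, "SimulationConfig")
    expect_equal(cfg$markerLength, 900L)
    expect_equal(diff(cfg$ampliconWindow) + 1L, 140L)
    expect_error(simulationConfig(nTaxa = 2), "nTaxa")
    expect_error(simulationConfig(lossRate = -1), "rates")
    expect_error(simulationConfig(hgtFraction = 1.5), "hgtFraction")
    expect_error(simulationConfig(ampliconWindow = c(800, 950)),
                 "ampliconWindow")
    expect_error(simulationConfig(withinFamilyIdentity = 0.4), "0.5")
})

test_that("simulated trees are ultrametric with height 1, seeded", {
    tr3 <- simulateTree(3, seed = 1)
    expect_equal(ape::Ntip(tr3), 3L)
    expect_equal(tr3$Nnode, 2L)        # one internal edge once unrooted
    expect_identical(ape::write.tree(simulateTree(12, seed = 1)),
                     ape::write.tree(simulateTree(12, seed = 1)))
    tr <- simulateTree(50, seed = 3)
    depths <- ape::node.depth.edgelength(tr)[seq_len(50)]
    expect_equal(mean(depths), 1, tolerance = 1e-9)
    expect_equal(max(abs(depths - 1)), 0, tolerance = 1e-9)
})

test_that("no gain and no loss reproduces the root repertoire everywhere", {
    cfg <- simulationConfig(nTaxa = 6, rootFamilyCount = 40, lossRate = 0,
                            gainRate = 0, seed = 2)
    tr <- simulateTree(6, seed = 2)
    res <- evolveGeneContent(tr, cfg)
    inc <- incidence(res$pa)
    expect_equal(ncol(inc), 40L)
    expect_true(all(inc))
    d <- paDistanceMatrix(res$pa)
    expect_true(all(d == 0))
    expect_true(all(res$truth$familyOrigin == "ancestral"))
})

test_that("pure-loss leaf counts match the analytic expectation", {
    cfg <- simulationConfig(nTaxa = 5, rootFamilyCount = 100, lossRate = 1,
                            gainRate = 0, seed = 1)
    tr <- simulateTree(5, seed = 10)
    leaf <- tr$tip.label[1]
    counts <- vapply(seq_len(200), function(i) {
        res <- evolveGeneContent(tr, cfg, seed = 1000 + i)
        length(res$truth$familyMembership[[leaf]])
    }, numeric(1))
    p <- exp(-1)                       # root-to-leaf distance is 1
    se <- sqrt(100 * p * (1 - p)) / sqrt(200)
    expect_lt(abs(mean(counts) - 100 * p), 3 * se)
})

test_that("transfer events replay against donor lineage histories", {
    cfg <- simulationConfig(nTaxa = 10, rootFamilyCount = 30,
                            lossRate = 0.1, gainRate = 2, hgtFraction = 1,
                            seed = 7)
    tr <- simulateTree(10, seed = 7)
    res <- evolveGeneContent(tr, cfg)
    ev <- res$truth$hgtEvents
    expect_gt(nrow(ev), 0)
    # every transferred family is carried by the donor branch's start node
    tre <- stats::reorder(tr, "cladewise")
    parentOf <- setNames(tre$edge[, 1], tre$edge[, 2])
    for (k in seq_len(nrow(ev)))
        expect_true(ev$family[k] %in%
                        res$truth$nodeFamilies[[parentOf[[as.character(
                            ev$donor[k])]]]])
    # with hgtFraction = 1 no novel families arise beyond fallbacks
    expect_true(all(res$truth$familyOrigin %in% c("ancestral", "gain")))
    # families at leaves that are not ancestral entered through transfers
    gained <- setdiff(unique(unlist(res$truth$familyMembership)),
                      paste0("F", seq_len(cfg$rootFamilyCount)))
    expect_true(all(gained %in% c(ev$family,
                                  names(res$truth$familyOrigin)[
                                      res$truth$familyOrigin == "gain"])))
})

test_that("gene content evolution is deterministic given a seed", {
    cfg <- simulationConfig(nTaxa = 6, rootFamilyCount = 20, seed = 5)
    tr <- simulateTree(6, seed = 5)
    a <- evolveGeneContent(tr, cfg)
    b <- evolveGeneContent(tr, cfg)
    expect_identical(incidence(a$pa), incidence(b$pa))
    m1 <- evolveMarker(tr, cfg)
    m2 <- evolveMarker(tr, cfg)
    expect_identical(as.character(m1), as.character(m2))
})

test_that("zero-length branches copy the parent marker sequence", {
    cfg <- simulationConfig(nTaxa = 3, markerLength = 200,
                            ampliconWindow = c(11L, 110L), seed = 3)
    tr <- twoTipTree(0, 0)
    msa <- evolveMarker(tr, cfg, seed = 3)
    expect_identical(as.character(msa[["A"]]), as.character(msa[["B"]]))
})

test_that("family sequences honor the identity structure", {
    cfg <- simulationConfig(nTaxa = 4, rootFamilyCount = 8, lossRate = 0,
                            gainRate = 0, withinFamilyIdentity = 1.0,
                            seed = 11)
    tr <- simulateTree(4, seed = 11)
    pa <- evolveGeneContent(tr, cfg)$pa
    fs <- emitFamilySequences(pa, cfg)
    for (f in unique(fs$family)) {
        copies <- as.character(fs$seqs[names(fs$family)[fs$family == f]])
        expect_equal(length(unique(copies)), 1L)
    }
    # distinct families stay far below the clustering threshold
    cfg2 <- simulationConfig(nTaxa = 4, rootFamilyCount = 8, lossRate = 0,
                             gainRate = 0, seed = 12)
    fs2 <- emitFamilySequences(pa, cfg2)
    set.seed(30)
    prot <- vapply(unique(fs2$family), function(f)
        as.character(fs2$seqs[[names(fs2$family)[fs2$family == f][1]]]),
        character(1))
    pairs <- utils::combn(length(prot), 2)
    sel <- pairs[, sample(ncol(pairs), 12)]
    ids <- vapply(seq_len(ncol(sel)), function(k)
        pairwiseIdentity(prot[sel[1, k]], prot[sel[2, k]]), numeric(1))
    expect_true(all(ids <= 0.3))
    # within-family copies straddle the threshold from above
    f1 <- unique(fs2$family)[1]
    copies <- fs2$seqs[names(fs2$family)[fs2$family == f1]]
    expect_gt(pairwiseIdentity(copies[[1]], copies[[2]]), 0.5)
})

test_that("clustering emitted sequences recovers the true families", {
    cfg <- simulationConfig(nTaxa = 3, rootFamilyCount = 8, lossRate = 0.3,
                            gainRate = 0.5, seed = 21)
    tr <- simulateTree(3, seed = 21)
    res <- evolveGeneContent(tr, cfg)
    fs <- emitFamilySequences(res$pa, cfg)
    cl <- greedyCluster(fs$seqs, fs$genome, threshold = 0.5)
    expect_equal(adjRandIndex(memberMap(cl)[names(fs$family)], fs$family),
                 1)
    pa2 <- buildPresenceAbsence(cl)
    expect_equal(unname(geneCounts(pa2)[sampleIds(res$pa)]),
                 unname(geneCounts(res$pa)))
})

test_that("environmental samples carry coherent truth tables", {
    cfg <- simulationConfig(nTaxa = 5, markerLength = 600,
                            ampliconWindow = c(201L, 340L), seed = 9)
    tr <- simulateTree(5, seed = 9)
    mk <- evolveMarker(tr, cfg)
    env <- simulateEnvironmentalSamples(mk, cfg, nSamples = 4,
                                        readsPerSample = 50, nNovel = 2,
                                        noiseRate = 0, seed = 9)
    expect_equal(length(env$samples), 4L)
    expect_true(all(vapply(env$samples, length, integer(1)) == 50L))
    expect_equal(unname(rowSums(otuCounts(env$truth))), rep(50, 4))
    expect_equal(unique(Biostrings::width(env$lineages)), 140L)
    # noise-free reads are exact copies of their lineage amplicon
    expect_true(all(as.character(env$samples[[1]]) %in%
                        as.character(env$lineages)))
    # determinism
    env2 <- simulateEnvironmentalSamples(mk, cfg, nSamples = 4,
                                         readsPerSample = 50, nNovel = 2,
                                         noiseRate = 0, seed = 9)
    expect_identical(otuCounts(env$truth), otuCounts(env2$truth))
    expect_error(simulateEnvironmentalSamples(mk, cfg, 2, 0), ">= 1")
})

test_that("simulation outputs write to plain-text files", {
    cfg <- simulationConfig(nTaxa = 3, rootFamilyCount = 5, lossRate = 0,
                            gainRate = 0, markerLength = 150,
                            ampliconWindow = c(11L, 110L), seed = 2)
    tr <- simulateTree(3, seed = 2)
    res <- evolveGeneContent(tr, cfg)
    fs <- emitFamilySequences(res$pa, cfg, lengthRange = c(65L, 120L))
    mk <- evolveMarker(tr, cfg)
    env <- simulateEnvironmentalSamples(mk, cfg, 2, 10, nNovel = 1,
                                        seed = 2)
    dir <- tempfile("sim")
    writeSimulation(dir, fs, marker = mk, env = env, truth = res$truth)
    expect_true(file.exists(file.path(dir, "t1.faa")))
    expect_true(file.exists(file.path(dir, "marker.faa")))
    expect_true(file.exists(file.path(dir, "true_tree.nwk")))
    expect_true(file.exists(file.path(dir, "samples", "S1.faa")))
    rd <- readGenomeFasta(file.path(dir, paste0(c("t1", "t2"), ".faa")))
    expect_true(all(startsWith(names(rd$seqs)[rd$genome == "t1"], "t1|")))
})
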