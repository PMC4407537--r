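gl10 <- genomeLayout("chr1", 10L)
gl <- genomeLayout("chr1", 1000L)

microF <- mkTrack(list(chr1 = c(0, 1, 1, 2, 2, 2, 0, 0, 1, 0)))
microP <- mkTrack(list(chr1 = c(0, .5, .5, 1, 1, 1, 0, 0, 0, 0)))

test_that("retention keeps states whose footprint is TF-enriched at some k", {
    p_uni <- trackFromRanges(grHalfOpen("chr1", 0, 1000, gl), gl, value = 0.1)
    f_s <- trackFromRanges(grHalfOpen("chr1", 100, 300, gl), gl, value = 3)
    # uniform signal: enrichment 1 at every k
    expect_false(stateRetentionTest(f_s, p_uni, gl))
    # all mass inside a 10% footprint: enrichment 10 at k = 0
    f10 <- trackFromRanges(grHalfOpen("chr1", 0, 100, gl), gl, value = 2)
    p10 <- trackFromRanges(grHalfOpen("chr1", 0, 100, gl), gl, value = 0.5)
    expect_true(stateRetentionTest(f10, p10, gl))
    expect_false(stateRetentionTest(zeroTrack(gl), p10, gl))
    expect_error(stateRetentionTest(f10, zeroTrack(gl), gl),
                 "configuration error")
})

test_that("label summaries sum the retained states", {
    a <- trackFromRanges(grHalfOpen("chr1", 0, 100, gl), gl)
    b <- trackFromRanges(grHalfOpen("chr1", 200, 300, gl), gl)
    expect_equal(decodeTrack(labelSummary(list(a))), decodeTrack(a))
    u <- labelSummary(list(a, b))
    expect_equal(trackIntegral(u), 200)
    expect_equal(trackIntegral(labelSummary(list(), layout = gl)), 0)
})

test_that("F-score at a cutoff reproduces the worked micro-instance", {
    expect_equal(fscoreAt(microF, microP, 0),
                 c(Se = 1, Sp = 2 / 3, F = 0.8))
    expect_equal(fscoreAt(microF, microP, 1),
                 c(Se = 0.75, Sp = 1, F = 6 / 7))
    expect_equal(fscoreAt(microF, microP, 2), c(Se = 0, Sp = 0, F = 0))
})

test_that("cutoff optimization is exhaustive with smallest-k ties", {
    opt <- optimizeCutoff(microF, microP)
    expect_equal(opt$k, 1)
    expect_equal(opt$F, 6 / 7)
    expect_equal(opt$trace$k, c(0, 1))
    # regions at the optimum
    r <- defineLabelRegions(microF, opt$k)
    expect_equal(start(r), 4)
    expect_equal(end(r), 6)
    # indicator summary: only k = 0 is searched
    ind <- trackFromRanges(grHalfOpen("chr1", 2, 6), gl10)
    p <- trackFromRanges(grHalfOpen("chr1", 2, 6), gl10, value = .5)
    expect_equal(optimizeCutoff(ind, p)$k, 0)
    expect_equal(nrow(optimizeCutoff(ind, p)$trace), 1)
    # mass concentrated exactly on the maximal footprint drives k to max - 1
    f <- mkTrack(list(chr1 = c(0, 1, 2, 3, 3, 2, 1, 0, 0, 0)))
    pm <- mkTrack(list(chr1 = c(0, 0, 0, 1, 1, 0, 0, 0, 0, 0)))
    expect_equal(optimizeCutoff(f, pm)$k, 2)
    expect_error(optimizeCutoff(zeroTrack(gl10), microP), "no-region")
})

test_that("optimization agrees with exhaustive enumeration on random input", {
    set.seed(5)
    for (rep in 1:20) {
        lens <- c(chr1 = 300)
        fl <- randStepVecs(lens, nIv = 4, maxVal = 3)$vecs
        pv <- list(chr1 = pmin(1, randStepVecs(lens, nIv = 3, maxVal = 1)$vecs$chr1 * 0.5))
        if (sum(pv$chr1) == 0 || sum(fl$chr1) == 0) next
        opt <- optimizeCutoff(mkTrack(fl), mkTrack(pv))
        o <- oracleOptimize(fl, pv)
        expect_equal(opt$k, o$k)
        expect_equal(opt$F, o$F)
        # reported F dominates the whole trace
        expect_true(all(opt$F >= opt$trace$F))
        # Se never increases with k
        expect_true(all(diff(opt$trace$Se) <= 1e-12))
    }
})

test_that("merging reproduces the documented structural rules", {
    # flank overlapping a promoter is merged into the promoter's flanks
    out <- mergeAndClassify(promoters = grHalfOpen("chr1", 180, 300),
                            flanks = grHalfOpen("chr1", 100, 200),
                            enhancers = GRanges(), ctcf = GRanges(),
                            layout = gl)
    expect_equal(length(out), 1)
    expect_equal(out$feature_class, "promoter")
    expect_equal(start(out), 101)
    expect_equal(end(out), 300)
    expect_equal(out$attached_flank_bp, 80)

    # enhancer overlapping a detached flank joins it as a proximal enhancer
    out2 <- mergeAndClassify(promoters = GRanges(),
                             flanks = grHalfOpen("chr1", 100, 200),
                             enhancers = grHalfOpen("chr1", 50, 120),
                             ctcf = GRanges(), layout = gl)
    expect_equal(length(out2), 1)
    expect_equal(out2$feature_class, "proximal_enhancer")
    expect_equal(start(out2), 51)
    expect_equal(end(out2), 200)

    # CTCF is never merged: both features are emitted, overlapping
    out3 <- mergeAndClassify(promoters = grHalfOpen("chr1", 100, 300),
                             flanks = GRanges(), enhancers = GRanges(),
                             ctcf = grHalfOpen("chr1", 150, 250), layout = gl)
    expect_equal(sort(out3$feature_class),
                 c("ctcf_binding", "promoter"))
    expect_false(isDisjoint(out3))
})

test_that("merging keeps non-CTCF classes disjoint and conserves bases", {
    set.seed(9)
    for (rep in 1:25) {
        rnd <- function(n) {
            s <- sort(sample(1:900, n))
            reduce(grHalfOpen("chr1", s, s + sample(10:80, n, replace = TRUE),
                              gl))
        }
        pr <- rnd(3); fl <- rnd(4); en <- rnd(4); ct <- rnd(2)
        out <- mergeAndClassify(pr, fl, en, ct, gl)
        nonctcf <- out[out$feature_class != "ctcf_binding"]
        expect_true(isDisjoint(nonctcf))
        # base conservation over the three merged classes
        expect_equal(sum(width(reduce(nonctcf))),
                     sum(width(reduce(c(pr, fl, en)))))
        # CTCF passes through unmodified
        expect_equal(sum(width(out[out$feature_class == "ctcf_binding"])),
                     sum(width(ct)))
    }
})

test_that("augmentation adds only fully unannotated regions", {
    feats <- mergeAndClassify(grHalfOpen("chr1", 100, 300), GRanges(),
                              GRanges(), GRanges(), gl)
    # isolated p_TF region is added; 1-bp-overlapping region is not
    p <- sumTracks(list(
        trackFromRanges(grHalfOpen("chr1", 500, 520, gl), gl, value = .5),
        trackFromRanges(grHalfOpen("chr1", 299, 340, gl), gl, value = .5)))
    out <- addUnannotatedTF(p, feats)
    tfb <- out[out$feature_class == "tf_binding_site"]
    expect_equal(length(tfb), 1)
    expect_equal(start(tfb), 501)
    expect_equal(decodeTrack(p)$chr1[300], 0.5)  # overlapping region existed
    # p_TF everywhere zero adds nothing
    expect_equal(length(addUnannotatedTF(zeroTrack(gl), feats)), length(feats))

    # open chromatin: inside an existing feature -> dropped; overlapping
    # peaks from two cell types -> one unioned feature
    open <- grHalfOpen("chr1", c(150, 700, 720), c(200, 730, 800), gl)
    out2 <- addOpenChromatin(open, out, gl)
    oc <- out2[out2$feature_class == "open_chromatin"]
    expect_equal(length(oc), 1)
    expect_equal(start(oc), 701)
    expect_equal(end(oc), 800)
})

test_that("stable identifiers are formatted, canonical and deterministic", {
    gr <- grHalfOpen("chr1", c(10, 50), c(20, 80), gl)
    gr$feature_class <- c("promoter", "distal_enhancer")
    gr$source_label <- c("promoter_tss", "enhancer")
    gr$attached_flank_bp <- c(0, 0)
    ids <- assignStableIds(gr, prefix = "SYNR")
    expect_equal(ids$stable_id[1], "SYNR00000000001")
    perm <- assignStableIds(gr[2:1], prefix = "SYNR")
    expect_equal(as.data.frame(perm), as.data.frame(ids))
    expect_equal(length(assignStableIds(gr[0])), 0)
    dup <- c(gr[1], gr[1])
    expect_error(assignStableIds(dup), "duplicate")
})

test_that("the full build runs the ordered pipeline on a fixture", {
    b <- simulateBundle(smallSimConfig(seed = 21))
    build <- suppressWarnings(runBuild(b$segmentations, b$peaks, b$tss,
                                       b$exons, b$layout,
                                       manifest = b$manifest))
    expect_s4_class(build, "RegulatoryBuild")
    feats <- regulatoryFeatures(build)
    expect_true(all(feats$feature_class %in% featureClasses()))
    expect_true(isDisjoint(feats[feats$feature_class != "ctcf_binding"]))
    # planted promoters all recovered
    rec <- truthRecall(b$truth, feats)
    expect_equal(rec$recall[rec$type == "promoter"], 1.0)
    # summary table covers every emitted class plus a total row
    expect_true("total" %in% buildSummary(build)$feature_class)
    # cutoff table rows correspond to labels that produced regions
    expect_true(all(cutoffTable(build)$F >= 0 & cutoffTable(build)$F <= 1))
    # empty TF manifest is a configuration error
    expect_error(suppressWarnings(runBuild(
        b$segmentations, b$peaks[b$peaks$target == "open-chromatin"],
        b$tss, b$exons, b$layout)), "configuration error")
})

test_that("a single-cell-type build degenerates to a {0} cutoff grid", {
    b <- simulateBundle(simulationConfig(
        seed = 4, nCellTypes = 1L, nChromosomes = 1L, chromLength = 60000L,
        nPromoters = 3L, nEnhancers = 4L, nCtcfSites = 3L, nTfs = 2L,
        stateNoise = 0, peakMissRate = 0, peakFpRate = 0))
    build <- suppressWarnings(runBuild(b$segmentations, b$peaks, b$tss,
                                       b$exons, b$layout,
                                       manifest = b$manifest))
    expect_true(all(cutoffTable(build)$k == 0))
})
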