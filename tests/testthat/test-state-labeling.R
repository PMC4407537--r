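gl <- genomeLayout("chr1", 1000L)

mkSeg <- function(starts0, ends0, states) {
    gr <- grHalfOpen("chr1", starts0, ends0, gl)
    gr$state <- states
    gr
}

test_that("state summaries count cell types per base", {
    segs <- list(
        c1 = mkSeg(c(0, 100), c(100, 1000), c("A", "B")),
        c2 = mkSeg(c(0, 50), c(50, 1000), c("A", "B")),
        c3 = mkSeg(0, 1000, "B"))
    fA <- stateSummary(segs, "A", gl)
    expect_equal(decodeTrack(fA)$chr1[25], 2)
    expect_equal(decodeTrack(fA)$chr1[75], 1)
    expect_equal(decodeTrack(fA)$chr1[200], 0)
    # absent state gives the zero track; unknown vs declared alphabet errors
    expect_equal(trackIntegral(stateSummary(segs, "Z", gl)), 0)
    expect_error(stateSummary(segs, "Z", gl, alphabet = c("A", "B")),
                 "unknown state")
    # partition: per-base sum over states equals the number of cell types
    fB <- stateSummary(segs, "B", gl)
    expect_equal(decodeTrack(sumTracks(list(fA, fB)))$chr1, rep(3, 1000))
})

test_that("fold enrichments follow their densities", {
    uni <- trackFromRanges(grHalfOpen("chr1", 0, 1000), gl, value = 0.2)
    regions <- grHalfOpen("chr1", 100, 300, gl)
    expect_equal(foldEnrichmentSignal(regions, uni, gl), 1.0)
    # all mass inside regions covering 1/5 of the genome -> 5
    conc <- trackFromRanges(grHalfOpen("chr1", 100, 300, gl), gl, value = 3)
    expect_equal(foldEnrichmentSignal(regions, conc, gl), 5.0)
    elsewhere <- trackFromRanges(grHalfOpen("chr1", 500, 600, gl), gl)
    expect_equal(foldEnrichmentSignal(regions, elsewhere, gl), 0.0)
    expect_error(foldEnrichmentSignal(GRanges(), uni, gl), "empty region")
    expect_error(foldEnrichmentSignal(regions, zeroTrack(gl), gl),
                 "zero genome-wide")

    # points: all 10 inside regions covering 10% of the genome -> 10
    pts <- grHalfOpen("chr1", seq(100, 190, by = 10), seq(101, 191, by = 10), gl)
    r10 <- grHalfOpen("chr1", 100, 200, gl)
    expect_equal(foldEnrichmentPoints(r10, pts, gl), 10)
    out <- grHalfOpen("chr1", 500, 600, gl)
    expect_equal(foldEnrichmentPoints(out, pts, gl), 0)

    # intervals: self-overlap gives G/|regions|; disjoint gives 0; genome-wide 1
    expect_equal(foldEnrichmentIntervals(r10, r10, gl), 10)
    expect_equal(foldEnrichmentIntervals(out, r10, gl), 0)
    expect_equal(foldEnrichmentIntervals(r10, grHalfOpen("chr1", 0, 1000, gl),
                                         gl), 1)
})

test_that("enrichment excludes masked bases from numerator and G", {
    mask <- grHalfOpen("chr1", 500, 1000, gl)
    sig <- maskTrack(trackFromRanges(grHalfOpen("chr1", 0, 1000, gl),
                                     gl, value = 1), mask)
    regions <- grHalfOpen("chr1", 0, 100, gl)
    # after masking, signal is uniform over the 500 bp left -> enrichment 1
    expect_equal(foldEnrichmentSignal(regions, sig, gl, mask = mask), 1.0)
})

test_that("state statistics match a per-base oracle on a toy genome", {
    # state footprint 0-200 on a 1 kb genome holding all TF mass
    f_s <- trackFromRanges(grHalfOpen("chr1", 0, 200, gl), gl, value = 2)
    p_TF <- trackFromRanges(grHalfOpen("chr1", 50, 150, gl), gl, value = 0.5)
    tss <- grHalfOpen("chr1", 100, 101, gl)
    exons <- grHalfOpen("chr1", 900, 950, gl)
    ctcf <- trackFromRanges(grHalfOpen("chr1", 0, 200, gl), gl, value = 0.25)
    st <- computeStateStatistics(f_s, p_TF, tss, exons, ctcf, gl,
                                 resolution = 100L)
    # mass fraction 1 inside a 20% footprint -> enrichment 5
    expect_equal(st$tf_enrichment, 5)
    expect_equal(st$tss_enrichment, (1 / 200) / (1 / 1000))
    expect_equal(st$exon_enrichment, 0)
    expect_equal(st$footprint_bp, 200)
    # identical shape -> correlation 1
    expect_equal(st$ctcf_correlation, 1.0)

    # genome-wide state: all enrichments are exactly 1
    whole <- trackFromRanges(grHalfOpen("chr1", 0, 1000, gl), gl)
    varying <- mkTrack(list(chr1 = rep(c(1, 2), 500)))
    st2 <- suppressWarnings(computeStateStatistics(
        whole, varying, tss, exons, varying, gl, resolution = 100L))
    expect_equal(st2$tf_enrichment, 1)
    expect_equal(st2$tss_enrichment, 1)
    expect_equal(st2$exon_enrichment, 1)

    # empty footprint is flagged, not an error
    st3 <- computeStateStatistics(zeroTrack(gl), p_TF, tss, exons, ctcf, gl)
    expect_equal(st3$footprint_bp, 0)
    expect_true(is.na(st3$tf_enrichment))
})

test_that("the decision tree is ordered, total and pure", {
    tree <- labelDecisionTree()
    row <- function(tf = 1, tss = 1, exon = 1, r = 0)
        data.frame(tf_enrichment = tf, tss_enrichment = tss,
                   exon_enrichment = exon, ctcf_correlation = r,
                   footprint_bp = 100)
    expect_equal(assignLabel(row(r = 0.9), tree), "ctcf")
    expect_equal(assignLabel(row(tss = 20, r = 0.1), tree), "promoter_tss")
    expect_equal(assignLabel(row(tf = 3, tss = 3), tree), "promoter_flank")
    expect_equal(assignLabel(row(tf = 3), tree), "enhancer")
    expect_equal(assignLabel(row(exon = 5), tree), "transcribed")
    expect_equal(assignLabel(row(), tree), "low_activity")
    # NA statistics never satisfy a rule
    expect_equal(assignLabel(row(tf = NA, tss = NA, exon = NA), tree),
                 "low_activity")
    expect_error(labelDecisionTree(list(list(when = "tf_enrichment > 1",
                                             label = "nonsense"))),
                 "unknown label")

    # pure function of the statistics: input order cannot matter
    tab <- rbind(row(tss = 20), row(tf = 3), row(r = 0.9))
    l1 <- assignStateLabels(cbind(state = c("s1", "s2", "s3"), tab), tree)
    l2 <- assignStateLabels(cbind(state = c("s3", "s2", "s1"), tab[3:1, ]),
                            tree)
    expect_equal(l1$label, rev(l2$label))
})
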