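gl10 <- genomeLayout("chr1", 10L)

test_that("layout construction validates names and lengths", {
    expect_error(genomeLayout(c("a", "a"), c(10, 20)), "unique")
    expect_error(genomeLayout(c("a", "b"), c(10, 0)), "positive")
    gl <- genomeLayout(c("chr1", "chr2"), c(1000L, 500L))
    expect_equal(genomeSize(gl), 1500)
    expect_equal(genomeSize(gl, grHalfOpen("chr1", 0, 100, gl)), 1400)
})

test_that("track construction equals value on intervals and coalesces", {
    f <- trackFromRanges(grHalfOpen("chr1", 2, 4), gl10, value = 1)
    expect_equal(trackIntegral(f), 2)
    expect_equal(decodeTrack(f)$chr1, c(0, 0, 1, 1, 0, 0, 0, 0, 0, 0))

    f0 <- trackFromRanges(GRanges(), gl10, value = 5)
    expect_equal(trackIntegral(f0), 0)

    # adjacent equal-valued intervals form a single run (canonical form)
    f2 <- trackFromRanges(grHalfOpen("chr1", c(0, 3), c(3, 6)), gl10)
    expect_equal(length(S4Vectors::runLength(f2$chr1)), 2) # value run + 0 run
    expect_equal(decodeTrack(f2)$chr1[1:6], rep(1, 6))

    expect_error(trackFromRanges(grHalfOpen("chr1", 5, 12), gl10),
                 "coordinate error")
    expect_error(trackFromRanges(grHalfOpen("chrX", 0, 5), gl10),
                 "coordinate error")
})

test_that("track sums follow pointwise arithmetic", {
    a <- trackFromRanges(grHalfOpen("chr1", 0, 4), gl10)
    b <- trackFromRanges(grHalfOpen("chr1", 2, 6), gl10)
    s <- sumTracks(list(a, b))
    expect_equal(decodeTrack(s)$chr1, c(1, 1, 2, 2, 1, 1, 0, 0, 0, 0))
    expect_equal(trackIntegral(s), trackIntegral(a) + trackIntegral(b))
    # identity with the zero function
    expect_equal(decodeTrack(sumTracks(list(a, zeroTrack(gl10)))),
                 decodeTrack(a))
    # disjoint indicators give the indicator of the union
    d <- sumTracks(list(trackFromRanges(grHalfOpen("chr1", 0, 2), gl10),
                        trackFromRanges(grHalfOpen("chr1", 5, 7), gl10)))
    expect_equal(decodeTrack(d)$chr1, c(1, 1, 0, 0, 0, 1, 1, 0, 0, 0))
    other <- genomeLayout("chr2", 10L)
    expect_error(sumTracks(list(a, zeroTrack(other))), "layout error")
})

test_that("probability union is 1 - prod(1 - p)", {
    half <- trackFromRanges(grHalfOpen("chr1", 0, 10), gl10, value = 0.5)
    expect_equal(decodeTrack(complementProduct(list(half, half)))$chr1,
                 rep(0.75, 10))
    one <- trackFromRanges(grHalfOpen("chr1", 0, 4), gl10, value = 0.3)
    expect_equal(decodeTrack(complementProduct(list(one))), decodeTrack(one))
    expect_equal(trackIntegral(complementProduct(list(), layout = gl10)), 0)
    bad <- trackFromRanges(grHalfOpen("chr1", 0, 4), gl10, value = 1.5)
    expect_error(complementProduct(list(bad)), "domain error")
})

test_that("strict thresholding returns maximal contiguous regions", {
    f <- mkTrack(list(chr1 = c(0, 0, 3, 3, 0)))
    r <- thresholdStrict(f, 2)
    expect_equal(start(r), 3)
    expect_equal(end(r), 4)
    expect_length(thresholdStrict(f, 3), 0)          # strict at the maximum
    everywhere <- thresholdStrict(mkTrack(list(chr1 = numeric(5))), -1)
    expect_equal(width(everywhere), 5)               # 0 > -1 everywhere
})

test_that("integrals are linear and respect domains", {
    f <- trackFromRanges(grHalfOpen("chr1", 0, 5), gl10, value = 2)
    expect_equal(trackIntegral(f), 10)
    expect_equal(trackIntegral(f, GRanges()), 0)
    ind <- trackFromRanges(grHalfOpen("chr1", 0, 4), gl10)
    expect_equal(trackIntegral(ind, grHalfOpen("chr1", 2, 6)), 2)
})

test_that("binned Pearson correlation behaves as correlation", {
    v <- c(0, 1, 2, 5, 1, 0, 3, 4, 2, 2)
    f <- mkTrack(list(chr1 = v))
    g <- mkTrack(list(chr1 = 6 - v))
    expect_equal(trackPearson(f, f, 2), 1.0)
    expect_equal(trackPearson(f, g, 2), -1.0)
    # exact linearity of bin means
    a <- mkTrack(list(chr1 = rep(c(0, 1, 2, 3), each = 2)))
    b <- mkTrack(list(chr1 = rep(c(1, 3, 5, 7), each = 2)))
    expect_equal(trackPearson(a, b, 2), 1.0)
    expect_error(trackPearson(mkTrack(list(chr1 = rep(1, 10))), f, 2),
                 "undefined correlation")
    # partial terminal bins are dropped
    expect_equal(trackPearson(f, g, 3), -1.0)
})

test_that("masking removes bases from tracks, intervals and G", {
    gr <- grHalfOpen("chr1", 0, 10, gl10)
    mask <- grHalfOpen("chr1", 4, 6, gl10)
    out <- maskRanges(gr, mask)
    expect_equal(start(out), c(1, 7))
    expect_equal(end(out), c(4, 10))
    expect_equal(decodeTrack(maskRanges(gr, GRanges()) |>
                                 trackFromRanges(gl10))$chr1, rep(1, 10))
    expect_length(maskRanges(gr, gr), 0)
    f <- trackFromRanges(gr, gl10, value = 2)
    expect_equal(decodeTrack(maskTrack(f, mask))$chr1,
                 c(2, 2, 2, 2, 0, 0, 2, 2, 2, 2))
})

test_that("random small instances agree with the per-base oracle", {
    set.seed(42)
    for (rep in 1:25) {
        lens <- c(chr1 = sample(200:800, 1), chr2 = sample(200:800, 1))
        gl <- layoutOfVecs(lapply(lens, numeric))
        r <- randStepVecs(lens)
        f <- mkTrack(r$vecs)
        k <- sample(0:3, 1)
        expect_same_regions(thresholdStrict(f, k), oracleThreshold(r$vecs, k))
        expect_equal(trackIntegral(f), oracleIntegral(r$vecs))
        g <- mkTrack(randStepVecs(lens)$vecs)
        dom <- thresholdStrict(g, 0)
        expect_equal(trackIntegral(f, dom),
                     oracleIntegral(r$vecs, indicatorVecs(dom, r$vecs)))
    }
})
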