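# Brute-force per-base-array oracles, independent of the package's
# run-length / interval-tree code paths. All oracles work on plain numeric
# vectors (one per chromosome, per-base values) and base R only.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
})

# encode a list of per-base vectors as the package's track representation
mkTrack <- function(vlist) {
    as(RleList(lapply(vlist, S4Vectors::Rle), compress = FALSE), "RleList")
}

decodeTrack <- function(f) lapply(as.list(f), as.numeric)

layoutOfVecs <- function(vlist) genomeLayout(names(vlist), lengths(vlist))

# GRanges from 0-based half-open coordinates (as in BED)
grHalfOpen <- function(chrom, start0, end0, layout = NULL) {
    gr <- GRanges(chrom, IRanges(start0 + 1, end0))
    if (!is.null(layout)) {
        GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
        GenomeInfoDb::seqinfo(gr) <- layout
    }
    gr
}

# per-base 0/1 membership vectors of a GRanges, by direct assignment
indicatorVecs <- function(gr, vlistTemplate) {
    out <- lapply(vlistTemplate, function(v) numeric(length(v)))
    for (i in seq_along(gr)) {
        chr <- as.character(seqnames(gr))[i]
        out[[chr]][start(gr)[i]:end(gr)[i]] <- 1
    }
    out
}

# intervals (1-based closed, per chrom) where vec > k, by linear scan
oracleThreshold <- function(vlist, k) {
    lapply(vlist, function(v) {
        r <- rle(v > k)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1
        cbind(start = starts[r$values], end = ends[r$values])
    })
}

oracleIntegral <- function(vlist, domInd = NULL) {
    if (is.null(domInd))
        return(sum(vapply(vlist, sum, numeric(1))))
    sum(vapply(names(vlist), function(ch)
        sum(vlist[[ch]] * domInd[[ch]]), numeric(1)))
}

oracleComplementProduct <- function(vlists) {
    template <- vlists[[1]]
    lapply(names(template), function(ch) {
        prod <- rep(1, length(template[[ch]]))
        for (vl in vlists)
            prod <- prod * (1 - vl[[ch]])
        1 - prod
    }) |> stats::setNames(names(template))
}

oracleBinMeans <- function(vlist, res) {
    unlist(lapply(vlist, function(v) {
        nb <- length(v) %/% res
        if (nb == 0) return(numeric(0))
        colMeans(matrix(v[seq_len(nb * res)], nrow = res))
    }), use.names = FALSE)
}

oraclePearson <- function(f, g, res) {
    stats::cor(oracleBinMeans(f, res), oracleBinMeans(g, res))
}

oracleFscore <- function(fl, ptf, k) {
    delta <- lapply(names(fl), function(ch) as.numeric(fl[[ch]] > k))
    names(delta) <- names(fl)
    num <- sum(vapply(names(fl), function(ch)
        sum(ptf[[ch]] * delta[[ch]]), numeric(1)))
    tot <- sum(vapply(ptf, sum, numeric(1)))
    dbp <- sum(vapply(delta, sum, numeric(1)))
    if (dbp == 0) return(c(Se = 0, Sp = 0, F = 0))
    Se <- num / tot
    Sp <- num / dbp
    c(Se = Se, Sp = Sp, F = if (Se + Sp > 0) 2 * Se * Sp / (Se + Sp) else 0)
}

oracleOptimize <- function(fl, ptf) {
    m <- max(vapply(fl, max, numeric(1)))
    ks <- 0:(m - 1)
    fs <- vapply(ks, function(k) oracleFscore(fl, ptf, k)[["F"]], numeric(1))
    list(k = ks[which.max(fs)], F = max(fs), allF = fs)
}

# random integer-valued step function as per-base vectors plus the interval
# list it was built from
randStepVecs <- function(chromLens, nIv = 6, maxVal = 4) {
    vl <- lapply(chromLens, function(L) numeric(L))
    iv <- list()
    for (j in seq_len(nIv)) {
        ch <- sample(names(chromLens), 1)
        L <- chromLens[[ch]]
        s <- sample.int(L, 1)
        e <- min(L, s + sample.int(max(4, L %/% 4), 1) - 1)
        val <- sample.int(maxVal, 1)
        vl[[ch]][s:e] <- vl[[ch]][s:e] + val
        iv[[length(iv) + 1]] <- list(chr = ch, start = s, end = e, value = val)
    }
    list(vecs = vl, intervals = iv)
}

# compare a package GRanges against oracle threshold runs
expect_same_regions <- function(gr, runs) {
    for (ch in names(runs)) {
        sub <- gr[as.character(seqnames(gr)) == ch]
        expect_equal(unname(start(sub)), unname(runs[[ch]][, "start"]))
        expect_equal(unname(end(sub)), unname(runs[[ch]][, "end"]))
    }
}

# small deterministic synthetic config for fast tests
smallSimConfig <- function(seed = 1, ...) {
    simulationConfig(seed = seed, nCellTypes = 3L, nChromosomes = 1L,
                     chromLength = 60000L, nPromoters = 4L, nEnhancers = 6L,
                     nCtcfSites = 4L, nTfs = 4L, ...)
}
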