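#' Genome layout
#'
#' A layout declares the chromosome universe every track and interval set in a
#' build lives on. It is a plain \linkS4class{Seqinfo}, the standard
#' Bioconductor container for chromosome names and lengths; the total genome
#' size G used as the background in all fold-enrichment denominators is the sum
#' of its sequence lengths (minus any exclusion mask).
#'
#' @param chromNames character vector of unique chromosome names.
#' @param chromLengths integer vector of chromosome lengths in bp (>= 1).
#' @return A \linkS4class{Seqinfo} object.
#' @examples
#' gl <- genomeLayout(c("chr1", "chr2"), c(1000L, 500L))
#' genomeSize(gl)
#' @export
genomeLayout <- function(chromNames, chromLengths) {
    if (anyDuplicated(chromNames))
        stop("chromosome names must be unique")
    if (any(chromLengths < 1))
        stop("chromosome lengths must be strictly positive")
    GenomeInfoDb::Seqinfo(seqnames = as.character(chromNames),
                          seqlengths = as.integer(chromLengths))
}

#' Total (unmasked) genome size
#'
#' @param layout a \linkS4class{Seqinfo} layout.
#' @param mask optional \linkS4class{GRanges} of excluded regions; masked bases
#'   are removed from the denominator G, mirroring the treatment of problematic
#'   regions excluded from both peak calls and segmentations.
#' @return Genome size in bp as a double.
#' @export
genomeSize <- function(layout, mask = NULL) {
    G <- sum(as.numeric(GenomeInfoDb::seqlengths(layout)))
    if (!is.null(mask) && length(mask) > 0)
        G <- G - sum(as.numeric(width(GenomicRanges::reduce(mask))))
    G
}

## Seqinfo of a track (RleList), reconstructed from names and element lengths.
.layoutOf <- function(f) {
    GenomeInfoDb::Seqinfo(seqnames = names(f),
                          seqlengths = as.integer(lengths(f)))
}

.sameLayout <- function(f, g) {
    identical(names(f), names(g)) && all(lengths(f) == lengths(g))
}

.checkLayouts <- function(fs) {
    if (length(fs) > 1 &&
        !all(vapply(fs[-1], .sameLayout, logical(1), g = fs[[1]])))
        stop("layout error: tracks are defined on different genome layouts")
}

## GRanges with the layout's seqinfo attached (errors on out-of-bounds).
.onLayout <- function(gr, layout) {
    if (!all(as.character(GenomicRanges::seqnames(gr)) %in%
             GenomeInfoDb::seqnames(layout)))
        stop("coordinate error: interval on undeclared chromosome")
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
    lens <- GenomeInfoDb::seqlengths(layout)[
        as.character(GenomicRanges::seqnames(gr))]
    if (any(GenomicRanges::start(gr) < 1) || any(GenomicRanges::end(gr) > lens))
        stop("coordinate error: interval beyond chromosome end")
    GenomeInfoDb::seqinfo(gr) <- layout
    gr
}

## IRangesList over the full chromosome universe of a layout, in order.
.asIRangesList <- function(gr, layout) {
    S4Vectors::split(GenomicRanges::ranges(gr),
                     factor(as.character(GenomicRanges::seqnames(gr)),
                            levels = GenomeInfoDb::seqnames(layout)))
}

#' The everywhere-zero track
#'
#' @inheritParams genomeSize
#' @return A numeric \linkS4class{RleList}, one run-length vector per
#'   chromosome, identically 0.
#' @export
zeroTrack <- function(layout) {
    lens <- GenomeInfoDb::seqlengths(layout)
    methods::as(IRanges::RleList(lapply(lens, function(L) S4Vectors::Rle(0, L)),
                                 compress = FALSE), "RleList")
}

#' Step function from an interval set
#'
#' Builds the genome-wide piecewise-constant function equal to \code{value} on
#' the (reduced) intervals and 0 elsewhere. Tracks are numeric
#' \linkS4class{RleList}s: run-length encoding keeps whole-genome signals cheap
#' and guarantees the canonical, coalesced representation.
#'
#' @param gr a \linkS4class{GRanges} interval set.
#' @param layout the \linkS4class{Seqinfo} layout.
#' @param value the constant value taken on the intervals.
#' @return A numeric \linkS4class{RleList}.
#' @examples
#' gl <- genomeLayout("chr1", 10L)
#' f <- trackFromRanges(GenomicRanges::GRanges("chr1", IRanges::IRanges(3, 4)), gl)
#' trackIntegral(f)
#' @export
trackFromRanges <- function(gr, layout, value = 1) {
    gr <- .onLayout(gr, layout)
    cov <- GenomicRanges::coverage(GenomicRanges::reduce(gr))
    methods::as(cov * as.numeric(value), "RleList")
}

#' Pointwise sum of tracks
#'
#' @param fs list of tracks (\linkS4class{RleList}) on one layout.
#' @param layout layout used when \code{fs} is empty (returns the zero track).
#' @return The pointwise sum as an \linkS4class{RleList}.
#' @export
sumTracks <- function(fs, layout = NULL) {
    if (length(fs) == 0) {
        if (is.null(layout))
            stop("layout required to sum an empty list of tracks")
        return(zeroTrack(layout))
    }
    .checkLayouts(fs)
    Reduce(`+`, fs)
}

#' Probability union of tracks
#'
#' Combines per-factor binding probability tracks under an independence
#' assumption: pointwise \eqn{1 - \prod_i (1 - p_i)}. All inputs must take
#' values in [0, 1]; so does the result, which dominates each input and is
#' bounded above by their pointwise sum.
#'
#' @param ps list of probability tracks (values in [0, 1]).
#' @inheritParams sumTracks
#' @return An \linkS4class{RleList} with values in [0, 1].
#' @export
complementProduct <- function(ps, layout = NULL) {
    if (length(ps) == 0) {
        if (is.null(layout))
            stop("layout required for an empty probability union")
        return(zeroTrack(layout))
    }
    .checkLayouts(ps)
    for (p in ps) {
        rng <- range(vapply(p, function(r) range(S4Vectors::runValue(r)),
                            numeric(2)))
        if (rng[1] < 0 || rng[2] > 1)
            stop("domain error: probability track has values outside [0, 1]")
    }
    ## scalar-first Rle arithmetic drops list names; restore them
    out <- 1 - Reduce(`*`, lapply(ps, function(p) 1 - p))
    names(out) <- names(ps[[1]])
    out
}

#' Strict thresholding of a track
#'
#' Returns the maximal contiguous regions where the track is strictly greater
#' than \code{k} (adjacent qualifying runs merged). Comparison is exact on
#' stored values; summary functions are integer-valued so no epsilon is used.
#'
#' @param f a track (\linkS4class{RleList}).
#' @param k the cutoff.
#' @return A \linkS4class{GRanges} of disjoint regions, with the track's
#'   layout as seqinfo.
#' @export
thresholdStrict <- function(f, k) {
    layout <- .layoutOf(f)
    irl <- lapply(names(f), function(chr) IRanges::IRanges(f[[chr]] > k))
    names(irl) <- names(f)
    n <- vapply(irl, length, integer(1))
    GenomicRanges::GRanges(rep(names(f), n),
                           do.call(c, unname(irl)),
                           seqinfo = layout)
}

#' Integral of a track
#'
#' Sum of value times length over the whole genome or restricted to a domain.
#'
#' @param f a track.
#' @param domain optional \linkS4class{GRanges}; when given, only bases inside
#'   it contribute.
#' @return The integral as a double.
#' @export
trackIntegral <- function(f, domain = NULL) {
    if (is.null(domain))
        return(sum(vapply(f, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                             S4Vectors::runLength(r)),
                          numeric(1))))
    if (length(domain) == 0)
        return(0)
    layout <- .layoutOf(f)
    irl <- .asIRangesList(GenomicRanges::reduce(.onLayout(domain, layout)),
                          layout)
    v <- IRanges::viewSums(IRanges::Views(f, irl))
    sum(vapply(v, sum, numeric(1)))
}

## Bin means of a track at fixed resolution; partial terminal bins dropped.
.binMeans <- function(f, resolution) {
    resolution <- as.integer(resolution)
    if (resolution < 1)
        stop("resolution must be >= 1 bp")
    out <- lapply(names(f), function(chr) {
        nb <- length(f[[chr]]) %/% resolution
        if (nb == 0)
            return(numeric(0))
        v <- IRanges::Views(f[[chr]],
                            IRanges::successiveIRanges(rep(resolution, nb)))
        IRanges::viewMeans(v)
    })
    unlist(out, use.names = FALSE)
}

#' Binned Pearson correlation of two tracks
#'
#' Both tracks are averaged in consecutive fixed-width bins (default 200 bp,
#' the segmentation resolution; partial terminal bins are dropped) and the
#' Pearson correlation of the bin means is returned.
#'
#' @param f,g tracks on one layout.
#' @param resolution bin width in bp.
#' @return Pearson r in [-1, 1].
#' @export
trackPearson <- function(f, g, resolution = 200L) {
    .checkLayouts(list(f, g))
    x <- .binMeans(f, resolution)
    y <- .binMeans(g, resolution)
    if (length(x) < 2)
        stop("at least 2 bins are required for a correlation")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("undefined correlation: constant track over bins")
    stats::cor(x, y)
}

#' Apply an exclusion mask
#'
#' Forces a track to 0 (or removes interval bases) on masked regions. All
#' downstream enrichment statistics additionally remove masked bases from the
#' genome size G via the \code{mask} argument of the enrichment functions.
#'
#' @param f a track.
#' @param gr a \linkS4class{GRanges} interval set.
#' @param mask \linkS4class{GRanges} of excluded regions.
#' @return Same type as the input, zeroed/trimmed on the mask.
#' @export
maskTrack <- function(f, mask) {
    if (is.null(mask) || length(mask) == 0)
        return(f)
    layout <- .layoutOf(f)
    keep <- 1 - trackFromRanges(mask, layout)
    names(keep) <- names(f)
    f * keep
}

#' @rdname maskTrack
#' @export
maskRanges <- function(gr, mask) {
    if (is.null(mask) || length(mask) == 0)
        return(GenomicRanges::reduce(gr))
    GenomicRanges::setdiff(gr, mask)
}
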