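#' Simulation configuration
#'
#' Parameters of the deterministic synthetic-epigenome generator. The defaults
#' define the package's reference study conditions: 2 chromosomes of 500 kb, 8
#' cell types, 30 promoter units (core plus two flanks plus a downstream
#' transcribed gene), 50 enhancers and 30 CTCF sites, element activity rate
#' 0.8 per cell type, per-interval segmentation mislabel probability 0.01,
#' peak miss rate 0.1, 2 false-positive peaks per Mb per assay, and 6 TFs with
#' 2 assays each (plus 2 CTCF assays and one open-chromatin assay per cell
#' type). Segment boundaries are jittered per cell type (uniform +/- 100 bp)
#' to emulate segmentation boundary uncertainty at 200 bp resolution.
#'
#' @param seed master seed; every output stream derives its own seed from it.
#' @param nCellTypes,nChromosomes,chromLength genome and panel dimensions.
#' @param nPromoters,nEnhancers,nCtcfSites planted element counts.
#' @param promoterLength,flankLength,enhancerLength,ctcfLength,geneLength
#'   min/max bp of each element type.
#' @param stateNoise per-interval probability that a segmentation interval is
#'   mislabeled with a uniformly drawn other state.
#' @param peakFpRate expected false-positive peaks per Mb per assay.
#' @param peakMissRate probability that a truly bound element lacks a peak in
#'   a given assay.
#' @param nTfs,assaysPerTf,ctcfAssays assay panel sizes; the first half of the
#'   TFs bind promoters (core plus flanks), the rest bind enhancers.
#' @param activityRate probability an element is active in a cell type (at
#'   least one active cell type is enforced).
#' @param boundaryJitter half-width (bp) of the uniform per-cell-type jitter
#'   of segment boundaries.
#' @param bgWindow background run window size (bp); background is emitted in
#'   windows so interval-level mislabeling produces realistic noise segments.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L, nCellTypes = 8L, nChromosomes = 2L,
                             chromLength = 500000L, nPromoters = 30L,
                             nEnhancers = 50L, nCtcfSites = 30L,
                             promoterLength = c(500L, 1500L),
                             flankLength = c(500L, 1000L),
                             enhancerLength = c(300L, 800L),
                             ctcfLength = c(200L, 400L),
                             geneLength = c(2000L, 4000L),
                             stateNoise = 0.01, peakFpRate = 2,
                             peakMissRate = 0.1, nTfs = 6L, assaysPerTf = 2L,
                             ctcfAssays = 2L, activityRate = 0.8,
                             boundaryJitter = 100L, bgWindow = 2000L) {
    cfg <- list(seed = as.integer(seed), nCellTypes = as.integer(nCellTypes),
                nChromosomes = as.integer(nChromosomes),
                chromLength = as.integer(chromLength),
                nPromoters = as.integer(nPromoters),
                nEnhancers = as.integer(nEnhancers),
                nCtcfSites = as.integer(nCtcfSites),
                promoterLength = promoterLength, flankLength = flankLength,
                enhancerLength = enhancerLength, ctcfLength = ctcfLength,
                geneLength = geneLength, stateNoise = stateNoise,
                peakFpRate = peakFpRate, peakMissRate = peakMissRate,
                nTfs = as.integer(nTfs), assaysPerTf = as.integer(assaysPerTf),
                ctcfAssays = as.integer(ctcfAssays),
                activityRate = activityRate,
                boundaryJitter = as.integer(boundaryJitter),
                bgWindow = as.integer(bgWindow))
    probs <- c(cfg$stateNoise, cfg$peakMissRate, cfg$activityRate)
    if (any(probs < 0 | probs > 1))
        stop("probabilities must lie in [0, 1]")
    if (any(c(cfg$nPromoters, cfg$nEnhancers, cfg$nCtcfSites) < 0))
        stop("element counts must be >= 0")
    occupancy <- cfg$nPromoters * (max(promoterLength) +
                                   2 * max(flankLength) + max(geneLength) + 500) +
        cfg$nEnhancers * (max(enhancerLength) + 500) +
        cfg$nCtcfSites * (max(ctcfLength) + 500)
    if (occupancy > 0.75 * cfg$nChromosomes * cfg$chromLength)
        stop("configuration error: planted elements exceed genome capacity")
    structure(cfg, class = "SimulationConfig")
}

## Segmentation state alphabet of the generator.
.SIM_STATES <- c(background = "0", promoter = "1", flank = "2",
                 enhancer = "3", ctcf = "4", transcribed = "5")

#' @rdname simulationConfig
#' @export
simulationStateAlphabet <- function() unname(.SIM_STATES)

## Deterministic sub-seed per logical output stream, so regenerating one
## stream never perturbs the others.
.subSeed <- function(master, key) {
    h <- 0
    for (ch in utf8ToInt(key))
        h <- (h * 31 + ch) %% 2147483563
    as.integer((h + as.numeric(master) * 7919) %% 2147483563)
}

.runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

## Jitter strictly increasing boundary positions, clamped to [lo, hi].
.jitterCuts <- function(cuts, j, lo, hi) {
    if (j <= 0)
        return(cuts)
    n <- length(cuts)
    cuts <- cuts + .runif_int(n, -j, j)
    cuts[1] <- max(cuts[1], lo)
    for (i in seq_len(n)[-1])
        cuts[i] <- max(cuts[i], cuts[i - 1] + 1)
    cuts[n] <- min(cuts[n], hi)
    for (i in rev(seq_len(n - 1)))
        cuts[i] <- min(cuts[i], cuts[i + 1] - 1)
    cuts
}

#' Generate a synthetic input bundle with planted ground truth
#'
#' Builds, entirely in memory, every input the consensus pipeline consumes:
#' per-cell-type segmentations over a planted regulatory landscape, TF and
#' open-chromatin peak calls with configurable miss and false-positive rates,
#' a gene annotation (TSS and exons), the assay manifest, and the planted
#' truth (element positions, types and per-cell-type activity). The output is
#' reproducible given the seed; \code{\link{writeBundle}} serializes it to the
#' exact file formats the pipeline reads.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return A list of class \code{SyntheticBundle} with elements
#'   \code{layout}, \code{segmentations}, \code{peaks}, \code{manifest},
#'   \code{tss}, \code{exons}, \code{genes}, \code{truth} (list with
#'   \code{elements} and \code{activity}) and \code{config}.
#' @export
simulateBundle <- function(config = simulationConfig()) {
    layout <- genomeLayout(paste0("chr", seq_len(config$nChromosomes)),
                           rep(config$chromLength, config$nChromosomes))
    chroms <- GenomeInfoDb::seqnames(layout)
    cellTypes <- paste0("cell", seq_len(config$nCellTypes))

    ## ---- planted truth -------------------------------------------------
    set.seed(.subSeed(config$seed, "truth"))
    ## plain integer interval bookkeeping: a 500 bp buffer separates planted
    ## spans so that per-cell-type boundary jitter can never make them collide
    placedS <- stats::setNames(vector("list", length(chroms)), chroms)
    placedE <- placedS
    placeSpan <- function(span) {
        for (try in seq_len(2000)) {
            chr <- chroms[.runif_int(1, 1, length(chroms))]
            start <- .runif_int(1, 501, config$chromLength - span - 500)
            end <- start + span - 1
            s <- placedS[[chr]]
            if (is.null(s) || length(s) == 0 ||
                !any(s <= end + 500 & placedE[[chr]] >= start - 500)) {
                placedS[[chr]] <<- c(s, start)
                placedE[[chr]] <<- c(placedE[[chr]], end)
                return(list(chr = chr, start = start, end = end))
            }
        }
        stop("configuration error: planted elements exceed genome capacity")
    }
    sampLen <- function(rng) .runif_int(1, rng[1], rng[2])

    units <- vector("list", config$nPromoters)
    for (i in seq_len(config$nPromoters)) {
        flL <- sampLen(config$flankLength)
        core <- sampLen(config$promoterLength)
        flR <- sampLen(config$flankLength)
        gene <- sampLen(config$geneLength)
        span <- placeSpan(flL + core + flR + gene)
        s <- span$start
        chr <- span$chr
        units[[i]] <- list(chr = chr,
                           cuts = c(s, s + flL, s + flL + core,
                                    s + flL + core + flR,
                                    s + flL + core + flR + gene))
    }
    enhancers <- lapply(seq_len(config$nEnhancers), function(i)
        placeSpan(sampLen(config$enhancerLength)))
    ctcfs <- lapply(seq_len(config$nCtcfSites), function(i)
        placeSpan(sampLen(config$ctcfLength)))

    ## element table: promoter core, two flanks per unit, enhancers, ctcf
    mkel <- function(chr, start, end, type, unit)
        GenomicRanges::GRanges(chr, IRanges::IRanges(start, end),
                               type = type, unit = unit, seqinfo = layout)
    el <- list()
    for (i in seq_len(config$nPromoters)) {
        u <- units[[i]]
        cu <- u$cuts
        el[[length(el) + 1]] <- mkel(u$chr, cu[2], cu[3] - 1, "promoter", i)
        el[[length(el) + 1]] <- mkel(u$chr, cu[1], cu[2] - 1, "flank", i)
        el[[length(el) + 1]] <- mkel(u$chr, cu[3], cu[4] - 1, "flank", i)
    }
    for (g in enhancers)
        el[[length(el) + 1]] <- mkel(g$chr, g$start, g$end, "enhancer", NA)
    for (g in ctcfs)
        el[[length(el) + 1]] <- mkel(g$chr, g$start, g$end, "ctcf", NA)
    elements <- do.call(c, el)
    elements$truth_id <- sprintf("E%04d", seq_along(elements))

    ## per-unit / per-element activity; >= 1 active cell type enforced
    drawActivity <- function() {
        a <- stats::rbinom(config$nCellTypes, 1, config$activityRate)
        if (sum(a) == 0)
            a[.runif_int(1, 1, config$nCellTypes)] <- 1L
        a
    }
    unitActivity <- matrix(0L, nrow = config$nPromoters,
                           ncol = config$nCellTypes)
    for (i in seq_len(config$nPromoters))
        unitActivity[i, ] <- drawActivity()
    activity <- matrix(0L, nrow = length(elements), ncol = config$nCellTypes,
                       dimnames = list(elements$truth_id, cellTypes))
    for (i in seq_along(elements)) {
        activity[i, ] <- if (!is.na(elements$unit[i]))
            unitActivity[elements$unit[i], ]
        else drawActivity()
    }

    ## gene annotation: TSS 150 bp into the core (beyond the boundary
    ## jitter, so flank states never cover it); gene spans through the
    ## downstream transcribed region; 3 exons (one at the TSS, two in-body)
    tssPos <- integer(config$nPromoters)
    geneRows <- vector("list", config$nPromoters)
    exonRows <- list()
    for (i in seq_len(config$nPromoters)) {
        u <- units[[i]]
        cu <- u$cuts
        tss <- cu[2] + 150
        tssPos[i] <- tss
        geneEnd <- cu[5] - 1
        geneRows[[i]] <- GenomicRanges::GRanges(
            u$chr, IRanges::IRanges(tss, geneEnd), strand = "+",
            gene_id = sprintf("G%04d", i), seqinfo = layout)
        bodyStart <- cu[4]
        bodyLen <- geneEnd - bodyStart + 1
        e2 <- bodyStart + round(0.2 * bodyLen)
        e3 <- bodyStart + round(0.6 * bodyLen)
        exonRows[[length(exonRows) + 1]] <- GenomicRanges::GRanges(
            u$chr, IRanges::IRanges(c(tss, e2, e3),
                                    width = c(150, 300, 300)),
            strand = "+", gene_id = sprintf("G%04d", i), seqinfo = layout)
    }
    genes <- do.call(c, geneRows)
    exons <- do.call(c, exonRows)
    exons <- exons[GenomicRanges::end(exons) <= GenomeInfoDb::seqlengths(
        layout)[as.character(GenomicRanges::seqnames(exons))]]
    tss <- GenomicRanges::GRanges(
        vapply(units, `[[`, character(1), "chr"),
        IRanges::IRanges(tssPos, width = 1), seqinfo = layout)

    ## ---- segmentations -------------------------------------------------
    alphabet <- unname(.SIM_STATES)
    elChr <- as.character(GenomicRanges::seqnames(elements))
    elStart <- GenomicRanges::start(elements)
    elEnd <- GenomicRanges::end(elements)
    segmentations <- lapply(cellTypes, function(ct) {
        set.seed(.subSeed(config$seed, paste0("seg/", ct)))
        ci <- match(ct, cellTypes)
        chrV <- character(0); startV <- integer(0)
        endV <- integer(0); stateV <- character(0)
        unitStates <- .SIM_STATES[c("flank", "promoter", "flank",
                                    "transcribed")]
        for (i in seq_len(config$nPromoters)) {
            if (!unitActivity[i, ci])
                next
            u <- units[[i]]
            cu <- .jitterCuts(u$cuts, config$boundaryJitter, 1,
                              config$chromLength)
            chrV <- c(chrV, rep(u$chr, 4))
            startV <- c(startV, cu[1:4])
            endV <- c(endV, cu[2:5] - 1)
            stateV <- c(stateV, unitStates)
        }
        for (i in which(elements$type %in% c("enhancer", "ctcf"))) {
            if (!activity[i, ci])
                next
            cu <- .jitterCuts(c(elStart[i], elEnd[i] + 1),
                              config$boundaryJitter, 1, config$chromLength)
            chrV <- c(chrV, elChr[i])
            startV <- c(startV, cu[1])
            endV <- c(endV, cu[2] - 1)
            stateV <- c(stateV, .SIM_STATES[[elements$type[i]]])
        }
        gr <- sort(GenomicRanges::GRanges(chrV,
                                          IRanges::IRanges(startV, endV),
                                          state = unname(stateV),
                                          seqinfo = layout))
        ## background fills every gap, in fixed-size windows
        gaps <- GenomicRanges::gaps(gr)
        gaps <- gaps[BiocGenerics::strand(gaps) == "*"]
        nwin <- (width(gaps) + config$bgWindow - 1L) %/% config$bgWindow
        bgStart <- unlist(lapply(seq_along(gaps), function(k)
            GenomicRanges::start(gaps)[k] +
                config$bgWindow * (seq_len(nwin[k]) - 1L)))
        bgEnd <- pmin(bgStart + config$bgWindow - 1L,
                      rep(GenomicRanges::end(gaps), nwin))
        bg <- GenomicRanges::GRanges(
            rep(as.character(GenomicRanges::seqnames(gaps)), nwin),
            IRanges::IRanges(bgStart, bgEnd),
            state = .SIM_STATES[["background"]], seqinfo = layout)
        gr <- sort(c(gr, bg))
        ## interval-level mislabeling
        if (config$stateNoise > 0) {
            flip <- stats::runif(length(gr)) < config$stateNoise
            if (any(flip)) {
                cur <- gr$state[flip]
                gr$state[flip] <- vapply(cur, function(sv)
                    sample(setdiff(alphabet, sv), 1), character(1))
            }
        }
        gr
    })
    names(segmentations) <- cellTypes

    ## ---- assay panel and peaks ----------------------------------------
    promSpan <- GenomicRanges::GRanges(
        vapply(units, `[[`, character(1), "chr"),
        IRanges::IRanges(vapply(units, function(u) u$cuts[1], numeric(1)),
                         vapply(units, function(u) u$cuts[4] - 1, numeric(1))),
        seqinfo = layout)
    enhGr <- elements[elements$type == "enhancer"]
    ctcfGr <- elements[elements$type == "ctcf"]
    genomeMb <- sum(as.numeric(GenomeInfoDb::seqlengths(layout))) / 1e6

    fpPeaks <- function() {
        nfp <- stats::rpois(1, config$peakFpRate * genomeMb)
        if (nfp == 0)
            return(GenomicRanges::GRanges(seqinfo = layout))
        chr <- chroms[.runif_int(nfp, 1, length(chroms))]
        start <- .runif_int(nfp, 1, config$chromLength - 200)
        GenomicRanges::GRanges(chr, IRanges::IRanges(start, width = 200),
                               seqinfo = layout)
    }
    assayPeaks <- function(targets, targetActivity, ci) {
        keep <- targetActivity[, ci] == 1 &
            stats::runif(length(targets)) >= config$peakMissRate
        pk <- c(GenomicRanges::granges(targets[keep]), fpPeaks())
        sort(pk)
    }

    manifest <- list()
    peakSets <- list()
    addAssay <- function(assayId, target, ct, gr) {
        manifest[[length(manifest) + 1]] <<- data.frame(
            path = file.path("peaks", paste0(assayId, ".bed")),
            target = target, cell_type = ct, assay_id = assayId)
        if (length(gr))
            S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
                target = rep(target, length(gr)),
                cell_type = rep(ct, length(gr)),
                assay_id = rep(assayId, length(gr)))
        else
            S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
                target = character(0), cell_type = character(0),
                assay_id = character(0))
        peakSets[[length(peakSets) + 1]] <<- gr
    }

    promActivity <- unitActivity
    enhActivity <- activity[elements$type == "enhancer", , drop = FALSE]
    ctcfActivity <- activity[elements$type == "ctcf", , drop = FALSE]
    nPromTfs <- ceiling(config$nTfs / 2)
    aix <- 0
    for (t in seq_len(config$nTfs)) {
        tfName <- sprintf("TF%02d", t)
        isProm <- t <= nPromTfs
        for (a in seq_len(config$assaysPerTf)) {
            aix <- aix + 1
            ct <- cellTypes[(aix - 1) %% config$nCellTypes + 1]
            ci <- match(ct, cellTypes)
            assayId <- paste(tfName, ct, a, sep = "_")
            set.seed(.subSeed(config$seed, paste0("peak/", assayId)))
            gr <- if (isProm) assayPeaks(promSpan, promActivity, ci)
                  else assayPeaks(enhGr, enhActivity, ci)
            addAssay(assayId, tfName, ct, gr)
        }
    }
    for (a in seq_len(config$ctcfAssays)) {
        aix <- aix + 1
        ct <- cellTypes[(aix - 1) %% config$nCellTypes + 1]
        ci <- match(ct, cellTypes)
        assayId <- paste("CTCF", ct, a, sep = "_")
        set.seed(.subSeed(config$seed, paste0("peak/", assayId)))
        addAssay(assayId, "CTCF", ct, assayPeaks(ctcfGr, ctcfActivity, ci))
    }
    for (ct in cellTypes) {
        ci <- match(ct, cellTypes)
        assayId <- paste0("open_", ct)
        set.seed(.subSeed(config$seed, paste0("peak/", assayId)))
        openTargets <- c(GenomicRanges::granges(promSpan),
                         GenomicRanges::granges(enhGr),
                         GenomicRanges::granges(ctcfGr))
        openAct <- rbind(promActivity, enhActivity, ctcfActivity)
        addAssay(assayId, "open-chromatin", ct,
                 assayPeaks(openTargets, openAct, ci))
    }
    peaks <- do.call(c, peakSets)
    manifest <- do.call(rbind, manifest)

    structure(list(layout = layout, segmentations = segmentations,
                   peaks = peaks, manifest = manifest, tss = tss,
                   exons = exons, genes = genes,
                   truth = list(elements = elements, activity = activity),
                   config = config),
              class = "SyntheticBundle")
}
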