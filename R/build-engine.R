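#' Build configuration
#'
#' Tunable parameters of the consensus build. Labels in \code{activeLabels}
#' produce consensus regions; the retention threshold is the minimum TF-signal
#' fold enrichment a state must reach (strictly) at some integer cutoff to be
#' kept.
#'
#' @param retentionEnrichmentThreshold fold-enrichment bound (default 2,
#'   strict).
#' @param cutoffSearchMax optional cap on the integer cutoff search.
#' @param activeLabels labels that produce consensus regions.
#' @param resolution correlation bin width in bp (default 200, the
#'   segmentation resolution).
#' @param idPrefix stable-identifier prefix.
#' @param ctcfTarget manifest target name for CTCF assays.
#' @param openTarget manifest target name for open-chromatin assays.
#' @param tree a \code{\link{labelDecisionTree}}.
#' @return A list of class \code{BuildConfig}.
#' @export
buildConfig <- function(retentionEnrichmentThreshold = 2,
                        cutoffSearchMax = NULL,
                        activeLabels = c("promoter_tss", "promoter_flank",
                                         "enhancer", "ctcf"),
                        resolution = 200L,
                        idPrefix = "REGB",
                        ctcfTarget = "CTCF",
                        openTarget = "open-chromatin",
                        tree = labelDecisionTree()) {
    if (retentionEnrichmentThreshold <= 0)
        stop("retention enrichment threshold must be > 0")
    if (!all(activeLabels %in% functionalLabels()))
        stop("active labels must come from the 8-label vocabulary")
    structure(list(retentionEnrichmentThreshold = retentionEnrichmentThreshold,
                   cutoffSearchMax = cutoffSearchMax,
                   activeLabels = activeLabels,
                   resolution = as.integer(resolution),
                   idPrefix = idPrefix,
                   ctcfTarget = ctcfTarget,
                   openTarget = openTarget,
                   tree = tree),
              class = "BuildConfig")
}

.maxValue <- function(f) {
    max(vapply(f, function(r) max(S4Vectors::runValue(r)), numeric(1)))
}

#' State retention test
#'
#' A state is retained iff some integer cutoff k in [0, max(f_s) - 1] gives
#' regions {f_s > k} whose TF-binding-signal fold enrichment strictly exceeds
#' the threshold (default 2). States failing the test contribute nothing to
#' the per-label summary functions.
#'
#' @param f_s state summary track.
#' @param p_TF combined TF binding probability track.
#' @param config a \code{\link{buildConfig}}.
#' @param layout the genome layout.
#' @param mask optional exclusion mask.
#' @return TRUE/FALSE.
#' @export
stateRetentionTest <- function(f_s, p_TF, layout, config = buildConfig(),
                               mask = NULL) {
    if (trackIntegral(p_TF) <= 0)
        stop("configuration error: zero genome-wide TF binding mass")
    m <- .maxValue(f_s)
    if (m <= 0)
        return(FALSE)
    ks <- 0:(m - 1)
    if (!is.null(config$cutoffSearchMax))
        ks <- ks[ks <= config$cutoffSearchMax]
    for (k in ks) {
        regions <- thresholdStrict(f_s, k)
        if (length(regions) == 0)
            next
        enr <- foldEnrichmentSignal(regions, p_TF, layout, mask)
        if (enr > config$retentionEnrichmentThreshold)
            return(TRUE)
    }
    FALSE
}

#' Per-label summary function
#'
#' Pointwise sum of the summary functions of the retained states carrying one
#' label: f_l = sum over s in S_l of f_s.
#'
#' @param retainedSummaries list of state summary tracks sharing a label.
#' @param layout the genome layout (used when the list is empty).
#' @return An integer-valued \linkS4class{RleList}.
#' @export
labelSummary <- function(retainedSummaries, layout = NULL) {
    if (length(retainedSummaries) == 0) {
        if (is.null(layout))
            stop("layout required for a label with no retained states")
        return(zeroTrack(layout))
    }
    sumTracks(retainedSummaries)
}

#' Sensitivity, specificity and F-score at a cutoff
#'
#' With delta the indicator of {f_l > k}:
#' Se = integral(p_TF * delta) / integral(p_TF),
#' Sp = integral(p_TF * delta) / integral(delta),
#' F  = 2 Se Sp / (Se + Sp).
#' An empty delta yields (0, 0, 0) so that F is total over the search grid.
#'
#' @param f_l label summary track.
#' @param p_TF combined TF binding probability track.
#' @param k integer cutoff.
#' @return Named numeric vector c(Se, Sp, F).
#' @export
fscoreAt <- function(f_l, p_TF, k) {
    total <- trackIntegral(p_TF)
    if (total <= 0)
        stop("configuration error: zero genome-wide TF binding mass")
    delta <- thresholdStrict(f_l, k)
    dbp <- sum(as.numeric(width(delta)))
    if (dbp == 0)
        return(c(Se = 0, Sp = 0, F = 0))
    num <- trackIntegral(p_TF, delta)
    Se <- num / total
    Sp <- num / dbp
    Fv <- if (Se + Sp > 0) 2 * Se * Sp / (Se + Sp) else 0
    c(Se = Se, Sp = Sp, F = Fv)
}

#' Optimal integer cutoff for a label
#'
#' Exhaustive search over integer cutoffs k = 0 ... max(f_l) - 1 (k = max
#' gives an empty indicator) for the k maximizing the F-score; ties break
#' toward the smallest k, favoring sensitivity.
#'
#' @inheritParams fscoreAt
#' @param kmax optional cap on the search grid.
#' @return List with elements \code{k}, \code{Se}, \code{Sp}, \code{F} and the
#'   full search \code{trace} (data.frame over every k evaluated).
#' @export
optimizeCutoff <- function(f_l, p_TF, kmax = NULL) {
    m <- .maxValue(f_l)
    if (m <= 0)
        stop("no-region error: label summary function is identically zero")
    ks <- 0:(m - 1)
    if (!is.null(kmax))
        ks <- ks[ks <= kmax]
    tr <- t(vapply(ks, function(k) fscoreAt(f_l, p_TF, k), numeric(3)))
    trace <- data.frame(k = ks, Se = tr[, "Se"], Sp = tr[, "Sp"], F = tr[, "F"])
    best <- which.max(trace$F)
    list(k = trace$k[best], Se = trace$Se[best], Sp = trace$Sp[best],
         F = trace$F[best], trace = trace)
}

#' Consensus regions of a label
#'
#' The contiguous regions where f_l strictly exceeds the optimized cutoff.
#'
#' @inheritParams fscoreAt
#' @param k_l the optimized cutoff for this label.
#' @return A \linkS4class{GRanges}.
#' @export
defineLabelRegions <- function(f_l, k_l) {
    thresholdStrict(f_l, k_l)
}

## bp of 'gr' covered by 'by', per range of gr
.overlapBp <- function(gr, by) {
    if (length(gr) == 0)
        return(numeric(0))
    by <- GenomicRanges::reduce(by)
    hits <- GenomicRanges::findOverlaps(gr, by)
    w <- width(IRanges::pintersect(GenomicRanges::ranges(gr)[S4Vectors::queryHits(hits)],
                                   GenomicRanges::ranges(by)[S4Vectors::subjectHits(hits)]))
    out <- numeric(length(gr))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- agg
    out
}

#' Merge label regions into classified features
#'
#' Applies the structural merge rules: enhancer regions overlapping a promoter
#' flank are unioned into the flank; flank regions overlapping a promoter are
#' unioned into the promoter (the absorbed bases recorded as
#' \code{attached_flank_bp}); enhancer regions left overlapping a promoter are
#' likewise absorbed so that non-CTCF classes stay pairwise disjoint.
#' Surviving flanks become proximal enhancers, surviving enhancer regions
#' distal enhancers. CTCF regions pass through unmodified and may overlap any
#' other class. Overlap always means at least one shared base.
#'
#' @param promoters,flanks,enhancers,ctcf \linkS4class{GRanges} region sets
#'   (each internally disjoint), as produced per label by
#'   \code{\link{defineLabelRegions}}.
#' @param layout the genome layout.
#' @return A \linkS4class{GRanges} with metadata columns \code{feature_class},
#'   \code{source_label}, \code{attached_flank_bp}.
#' @export
mergeAndClassify <- function(promoters, flanks, enhancers, ctcf, layout) {
    prom0 <- GenomicRanges::reduce(.onLayout(promoters, layout))
    prom <- prom0
    fl <- GenomicRanges::reduce(.onLayout(flanks, layout))
    enh <- GenomicRanges::reduce(.onLayout(enhancers, layout))
    ct <- GenomicRanges::reduce(.onLayout(ctcf, layout))
    repeat {
        h <- IRanges::overlapsAny(enh, fl)
        if (any(h)) {
            fl <- GenomicRanges::reduce(c(fl, enh[h]))
            enh <- enh[!h]
            next
        }
        h <- IRanges::overlapsAny(fl, prom)
        if (any(h)) {
            prom <- GenomicRanges::reduce(c(prom, fl[h]))
            fl <- fl[!h]
            next
        }
        h <- IRanges::overlapsAny(enh, prom)
        if (any(h)) {
            prom <- GenomicRanges::reduce(c(prom, enh[h]))
            enh <- enh[!h]
            next
        }
        break
    }
    mk <- function(gr, cls, lab, attached = 0) {
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            feature_class = rep(cls, length(gr)),
            source_label = rep(lab, length(gr)),
            attached_flank_bp = rep(attached, length.out = max(length(gr), 0))[
                seq_len(length(gr))])
        gr
    }
    attached <- width(prom) - .overlapBp(prom, prom0)
    out <- c(mk(prom, "promoter", "promoter_tss", attached),
             mk(fl, "proximal_enhancer", "promoter_flank"),
             mk(enh, "distal_enhancer", "enhancer"),
             mk(ct, "ctcf_binding", "ctcf"))
    sort(out)
}

#' Add unannotated TF binding sites
#'
#' Every contiguous region where p_TF is strictly positive that shares no base
#' with any existing feature (of any class) is added as a
#' \code{tf_binding_site} feature.
#'
#' @param p_TF combined TF binding probability track.
#' @param features existing classified features (\linkS4class{GRanges}).
#' @return Features with the additions appended (sorted).
#' @export
addUnannotatedTF <- function(p_TF, features) {
    regs <- thresholdStrict(p_TF, 0)
    keep <- regs[!IRanges::overlapsAny(regs, features)]
    if (length(keep)) {
        S4Vectors::mcols(keep) <- S4Vectors::DataFrame(
            feature_class = rep("tf_binding_site", length(keep)),
            source_label = rep(NA_character_, length(keep)),
            attached_flank_bp = rep(0, length(keep)))
        features <- c(features, keep)
    }
    sort(features)
}

#' Add unannotated open chromatin
#'
#' Open-chromatin peaks from all cell types are unioned; each resulting region
#' that shares no base with any existing feature (including the TF-binding
#' additions, which come first) is added as an \code{open_chromatin} feature.
#'
#' @param openPeaks \linkS4class{GRanges} of open-chromatin peaks (any cell
#'   types; unioned before comparison).
#' @param features existing features, including \code{tf_binding_site} ones.
#' @param layout the genome layout.
#' @return Features with the additions appended (sorted).
#' @export
addOpenChromatin <- function(openPeaks, features, layout) {
    op <- GenomicRanges::reduce(.onLayout(openPeaks, layout))
    keep <- op[!IRanges::overlapsAny(op, features)]
    if (length(keep)) {
        S4Vectors::mcols(keep) <- S4Vectors::DataFrame(
            feature_class = rep("open_chromatin", length(keep)),
            source_label = rep(NA_character_, length(keep)),
            attached_flank_bp = rep(0, length(keep)))
        features <- c(features, keep)
    }
    sort(features)
}

#' Assign stable identifiers
#'
#' Features are put in canonical order (chromosome, start, end, class) and
#' numbered with a zero-padded 11-digit ordinal appended to the prefix, so
#' identical inputs always produce identical identifiers.
#'
#' @param features classified features.
#' @param prefix identifier prefix.
#' @return The features, canonically sorted, with a \code{stable_id} column.
#' @export
assignStableIds <- function(features, prefix = "REGB") {
    if (length(features) == 0) {
        S4Vectors::mcols(features)$stable_id <- character(0)
        return(features)
    }
    ord <- order(as.integer(GenomicRanges::seqnames(features)),
                 GenomicRanges::start(features), GenomicRanges::end(features),
                 match(features$feature_class, featureClasses()))
    features <- features[ord]
    key <- paste(GenomicRanges::seqnames(features),
                 GenomicRanges::start(features), GenomicRanges::end(features),
                 features$feature_class)
    if (anyDuplicated(key))
        stop("input error: duplicate features (same coordinates and class)")
    features$stable_id <- sprintf("%s%011d", prefix, seq_along(features))
    features
}

#' Run the full consensus build
#'
#' Executes the ordered pipeline: per-TF probability tracks and their
#' independence union p_TF; per-state summary functions and statistics; label
#' assignment by the decision tree; state retention against TF signal;
#' per-label summary functions, F-score cutoff optimization and region
#' calling; structural merging and classification; augmentation with
#' unannotated TF binding sites and open chromatin; stable identifiers;
#' per-cell-type binary activity; and the per-class summary table.
#'
#' @param segmentations named list (cell type -> \linkS4class{GRanges} with a
#'   \code{state} column).
#' @param peaks \linkS4class{GRanges} of all peak calls with \code{target},
#'   \code{cell_type}, \code{assay_id} metadata (see \code{\link{readPeaks}}).
#' @param tss \linkS4class{GRanges} of TSS positions.
#' @param exons \linkS4class{GRanges} of exonic intervals.
#' @param layout the genome layout.
#' @param config a \code{\link{buildConfig}}.
#' @param mask optional exclusion mask applied to every input and removed from
#'   the background genome size.
#' @param manifest optional manifest data.frame declaring assays that produced
#'   no peaks (columns \code{target}, \code{assay_id}).
#' @return A \linkS4class{RegulatoryBuild}.
#' @export
runBuild <- function(segmentations, peaks, tss, exons, layout,
                     config = buildConfig(), mask = NULL, manifest = NULL) {
    peaks <- .onLayout(peaks, layout)
    if (!is.null(mask) && length(mask)) {
        mask <- GenomicRanges::reduce(.onLayout(mask, layout))
        peaks <- .maskKeepMcols(peaks, mask)
        segmentations <- lapply(segmentations, .maskKeepMcols, mask = mask)
        tss <- tss[!IRanges::overlapsAny(tss, mask)]
        exons <- GenomicRanges::setdiff(.onLayout(exons, layout), mask)
    }
    isOpen <- peaks$target == config$openTarget
    tfPeaks <- peaks[!isOpen]
    openPeaks <- peaks[isOpen]
    tfTargets <- unique(tfPeaks$target)
    if (!is.null(manifest))
        tfTargets <- unique(c(tfTargets,
                              manifest$target[manifest$target != config$openTarget]))
    if (length(tfTargets) == 0)
        stop("configuration error: no TF assays; p_TF has zero mass")
    assayIdsOf <- function(t) {
        ids <- unique(tfPeaks$assay_id[tfPeaks$target == t])
        if (!is.null(manifest))
            ids <- unique(c(ids, manifest$assay_id[manifest$target == t]))
        ids
    }
    tracks <- lapply(tfTargets, function(t)
        tfProbability(tfPeaks, layout, tf = t, assayIds = assayIdsOf(t)))
    names(tracks) <- tfTargets
    p_TF <- overallTFProbability(tracks, layout)
    if (trackIntegral(p_TF) <= 0)
        stop("configuration error: p_TF has zero genome-wide mass")
    ctcf <- ctcfDensity(tfPeaks, layout, ctcfTarget = config$ctcfTarget,
                        assayIds = assayIdsOf(config$ctcfTarget))

    states <- sort(unique(unlist(lapply(segmentations, function(s) s$state))))
    summaries <- lapply(states, function(s)
        stateSummary(segmentations, s, layout))
    names(summaries) <- states
    stats <- do.call(rbind, lapply(states, function(s)
        cbind(data.frame(state = s),
              computeStateStatistics(summaries[[s]], p_TF, tss, exons, ctcf,
                                     layout, config$resolution, mask))))
    stats <- assignStateLabels(stats, config$tree)
    stats$retained <- vapply(seq_len(nrow(stats)), function(i) {
        if (!stats$label[i] %in% config$activeLabels)
            return(FALSE)
        stateRetentionTest(summaries[[stats$state[i]]], p_TF, layout, config,
                           mask)
    }, logical(1))

    cutoffs <- list()
    traces <- list()
    regionsOf <- function(lab) {
        sel <- stats$state[stats$label == lab & stats$retained]
        if (length(sel) == 0) {
            if (lab %in% config$activeLabels)
                warning("label '", lab, "' has no retained states; ",
                        "it produces no consensus regions")
            return(GenomicRanges::GRanges(seqinfo = layout))
        }
        f_l <- labelSummary(summaries[sel], layout)
        opt <- optimizeCutoff(f_l, p_TF, kmax = config$cutoffSearchMax)
        cutoffs[[lab]] <<- data.frame(label = lab, k = opt$k, Se = opt$Se,
                                      Sp = opt$Sp, F = opt$F)
        traces[[lab]] <<- opt$trace
        defineLabelRegions(f_l, opt$k)
    }
    promR <- regionsOf("promoter_tss")
    flankR <- regionsOf("promoter_flank")
    enhR <- regionsOf("enhancer")
    ctcfR <- regionsOf("ctcf")

    feats <- mergeAndClassify(promR, flankR, enhR, ctcfR, layout)
    feats <- addUnannotatedTF(p_TF, feats)
    feats <- addOpenChromatin(openPeaks, feats, layout)
    feats <- assignStableIds(feats, config$idPrefix)

    stateLabelMap <- stats[, c("state", "label")]
    tfByCell <- S4Vectors::split(tfPeaks, tfPeaks$cell_type)
    openByCell <- S4Vectors::split(openPeaks, openPeaks$cell_type)
    activity <- annotateActivity(feats, segmentations, stateLabelMap,
                                 as.list(tfByCell), as.list(openByCell))

    methods::new("RegulatoryBuild",
                 features = feats,
                 cutoffs = if (length(cutoffs)) do.call(rbind, cutoffs)
                           else data.frame(label = character(0), k = integer(0),
                                           Se = numeric(0), Sp = numeric(0),
                                           F = numeric(0)),
                 traces = traces,
                 stateLabels = stats,
                 activity = activity,
                 layout = layout,
                 buildSummary = summarizeBuild(feats, layout, mask))
}

## setdiff that preserves per-range metadata by subtracting the mask per row
.maskKeepMcols <- function(gr, mask) {
    if (length(gr) == 0)
        return(gr)
    hits <- GenomicRanges::findOverlaps(gr, mask)
    if (length(hits) == 0)
        return(gr)
    untouched <- gr[-unique(S4Vectors::queryHits(hits))]
    pieces <- lapply(unique(S4Vectors::queryHits(hits)), function(i) {
        kept <- GenomicRanges::setdiff(gr[i], mask)
        if (length(kept) == 0)
            return(NULL)
        S4Vectors::mcols(kept) <- S4Vectors::mcols(gr[i])[
            rep(1, length(kept)), , drop = FALSE]
        kept
    })
    pieces <- pieces[!vapply(pieces, is.null, logical(1))]
    sort(do.call(c, c(list(untouched), pieces)))
}
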