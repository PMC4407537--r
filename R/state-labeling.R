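#' Cross-cell-type state summary function
#'
#' For a segmentation state s, builds the genome-wide integer track f_s giving
#' at every base the number of cell types whose segmentation assigns that base
#' to state s. Over the unmasked genome the summaries of all states partition
#' the cell-type count: sum_s f_s(x) = number of cell types.
#'
#' @param segmentations named list (cell type -> \linkS4class{GRanges} with a
#'   \code{state} metadata column) of per-cell-type segmentations.
#' @param state the state identifier to summarize.
#' @param layout the \linkS4class{Seqinfo} genome layout.
#' @param alphabet optional declared state alphabet; when supplied, a state
#'   outside it is an error (a state merely absent from the data yields the
#'   zero track).
#' @return An integer-valued \linkS4class{RleList}.
#' @export
stateSummary <- function(segmentations, state, layout, alphabet = NULL) {
    if (length(segmentations) == 0)
        stop("at least one segmentation is required")
    if (!is.null(alphabet) && !state %in% alphabet)
        stop("input error: unknown state id '", state, "'")
    per <- lapply(segmentations, function(seg)
        trackFromRanges(seg[seg$state == state], layout))
    sumTracks(per, layout)
}

## |regions| in bp after reduction (and optional masking)
.regionBp <- function(regions, mask = NULL) {
    sum(as.numeric(width(GenomicRanges::reduce(maskRanges(regions, mask)))))
}

#' Fold enrichment of a signal track in a region set
#'
#' Mean signal density inside the regions divided by the genome-wide mean
#' density. Masked bases are excluded from both the regions and the genome
#' size G.
#'
#' @param regions \linkS4class{GRanges} region set (non-empty).
#' @param signal a track (\linkS4class{RleList}).
#' @param layout the genome layout.
#' @param mask optional exclusion mask.
#' @return Fold enrichment >= 0 (1 = genome background).
#' @export
foldEnrichmentSignal <- function(regions, signal, layout, mask = NULL) {
    regions <- maskRanges(.onLayout(regions, layout), mask)
    bp <- .regionBp(regions)
    if (bp == 0)
        stop("undefined enrichment: empty region set")
    total <- trackIntegral(signal)
    if (total <= 0)
        stop("undefined enrichment: signal has zero genome-wide mass")
    local <- trackIntegral(signal, regions)
    (local / bp) / (total / genomeSize(layout, mask))
}

#' Fold enrichment of point features (e.g. TSSs) in a region set
#'
#' @param points \linkS4class{GRanges} of positions (e.g. width-1 TSS anchors).
#' @inheritParams foldEnrichmentSignal
#' @return Fold enrichment >= 0.
#' @export
foldEnrichmentPoints <- function(regions, points, layout, mask = NULL) {
    regions <- maskRanges(.onLayout(regions, layout), mask)
    bp <- .regionBp(regions)
    if (bp == 0)
        stop("undefined enrichment: empty region set")
    if (length(points) == 0)
        stop("undefined enrichment: no points genome-wide")
    inside <- sum(IRanges::overlapsAny(points, regions))
    (inside / bp) / (length(points) / genomeSize(layout, mask))
}

#' Fold enrichment of interval features (e.g. exons) in a region set
#'
#' Base-level overlap variant: fraction of region bases covered by the
#' features relative to the genome-wide feature density.
#'
#' @param features non-empty \linkS4class{GRanges} of annotation intervals.
#' @inheritParams foldEnrichmentSignal
#' @return Fold enrichment >= 0.
#' @export
foldEnrichmentIntervals <- function(regions, features, layout, mask = NULL) {
    regions <- maskRanges(.onLayout(regions, layout), mask)
    features <- maskRanges(.onLayout(features, layout), mask)
    bp <- .regionBp(regions)
    if (bp == 0)
        stop("undefined enrichment: empty region set")
    featbp <- sum(as.numeric(width(features)))
    if (featbp == 0)
        stop("undefined enrichment: empty feature set")
    ov <- sum(as.numeric(width(GenomicRanges::intersect(
        GenomicRanges::reduce(regions), features, ignore.strand = TRUE))))
    (ov / bp) / (featbp / genomeSize(layout, mask))
}

#' Statistics of one segmentation state
#'
#' Computes, over the contiguous regions where the state's summary function
#' f_s is strictly positive: fold enrichment for the combined TF binding
#' signal, for TSS positions and for exonic bases, plus the binned Pearson
#' correlation of f_s with the CTCF binding density. These four quantities
#' drive the label decision tree. A state with an empty footprint gets
#' footprint 0 and NA enrichments; an undefined correlation (constant track)
#' is mapped to 0 with a warning.
#'
#' @param f_s the state summary track.
#' @param p_TF combined TF binding probability track.
#' @param tss \linkS4class{GRanges} of TSS positions.
#' @param exons \linkS4class{GRanges} of exonic intervals.
#' @param ctcf CTCF binding density track.
#' @param layout the genome layout.
#' @param resolution correlation bin width in bp.
#' @param mask optional exclusion mask.
#' @return One-row data.frame: tf_enrichment, tss_enrichment, exon_enrichment,
#'   ctcf_correlation, footprint_bp.
#' @export
computeStateStatistics <- function(f_s, p_TF, tss, exons, ctcf, layout,
                                   resolution = 200L, mask = NULL) {
    regions <- thresholdStrict(f_s, 0)
    bp <- .regionBp(regions, mask)
    if (bp == 0)
        return(data.frame(tf_enrichment = NA_real_, tss_enrichment = NA_real_,
                          exon_enrichment = NA_real_, ctcf_correlation = 0,
                          footprint_bp = 0))
    enr <- function(fun, feat) tryCatch(fun(regions, feat, layout, mask),
                                        error = function(e) NA_real_)
    r <- tryCatch(trackPearson(f_s, ctcf, resolution), error = function(e) {
        warning("undefined CTCF correlation (constant track); using 0")
        0
    })
    data.frame(tf_enrichment = enr(foldEnrichmentSignal, p_TF),
               tss_enrichment = enr(foldEnrichmentPoints, tss),
               exon_enrichment = enr(foldEnrichmentIntervals, exons),
               ctcf_correlation = r,
               footprint_bp = bp)
}

#' Per-state statistics for every observed state
#'
#' @inheritParams stateSummary
#' @inheritParams computeStateStatistics
#' @return data.frame with one row per state (column \code{state} first).
#' @export
stateStatisticsTable <- function(segmentations, p_TF, tss, exons, ctcf, layout,
                                 resolution = 200L, mask = NULL,
                                 alphabet = NULL) {
    states <- sort(unique(unlist(lapply(segmentations, function(s) s$state))))
    if (!is.null(alphabet))
        states <- sort(unique(c(states, alphabet)))
    rows <- lapply(states, function(s) {
        f_s <- stateSummary(segmentations, s, layout, alphabet)
        cbind(data.frame(state = s),
              computeStateStatistics(f_s, p_TF, tss, exons, ctcf, layout,
                                     resolution, mask))
    })
    do.call(rbind, rows)
}

#' Label decision tree
#'
#' An ordered rule list mapping state statistics to a functional label; the
#' first rule whose predicate holds wins, and a default label guarantees
#' totality. Predicates are R expressions over the statistic names
#' (\code{tf_enrichment}, \code{tss_enrichment}, \code{exon_enrichment},
#' \code{ctcf_correlation}, \code{footprint_bp}); NA comparisons count as
#' FALSE. The shipped default encodes the four published inputs of the tree:
#' CTCF correlation, then TSS, TF and exon enrichments. \code{repressed} and
#' \code{heterochromatin} are only reachable through user-configured rules
#' since no mark-free criterion distinguishes them.
#'
#' @param rules list of \code{list(when = <predicate string>, label = <label>)}
#'   entries, in priority order; NULL gives the default tree.
#' @param default label returned when no rule matches.
#' @return An object of class \code{LabelDecisionTree}.
#' @examples
#' tree <- labelDecisionTree()
#' assignLabel(data.frame(tf_enrichment = 1, tss_enrichment = 20,
#'                        exon_enrichment = 1, ctcf_correlation = 0.1,
#'                        footprint_bp = 100), tree)
#' @export
labelDecisionTree <- function(rules = NULL, default = "low_activity") {
    if (is.null(rules))
        rules <- list(
            list(when = "ctcf_correlation >= 0.25", label = "ctcf"),
            list(when = "tss_enrichment >= 5", label = "promoter_tss"),
            list(when = "tf_enrichment >= 2 & tss_enrichment >= 2",
                 label = "promoter_flank"),
            list(when = "tf_enrichment >= 2", label = "enhancer"),
            list(when = "exon_enrichment >= 2", label = "transcribed"))
    labs <- c(vapply(rules, function(r) r$label, character(1)), default)
    if (!all(labs %in% functionalLabels()))
        stop("unknown label(s): ", paste(setdiff(labs, functionalLabels()),
                                         collapse = ", "))
    structure(list(rules = rules, default = default),
              class = "LabelDecisionTree")
}

#' @rdname labelDecisionTree
#' @param stats a one-row data.frame (or named list) of state statistics.
#' @param tree a \code{LabelDecisionTree}.
#' @export
assignLabel <- function(stats, tree) {
    env <- as.list(stats)
    for (rule in tree$rules) {
        hit <- eval(parse(text = rule$when), envir = env)
        if (isTRUE(hit))
            return(rule$label)
    }
    tree$default
}

#' Assign labels to every state in a statistics table
#'
#' @param statsTable output of \code{\link{stateStatisticsTable}}.
#' @inheritParams assignLabel
#' @return The table with a \code{label} column appended.
#' @export
assignStateLabels <- function(statsTable, tree = labelDecisionTree()) {
    statsTable$label <- vapply(seq_len(nrow(statsTable)), function(i)
        assignLabel(statsTable[i, , drop = FALSE], tree), character(1))
    statsTable
}
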