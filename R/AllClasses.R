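#' @import methods
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
NULL

#' Closed vocabularies
#'
#' The eight functional labels a segmentation state can receive, and the six
#' feature classes a consensus regulatory feature can carry.
#'
#' @return Character vector of allowed values.
#' @export
functionalLabels <- function() {
    c("promoter_tss", "promoter_flank", "enhancer", "ctcf",
      "transcribed", "repressed", "low_activity", "heterochromatin")
}

#' @rdname functionalLabels
#' @export
featureClasses <- function() {
    c("promoter", "proximal_enhancer", "distal_enhancer",
      "ctcf_binding", "tf_binding_site", "open_chromatin")
}

#' TFTrack: per-factor binding probability track
#'
#' Holds the genome-wide binding probability of one transcription factor:
#' at every base, the number of assays with an overlapping peak divided by the
#' total number of assays observed for that factor (an approximate binomial
#' estimator of peak presence). Values are therefore multiples of
#' 1/\code{nAssays} in [0, 1].
#'
#' @slot tf factor name.
#' @slot p numeric \linkS4class{RleList} probability track.
#' @slot nAssays number of assays in the denominator.
#' @aliases TFTrack-class
#' @exportClass TFTrack
setClass("TFTrack",
         representation(tf = "character", p = "RleList", nAssays = "integer"))

setValidity("TFTrack", function(object) {
    if (length(object@tf) != 1 || !nzchar(object@tf))
        return("'tf' must be a single non-empty name")
    if (length(object@nAssays) != 1 || object@nAssays < 1)
        return("'nAssays' must be a single count >= 1")
    vals <- unlist(lapply(object@p, S4Vectors::runValue), use.names = FALSE)
    if (length(vals) && (min(vals) < 0 || max(vals) > 1))
        return("probability values must lie in [0, 1]")
    if (length(vals) &&
        any(abs(vals * object@nAssays - round(vals * object@nAssays)) > 1e-9))
        return("probability values must be multiples of 1/nAssays")
    TRUE
})

setMethod("show", "TFTrack", function(object) {
    cat("TFTrack for", object@tf, "(", object@nAssays, "assays )\n")
    cat("  genome:", sum(as.numeric(lengths(object@p))), "bp on",
        length(object@p), "chromosome(s);",
        "integral:", signif(trackIntegral(object@p), 6), "\n")
})

#' @rdname TFTrack-class
#' @param object a \code{TFTrack}.
#' @export
tfName <- function(object) object@tf

#' @rdname TFTrack-class
#' @export
tfProbabilityTrack <- function(object) object@p

#' @rdname TFTrack-class
#' @export
nAssays <- function(object) object@nAssays

#' RegulatoryBuild: the consensus annotation
#'
#' Result container for a full build: the consensus regulatory features with
#' their classes and stable identifiers, the per-label cutoff-optimization
#' results, the per-state statistics and labels, the per-cell-type binary
#' activity matrix, and a summary table of counts, lengths and genome coverage
#' per feature class.
#'
#' @slot features \linkS4class{GRanges} with metadata columns
#'   \code{stable_id}, \code{feature_class}, \code{source_label},
#'   \code{attached_flank_bp}.
#' @slot cutoffs data.frame with one row per active label: k, Se, Sp, F.
#' @slot traces named list (per label) of the full per-k search trace.
#' @slot stateLabels data.frame of per-state statistics, label and retention.
#' @slot activity integer matrix, features x cell types, 0/1.
#' @slot layout \linkS4class{Seqinfo} genome layout.
#' @slot buildSummary data.frame of per-class count/length/coverage summaries.
#' @aliases RegulatoryBuild-class
#' @exportClass RegulatoryBuild
setClass("RegulatoryBuild",
         representation(features = "GRanges", cutoffs = "data.frame",
                        traces = "list", stateLabels = "data.frame",
                        activity = "matrix", layout = "Seqinfo",
                        buildSummary = "data.frame"))

setValidity("RegulatoryBuild", function(object) {
    fts <- object@features
    need <- c("stable_id", "feature_class", "source_label", "attached_flank_bp")
    if (!all(need %in% colnames(S4Vectors::mcols(fts))))
        return("features must carry stable_id, feature_class, source_label, attached_flank_bp")
    if (length(fts)) {
        if (anyDuplicated(fts$stable_id))
            return("stable ids must be unique")
        if (!all(fts$feature_class %in% featureClasses()))
            return("unknown feature class")
        nonctcf <- fts[fts$feature_class != "ctcf_binding"]
        if (!GenomicRanges::isDisjoint(nonctcf))
            return("non-CTCF features must be pairwise disjoint")
    }
    if (nrow(object@activity) != length(fts))
        return("activity matrix must have one row per feature")
    TRUE
})

setMethod("show", "RegulatoryBuild", function(object) {
    cat("RegulatoryBuild:", length(object@features), "features on",
        length(GenomeInfoDb::seqnames(object@layout)), "chromosome(s),",
        ncol(object@activity), "cell type(s)\n")
    if (length(object@features)) {
        tab <- table(object@features$feature_class)
        for (cl in names(tab)) cat(sprintf("  %-18s %d\n", cl, tab[[cl]]))
        cov <- sum(as.numeric(width(GenomicRanges::reduce(object@features))))
        cat(sprintf("  genome coverage: %.2f%%\n",
                    100 * cov / genomeSize(object@layout)))
    }
})

#' @rdname RegulatoryBuild-class
#' @param object a \code{RegulatoryBuild}.
#' @export
regulatoryFeatures <- function(object) object@features

#' @rdname RegulatoryBuild-class
#' @export
cutoffTable <- function(object) object@cutoffs

#' @rdname RegulatoryBuild-class
#' @param label a functional label present in the cutoff table.
#' @export
cutoffTrace <- function(object, label) object@traces[[label]]

#' @rdname RegulatoryBuild-class
#' @export
stateLabelTable <- function(object) object@stateLabels

#' @rdname RegulatoryBuild-class
#' @export
activityMatrix <- function(object) object@activity

#' @rdname RegulatoryBuild-class
#' @export
buildLayout <- function(object) object@layout

#' @rdname RegulatoryBuild-class
#' @export
buildSummary <- function(object) object@buildSummary
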