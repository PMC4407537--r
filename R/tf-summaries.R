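#' Per-TF binding probability track
#'
#' For one transcription factor, counts at every base the number of assays with
#' an overlapping peak call and divides by the number of assays, yielding an
#' approximate binomial estimate of peak presence across the observed
#' experiments. The denominator counts every assay supplied for the factor,
#' including cell types where it never binds.
#'
#' @param peaks a \linkS4class{GRanges} of peak calls with metadata columns
#'   \code{target}, \code{cell_type}, \code{assay_id} (as read by
#'   \code{\link{readPeaks}}), or peaks of a single assay set.
#' @param layout the \linkS4class{Seqinfo} genome layout.
#' @param tf the factor to summarize; may be omitted when \code{peaks} contains
#'   a single target.
#' @param assayIds optional character vector of all assay identifiers for this
#'   factor; supplies the denominator when some assays produced no peaks
#'   (declared in the manifest but absent from \code{peaks}).
#' @return A \linkS4class{TFTrack}.
#' @export
tfProbability <- function(peaks, layout, tf = NULL, assayIds = NULL) {
    if (!"target" %in% colnames(S4Vectors::mcols(peaks)))
        stop("peaks must carry a 'target' metadata column")
    targets <- unique(peaks$target)
    if (is.null(tf)) {
        if (length(targets) > 1)
            stop("input error: peaks mix several targets; pass 'tf'")
        tf <- targets
    } else {
        peaks <- peaks[peaks$target == tf]
    }
    assays <- if (is.null(assayIds)) unique(peaks$assay_id) else unique(assayIds)
    if (length(assays) == 0)
        stop("input error: no assays for target '", tf, "'")
    n <- length(assays)
    per <- lapply(assays, function(a)
        trackFromRanges(peaks[peaks$assay_id == a], layout))
    p <- sumTracks(per, layout) / n
    methods::new("TFTrack", tf = as.character(tf), p = p, nAssays = as.integer(n))
}

#' Combined TF binding probability
#'
#' Combines the per-factor probability tracks under approximate independence of
#' the factors: at every base, \eqn{p_{TF} = 1 - \prod_t (1 - p_t)}. Each
#' factor enters the product exactly once.
#'
#' @param tracks list of \linkS4class{TFTrack}s, one per factor.
#' @inheritParams tfProbability
#' @return A numeric \linkS4class{RleList} with values in [0, 1].
#' @export
overallTFProbability <- function(tracks, layout = NULL) {
    nms <- vapply(tracks, tfName, character(1))
    if (anyDuplicated(nms))
        stop("input error: duplicate TF names; each factor enters once")
    complementProduct(lapply(tracks, tfProbabilityTrack), layout)
}

#' CTCF binding density
#'
#' The per-factor probability track of CTCF, computed exactly like any other
#' factor, used as the correlation target when labeling segmentation states.
#'
#' @inheritParams tfProbability
#' @param ctcfTarget target name identifying CTCF assays in the peak table.
#' @return A numeric \linkS4class{RleList} with values in [0, 1].
#' @export
ctcfDensity <- function(peaks, layout, ctcfTarget = "CTCF", assayIds = NULL) {
    sel <- peaks[peaks$target == ctcfTarget]
    if (length(sel) == 0 && length(assayIds) == 0)
        stop("configuration error: no ", ctcfTarget,
             " assays; CTCF density is a required input of the label tree")
    tfProbabilityTrack(tfProbability(sel, layout, tf = ctcfTarget,
                                     assayIds = assayIds))
}
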