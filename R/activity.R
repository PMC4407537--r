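#' Per-cell-type binary activity
#'
#' Annotates every consensus feature with an active/inactive call in every
#' cell type. Segmentation-derived classes (promoter, proximal and distal
#' enhancer, CTCF binding) are active in a cell type iff the feature overlaps
#' at least one interval of that cell type's segmentation whose state carries
#' the feature's source label; promoter features additionally accept
#' promoter-flank states, since flanks were merged into them. TF-binding-site
#' features are active iff overlapped by any TF peak of the cell type, and
#' open-chromatin features iff overlapped by one of its open-chromatin peaks.
#' A cell type with no segmentation is reported inactive for
#' segmentation-derived features, with a warning.
#'
#' @param features classified features (\linkS4class{GRanges} with
#'   \code{feature_class} and \code{source_label}).
#' @param segmentations named list (cell type -> \linkS4class{GRanges} with a
#'   \code{state} column).
#' @param stateLabels data.frame mapping \code{state} to \code{label}.
#' @param tfPeaksByCellType named list (cell type -> \linkS4class{GRanges}) of
#'   TF peaks.
#' @param openPeaksByCellType named list (cell type -> \linkS4class{GRanges})
#'   of open-chromatin peaks.
#' @return Integer 0/1 matrix, one row per feature (rownames = stable ids when
#'   present), one column per declared cell type.
#' @export
annotateActivity <- function(features, segmentations, stateLabels,
                             tfPeaksByCellType = list(),
                             openPeaksByCellType = list()) {
    cellTypes <- unique(c(names(segmentations), names(tfPeaksByCellType),
                          names(openPeaksByCellType)))
    act <- matrix(0L, nrow = length(features), ncol = length(cellTypes),
                  dimnames = list(features$stable_id, cellTypes))
    if (length(features) == 0 || length(cellTypes) == 0)
        return(act)
    segClasses <- c("promoter", "proximal_enhancer", "distal_enhancer",
                    "ctcf_binding")
    isSeg <- features$feature_class %in% segClasses
    qualifying <- lapply(seq_along(features), function(i) {
        if (!isSeg[i])
            return(character(0))
        if (features$feature_class[i] == "promoter")
            c("promoter_tss", "promoter_flank")
        else features$source_label[i]
    })
    missingSeg <- character(0)
    for (ct in cellTypes) {
        seg <- segmentations[[ct]]
        if (is.null(seg)) {
            if (any(isSeg))
                missingSeg <- c(missingSeg, ct)
        } else {
            segLab <- stateLabels$label[match(seg$state, stateLabels$state)]
            for (lab in unique(unlist(qualifying))) {
                evid <- seg[!is.na(segLab) & segLab == lab]
                if (length(evid) == 0)
                    next
                rows <- which(vapply(qualifying, function(q) lab %in% q,
                                     logical(1)))
                hit <- IRanges::overlapsAny(features[rows], evid)
                act[rows[hit], ct] <- 1L
            }
        }
        tfp <- tfPeaksByCellType[[ct]]
        if (!is.null(tfp) && length(tfp)) {
            rows <- which(features$feature_class == "tf_binding_site")
            hit <- IRanges::overlapsAny(features[rows], tfp)
            act[rows[hit], ct] <- 1L
        }
        opp <- openPeaksByCellType[[ct]]
        if (!is.null(opp) && length(opp)) {
            rows <- which(features$feature_class == "open_chromatin")
            hit <- IRanges::overlapsAny(features[rows], opp)
            act[rows[hit], ct] <- 1L
        }
    }
    if (length(missingSeg))
        warning("no segmentation for cell type(s) ",
                paste(unique(missingSeg), collapse = ", "),
                "; segmentation-derived features reported inactive there")
    act
}
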