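#' Recall of a reference region set
#'
#' A reference region counts as recalled iff it shares at least one base with
#' at least one feature of any class (the weakest overlap criterion consistent
#' with "covered by one of our annotations").
#'
#' @param reference non-empty \linkS4class{GRanges} of reference regions.
#' @param features \linkS4class{GRanges} of build features.
#' @return List with \code{n_reference}, \code{n_recalled} and \code{recall}.
#' @export
recallReport <- function(reference, features) {
    if (length(reference) == 0)
        stop("input error: empty reference region set")
    n <- length(reference)
    rec <- sum(IRanges::overlapsAny(reference, features))
    list(n_reference = n, n_recalled = rec, recall = rec / n)
}

#' Summary table of a build
#'
#' Per feature class and overall: feature count, mean and population standard
#' deviation of length (divide-by-n), total bp and percent genome coverage.
#' Overall coverage counts every base once even where CTCF features overlap
#' other classes.
#'
#' @param features classified features.
#' @param layout the genome layout.
#' @param mask optional exclusion mask (removed from the genome size).
#' @return data.frame with one row per class plus a Total row.
#' @export
summarizeBuild <- function(features, layout, mask = NULL) {
    G <- genomeSize(layout, mask)
    popSd <- function(x) if (length(x)) sqrt(mean((x - mean(x))^2)) else NA_real_
    classes <- intersect(featureClasses(), unique(features$feature_class))
    rows <- lapply(classes, function(cl) {
        w <- width(features[features$feature_class == cl])
        data.frame(feature_class = cl, n = length(w), mean_bp = mean(w),
                   sd_bp = popSd(w), total_bp = sum(as.numeric(w)),
                   genome_pct = 100 * sum(as.numeric(w)) / G)
    })
    covered <- sum(as.numeric(width(GenomicRanges::reduce(features))))
    w <- width(features)
    total <- data.frame(feature_class = "total", n = length(features),
                        mean_bp = if (length(w)) mean(w) else NA_real_,
                        sd_bp = popSd(w), total_bp = covered,
                        genome_pct = 100 * covered / G)
    out <- do.call(rbind, c(rows, list(total)))
    rownames(out) <- NULL
    out
}

#' Recall of planted truth elements, per type
#'
#' Convenience wrapper around \code{\link{recallReport}} for the synthetic
#' generator's ground truth: recall of each planted element type against the
#' build's features.
#'
#' @param truth a truth object from \code{\link{simulateBundle}} (or any list
#'   with an \code{elements} \linkS4class{GRanges} carrying a \code{type}
#'   column).
#' @param features build features.
#' @return data.frame with one row per element type: n, n_recalled, recall.
#' @export
truthRecall <- function(truth, features) {
    el <- truth$elements
    types <- unique(el$type)
    rows <- lapply(types, function(tp) {
        r <- recallReport(el[el$type == tp], features)
        data.frame(type = tp, n = r$n_reference, n_recalled = r$n_recalled,
                   recall = r$recall)
    })
    do.call(rbind, rows)
}

#' Activity accuracy against planted truth
#'
#' For every planted element matched (by any overlap) to at least one build
#' feature of a compatible class, compares the truth activity of the element
#' with the predicted activity (OR over its matched features) in every cell
#' type, and reports the fraction of agreeing element-by-cell-type calls.
#'
#' @param truth a truth object from \code{\link{simulateBundle}}.
#' @param build a \linkS4class{RegulatoryBuild}.
#' @return List with \code{n_elements_matched}, \code{n_calls} and
#'   \code{accuracy}.
#' @export
truthActivityAccuracy <- function(truth, build) {
    el <- truth$elements
    feats <- regulatoryFeatures(build)
    act <- activityMatrix(build)
    compat <- list(promoter = c("promoter", "proximal_enhancer"),
                   flank = c("promoter", "proximal_enhancer",
                             "distal_enhancer"),
                   enhancer = c("proximal_enhancer", "distal_enhancer"),
                   ctcf = "ctcf_binding")
    cts <- intersect(colnames(truth$activity), colnames(act))
    agree <- 0
    total <- 0
    matched <- 0
    for (i in seq_along(el)) {
        ok <- feats$feature_class %in% compat[[el$type[i]]]
        hits <- which(ok & IRanges::overlapsAny(feats, el[i]))
        if (length(hits) == 0)
            next
        matched <- matched + 1
        pred <- as.integer(colSums(act[hits, cts, drop = FALSE]) > 0)
        tru <- truth$activity[el$truth_id[i], cts]
        agree <- agree + sum(pred == tru)
        total <- total + length(cts)
    }
    list(n_elements_matched = matched, n_calls = total,
         accuracy = if (total) agree / total else NA_real_)
}
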