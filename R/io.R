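#' Read and write tracks and interval sets
#'
#' Tracks serialize as bedGraph (track lines ignored on read, omitted on
#' write; zero-valued runs omitted since unlisted bases are implicitly 0) and
#' interval sets as BED3. All conversions between the 0-based half-open
#' on-disk convention and in-memory coordinates are delegated to rtracklayer.
#'
#' @param path file path.
#' @param layout the \linkS4class{Seqinfo} genome layout.
#' @return \code{readTrack}: an \linkS4class{RleList}; \code{readBed}: a
#'   \linkS4class{GRanges}.
#' @export
readTrack <- function(path, layout) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    gr <- .onLayout(gr, layout)
    methods::as(GenomicRanges::coverage(gr, weight = gr$score), "RleList")
}

#' @rdname readTrack
#' @param f a track.
#' @export
writeTrack <- function(f, path) {
    gr <- methods::as(f, "GRanges")
    gr <- gr[gr$score != 0]
    rtracklayer::export.bedGraph(gr, path)
    invisible(path)
}

#' @rdname readTrack
#' @export
readBed <- function(path, layout) {
    .onLayout(rtracklayer::import(path, format = "BED"), layout)
}

#' @rdname readTrack
#' @param gr a \linkS4class{GRanges}.
#' @param keepMcols keep metadata columns (name/score) on export.
#' @export
writeBed <- function(gr, path, keepMcols = FALSE) {
    if (!keepMcols)
        gr <- GenomicRanges::granges(gr)
    rtracklayer::export.bed(gr, path)
    invisible(path)
}

#' Read per-cell-type segmentations
#'
#' One BED file per cell type (file name minus extension = cell type); the
#' BED name column carries the state identifier of each interval.
#'
#' @param dir directory of segmentation BED files.
#' @param layout the genome layout.
#' @return Named list (cell type -> \linkS4class{GRanges} with a \code{state}
#'   column).
#' @export
readSegmentations <- function(dir, layout) {
    files <- sort(list.files(dir, pattern = "\\.bed$", full.names = TRUE))
    if (length(files) == 0)
        stop("no segmentation BED files found in ", dir)
    segs <- lapply(files, function(fp) {
        gr <- .onLayout(rtracklayer::import(fp, format = "BED"), layout)
        if (is.null(gr$name))
            stop("segmentation BED must carry state ids in the name column: ",
                 fp)
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(state = gr$name)
        sort(gr)
    })
    names(segs) <- sub("\\.bed$", "", basename(files))
    segs
}

#' @rdname readSegmentations
#' @param segmentations named list of segmentation \linkS4class{GRanges}.
#' @export
writeSegmentations <- function(segmentations, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (ct in names(segmentations)) {
        gr <- segmentations[[ct]]
        gr$name <- gr$state
        gr$state <- NULL
        rtracklayer::export.bed(gr, file.path(dir, paste0(ct, ".bed")))
    }
    invisible(dir)
}

#' Read an assay manifest and its peak files
#'
#' The manifest is tab-separated with columns \code{path} (relative to the
#' manifest unless absolute), \code{target} (TF name, \code{CTCF}, or
#' \code{open-chromatin}), \code{cell_type} and \code{assay_id}.
#'
#' @param path manifest file path.
#' @return \code{readPeakManifest}: a data.frame; \code{readPeaks}: a
#'   \linkS4class{GRanges} with \code{target}, \code{cell_type} and
#'   \code{assay_id} metadata columns covering every assay with peaks.
#' @export
readPeakManifest <- function(path) {
    m <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("path", "target", "cell_type", "assay_id")
    if (!all(need %in% colnames(m)))
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    if (any(!nzchar(m$target)))
        stop("manifest targets must be non-empty")
    m
}

#' @rdname readPeakManifest
#' @param manifest a manifest data.frame.
#' @param layout the genome layout.
#' @param baseDir directory manifest paths are relative to.
#' @export
readPeaks <- function(manifest, layout, baseDir = ".") {
    sets <- lapply(seq_len(nrow(manifest)), function(i) {
        fp <- manifest$path[i]
        if (!grepl("^/", fp))
            fp <- file.path(baseDir, fp)
        gr <- .onLayout(rtracklayer::import(fp, format = "BED"), layout)
        score <- if (!is.null(gr$score)) gr$score else rep(NA_real_, length(gr))
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            target = rep(manifest$target[i], length(gr)),
            cell_type = rep(manifest$cell_type[i], length(gr)),
            assay_id = rep(manifest$assay_id[i], length(gr)),
            score = score)
        gr
    })
    do.call(c, sets)
}

#' Read gene annotation
#'
#' Accepts GFF3 with \code{gene} and \code{exon} features (TSS = 5' end of
#' each gene) or a pair of BED files (TSS positions and exon intervals).
#'
#' @param path GFF3 file path.
#' @param layout the genome layout.
#' @return List with \code{tss} (width-1 \linkS4class{GRanges}) and
#'   \code{exons}.
#' @export
readAnnotationGFF3 <- function(path, layout) {
    gr <- .onLayout(rtracklayer::import(path, format = "gff3"), layout)
    genes <- gr[gr$type == "gene"]
    exons <- gr[gr$type == "exon"]
    if (length(genes) == 0)
        stop("annotation has no gene features")
    list(tss = GenomicRanges::resize(genes, width = 1, fix = "start"),
         exons = GenomicRanges::granges(exons))
}

#' @rdname readAnnotationGFF3
#' @param tssPath,exonPath BED files of TSS positions and exon intervals.
#' @export
readAnnotationBeds <- function(tssPath, exonPath, layout) {
    tss <- .onLayout(rtracklayer::import(tssPath, format = "BED"), layout)
    list(tss = GenomicRanges::resize(GenomicRanges::granges(tss), width = 1,
                                     fix = "start"),
         exons = GenomicRanges::granges(
             .onLayout(rtracklayer::import(exonPath, format = "BED"), layout)))
}

#' Read a chromosome sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path file path.
#' @return A \linkS4class{Seqinfo} layout.
#' @export
readChromSizes <- function(path) {
    df <- utils::read.delim(path, header = FALSE,
                            col.names = c("chrom", "length"))
    genomeLayout(df$chrom, df$length)
}

#' @rdname readChromSizes
#' @param layout a \linkS4class{Seqinfo} layout.
#' @export
writeChromSizes <- function(layout, path) {
    utils::write.table(
        data.frame(chrom = GenomeInfoDb::seqnames(layout),
                   length = GenomeInfoDb::seqlengths(layout)),
        path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a build configuration from YAML
#'
#' Any omitted key falls back to the \code{\link{buildConfig}} default. The
#' decision tree is given as an ordered rule list under \code{decision_tree}.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @return A \code{BuildConfig}.
#' @export
readBuildConfig <- function(path = NULL) {
    if (is.null(path))
        return(buildConfig())
    y <- yaml::read_yaml(path)
    tree <- if (!is.null(y$decision_tree))
        labelDecisionTree(y$decision_tree$rules,
                          default = y$decision_tree$default %||% "low_activity")
    else labelDecisionTree()
    pick <- function(key, default) if (!is.null(y[[key]])) y[[key]] else default
    buildConfig(
        retentionEnrichmentThreshold = pick("retention_enrichment_threshold", 2),
        cutoffSearchMax = y$cutoff_search_max,
        activeLabels = pick("active_labels",
                            c("promoter_tss", "promoter_flank", "enhancer",
                              "ctcf")),
        resolution = pick("resolution", 200L),
        idPrefix = pick("id_prefix", "REGB"),
        ctcfTarget = pick("ctcf_target", "CTCF"),
        openTarget = pick("open_chromatin_target", "open-chromatin"),
        tree = tree)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.CLASS_RGB <- c(promoter = "#FF0000", proximal_enhancer = "#FFA500",
                distal_enhancer = "#FFD700", ctcf_binding = "#40E0D0",
                tf_binding_site = "#C0C0C0", open_chromatin = "#696969")

#' Export a build
#'
#' GFF3 carries one line per feature with ID, feature class, source label,
#' attached flank bp and the cell types in which the feature is active; BED9
#' colors features by class. Cutoff traces, the state/label table, the
#' summary table and the activity matrix are written tab-separated.
#'
#' @param build a \linkS4class{RegulatoryBuild}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
exportBuildGFF3 <- function(build, path) {
    fts <- regulatoryFeatures(build)
    act <- activityMatrix(build)
    bound <- vapply(seq_len(length(fts)), function(i) {
        on <- colnames(act)[act[i, ] == 1]
        if (length(on)) paste(on, collapse = ",") else "none"
    }, character(1))
    out <- GenomicRanges::granges(fts)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        source = rep("regbuildr", length(fts)),
        type = fts$feature_class,
        ID = fts$stable_id,
        feature_class = fts$feature_class,
        source_label = fts$source_label,
        attached_flank_bp = fts$attached_flank_bp,
        active_cell_types = bound)
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}

#' @rdname exportBuildGFF3
#' @export
exportBuildBED <- function(build, path) {
    fts <- regulatoryFeatures(build)
    out <- GenomicRanges::granges(fts)
    out$name <- fts$stable_id
    out$score <- rep(0L, length(fts))
    out$itemRgb <- unname(.CLASS_RGB[fts$feature_class])
    out$thick <- GenomicRanges::ranges(out)
    rtracklayer::export.bed(out, path)
    invisible(path)
}

#' @rdname exportBuildGFF3
#' @param cellType one cell type; its per-feature activity is written as a
#'   GFF3 \code{activity} attribute.
#' @export
exportCellTypeGFF3 <- function(build, cellType, path) {
    act <- activityMatrix(build)
    if (!cellType %in% colnames(act))
        stop("unknown cell type: ", cellType)
    fts <- regulatoryFeatures(build)
    out <- GenomicRanges::granges(fts)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
        source = rep("regbuildr", length(fts)),
        type = fts$feature_class,
        ID = fts$stable_id,
        activity = ifelse(act[, cellType] == 1, "active", "inactive"))
    rtracklayer::export(out, path, format = "gff3")
    invisible(path)
}

#' @rdname exportBuildGFF3
#' @export
writeBuildTables <- function(build, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(cutoffTable(build), file.path(dir, "cutoffs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (lab in names(build@traces))
        utils::write.table(build@traces[[lab]],
                           file.path(dir, paste0("cutoff_trace_", lab, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(stateLabelTable(build),
                       file.path(dir, "state_labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(buildSummary(build), file.path(dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    act <- data.frame(stable_id = rownames(activityMatrix(build)),
                      activityMatrix(build), check.names = FALSE)
    utils::write.table(act, file.path(dir, "activity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Serialize a synthetic bundle to disk
#'
#' Writes exactly the formats the pipeline reads: per-cell-type segmentation
#' BEDs, per-assay peak BEDs with a manifest, a GFF3 gene annotation, and the
#' planted truth (elements BED, TSS BED, activity matrix). Writing the same
#' bundle twice produces byte-identical files.
#'
#' @param bundle a \code{SyntheticBundle} from \code{\link{simulateBundle}}.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
writeBundle <- function(bundle, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeChromSizes(bundle$layout, file.path(dir, "chrom.sizes"))
    writeSegmentations(bundle$segmentations, file.path(dir, "segmentations"))
    dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
    for (i in seq_len(nrow(bundle$manifest))) {
        aid <- bundle$manifest$assay_id[i]
        gr <- bundle$peaks[bundle$peaks$assay_id == aid]
        rtracklayer::export.bed(GenomicRanges::granges(gr),
                                file.path(dir, "peaks", paste0(aid, ".bed")))
    }
    utils::write.table(bundle$manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ann <- c(GenomicRanges::granges(bundle$genes),
             GenomicRanges::granges(bundle$exons))
    S4Vectors::mcols(ann) <- S4Vectors::DataFrame(
        source = rep("regbuildr-sim", length(ann)),
        type = c(rep("gene", length(bundle$genes)),
                 rep("exon", length(bundle$exons))),
        ID = c(bundle$genes$gene_id,
               paste0(bundle$exons$gene_id, ".e",
                      seq_along(bundle$exons))))
    rtracklayer::export(sort(ann), file.path(dir, "annotation.gff3"),
                        format = "gff3")
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
    el <- bundle$truth$elements
    elbed <- GenomicRanges::granges(el)
    elbed$name <- paste(el$truth_id, el$type, sep = "|")
    rtracklayer::export.bed(elbed, file.path(dir, "truth", "elements.bed"))
    rtracklayer::export.bed(bundle$tss, file.path(dir, "truth", "tss.bed"))
    act <- data.frame(truth_id = rownames(bundle$truth$activity),
                      bundle$truth$activity, check.names = FALSE)
    utils::write.table(act, file.path(dir, "truth", "activity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Run a build from files on disk
#'
#' Thin file-level wrapper: reads the manifest and peaks, the segmentation
#' directory, the gene annotation and an optional YAML configuration and
#' exclusion mask, runs \code{\link{runBuild}}, and (when \code{outDir} is
#' given) writes the GFF3/BED exports and all tab-separated tables.
#'
#' @param manifestPath assay manifest (TSV).
#' @param segmentationDir directory of per-cell-type segmentation BEDs.
#' @param annotationPath GFF3 gene annotation.
#' @param layout the genome layout.
#' @param configPath optional YAML configuration.
#' @param maskPath optional BED exclusion mask.
#' @param outDir optional output directory.
#' @return A \linkS4class{RegulatoryBuild}.
#' @export
runBuildFromFiles <- function(manifestPath, segmentationDir, annotationPath,
                              layout, configPath = NULL, maskPath = NULL,
                              outDir = NULL) {
    manifest <- readPeakManifest(manifestPath)
    peaks <- readPeaks(manifest, layout, baseDir = dirname(manifestPath))
    segs <- readSegmentations(segmentationDir, layout)
    ann <- readAnnotationGFF3(annotationPath, layout)
    config <- readBuildConfig(configPath)
    mask <- if (!is.null(maskPath)) readBed(maskPath, layout) else NULL
    build <- runBuild(segs, peaks, ann$tss, ann$exons, layout,
                      config = config, mask = mask, manifest = manifest)
    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        exportBuildGFF3(build, file.path(outDir, "regulatory_features.gff3"))
        exportBuildBED(build, file.path(outDir, "regulatory_features.bed"))
        writeBuildTables(build, outDir)
    }
    build
}
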