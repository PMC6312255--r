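#' Assign dose groups from continuous dose
#'
#' Bins lifetime external gamma dose (mGy) into the four study groups.
#' Zero dose is \code{control}; doses strictly below the first boundary are
#' \code{low}; doses from the first boundary up to and including the second
#' are \code{medium}; anything above is \code{high}. The mapping is total
#' and monotone in dose.
#'
#' @param dose_mGy numeric vector of non-negative doses in mGy.
#' @param boundaries increasing pair of group boundaries in mGy
#'   (default c(100, 500)).
#' @return factor with levels control, low, medium, high.
#' @examples
#' assignDoseGroup(c(0, 50, 100, 500, 600))
#' @export
assignDoseGroup <- function(dose_mGy, boundaries = c(100, 500)) {
    stopifnot(length(boundaries) == 2L, boundaries[1L] < boundaries[2L])
    if (any(!is.finite(dose_mGy)) || any(dose_mGy < 0))
        stop("dose_mGy must be finite and non-negative")
    grp <- ifelse(dose_mGy == 0, "control",
           ifelse(dose_mGy < boundaries[1L], "low",
           ifelse(dose_mGy <= boundaries[2L], "medium", "high")))
    factor(grp, levels = .doseGroupLevels)
}

#' Read / write a feature x sample numeric table
#'
#' Tab-separated, UTF-8, header row of sample ids; first column holds the
#' feature identifier. Missing values are written as \code{NA}.
#'
#' @param path file path.
#' @return \code{readMatrixTSV}: a numeric matrix with dimnames.
#' @export
readMatrixTSV <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("matrix file needs a feature column plus samples")
    if (anyDuplicated(df[[1L]]))
        stop("duplicate feature id: ", df[[1L]][duplicated(df[[1L]])][1L])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric values in matrix file ", path)
    rownames(m) <- as.character(df[[1L]])
    m
}

#' @rdname readMatrixTSV
#' @param x numeric matrix with row and column names.
#' @param feature_col name for the first (feature id) column.
#' @export
writeMatrixTSV <- function(x, path, feature_col = "feature_id") {
    df <- data.frame(rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- feature_col
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

readMetadataTSV <- function(path) {
    md <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    need <- c("sample_id", "dose_mGy", "age_years", "bmi", "smoker",
              "drinker")
    missing <- setdiff(need, colnames(md))
    if (length(missing))
        stop("metadata lacks column(s): ", paste(missing, collapse = ", "))
    if (anyDuplicated(md$sample_id))
        stop("duplicate sample_id: ",
             md$sample_id[duplicated(md$sample_id)][1L])
    md$smoker <- as.logical(md$smoker)
    md$drinker <- as.logical(md$drinker)
    md
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>member...}.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors; each element carries a
#'   \code{"description"} attribute.
#' @export
readGMT <- function(path) {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    sets <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop("GMT line ", i, " has fewer than 3 fields")
        members <- unique(f[-(1:2)])
        members <- members[nzchar(members)]
        if (!length(members)) stop("GMT line ", i, " defines an empty set")
        s <- members
        attr(s, "description") <- f[2L]
        if (f[1L] %in% names(sets))
            stop("duplicate gene-set name: ", f[1L])
        sets[[f[1L]]] <- s
    }
    sets
}

#' @rdname readGMT
#' @param sets named list of character vectors (optional
#'   \code{"description"} attributes).
#' @export
writeGMT <- function(sets, path) {
    lines <- vapply(names(sets), function(nm) {
        d <- attr(sets[[nm]], "description")
        if (is.null(d)) d <- nm
        paste(c(nm, d, as.character(sets[[nm]])), collapse = "\t")
    }, character(1L))
    writeLines(lines, path, useBytes = TRUE)
    invisible(path)
}

#' Read a full study from its on-disk tables
#'
#' Loads the protein abundance matrix, transcript count matrix, sample
#' metadata, gene-protein feature map and gene sets, cross-validates all
#' identifiers and returns a \linkS4class{RadStudy}.
#'
#' @param abundance_path,counts_path TSV matrices (feature id first column).
#' @param metadata_path TSV with columns sample_id, dose_mGy, age_years,
#'   bmi, smoker, drinker (dose_group derived).
#' @param map_path two-column TSV gene_id, protein_id; \code{NULL} for none.
#' @param genesets_path GMT file; \code{NULL} for none.
#' @param config a \code{\link{radConfig}}.
#' @return a validated \linkS4class{RadStudy}.
#' @export
readStudy <- function(abundance_path, metadata_path, counts_path = NULL,
                      map_path = NULL, genesets_path = NULL,
                      config = radConfig()) {
    abundance <- readMatrixTSV(abundance_path)
    metadata <- readMetadataTSV(metadata_path)
    counts <- if (!is.null(counts_path)) readMatrixTSV(counts_path)
    fmap <- if (!is.null(map_path)) {
        fm <- utils::read.delim(map_path, check.names = FALSE,
                                stringsAsFactors = FALSE)
        if (!all(c("gene_id", "protein_id") %in% colnames(fm)))
            stop("feature map needs columns gene_id, protein_id")
        fm
    }
    gs <- if (!is.null(genesets_path)) readGMT(genesets_path) else list()
    RadStudy(abundance, metadata, counts = counts, featureMap = fmap,
             geneSets = gs, config = config)
}

#' Write a RadStudy to a directory of TSV/GMT files
#'
#' Inverse of \code{\link{readStudy}}; also writes ground-truth tables for
#' simulated studies.
#'
#' @param study a \linkS4class{RadStudy}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeMatrixTSV(SummarizedExperiment::assay(proteome(study), "abundance"),
                   file.path(dir, "abundance.tsv"), "protein_id")
    md <- sampleMetadata(study)
    utils::write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (ncol(transcriptome(study)))
        writeMatrixTSV(SummarizedExperiment::assay(transcriptome(study),
                                                   "counts"),
                       file.path(dir, "counts.tsv"), "gene_id")
    if (nrow(featureMap(study)))
        utils::write.table(featureMap(study),
                           file.path(dir, "feature_map.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    if (length(geneSets(study)))
        writeGMT(geneSets(study), file.path(dir, "gene_sets.gmt"))
    tt <- truthTables(study)
    for (nm in names(tt))
        utils::write.table(tt[[nm]],
                           file.path(dir, paste0("truth_", nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Write a per-feature result table
#'
#' Tab-separated report with a stable column order and rows sorted by the
#' feature identifier (first column), so identical inputs give
#' byte-identical files.
#'
#' @param results data.frame whose first column identifies the feature.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFeatureReport <- function(results, path) {
    results <- as.data.frame(results)
    if (nrow(results))
        results <- results[order(results[[1L]]), , drop = FALSE]
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}
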