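#' @include AllGenerics.R
NULL

#' RadStudy: container for a paired proteome/transcriptome dose study
#'
#' A \code{RadStudy} bundles the two omics layers of a radiation-exposure
#' study together with the sample covariates, the gene-to-protein feature
#' map and the gene-set collections used for over-representation analysis.
#' The proteome layer is a \linkS4class{SummarizedExperiment} with a single
#' \code{"abundance"} assay (real-valued, \code{NA} allowed) whose
#' \code{colData} carries the per-sample covariates; the transcriptome layer
#' is a \linkS4class{SummarizedExperiment} with an integer \code{"counts"}
#' assay over a (possibly different, typically smaller) set of samples.
#'
#' Sample covariates are \code{sample_id}, \code{dose_mGy} (lifetime
#' external gamma dose), \code{dose_group} (control / low / medium / high,
#' a deterministic function of dose, see \code{\link{assignDoseGroup}}),
#' \code{age_years}, \code{bmi}, \code{smoker}, \code{drinker}.
#'
#' @slot proteome SummarizedExperiment, proteins x samples, assay "abundance".
#' @slot transcriptome SummarizedExperiment, genes x samples, assay "counts".
#' @slot featureMap data.frame with columns \code{gene_id}, \code{protein_id};
#'   many genes may map to one protein, duplicate pairs are invalid.
#' @slot geneSets named list of character vectors of feature identifiers;
#'   each element may carry a \code{"description"} attribute.
#' @slot config list of analysis settings, see \code{\link{radConfig}}.
#' @slot truth list of ground-truth tables when the study was simulated
#'   (elements \code{proteome} and \code{transcriptome}); empty otherwise.
#'
#' @seealso \code{\link{simulateStudy}}, \code{\link{readStudy}}
#' @aliases RadStudy proteome transcriptome featureMap geneSets
#'   sampleMetadata truthTables runConfig
#' @name RadStudy-class
#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass RadStudy
setClass("RadStudy",
    representation(
        proteome      = "SummarizedExperiment",
        transcriptome = "SummarizedExperiment",
        featureMap    = "data.frame",
        geneSets      = "list",
        config        = "list",
        truth         = "list"
    )
)

.metadataColumns <- c("sample_id", "dose_mGy", "dose_group", "age_years",
                      "bmi", "smoker", "drinker")

.validRadStudy <- function(object) {
    msg <- character()
    cd <- SummarizedExperiment::colData(object@proteome)
    missing <- setdiff(.metadataColumns, colnames(cd))
    if (length(missing))
        msg <- c(msg, paste0("proteome colData lacks column(s): ",
                             paste(missing, collapse = ", ")))
    if (anyDuplicated(cd$sample_id))
        msg <- c(msg, paste0("duplicate sample_id: ",
                             cd$sample_id[duplicated(cd$sample_id)][1L]))
    if ("dose_mGy" %in% colnames(cd) && any(cd$dose_mGy < 0, na.rm = TRUE))
        msg <- c(msg, "negative dose_mGy in metadata")
    if (anyDuplicated(rownames(object@proteome)))
        msg <- c(msg, "duplicate protein feature ids")
    if (ncol(object@transcriptome)) {
        cnt <- SummarizedExperiment::assay(object@transcriptome, "counts")
        if (any(cnt < 0, na.rm = TRUE) ||
            any(abs(cnt - round(cnt)) > 1e-8, na.rm = TRUE))
            msg <- c(msg, "transcriptome counts must be non-negative integers")
        extra <- setdiff(colnames(object@transcriptome), cd$sample_id)
        if (length(extra))
            msg <- c(msg, paste0("transcriptome sample not in metadata: ",
                                 extra[1L]))
    }
    fm <- object@featureMap
    if (nrow(fm)) {
        if (!all(c("gene_id", "protein_id") %in% colnames(fm)))
            msg <- c(msg, "featureMap needs columns gene_id, protein_id")
        else if (anyDuplicated(paste(fm$gene_id, fm$protein_id, sep = "\r")))
            msg <- c(msg, "duplicate (gene_id, protein_id) pair in featureMap")
    }
    gs <- object@geneSets
    if (length(gs)) {
        if (is.null(names(gs)) || anyDuplicated(names(gs)))
            msg <- c(msg, "geneSets must have unique names")
        if (any(lengths(gs) == 0L))
            msg <- c(msg, "empty gene set in geneSets")
    }
    if (length(msg)) msg else TRUE
}

setValidity("RadStudy", .validRadStudy)

#' Construct a RadStudy from matrices and tables
#'
#' @param abundance numeric matrix, proteins x samples (NA allowed), with
#'   row and column names.
#' @param metadata data.frame of per-sample covariates; must contain
#'   \code{sample_id}, \code{dose_mGy}, \code{age_years}, \code{bmi},
#'   \code{smoker}, \code{drinker}. \code{dose_group} is derived from
#'   \code{dose_mGy} when absent.
#' @param counts optional integer matrix, genes x samples; its samples must
#'   appear in \code{metadata}.
#' @param featureMap optional data.frame mapping \code{gene_id} to
#'   \code{protein_id}.
#' @param geneSets optional named list of identifier vectors.
#' @param config analysis settings, see \code{\link{radConfig}}.
#' @param truth optional list of ground-truth tables (simulation only).
#' @return A validated \linkS4class{RadStudy}.
#' @export
RadStudy <- function(abundance, metadata, counts = NULL, featureMap = NULL,
                     geneSets = list(), config = radConfig(), truth = list()) {
    abundance <- as.matrix(abundance)
    metadata <- as.data.frame(metadata)
    if (!"dose_group" %in% colnames(metadata))
        metadata$dose_group <- assignDoseGroup(metadata$dose_mGy,
                                               config$dose_boundaries)
    metadata$dose_group <- factor(metadata$dose_group,
                                  levels = .doseGroupLevels)
    missing <- setdiff(colnames(abundance), metadata$sample_id)
    if (length(missing))
        stop("abundance sample not in metadata: ", missing[1L])
    metadata <- metadata[match(colnames(abundance), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- metadata$sample_id
    prot <- SummarizedExperiment::SummarizedExperiment(
        assays = list(abundance = abundance),
        colData = S4Vectors::DataFrame(metadata, check.names = FALSE))
    if (is.null(counts)) {
        trans <- SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = matrix(integer(), 0L, 0L)))
    } else {
        counts <- as.matrix(counts)
        storage.mode(counts) <- "double"
        bad <- setdiff(colnames(counts), metadata$sample_id)
        if (length(bad))
            stop("counts sample not in metadata: ", bad[1L])
        md2 <- metadata[match(colnames(counts), metadata$sample_id), ,
                        drop = FALSE]
        trans <- SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts),
            colData = S4Vectors::DataFrame(md2, check.names = FALSE))
    }
    if (is.null(featureMap))
        featureMap <- data.frame(gene_id = character(),
                                 protein_id = character())
    new("RadStudy", proteome = prot, transcriptome = trans,
        featureMap = as.data.frame(featureMap), geneSets = geneSets,
        config = unclass(config), truth = truth)
}

#' @rdname RadStudy-class
#' @param x a RadStudy
#' @export
setMethod("proteome", "RadStudy", function(x) x@proteome)

#' @rdname RadStudy-class
#' @export
setMethod("transcriptome", "RadStudy", function(x) x@transcriptome)

#' @rdname RadStudy-class
#' @export
setMethod("featureMap", "RadStudy", function(x) x@featureMap)

#' @rdname RadStudy-class
#' @export
setMethod("geneSets", "RadStudy", function(x) x@geneSets)

#' @rdname RadStudy-class
#' @export
setMethod("truthTables", "RadStudy", function(x) x@truth)

#' @rdname RadStudy-class
#' @export
setMethod("runConfig", "RadStudy", function(x) x@config)

#' @rdname RadStudy-class
#' @export
setMethod("sampleMetadata", "RadStudy", function(x) {
    as.data.frame(SummarizedExperiment::colData(x@proteome))
})

setMethod("show", "RadStudy", function(object) {
    md <- sampleMetadata(object)
    cat("RadStudy\n")
    cat(sprintf("  proteome:      %d proteins x %d samples\n",
                nrow(object@proteome), ncol(object@proteome)))
    cat(sprintf("  transcriptome: %d genes x %d samples\n",
                nrow(object@transcriptome), ncol(object@transcriptome)))
    cat(sprintf("  dose groups:   %s\n",
                paste(sprintf("%s=%d", levels(factor(md$dose_group)),
                              table(factor(md$dose_group))), collapse = " ")))
    cat(sprintf("  feature map:   %d gene-protein pairs\n",
                nrow(object@featureMap)))
    cat(sprintf("  gene sets:     %d\n", length(object@geneSets)))
    if (length(object@truth))
        cat("  ground truth:  present (simulated study)\n")
    invisible(NULL)
})
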