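#' Run the full integrative analysis pipeline
#'
#' Executes the complete stage order on a \linkS4class{RadStudy}:
#' per-protein QC (Dixon screen, Shapiro-Wilk), Box-Cox transformation,
#' dose/age deconvolution, dose-group differential analysis with shape
#' classification, transcript differential expression, Fisher
#' integration with the restrictive comparator, gene-set
#' over-representation for both feature lists, and exploratory
#' correlation / clustering. All stochastic stages derive child seeds
#' from \code{runConfig(study)$seed}, so repeated runs produce
#' byte-identical outputs.
#'
#' @param study a \linkS4class{RadStudy}; when NULL, a default synthetic
#'   study is generated from \code{config} (set \code{simulate = TRUE}
#'   explicitly to acknowledge this).
#' @param outDir optional output directory; when given, per-feature TSV
#'   reports and a machine-readable \code{summary.json} are written.
#' @param config a \code{\link{radConfig}}; defaults to the study's own.
#' @param simulate generate a synthetic study when \code{study} is NULL.
#' @param simulateArgs list of overrides passed to
#'   \code{\link{simulateStudy}}.
#' @return (invisibly) a list with all stage outputs (\code{qc},
#'   \code{deconvolution}, \code{dose_response}, \code{dose_sets},
#'   \code{transcript_de}, \code{integration}, \code{restrictive},
#'   \code{enrichment}, \code{explore}) and \code{summary}, the compact
#'   machine-readable digest.
#' @examples
#' res <- runStudy(simulate = TRUE,
#'                 simulateArgs = list(nProteins = 40, nGenes = 150))
#' res$summary$deconvolution_counts
#' @export
runStudy <- function(study = NULL, outDir = NULL, config = NULL,
                     simulate = is.null(study), simulateArgs = list()) {
    if (is.null(study)) {
        if (!simulate)
            stop("no study given and simulate = FALSE")
        if (is.null(config)) config <- radConfig()
        study <- do.call(simulateStudy,
                         c(list(seed = config$seed, config = config),
                           simulateArgs))
    }
    if (is.null(config)) config <- runConfig(study)
    md <- sampleMetadata(study)
    abundance <- SummarizedExperiment::assay(proteome(study), "abundance")

    qc <- qcScreen(abundance, md, alpha = config$dixon_alpha,
                   removeOutliers = config$remove_outliers)
    abundance <- qc$abundance
    trans <- transformAbundance(abundance, md)

    dec <- deconvolve(abundance, md, config = config, boxcox = TRUE)
    dr <- doseResponse(trans$transformed, md, config = config)
    sets <- summarizeDoseSets(dr$results, config$posthoc_alpha)

    de <- NULL
    integ <- list(records = NULL, restrictive = NULL, coherence = NA)
    enr <- NULL
    termCmp <- NULL
    if (ncol(transcriptome(study)) >= 4L && nrow(featureMap(study))) {
        de <- transcriptDE(study, config = config)
        geneTable <- data.frame(
            gene_id = de$results$gene_id,
            p = de$results$wald_p,
            direction = signDir(de$results$log2_fold_change),
            stringsAsFactors = FALSE)
        proteinTable <- if (config$integration_protein_test == "dunnett") {
            data.frame(protein_id = dr$results$feature_id,
                       p = dr$results$p_high,
                       direction = dr$results$dir_high,
                       stringsAsFactors = FALSE)
        } else {
            pw <- proteinHighVsControlP(abundance, md)
            data.frame(protein_id = pw$protein_id, p = pw$p,
                       direction = pw$direction, stringsAsFactors = FALSE)
        }
        records <- integrateOmics(proteinTable, geneTable,
                                  featureMap(study))
        restr <- restrictiveIntersection(proteinTable, geneTable,
                                         featureMap(study),
                                         alpha = config$posthoc_alpha)
        integ <- list(records = records, restrictive = restr,
                      coherence = coherenceReport(
                          records, config$fdr_level))
        if (length(geneSets(study))) {
            universe <- geneTable$gene_id[!is.na(geneTable$p)]
            glRestr <- intersect(unique(restr$pairs$gene_id), universe)
            glInteg <- intersect(unique(records$gene_id[
                !is.na(records$bh_adjusted_combined_p) &
                records$bh_adjusted_combined_p <= config$fdr_level]),
                universe)
            eR <- fisherEnrich(glRestr, universe, geneSets(study))
            eI <- fisherEnrich(glInteg, universe, geneSets(study))
            enr <- list(restrictive = eR, integrative = eI)
            termCmp <- compareTermSets(
                eR$set_name[eR$bh_adjusted_p <= config$enrich_alpha],
                eI$set_name[eI$bh_adjusted_p <= config$enrich_alpha])
        }
    }

    corDA <- spearmanCorrelation(md$dose_mGy, md$age_years)
    doseSig <- dr$results$feature_id[
        dr$results$shape %in% c("up", "down") &
        dec$classification$category[
            match(dr$results$feature_id,
                  dec$classification$feature_id)] == "dose_only"]
    clus <- NULL
    if (length(doseSig) >= 2L) {
        dmat <- spearmanDistanceMatrix(
            trans$transformed[doseSig, , drop = FALSE])
        hc <- hierarchicalCluster(dmat)
        clus <- list(order = hc$order, labels2 = hc$cut(2L),
                     features = doseSig)
    }

    summary <- list(
        seed = config$seed,
        n_samples = nrow(md),
        n_proteins = nrow(abundance),
        n_genes = if (is.null(de)) 0L else nrow(de$results),
        dose_age_spearman = round(corDA$rho, 6),
        deconvolution_counts = as.list(dec$counts),
        kw_selected = sum(dr$results$q_value <= config$fdr_level,
                          na.rm = TRUE),
        pi0 = round(dr$pi0, 6),
        shape_counts = as.list(sets$shape_counts),
        group_counts = stats::setNames(
            lapply(seq_len(nrow(sets$group_counts)), function(i)
                list(up = sets$group_counts$up[i],
                     down = sets$group_counts$down[i])),
            sets$group_counts$group),
        de_up = if (is.null(de)) 0L else
            sum(de$results$bh_adjusted_p <= config$fdr_level &
                de$results$log2_fold_change > 0, na.rm = TRUE),
        de_down = if (is.null(de)) 0L else
            sum(de$results$bh_adjusted_p <= config$fdr_level &
                de$results$log2_fold_change < 0, na.rm = TRUE),
        integrative_pairs = if (is.null(integ$records)) 0L else
            sum(integ$records$bh_adjusted_combined_p <= config$fdr_level,
                na.rm = TRUE),
        restrictive_pairs = if (is.null(integ$restrictive)) 0L else
            integ$restrictive$n_pairs,
        coherence = if (is.na(integ$coherence)) NULL else
            round(integ$coherence, 6),
        term_sets = if (is.null(termCmp)) NULL else
            termCmp[c("n_restrictive", "n_integrative", "n_common")])

    out <- list(qc = qc$qc, transform = trans[c("lambda", "shift")],
                deconvolution = dec, dose_response = dr,
                dose_sets = sets, transcript_de = de,
                integration = integ, enrichment = enr,
                term_comparison = termCmp,
                explore = list(dose_age = corDA, clustering = clus),
                summary = summary)

    if (!is.null(outDir)) {
        dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        writeFeatureReport(dec$classification,
                           file.path(outDir, "deconvolution.tsv"))
        writeFeatureReport(dr$results,
                           file.path(outDir, "dose_response.tsv"))
        if (!is.null(de))
            writeFeatureReport(de$results,
                               file.path(outDir, "transcript_de.tsv"))
        if (!is.null(integ$records) && nrow(integ$records))
            writeFeatureReport(integ$records,
                               file.path(outDir, "integration.tsv"))
        jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                             auto_unbox = TRUE, digits = NA,
                             pretty = TRUE, null = "null")
    }
    invisible(out)
}
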