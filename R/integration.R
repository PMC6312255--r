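# Proteome-transcriptome integration: high-vs-control protein tests,
# minimum-p gene selection per protein, Fisher combined p-values with one
# BH correction, and the restrictive-intersection comparator.

#' High-dose vs control protein test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison of the high-dose
#' group with the control group for every protein, exact when the
#' combined sample size is at most 20 and the values are untied.
#' Direction is the sign of the difference of group medians. Proteins
#' lacking two observed values in either group get NA.
#'
#' @param abundance proteins x samples matrix.
#' @param metadata sample covariates aligned to columns.
#' @return data.frame: protein_id, p, direction, n_control, n_high.
#' @export
proteinHighVsControlP <- function(abundance, metadata) {
    ctrl <- metadata$dose_group == "control"
    high <- metadata$dose_group == "high"
    n <- nrow(abundance)
    p <- rep(NA_real_, n)
    dir <- rep(NA_integer_, n)
    nc <- nh <- rep(0L, n)
    for (i in seq_len(n)) {
        a <- abundance[i, ctrl]; a <- a[!is.na(a)]
        b <- abundance[i, high]; b <- b[!is.na(b)]
        nc[i] <- length(a); nh[i] <- length(b)
        if (length(a) < 2L || length(b) < 2L) next
        if (diff(range(c(a, b))) == 0) {
            p[i] <- 1; dir[i] <- 0L
            next
        }
        exact <- (length(a) + length(b)) <= 20L &&
            !anyDuplicated(c(a, b))
        wt <- suppressWarnings(
            stats::wilcox.test(b, a, exact = exact, correct = !exact))
        p[i] <- wt$p.value
        dir[i] <- signDir(stats::median(b) - stats::median(a))
    }
    data.frame(protein_id = rownames(abundance), p = p, direction = dir,
               n_control = nc, n_high = nh, stringsAsFactors = FALSE)
}

#' Fisher's combined probability for a pair of p-values
#'
#' Combines two independent p-values by \code{stat = -2 (ln p1 + ln p2)};
#' under the joint null the statistic is chi-square with 4 degrees of
#' freedom, whose survival function has the closed form
#' \code{exp(-x/2) (1 + x/2)}. Zero p-values are clamped to 1e-300 with
#' a warning (discrete tests can reach machine zero).
#'
#' @param p1,p2 numeric vectors in (0, 1] (recycled to common length).
#' @return list with \code{stat} and \code{p} (the combined p-value).
#' @examples
#' fisherCombine(0.05, 0.05)$p   # about 0.0175
#' @export
fisherCombine <- function(p1, p2) {
    k <- max(length(p1), length(p2))
    p1 <- rep_len(p1, k); p2 <- rep_len(p2, k)
    if (any(is.na(p1)) || any(is.na(p2)) ||
        any(p1 < 0 | p1 > 1) || any(p2 < 0 | p2 > 1))
        stop("p-values must lie in (0, 1]")
    if (any(p1 == 0) || any(p2 == 0)) {
        warning("zero p-value(s) clamped to 1e-300")
        p1 <- pmax(p1, 1e-300); p2 <- pmax(p2, 1e-300)
    }
    stat <- -2 * (log(p1) + log(p2))
    list(stat = stat, p = exp(-stat / 2) * (1 + stat / 2))
}

#' Pair proteins with their minimum-p mapped gene
#'
#' For every protein with at least one mapped, tested gene the gene with
#' the smallest p-value is chosen (ties broken by lexicographic gene
#' id); proteins without any tested mapped gene are reported separately.
#'
#' @param proteinTable data.frame with protein_id, p, direction.
#' @param geneTable data.frame with gene_id, p, direction.
#' @param featureMap data.frame gene_id / protein_id.
#' @return list with \code{pairs} (protein_id, gene_id, protein_p,
#'   gene_p, protein_direction, gene_direction) and \code{unmapped}
#'   (protein ids).
#' @export
mapFeatures <- function(proteinTable, geneTable, featureMap) {
    gT <- geneTable[!is.na(geneTable$p), , drop = FALSE]
    fm <- featureMap[featureMap$gene_id %in% gT$gene_id, , drop = FALSE]
    pT <- proteinTable[!is.na(proteinTable$p), , drop = FALSE]
    fm <- fm[fm$protein_id %in% pT$protein_id, , drop = FALSE]
    fm$gene_p <- gT$p[match(fm$gene_id, gT$gene_id)]
    # order by (protein, p, gene id) so the first row per protein is the
    # minimum-p gene with the lexicographic tie-break
    fm <- fm[order(fm$protein_id, fm$gene_p, fm$gene_id), , drop = FALSE]
    chosen <- fm[!duplicated(fm$protein_id), , drop = FALSE]
    pairs <- data.frame(
        protein_id = chosen$protein_id,
        gene_id = chosen$gene_id,
        protein_p = pT$p[match(chosen$protein_id, pT$protein_id)],
        gene_p = chosen$gene_p,
        protein_direction = pT$direction[match(chosen$protein_id,
                                               pT$protein_id)],
        gene_direction = gT$direction[match(chosen$gene_id, gT$gene_id)],
        stringsAsFactors = FALSE)
    rownames(pairs) <- NULL
    unmapped <- setdiff(proteinTable$protein_id, pairs$protein_id)
    list(pairs = pairs, unmapped = unmapped)
}

#' Integrate proteome and transcriptome evidence per gene-protein pair
#'
#' Builds the matched pairs via \code{\link{mapFeatures}}, combines the
#' two p-values of each pair with \code{\link{fisherCombine}}, applies a
#' single BH correction over all pairs, and flags direction coherence.
#'
#' @inheritParams mapFeatures
#' @return data.frame of integration records: protein_id, gene_id,
#'   protein_p, gene_p, fisher_stat, combined_p, bh_adjusted_combined_p,
#'   protein_direction, gene_direction, coherent.
#' @export
integrateOmics <- function(proteinTable, geneTable, featureMap) {
    mp <- mapFeatures(proteinTable, geneTable, featureMap)
    pairs <- mp$pairs
    if (!nrow(pairs)) {
        pairs$fisher_stat <- pairs$combined_p <-
            pairs$bh_adjusted_combined_p <- numeric(0)
        pairs$coherent <- logical(0)
        return(pairs)
    }
    fc <- fisherCombine(pairs$protein_p, pairs$gene_p)
    pairs$fisher_stat <- fc$stat
    pairs$combined_p <- fc$p
    pairs$bh_adjusted_combined_p <- stats::p.adjust(fc$p, "BH")
    pairs$coherent <- pairs$protein_direction * pairs$gene_direction > 0
    pairs
}

#' Restrictive intersection of independently significant features
#'
#' The comparator to the integrative route: mapped gene-protein pairs
#' whose members are \emph{both} significant at \code{alpha} in their own
#' data set, partitioned by direction agreement.
#'
#' @inheritParams mapFeatures
#' @param alpha per-layer significance level (default 0.05).
#' @return list with \code{pairs} (all qualifying map pairs with a
#'   \code{bucket} column: up_up, down_down or discordant),
#'   \code{n_pairs}, \code{n_proteins}.
#' @export
restrictiveIntersection <- function(proteinTable, geneTable, featureMap,
                                    alpha = 0.05) {
    pSig <- proteinTable[!is.na(proteinTable$p) &
                         proteinTable$p <= alpha, , drop = FALSE]
    gSig <- geneTable[!is.na(geneTable$p) & geneTable$p <= alpha, ,
                      drop = FALSE]
    fm <- featureMap[featureMap$protein_id %in% pSig$protein_id &
                     featureMap$gene_id %in% gSig$gene_id, , drop = FALSE]
    if (nrow(fm)) {
        pd <- pSig$direction[match(fm$protein_id, pSig$protein_id)]
        gd <- gSig$direction[match(fm$gene_id, gSig$gene_id)]
        bucket <- ifelse(pd > 0 & gd > 0, "up_up",
                  ifelse(pd < 0 & gd < 0, "down_down", "discordant"))
        pairs <- data.frame(protein_id = fm$protein_id,
                            gene_id = fm$gene_id,
                            protein_direction = pd, gene_direction = gd,
                            bucket = bucket, stringsAsFactors = FALSE)
    } else {
        pairs <- data.frame(protein_id = character(),
                            gene_id = character(),
                            protein_direction = integer(),
                            gene_direction = integer(),
                            bucket = character(),
                            stringsAsFactors = FALSE)
    }
    rownames(pairs) <- NULL
    list(pairs = pairs, n_pairs = nrow(pairs),
         n_proteins = length(unique(pairs$protein_id)))
}

#' Direction coherence among significant integrated pairs
#'
#' @param records integration records from \code{\link{integrateOmics}}.
#' @param alpha BH threshold on the combined p-value (default 0.05).
#' @return fraction of significant pairs whose protein and gene
#'   directions agree; NA when no pair is significant.
#' @export
coherenceReport <- function(records, alpha = 0.05) {
    sig <- records[!is.na(records$bh_adjusted_combined_p) &
                   records$bh_adjusted_combined_p <= alpha, , drop = FALSE]
    if (!nrow(sig)) return(NA_real_)
    mean(sig$coherent)
}
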