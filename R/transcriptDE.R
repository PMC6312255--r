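# Minimal negative-binomial differential expression for the two-group
# (control vs high dose) transcript design: total-count filter,
# median-of-ratios size factors, method-of-moments dispersions with a
# robust 1/mu trend, and a per-gene NB Wald test with BH correction.

#' Discard transcripts with low total counts
#'
#' A gene is kept iff its total count across all samples is at least
#' \code{minTotal} (strictly-less-than rule: a total equal to the
#' threshold is kept).
#'
#' @param counts genes x samples count matrix.
#' @param minTotal threshold on the per-gene total (default 15).
#' @return list with \code{counts} (kept rows) and \code{removed}
#'   (character vector of discarded gene ids).
#' @export
filterLowCounts <- function(counts, minTotal = 15) {
    keep <- rowSums(counts) >= minTotal
    list(counts = counts[keep, , drop = FALSE],
         removed = rownames(counts)[!keep])
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization constants: the median, over genes expressed
#' in every sample, of the ratio of the sample's count to the gene's
#' geometric mean, rescaled so the factors have geometric mean 1.
#'
#' @param counts genes x samples count matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
medianRatioSizeFactors <- function(counts) {
    if (ncol(counts) == 1L)
        return(stats::setNames(1, colnames(counts)))
    allPos <- rowSums(counts > 0) == ncol(counts)
    if (!any(allPos))
        stop("no gene has positive counts in every sample; ",
             "a pseudo-reference fallback would be required")
    lc <- log(counts[allPos, , drop = FALSE])
    geo <- rowMeans(lc)
    s <- exp(apply(lc - geo, 2L, stats::median))
    s <- s / exp(mean(log(s)))
    stats::setNames(s, colnames(counts))
}

# Robust linear fit of genewise dispersion on 1/mu: one ordinary fit,
# then a refit excluding points whose residuals exceed 2 MADs.
.dispersionTrend <- function(alpha, mu) {
    ok <- is.finite(alpha) & alpha > 0 & is.finite(mu) & mu > 0
    if (sum(ok) < 10L) return(NULL)
    x <- 1 / mu[ok]; y <- alpha[ok]
    fit <- stats::lm(y ~ x)
    r <- stats::resid(fit)
    keep <- abs(r) <= 2 * stats::mad(r) + 1e-12
    if (sum(keep) >= 10L) fit <- stats::lm(y[keep] ~ x[keep])
    cf <- stats::coef(fit)
    function(m) pmax(1e-8, cf[[1L]] + cf[[2L]] / m)
}

#' Estimate per-gene NB dispersions
#'
#' Method-of-moments dispersion on size-factor-normalized counts with
#' group means removed, a robust \code{a0/mu + a1} trend fitted across
#' genes, and conservative moderation: the final dispersion is the
#' larger of the genewise estimate and the trend (genewise estimates
#' that are negative fall back to the trend). Taking the maximum rather
#' than an average removes the chance dispersion underestimates that
#' otherwise inflate the Wald tail at two-versus-two sample sizes.
#' With fewer than 50 genes the trend is skipped and a common
#' dispersion (the median genewise value) takes its place.
#'
#' @param counts genes x samples count matrix (filtered).
#' @param sizeFactors from \code{\link{medianRatioSizeFactors}}.
#' @param group two-level factor over samples; each level needs at least
#'   2 samples.
#' @return numeric vector of final dispersions (floored at 1e-8).
#' @export
estimateNBDispersions <- function(counts, sizeFactors, group) {
    group <- factor(group)
    if (any(table(group) < 2L)) stop("need >= 2 samples per group")
    z <- sweep(counts, 2L, sizeFactors, "/")
    mu <- rowMeans(z)
    groupIdx <- split(seq_len(ncol(z)), group)
    ss <- df <- 0
    for (cols in groupIdx) {
        m <- rowMeans(z[, cols, drop = FALSE])
        ss <- ss + rowSums((z[, cols, drop = FALSE] - m)^2)
        df <- df + length(cols) - 1L
    }
    v <- ss / df
    # MoM: Var(z) ~ mu * mean(1/s) + alpha * mu^2
    shot <- mu * mean(1 / sizeFactors)
    genewise <- (v - shot) / mu^2
    genewise[!is.finite(genewise)] <- NA_real_
    trend <- if (nrow(counts) >= 50L) .dispersionTrend(genewise, mu)
    if (is.null(trend)) {
        common <- stats::median(genewise[is.finite(genewise) &
                                         genewise > 0])
        if (!is.finite(common)) common <- 1e-8
        final <- ifelse(is.finite(genewise) & genewise > 0,
                        pmax(genewise, common), max(1e-8, common))
    } else {
        tr <- trend(mu)
        final <- ifelse(is.finite(genewise) & genewise > 0,
                        pmax(genewise, tr), tr)
    }
    stats::setNames(pmax(final, 1e-8), rownames(counts))
}

# Single-gene NB GLM (log link, offset log size factor, two-group
# design) by iteratively reweighted least squares at fixed dispersion.
.nbWaldGene <- function(y, offset, x, alpha, maxit = 100L) {
    X <- cbind(1, x)
    beta <- c(log(mean(pmax(y, 0.5) / exp(offset))), 0)
    conv <- FALSE
    for (it in seq_len(maxit)) {
        eta <- drop(X %*% beta) + offset
        mu <- pmax(exp(eta), 1e-10)
        w <- mu / (1 + alpha * mu)
        zWork <- drop(X %*% beta) + (y - mu) / mu
        XtW <- t(X * w)
        fisher <- XtW %*% X
        upd <- tryCatch(solve(fisher, XtW %*% zWork),
                        error = function(e) NULL)
        if (is.null(upd) || any(!is.finite(upd))) break
        delta <- max(abs(upd - beta))
        beta <- drop(upd)
        beta <- pmin(pmax(beta, -50), 50)
        if (delta < 1e-8) { conv <- TRUE; break }
    }
    if (!conv)
        return(list(beta = NA_real_, se = NA_real_, p = NA_real_,
                    converged = FALSE))
    eta <- drop(X %*% beta) + offset
    mu <- pmax(exp(eta), 1e-10)
    w <- mu / (1 + alpha * mu)
    fisher <- t(X * w) %*% X
    se <- sqrt(diag(solve(fisher)))[2L]
    zstat <- beta[2L] / se
    list(beta = beta[2L], se = se,
         p = 2 * stats::pnorm(-abs(zstat)), converged = TRUE)
}

#' Negative-binomial Wald test, high dose vs control
#'
#' Per gene, a log-link NB GLM with a group indicator is fitted by
#' iteratively reweighted least squares at the fixed per-gene
#' dispersion; the Wald statistic for the group coefficient is referred
#' to the standard Gaussian and BH-adjusted across tested genes. Genes
#' failing to converge within 100 iterations are flagged with NA
#' p-values.
#'
#' @param counts filtered genes x samples count matrix.
#' @param sizeFactors per-sample factors.
#' @param dispersions per-gene NB dispersions.
#' @param group two-level factor; the \emph{first} level is the
#'   reference (control).
#' @return data.frame: gene_id, base_mean, log2_fold_change, wald_p,
#'   bh_adjusted_p, converged.
#' @export
nbWaldTest <- function(counts, sizeFactors, dispersions, group) {
    group <- factor(group)
    if (nlevels(group) != 2L || any(table(group) < 2L))
        stop("design must have two groups with >= 2 samples each")
    x <- as.numeric(group == levels(group)[2L])
    offset <- log(sizeFactors)
    z <- sweep(counts, 2L, sizeFactors, "/")
    n <- nrow(counts)
    beta <- p <- rep(NA_real_, n)
    converged <- logical(n)
    for (i in seq_len(n)) {
        fit <- .nbWaldGene(counts[i, ], offset, x, dispersions[i])
        beta[i] <- fit$beta
        p[i] <- fit$p
        converged[i] <- fit$converged
    }
    padj <- rep(NA_real_, n)
    padj[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], "BH")
    data.frame(gene_id = rownames(counts),
               base_mean = rowMeans(z),
               log2_fold_change = beta / log(2),
               wald_p = p,
               bh_adjusted_p = padj,
               converged = converged,
               stringsAsFactors = FALSE)
}

#' Within-group replicate correlation
#'
#' Pairwise correlation between samples on the
#' \code{log2(normalized count + 1)} scale, the standard quality check
#' for sequencing replicates.
#'
#' @param counts genes x samples count matrix.
#' @param sizeFactors optional; computed by median-of-ratios if missing.
#' @param method "pearson" (default) or "spearman".
#' @return symmetric sample x sample correlation matrix.
#' @export
replicateCorrelation <- function(counts, sizeFactors = NULL,
                                 method = c("pearson", "spearman")) {
    method <- match.arg(method)
    if (ncol(counts) < 2L) stop("need at least 2 samples")
    if (is.null(sizeFactors))
        sizeFactors <- medianRatioSizeFactors(counts)
    lz <- log2(sweep(counts, 2L, sizeFactors, "/") + 1)
    stats::cor(lz, method = method)
}

#' Two-group transcript differential expression
#'
#' Orchestrates the count filter, size factors, dispersion estimation
#' and the NB Wald test for a control vs high-dose design. Filtered
#' genes are retained in the output with \code{filtered = TRUE} and NA
#' statistics.
#'
#' @param counts genes x samples count matrix, or a
#'   \linkS4class{RadStudy} (its transcriptome assay and dose groups are
#'   used).
#' @param group two-level factor over samples, reference first (derived
#'   from dose groups for a study).
#' @param config a \code{\link{radConfig}}.
#' @return list with \code{results} (DE table over all input genes),
#'   \code{size_factors}, \code{dispersions}, \code{removed}.
#' @examples
#' study <- simulateStudy(seed = 1, nProteins = 40, nGenes = 150)
#' de <- transcriptDE(study)
#' head(de$results)
#' @export
transcriptDE <- function(counts, group = NULL, config = radConfig()) {
    if (is(counts, "RadStudy")) {
        se <- transcriptome(counts)
        group <- factor(
            SummarizedExperiment::colData(se)$dose_group,
            levels = c("control", "high"))
        counts <- SummarizedExperiment::assay(se, "counts")
    }
    group <- droplevels(factor(group))
    flt <- filterLowCounts(counts, config$min_total_counts)
    sf <- medianRatioSizeFactors(flt$counts)
    disp <- estimateNBDispersions(flt$counts, sf, group)
    res <- nbWaldTest(flt$counts, sf, disp, group)
    res$filtered <- FALSE
    if (length(flt$removed)) {
        resF <- data.frame(gene_id = flt$removed, base_mean = NA_real_,
                           log2_fold_change = NA_real_, wald_p = NA_real_,
                           bh_adjusted_p = NA_real_, converged = NA,
                           filtered = TRUE, stringsAsFactors = FALSE)
        res <- rbind(res, resF)
    }
    res <- res[match(rownames(counts), res$gene_id), , drop = FALSE]
    rownames(res) <- NULL
    list(results = res, size_factors = sf, dispersions = disp,
         removed = flt$removed)
}
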