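# Exploratory views: covariate correlation and sample clustering with a
# Spearman correlation distance.

#' Spearman rank correlation with p-value
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' exact permutation distribution for n <= \code{exactMaxN} untied
#' samples and the t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length, n >= 4, non-constant.
#' @param exactMaxN largest n for the exact null (default 9).
#' @return list with \code{rho} and \code{p}.
#' @export
spearmanCorrelation <- function(x, y, exactMaxN = 9L) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 4L) stop("need at least 4 paired values")
    if (diff(range(x)) == 0 || diff(range(y)) == 0)
        stop("constant vector has no defined rank correlation")
    ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman",
                        exact = length(x) <= exactMaxN))
    list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Spearman correlation distance between samples
#'
#' \code{d(i, j) = 1 - rho(sample_i, sample_j)} over the given feature
#' rows; symmetric with a zero diagonal. Distances range in [0, 2]
#' (2 for perfectly anti-correlated profiles).
#'
#' @param abundance features x samples matrix (a feature subset, e.g.
#'   the significant dose-dependent proteins).
#' @return sample x sample distance matrix.
#' @export
spearmanDistanceMatrix <- function(abundance) {
    if (nrow(abundance) < 2L || ncol(abundance) < 2L)
        stop("need at least 2 features and 2 samples")
    constant <- apply(abundance, 2L, function(v)
        diff(range(v, na.rm = TRUE)) == 0)
    if (any(constant))
        stop("constant sample profile: ",
             colnames(abundance)[constant][1L])
    d <- 1 - stats::cor(abundance, method = "spearman",
                        use = "pairwise.complete.obs")
    diag(d) <- 0
    d
}

#' Agglomerative clustering of samples
#'
#' Hierarchical clustering on a precomputed distance matrix (average
#' linkage by default, as is usual with correlation distances), with a
#' cut utility returning k cluster labels.
#'
#' @param d symmetric distance matrix.
#' @param linkage "average" (default), "complete" or "ward.D2".
#' @return list with \code{tree} (hclust), \code{order} (leaf ordering),
#'   \code{cut} (function of k returning integer labels).
#' @examples
#' m <- matrix(rnorm(40), 8, 5)
#' cl <- hierarchicalCluster(spearmanDistanceMatrix(m))
#' cl$cut(2)
#' @export
hierarchicalCluster <- function(d, linkage = c("average", "complete",
                                               "ward.D2")) {
    linkage <- match.arg(linkage)
    n <- nrow(d)
    if (n == 1L) {
        lab <- rownames(d)
        return(list(tree = NULL, order = 1L,
                    cut = function(k) {
                        if (k > 1L) stop("k exceeds the number of samples")
                        stats::setNames(1L, lab)
                    }))
    }
    tree <- stats::hclust(stats::as.dist(d), method = linkage)
    list(tree = tree, order = tree$order,
         cut = function(k) {
             if (k > n) stop("k exceeds the number of samples")
             stats::cutree(tree, k)
         })
}
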