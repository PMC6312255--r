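# Dose-group differential analysis: Kruskal-Wallis screening with Storey
# q-values, Dunnett many-to-one post-hoc tests, and classification of the
# dose-response shape including the non-monotone U / cap patterns.

# All distinct assignments of N items to groups of the given sizes,
# returned as an integer label matrix (assignments x N). Used for the
# exact small-sample Kruskal-Wallis p-value.
.groupAssignments <- function(sizes) {
    n <- sum(sizes)
    rec <- function(avail, sizes) {
        if (length(sizes) == 1L) {
            lab <- integer(n)
            lab[avail] <- 1L
            return(list(lab))
        }
        out <- list()
        sel <- utils::combn(avail, sizes[1L], simplify = FALSE)
        for (s in sel) {
            rest <- rec(setdiff(avail, s), sizes[-1L])
            for (r in rest) {
                r[s] <- length(sizes)
                out[[length(out) + 1L]] <- r
            }
        }
        out
    }
    labs <- rec(seq_len(n), rev(sizes))
    do.call(rbind, lapply(labs, function(l) length(sizes) + 1L - l))
}

.kwStatistic <- function(r, labels, sizes, tieC) {
    N <- length(r)
    sums <- vapply(split(r, labels), sum, numeric(1L))
    (12 / (N * (N + 1)) * sum(sums^2 / sizes) - 3 * (N + 1)) / tieC
}

#' Kruskal-Wallis test with exact small-sample p-value
#'
#' Rank-based k-group comparison with the usual tie correction. For a
#' total sample size of at most \code{exactMaxN} the p-value is computed
#' exactly by enumerating every distinct assignment of the observed
#' ranks to the group sizes; otherwise the chi-square approximation with
#' g - 1 degrees of freedom is used. A sample in which every value is
#' tied yields H = 0, p = 1.
#'
#' @param values numeric vector (NA dropped together with its label).
#' @param groups group labels, any type coercible to factor; at least two
#'   groups with two or more observations each.
#' @param exactMaxN largest total n for which the exact permutation null
#'   is enumerated (default 10).
#' @return list with \code{H}, \code{p} and \code{method} ("exact" or
#'   "chisq").
#' @examples
#' kruskalWallis(1:12, rep(1:4, each = 3))$H
#' @export
kruskalWallis <- function(values, groups, exactMaxN = 10L) {
    ok <- !is.na(values) & !is.na(groups)
    values <- values[ok]
    groups <- factor(groups[ok])
    groups <- droplevels(groups)
    sizes <- table(groups)
    if (length(sizes) < 2L || any(sizes < 2L))
        stop("need at least 2 groups with at least 2 values each")
    if (diff(range(values)) == 0)
        return(list(H = 0, p = 1, method = "degenerate"))
    N <- length(values)
    r <- rank(values)
    ties <- table(values)
    tieC <- 1 - sum(ties^3 - ties) / (N^3 - N)
    labels <- as.integer(groups)
    H <- .kwStatistic(r, labels, as.numeric(sizes), tieC)
    if (N <= exactMaxN) {
        labs <- .groupAssignments(as.integer(sizes))
        Hperm <- apply(labs, 1L, function(l)
            .kwStatistic(r, l, as.numeric(sizes), tieC))
        # the observed labelling is one of the enumerated ones, so the
        # exact p is the fraction of assignments at least as extreme
        p <- mean(Hperm >= H - 1e-12)
        method <- "exact"
    } else {
        p <- stats::pchisq(H, df = length(sizes) - 1L, lower.tail = FALSE)
        method <- "chisq"
    }
    list(H = H, p = p, method = method)
}

#' Storey q-values with fixed lambda
#'
#' Estimates the null proportion as
#' \code{pi0 = min(1, #\{p > lambda\} / (m (1 - lambda)))} and converts
#' p-values to q-values by the step-up cumulative-minimum rule
#' \code{q_(i) = min_(j >= i) pi0 m p_(j) / j}. When pi0 caps at 1 the
#' q-values coincide exactly with Benjamini-Hochberg adjusted p-values.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param lambda tuning constant in (0, 1), default 0.5.
#' @return list with \code{q} (same order as input) and \code{pi0}.
#' @export
storeyQvalues <- function(p, lambda = 0.5) {
    if (!length(p)) stop("empty p-value vector")
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    q <- pmin(1, cummin(pi0 * m * p[o] / (m:1)))[ro]
    list(q = q, pi0 = pi0)
}

#' Dunnett many-to-one comparisons against the control group
#'
#' Two-sided comparisons of each treatment group with the shared control
#' using pooled-variance t statistics. Family-wise adjusted p-values are
#' tail probabilities of the k-variate t distribution with the standard
#' Dunnett correlation \code{rho_ij = sqrt(n_i n_j / ((n_i + n0)(n_j +
#' n0)))}, evaluated by the Genz-Bretz quasi-Monte-Carlo algorithm at
#' absolute tolerance 1e-4 from a fixed seed, so repeated calls give
#' identical output.
#'
#' @param values numeric vector.
#' @param groups factor; its first level (or \code{control}) is the
#'   control group. Every group needs at least 2 values.
#' @param control name of the control level.
#' @param seed integer seed for the quasi-Monte-Carlo integration.
#' @return data.frame with one row per treatment group: \code{group},
#'   \code{estimate} (treatment mean minus control mean), \code{t},
#'   \code{p_adj}, \code{direction} (-1, 0, 1).
#' @export
dunnettVsControl <- function(values, groups, control = "control",
                             seed = 1L) {
    ok <- !is.na(values) & !is.na(groups)
    values <- values[ok]
    groups <- droplevels(factor(groups[ok]))
    if (!control %in% levels(groups))
        stop("control level '", control, "' not present")
    groups <- stats::relevel(groups, control)
    sizes <- table(groups)
    if (any(sizes < 2L))
        stop("every group needs at least 2 values")
    g <- length(sizes)
    k <- g - 1L
    means <- tapply(values, groups, mean)
    vars <- tapply(values, groups, stats::var)
    N <- length(values)
    df <- N - g
    s2 <- sum((sizes - 1) * vars) / df
    if (s2 <= 0) stop("zero pooled variance")
    n0 <- sizes[1L]
    ni <- sizes[-1L]
    est <- means[-1L] - means[1L]
    tstat <- est / sqrt(s2 * (1 / ni + 1 / n0))
    R <- diag(k)
    for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
        R[i, j] <- sqrt(ni[i] * ni[j] /
                        ((ni[i] + n0) * (ni[j] + n0)))
    padj <- withSeed(seed, vapply(abs(tstat), function(tt) {
        pr <- mvtnorm::pmvt(lower = rep(-tt, k), upper = rep(tt, k),
                            df = df, corr = R,
                            algorithm = mvtnorm::GenzBretz(
                                abseps = 1e-4, maxpts = 100000L))
        min(1, max(0, 1 - as.numeric(pr)))
    }, numeric(1L)))
    data.frame(group = names(sizes)[-1L],
               estimate = as.numeric(est),
               t = as.numeric(tstat),
               p_adj = padj,
               direction = signDir(as.numeric(est)),
               stringsAsFactors = FALSE)
}

#' Classify a protein's dose-response shape
#'
#' A feature is \code{flat} when its Storey q-value exceeds the FDR
#' level. Otherwise, when at least one Dunnett comparison is significant
#' and all significant comparisons share a direction, the shape is
#' \code{up} or \code{down}; in the remaining cases (no significant
#' comparison, or mixed directions) the quadratic contrast over the
#' ordered dose-group means decides between \code{u_shape} (positive
#' curvature) and \code{cap_shape} (negative curvature).
#'
#' @param q Storey q-value of the feature.
#' @param dunnett data.frame from \code{\link{dunnettVsControl}}.
#' @param groupMeans mean transformed abundance per dose group, ordered
#'   control, low, medium, high (names optional).
#' @param fdr_level,posthoc_alpha thresholds (defaults 0.05).
#' @return one of "flat", "up", "down", "u_shape", "cap_shape".
#' @export
classifyShape <- function(q, dunnett, groupMeans, fdr_level = 0.05,
                          posthoc_alpha = 0.05) {
    if (is.na(q) || q > fdr_level) return("flat")
    sig <- dunnett$p_adj <= posthoc_alpha
    dirs <- dunnett$direction[sig]
    if (length(dirs) && all(dirs > 0)) return("up")
    if (length(dirs) && all(dirs < 0)) return("down")
    ok <- !is.na(groupMeans)
    rk <- seq_along(groupMeans)[ok] - 1
    mm <- groupMeans[ok]
    if (length(mm) < 3L) return("flat")
    curv <- stats::coef(stats::lm(mm ~ rk + I(rk^2)))[["I(rk^2)"]]
    if (curv >= 0) "u_shape" else "cap_shape"
}

#' Dose-group differential analysis across a proteome
#'
#' Per feature: Kruskal-Wallis over the four dose groups, Storey
#' q-values across features, Dunnett post-hoc comparisons against the
#' control for the q-selected features, and dose-response shape
#' classification. Features lacking two observed values in two or more
#' groups are skipped (NA statistics, shape "flat").
#'
#' @param abundance proteins x samples matrix on the analysis
#'   (transformed) scale, or a \linkS4class{RadStudy} (then the abundance
#'   assay is Box-Cox transformed first).
#' @param metadata sample covariates (ignored for a study).
#' @param config a \code{\link{radConfig}}.
#' @return list with \code{results} (per-feature data.frame: feature_id,
#'   kw_H, kw_p, q_value, p_low, dir_low, p_medium, dir_medium, p_high,
#'   dir_high, shape) and \code{pi0}.
#' @examples
#' study <- simulateStudy(seed = 1, nProteins = 40, nGenes = 100)
#' dr <- doseResponse(study)
#' table(dr$results$shape)
#' @export
doseResponse <- function(abundance, metadata = NULL, config = radConfig()) {
    if (is(abundance, "RadStudy")) {
        metadata <- sampleMetadata(abundance)
        abundance <- transformAbundance(
            SummarizedExperiment::assay(proteome(abundance),
                                        "abundance"), metadata)$transformed
    }
    stopifnot(ncol(abundance) == nrow(metadata))
    grp <- factor(metadata$dose_group, levels = .doseGroupLevels)
    nf <- nrow(abundance)
    H <- p <- rep(NA_real_, nf)
    for (i in seq_len(nf)) {
        v <- abundance[i, ]
        ok <- !is.na(v)
        sizes <- table(grp[ok])
        if (sum(sizes >= 2L) < 2L) next
        keep <- ok & grp %in% names(sizes)[sizes >= 2L]
        kw <- kruskalWallis(v[keep], droplevels(grp[keep]))
        H[i] <- kw$H
        p[i] <- kw$p
    }
    tested <- which(!is.na(p))
    q <- rep(NA_real_, nf)
    pi0 <- NA_real_
    if (length(tested)) {
        sq <- storeyQvalues(p[tested], config$storey_lambda)
        q[tested] <- sq$q
        pi0 <- sq$pi0
    }
    treatments <- setdiff(.doseGroupLevels, "control")
    pd <- matrix(NA_real_, nf, 3L, dimnames = list(NULL, treatments))
    dd <- matrix(NA_integer_, nf, 3L, dimnames = list(NULL, treatments))
    shape <- rep("flat", nf)
    sel <- which(!is.na(q) & q <= config$fdr_level)
    dunnettSeed <- childSeed(config$seed, "dunnett")
    for (i in sel) {
        v <- abundance[i, ]
        ok <- !is.na(v)
        dn <- tryCatch(
            dunnettVsControl(v[ok], grp[ok], seed = dunnettSeed),
            error = function(e) NULL)
        if (is.null(dn)) next
        pd[i, dn$group] <- dn$p_adj
        dd[i, dn$group] <- dn$direction
        gm <- tapply(v[ok], grp[ok], mean)[.doseGroupLevels]
        shape[i] <- classifyShape(q[i], dn, gm, config$fdr_level,
                                  config$posthoc_alpha)
    }
    results <- data.frame(
        feature_id = rownames(abundance),
        kw_H = H, kw_p = p, q_value = q,
        p_low = pd[, "low"], dir_low = dd[, "low"],
        p_medium = pd[, "medium"], dir_medium = dd[, "medium"],
        p_high = pd[, "high"], dir_high = dd[, "high"],
        shape = shape,
        stringsAsFactors = FALSE)
    list(results = results, pi0 = pi0)
}

#' Summarize significant dose-response sets
#'
#' Produces the per-group counts of strictly up- and down-regulated
#' proteins (features whose shape is monotone and whose Dunnett
#' comparison in that group is significant in the matching direction),
#' the number of non-monotone (U / cap) features, and the Venn-cell
#' overlaps of the per-group up and down sets.
#'
#' @param results per-feature table from \code{\link{doseResponse}}.
#' @param posthoc_alpha Dunnett significance level.
#' @return list with \code{group_counts} (data.frame group/up/down),
#'   \code{shape_counts}, \code{venn_up}, \code{venn_down} (named counts
#'   of the 7 Venn cells over low/medium/high membership).
#' @export
summarizeDoseSets <- function(results, posthoc_alpha = 0.05) {
    treatments <- c("low", "medium", "high")
    memb <- function(dirWanted) {
        keep <- results$shape == ifelse(dirWanted > 0, "up", "down")
        m <- vapply(treatments, function(g) {
            pa <- results[[paste0("p_", g)]]
            di <- results[[paste0("dir_", g)]]
            keep & !is.na(pa) & pa <= posthoc_alpha &
                !is.na(di) & di == dirWanted
        }, logical(nrow(results)))
        matrix(m, nrow = nrow(results), ncol = length(treatments),
               dimnames = list(NULL, treatments))
    }
    vennCells <- function(m) {
        if (!is.matrix(m)) m <- matrix(m, ncol = 3L,
                                       dimnames = list(NULL, treatments))
        cells <- c("low", "medium", "high", "low&medium", "low&high",
                   "medium&high", "low&medium&high")
        key <- apply(m, 1L, function(r)
            paste(treatments[r], collapse = "&"))
        tab <- table(factor(key[key != ""], levels = cells))
        stats::setNames(as.integer(tab), cells)
    }
    up <- memb(1L); down <- memb(-1L)
    group_counts <- data.frame(
        group = treatments,
        up = colSums(up), down = colSums(down),
        row.names = NULL, stringsAsFactors = FALSE)
    shape_counts <- table(factor(results$shape,
                                 levels = c("up", "down", "u_shape",
                                            "cap_shape", "flat")))
    list(group_counts = group_counts,
         shape_counts = stats::setNames(as.integer(shape_counts),
                                        names(shape_counts)),
         venn_up = vennCells(up), venn_down = vennCells(down))
}
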