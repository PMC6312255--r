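# Per-feature QC: Dixon outlier screen, normality assessment, Box-Cox.

# -- Dixon ratio test ---------------------------------------------------

# Ratio variant depends on sample size, following standard practice:
# r10 for n <= 7, r11 for 8-10, r21 for 11-13, r22 for n >= 14.
# Returns the ratios for the low and the high extreme of sorted x.
.dixonRatios <- function(xs) {
    n <- length(xs)
    if (n <= 7L) {
        lo <- (xs[2L] - xs[1L]) / (xs[n] - xs[1L])
        hi <- (xs[n] - xs[n - 1L]) / (xs[n] - xs[1L])
    } else if (n <= 10L) {
        lo <- (xs[2L] - xs[1L]) / (xs[n - 1L] - xs[1L])
        hi <- (xs[n] - xs[n - 1L]) / (xs[n] - xs[2L])
    } else if (n <= 13L) {
        lo <- (xs[3L] - xs[1L]) / (xs[n - 1L] - xs[1L])
        hi <- (xs[n] - xs[n - 2L]) / (xs[n] - xs[2L])
    } else {
        lo <- (xs[3L] - xs[1L]) / (xs[n - 2L] - xs[1L])
        hi <- (xs[n] - xs[n - 2L]) / (xs[n] - xs[3L])
    }
    c(low = lo, high = hi)
}

# Vectorised version over a matrix of row-sorted samples (rows = draws).
.dixonStatMatrix <- function(xs) {
    n <- ncol(xs)
    if (n <= 7L) {
        lo <- (xs[, 2L] - xs[, 1L]) / (xs[, n] - xs[, 1L])
        hi <- (xs[, n] - xs[, n - 1L]) / (xs[, n] - xs[, 1L])
    } else if (n <= 10L) {
        lo <- (xs[, 2L] - xs[, 1L]) / (xs[, n - 1L] - xs[, 1L])
        hi <- (xs[, n] - xs[, n - 1L]) / (xs[, n] - xs[, 2L])
    } else if (n <= 13L) {
        lo <- (xs[, 3L] - xs[, 1L]) / (xs[, n - 1L] - xs[, 1L])
        hi <- (xs[, n] - xs[, n - 2L]) / (xs[, n] - xs[, 2L])
    } else {
        lo <- (xs[, 3L] - xs[, 1L]) / (xs[, n - 2L] - xs[, 1L])
        hi <- (xs[, n] - xs[, n - 2L]) / (xs[, n] - xs[, 3L])
    }
    pmax(lo, hi)
}

.dixonCache <- new.env(parent = emptyenv())

#' Critical value of the two-sided Dixon outlier test
#'
#' Critical values are generated once per sample size by Monte Carlo under
#' the Gaussian null (statistic: the larger of the low- and high-extreme
#' Dixon ratios, variant chosen by n) from a fixed internal seed, then
#' cached for the session. They agree with published two-sided tables to
#' Monte-Carlo accuracy.
#'
#' @param n sample size, 3 to 30.
#' @param alpha test level: 0.01, 0.05 or 0.10.
#' @param nrep Monte Carlo draws (default 1e6).
#' @return the (1 - alpha) null quantile of the two-sided Dixon ratio.
#' @export
dixonCritical <- function(n, alpha = 0.05, nrep = 1e6) {
    stopifnot(n >= 3L, n <= 30L)
    if (!alpha %in% c(0.01, 0.05, 0.10))
        stop("alpha must be one of 0.01, 0.05, 0.10")
    key <- sprintf("n%02d", n)
    if (is.null(.dixonCache[[key]])) {
        .dixonCache[[key]] <- withSeed(20150 + n, {
            chunk <- 1e5L
            stat <- numeric(0)
            reps <- 0L
            while (reps < nrep) {
                m <- min(chunk, nrep - reps)
                x <- matrix(stats::rnorm(m * n), m, n)
                xs <- matrix(x[order(row(x), x)], m, n, byrow = TRUE)
                stat <- c(stat, .dixonStatMatrix(xs))
                reps <- reps + m
            }
            stats::quantile(stat, c(0.90, 0.95, 0.99), names = FALSE)
        })
    }
    .dixonCache[[key]][match(alpha, c(0.10, 0.05, 0.01))]
}

#' Dixon outlier screen for a small sample
#'
#' Two-sided Dixon ratio test for a single outlying value in a sample of
#' 3 to 30 observations. The ratio variant follows the sample size (r10
#' up to n = 7, r11 for 8-10, r21 for 11-13, r22 beyond); the larger of
#' the low- and high-extreme ratios is compared with the Monte-Carlo null
#' quantile from \code{\link{dixonCritical}}. At most one value is
#' flagged per call; a zero-range sample flags nothing. The decision is
#' invariant under affine transforms with positive slope.
#'
#' @param values numeric vector, length 3 to 30, no NA.
#' @param alpha level: 0.01, 0.05 or 0.10.
#' @return list with \code{flags} (logical vector, at most one TRUE),
#'   \code{statistic}, \code{critical} and \code{index} (NA when nothing
#'   is flagged).
#' @examples
#' dixonOutlier(c(1, 2, 3, 4, 100))$index
#' @export
dixonOutlier <- function(values, alpha = 0.05) {
    if (anyNA(values) || !is.numeric(values))
        stop("values must be numeric without NA")
    n <- length(values)
    if (n < 3L) stop("Dixon test needs at least 3 values")
    if (n > 30L) stop("Dixon test supports at most 30 values")
    flags <- logical(n)
    if (diff(range(values)) == 0)
        return(list(flags = flags, statistic = 0,
                    critical = dixonCritical(n, alpha), index = NA_integer_))
    ord <- order(values)
    r <- .dixonRatios(values[ord])
    stat <- max(r)
    crit <- dixonCritical(n, alpha)
    idx <- NA_integer_
    if (is.finite(stat) && stat > crit) {
        idx <- if (which.max(r) == 1L) ord[1L] else ord[n]
        flags[idx] <- TRUE
    }
    list(flags = flags, statistic = unname(stat), critical = unname(crit),
         index = idx)
}

#' Shapiro-Wilk normality p-value
#'
#' Thin wrapper over \code{\link[stats]{shapiro.test}} with the argument
#' checks the pipeline relies on (3 <= n <= 5000, non-constant input).
#'
#' @param values numeric vector.
#' @return p-value for the null hypothesis of normality.
#' @export
shapiroNormality <- function(values) {
    values <- values[!is.na(values)]
    if (length(values) < 3L || length(values) > 5000L)
        stop("Shapiro-Wilk requires 3 to 5000 values")
    if (diff(range(values)) == 0) stop("constant sample has no defined test")
    stats::shapiro.test(values)$p.value
}

# Box-Cox profile log-likelihood for positive y at a vector of lambdas.
# With a design matrix X the likelihood is profiled over the regression
# coefficients (classical Box-Cox for a linear model); without one the
# model is intercept-only, i.e. the marginal transform.
.boxcoxLoglik <- function(y, lambdas, qrX = NULL) {
    n <- length(y)
    w <- log(y)
    wbar <- mean(w)
    # evaluate on geometric-mean-scaled data: algebraically identical to
    # the usual -n/2 log Var(z) + (lambda-1) sum(log y), but immune to
    # variance underflow when the data sit far from 1 on the log scale
    d <- exp(w - wbar)
    vapply(lambdas, function(l) {
        z <- if (abs(l) < 1e-12) w - wbar else (d^l - 1) / l
        v <- if (is.null(qrX)) mean((z - mean(z))^2)
             else sum(qr.resid(qrX, z)^2) / n
        if (!is.finite(v) || v <= 0) return(-Inf)
        -n / 2 * log(v) - n * wbar
    }, numeric(1L))
}

#' Box-Cox transformation by profile maximum likelihood
#'
#' Estimates the power-transform parameter lambda by maximising the
#' profile log-likelihood over a dense grid on [-3, 3] (step 0.01)
#' followed by golden-section refinement within the bracketing grid
#' cells. Non-positive inputs are first shifted by \code{1 - min(y)} so
#' the transform is defined; the shift is reported. The transform is
#' \code{(y^lambda - 1)/lambda} for lambda != 0 and \code{log(y)} at 0.
#'
#' When a design matrix \code{X} is supplied the likelihood is profiled
#' over its regression coefficients (the classical Box-Cox procedure for
#' a linear model), so lambda normalizes the model residuals rather than
#' the marginal distribution; without it the model is intercept-only and
#' the marginal transform is returned.
#'
#' @param values numeric vector; finite, at least 3 distinct values.
#' @param gridFrom,gridTo,gridBy search grid for lambda.
#' @param X optional design matrix (including the intercept column)
#'   aligned to \code{values}.
#' @param snap replace the continuous MLE by the nearest interpretable
#'   exponent (-2, -1, -1/2, 0, 1/3, 1/2, 1, 2) whenever that value lies
#'   inside the 95 percent profile-likelihood interval (the usual
#'   recommendation for power transforms, and it avoids carrying
#'   estimation noise in lambda into downstream regressions). Default
#'   FALSE: return the exact MLE.
#' @return list with \code{lambda}, \code{shift}, \code{transformed},
#'   \code{loglik} (profile log-likelihood at lambda).
#' @examples
#' r <- boxcoxTransform(exp(rnorm(100)))
#' abs(r$lambda) < 0.5
#' @export
boxcoxTransform <- function(values, gridFrom = -3, gridTo = 3,
                            gridBy = 0.01, X = NULL, snap = FALSE) {
    if (any(!is.finite(values))) stop("values must be finite")
    if (length(unique(values)) < 3L)
        stop("need at least 3 distinct values")
    shift <- if (min(values) <= 0) 1 - min(values) else 0
    y <- values + shift
    qrX <- if (!is.null(X)) qr(X)
    grid <- seq(gridFrom, gridTo, by = gridBy)
    ll <- .boxcoxLoglik(y, grid, qrX)
    i <- which.max(ll)
    lo <- grid[max(1L, i - 1L)]
    hi <- grid[min(length(grid), i + 1L)]
    # golden-section refinement inside the bracketing cells
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- .boxcoxLoglik(y, x1, qrX); f2 <- .boxcoxLoglik(y, x2, qrX)
    while (b - a > 1e-6) {
        if (f1 < f2) {
            a <- x1; x1 <- x2; f1 <- f2
            x2 <- a + gr * (b - a); f2 <- .boxcoxLoglik(y, x2, qrX)
        } else {
            b <- x2; x2 <- x1; f2 <- f1
            x1 <- b - gr * (b - a); f1 <- .boxcoxLoglik(y, x1, qrX)
        }
    }
    lambda <- (a + b) / 2
    llHat <- .boxcoxLoglik(y, lambda, qrX)
    if (llHat < ll[i]) { lambda <- grid[i]; llHat <- ll[i] }
    if (snap) {
        # 95% profile-likelihood interval (chi-square-1 cutoff)
        inCI <- grid[ll >= llHat - stats::qchisq(0.95, 1) / 2]
        ladder <- c(-2, -1, -0.5, 0, 1 / 3, 0.5, 1, 2)
        ok <- ladder >= min(inCI) & ladder <= max(inCI)
        if (any(ok)) {
            lambda <- ladder[ok][which.min(abs(ladder[ok] - lambda))]
            llHat <- .boxcoxLoglik(y, lambda, qrX)
        }
    }
    z <- if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
    list(lambda = lambda, shift = shift, transformed = z, loglik = llHat)
}

#' Transform an abundance matrix feature-wise by Box-Cox
#'
#' Applies \code{\link{boxcoxTransform}} to each protein across all
#' samples (missing values are excluded and remain missing in the
#' output). When \code{metadata} is given, lambda is profiled against
#' the full covariate model (dose, age, dose x age, BMI) so the
#' transform normalizes the model residuals instead of the raw marginal,
#' which would otherwise be warped by strong covariate effects.
#' Features with fewer than 3 distinct observed values are returned
#' untransformed with lambda NA.
#'
#' @param abundance proteins x samples numeric matrix.
#' @param metadata optional sample covariates aligned to columns.
#' @param snap snap lambda to interpretable exponents when supported by
#'   the profile likelihood (default TRUE; see
#'   \code{\link{boxcoxTransform}}).
#' @return list with \code{transformed} (same shape as input),
#'   \code{lambda} and \code{shift} per-feature vectors.
#' @export
transformAbundance <- function(abundance, metadata = NULL, snap = TRUE) {
    out <- abundance
    Xfull <- if (!is.null(metadata))
        cbind(1, as.matrix(.modelCovariates(metadata)))
    lambda <- shift <- rep(NA_real_, nrow(abundance))
    for (i in seq_len(nrow(abundance))) {
        ok <- !is.na(abundance[i, ])
        y <- abundance[i, ok]
        if (length(unique(y)) < 3L) next
        r <- boxcoxTransform(y, X = if (is.null(Xfull)) NULL
                                    else Xfull[ok, , drop = FALSE],
                             snap = snap)
        out[i, ok] <- r$transformed
        lambda[i] <- r$lambda
        shift[i] <- r$shift
    }
    names(lambda) <- names(shift) <- rownames(abundance)
    list(transformed = out, lambda = lambda, shift = shift)
}

#' Per-feature, per-group outlier and normality QC table
#'
#' Runs the Dixon screen and the Shapiro-Wilk test within each dose group
#' for every feature, mirroring the per-protein QC stage of the pipeline.
#' Flags are reported, not removed, unless \code{removeOutliers} is TRUE,
#' in which case flagged values are set to NA in the returned matrix.
#'
#' @param abundance proteins x samples matrix.
#' @param metadata sample covariates aligned to columns.
#' @param alpha Dixon level.
#' @param removeOutliers replace flagged values by NA (default FALSE).
#' @return list with \code{qc} (data.frame: feature_id, group, n,
#'   outlier_flagged, outlier_sample, shapiro_p) and \code{abundance}
#'   (possibly with outliers blanked).
#' @export
qcScreen <- function(abundance, metadata, alpha = 0.05,
                     removeOutliers = FALSE) {
    groups <- split(seq_len(ncol(abundance)), metadata$dose_group)
    rows <- list()
    out <- abundance
    for (g in names(groups)) {
        cols <- groups[[g]]
        for (i in seq_len(nrow(abundance))) {
            v <- abundance[i, cols]
            ok <- !is.na(v)
            flagged <- FALSE; outlierSample <- NA_character_
            shp <- NA_real_
            if (sum(ok) >= 3L && diff(range(v[ok])) > 0) {
                dx <- dixonOutlier(v[ok], alpha)
                if (!is.na(dx$index)) {
                    flagged <- TRUE
                    outlierSample <- colnames(abundance)[cols][ok][dx$index]
                    if (removeOutliers)
                        out[i, match(outlierSample,
                                     colnames(abundance))] <- NA_real_
                }
                shp <- shapiroNormality(v[ok])
            }
            rows[[length(rows) + 1L]] <- data.frame(
                feature_id = rownames(abundance)[i], group = g,
                n = sum(ok), outlier_flagged = flagged,
                outlier_sample = outlierSample, shapiro_p = shp,
                stringsAsFactors = FALSE)
        }
    }
    list(qc = do.call(rbind, rows), abundance = out)
}
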