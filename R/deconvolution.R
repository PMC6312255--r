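# Dose/age confounder deconvolution: per-protein backward stepwise OLS
# with AIC, then classification of each protein's dependence structure.

.deconvTerms <- c("dose", "age", "dose_age", "bmi")

# Standardized covariate frame used by all per-feature model fits.
# Dose enters as a continuous standardized covariate; the interaction is
# the product of the standardized main effects.
.modelCovariates <- function(metadata) {
    std <- function(x) {
        s <- stats::sd(x)
        if (s == 0) x - mean(x) else (x - mean(x)) / s
    }
    d <- std(metadata$dose_mGy)
    a <- std(metadata$age_years)
    data.frame(dose = d, age = a, dose_age = d * a,
               bmi = std(metadata$bmi))
}

# Lean OLS with Gaussian log-likelihood and per-coefficient p-values.
# AIC counts the intercept, the slope terms and the residual variance.
.olsFit <- function(y, X, termNames) {
    n <- length(y)
    qrx <- qr(X)
    if (qrx$rank < ncol(X)) {
        bad <- colnames(X)[qrx$pivot[seq(qrx$rank + 1L, ncol(X))]]
        stop("rank-deficient design; collinear term(s): ",
             paste(bad, collapse = ", "))
    }
    coef <- qr.coef(qrx, y)
    res <- y - X %*% coef
    rss <- sum(res^2)
    p <- ncol(X)
    df <- n - p
    sigma2 <- rss / df
    XtXinv <- chol2inv(qr.R(qrx))
    se <- sqrt(diag(XtXinv) * sigma2)
    tval <- coef / se
    pval <- 2 * stats::pt(-abs(tval), df)
    ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
    aic <- 2 * (p + 1) - 2 * ll
    list(terms = termNames, coef = coef, se = se, p = pval,
         loglik = ll, aic = aic, n = n, df = df)
}

#' Fit the per-protein covariate model
#'
#' Ordinary least squares of a (transformed) protein abundance on any
#' subset of the standardized covariate terms dose, age, dose x age and
#' BMI, with intercept. The reported AIC is \code{2k - 2 logLik} with k
#' counting the intercept, slopes and the residual variance.
#'
#' @param y numeric response (transformed abundances).
#' @param terms character subset of \code{c("dose", "age", "dose_age",
#'   "bmi")}; empty for intercept-only.
#' @param metadata sample covariates aligned to \code{y}.
#' @return list with coefficient table components (\code{terms},
#'   \code{coef}, \code{se}, \code{p}), \code{loglik}, \code{aic}.
#' @export
fitDoseAgeModel <- function(y, terms, metadata) {
    stopifnot(all(terms %in% .deconvTerms))
    cov <- .modelCovariates(metadata)
    ok <- !is.na(y)
    if (sum(ok) <= length(terms) + 2L)
        stop("too few observations for ", length(terms), " terms")
    X <- cbind("(Intercept)" = 1,
               as.matrix(cov[ok, terms, drop = FALSE]))
    .olsFit(y[ok], X, c("(Intercept)", terms))
}

#' Backward stepwise model selection by AIC
#'
#' Starts from the full model (dose, age, dose x age, BMI) and removes,
#' at each step, the single term whose removal lowers AIC the most,
#' until no removal lowers AIC. Marginality is respected: a main effect
#' can only be dropped after the dose x age interaction. Exact AIC ties
#' are broken by removing the term with the larger coefficient p-value
#' in the current model.
#'
#' @inheritParams fitDoseAgeModel
#' @param fullTerms starting term set (default all four).
#' @return the final model as returned by \code{\link{fitDoseAgeModel}},
#'   with an extra element \code{path} recording the removed terms in
#'   order.
#' @export
backwardStepwiseAIC <- function(y, metadata,
                                fullTerms = .deconvTerms) {
    terms <- fullTerms
    fit <- fitDoseAgeModel(y, terms, metadata)
    path <- character()
    repeat {
        removable <- terms
        if ("dose_age" %in% terms)
            removable <- setdiff(removable, c("dose", "age"))
        if (!length(removable)) break
        cand <- lapply(removable, function(t)
            fitDoseAgeModel(y, setdiff(terms, t), metadata))
        aics <- vapply(cand, `[[`, numeric(1L), "aic")
        if (min(aics) >= fit$aic - 1e-12) break
        best <- which(aics <= min(aics) + 1e-10)
        if (length(best) > 1L) {
            pcur <- fit$p[match(removable[best], fit$terms)]
            best <- best[which.max(pcur)]
        } else best <- best[1L]
        path <- c(path, removable[best])
        terms <- setdiff(terms, removable[best])
        fit <- cand[[best]]
    }
    fit$path <- path
    fit
}

#' Classify a protein's covariate dependence
#'
#' Applies the category rules to the final stepwise model: a protein is
#' dose-only dependent when the dose term is retained and significant
#' while neither age nor the dose x age interaction is; age-only is the
#' symmetric case; dose-and-age when both main effects are significant
#' or the interaction is; BMI when only the BMI term is significant;
#' anything else (including the intercept-only model) is unclassified
#' ("none").
#'
#' @param model final model from \code{\link{backwardStepwiseAIC}}.
#' @param alpha coefficient significance level (default 0.05).
#' @return one of "dose_only", "age_only", "dose_age", "bmi", "none".
#' @export
classifyDependency <- function(model, alpha = 0.05) {
    sig <- model$terms[model$terms != "(Intercept)" & model$p < alpha]
    doseSig <- "dose" %in% sig
    ageSig <- "age" %in% sig
    intSig <- "dose_age" %in% sig
    bmiSig <- "bmi" %in% sig
    if (intSig || (doseSig && ageSig)) return("dose_age")
    if (doseSig && !ageSig) return("dose_only")
    if (ageSig && !doseSig) return("age_only")
    if (bmiSig) return("bmi")
    "none"
}

#' Deconvolve dose and age dependence across a proteome
#'
#' Per protein: Box-Cox transform across samples, backward stepwise AIC
#' model selection over {dose, age, dose x age, BMI}, and category
#' assignment via \code{\link{classifyDependency}}. Proteins with too few
#' observed values are reported as "none" with NA model columns.
#'
#' @param abundance proteins x samples matrix (raw scale; transformed
#'   internally), or a \linkS4class{RadStudy}.
#' @param metadata sample covariates (ignored when a study is given).
#' @param config a \code{\link{radConfig}}.
#' @param boxcox transform each feature before fitting (default TRUE).
#' @return list with \code{classification} (data.frame: feature_id,
#'   category, retained, p_dose, p_age, p_dose_age, p_bmi, aic, lambda)
#'   and \code{counts} (named vector of category counts summing to the
#'   number of features).
#' @examples
#' study <- simulateStudy(seed = 1, nProteins = 40, nGenes = 100)
#' dec <- deconvolve(study)
#' dec$counts
#' @export
deconvolve <- function(abundance, metadata = NULL, config = radConfig(),
                       boxcox = TRUE) {
    if (is(abundance, "RadStudy")) {
        metadata <- sampleMetadata(abundance)
        abundance <- SummarizedExperiment::assay(proteome(abundance),
                                                 "abundance")
    }
    stopifnot(ncol(abundance) == nrow(metadata))
    nf <- nrow(abundance)
    category <- rep("none", nf)
    retained <- character(nf)
    pmat <- matrix(NA_real_, nf, 4L,
                   dimnames = list(NULL, .deconvTerms))
    aic <- lambda <- rep(NA_real_, nf)
    Xfull <- cbind(1, as.matrix(.modelCovariates(metadata)))
    for (i in seq_len(nf)) {
        y <- abundance[i, ]
        ok <- !is.na(y)
        if (sum(ok) < 10L || length(unique(y[ok])) < 3L) next
        if (boxcox) {
            # lambda profiled against the full covariate model, so the
            # transform Gaussianizes residuals, not the signal-bearing
            # marginal
            bc <- boxcoxTransform(y[ok], X = Xfull[ok, , drop = FALSE],
                                  snap = TRUE)
            y[ok] <- bc$transformed
            lambda[i] <- bc$lambda
        }
        fit <- backwardStepwiseAIC(y, metadata)
        category[i] <- classifyDependency(fit, config$coef_alpha)
        kept <- setdiff(fit$terms, "(Intercept)")
        retained[i] <- paste(kept, collapse = ",")
        pmat[i, kept] <- fit$p[match(kept, fit$terms)]
        aic[i] <- fit$aic
    }
    classification <- data.frame(
        feature_id = rownames(abundance),
        category = category,
        retained = retained,
        p_dose = pmat[, "dose"], p_age = pmat[, "age"],
        p_dose_age = pmat[, "dose_age"], p_bmi = pmat[, "bmi"],
        aic = aic, lambda = lambda,
        stringsAsFactors = FALSE)
    counts <- table(factor(category,
                           levels = c("dose_only", "age_only", "dose_age",
                                      "bmi", "none")))
    list(classification = classification,
         counts = stats::setNames(as.integer(counts), names(counts)))
}
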