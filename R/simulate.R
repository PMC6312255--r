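#' Simulate the worker cohort covariates
#'
#' Draws a cohort with the dose-group structure of the study design:
#' unexposed controls plus low (<100 mGy), medium (100-500 mGy) and high
#' (>500 mGy) exposure groups. Age is coupled to dose through a Gaussian
#' copula on the dose ranks so that the realized Spearman correlation is
#' close to \code{doseAgeRho} (the cohort the generator emulates shows
#' rho about 0.7). BMI is independent of both; all subjects are smokers
#' and drinkers, so these covariates carry no information.
#'
#' @param groupSizes integer vector of length 4: control, low, medium,
#'   high group sizes (default \code{c(3, 6, 10, 10)}).
#' @param doseAgeRho target Spearman correlation between dose and age,
#'   in (0, 1) (default 0.7). Attained within about +/-0.1 at the default
#'   sizes; a warning is emitted for very small cohorts where the rank
#'   coupling is necessarily coarse.
#' @param seed integer seed.
#' @param ageMean,ageSd marginal age distribution in years (default 60, 8).
#' @param bmiMean,bmiSd marginal BMI distribution (default 27, 3).
#' @return data.frame of sample covariates (one row per sample) with
#'   columns sample_id, dose_mGy, dose_group, age_years, bmi, smoker,
#'   drinker.
#' @examples
#' md <- simulateCohort(seed = 1)
#' table(md$dose_group)
#' @export
simulateCohort <- function(groupSizes = c(3L, 6L, 10L, 10L),
                           doseAgeRho = 0.7, seed = 1L,
                           ageMean = 60, ageSd = 8,
                           bmiMean = 27, bmiSd = 3) {
    stopifnot(length(groupSizes) == 4L, all(groupSizes >= 2L),
              doseAgeRho > 0, doseAgeRho < 1)
    n <- sum(groupSizes)
    if (n < 10L)
        warning("very small cohort: target dose-age correlation is ",
                "attained only approximately")
    withSeed(seed, {
        dose <- c(rep(0, groupSizes[1L]),
                  stats::runif(groupSizes[2L], 10, 99),
                  stats::runif(groupSizes[3L], 100, 500),
                  stats::runif(groupSizes[4L], 501, 2000))
        # Gaussian copula: normal scores of the dose ranks, mixed with
        # independent noise at the latent correlation that maps to the
        # requested Spearman rho for a bivariate Gaussian.
        rhoLatent <- 2 * sin(pi * doseAgeRho / 6)
        zd <- stats::qnorm((rank(dose, ties.method = "random") - 0.5) / n)
        za <- rhoLatent * zd + sqrt(1 - rhoLatent^2) * stats::rnorm(n)
        age <- stats::qnorm(stats::pnorm(za), mean = ageMean, sd = ageSd)
        bmi <- pmax(16, stats::rnorm(n, bmiMean, bmiSd))
        data.frame(
            sample_id = sprintf("S%02d", seq_len(n)),
            dose_mGy = round(dose, 1),
            dose_group = assignDoseGroup(dose),
            age_years = round(age, 1),
            bmi = round(bmi, 1),
            smoker = TRUE,
            drinker = TRUE,
            stringsAsFactors = FALSE)
    })
}

# Non-monotone group-mean patterns over ordered dose-group ranks 0..3,
# in residual-SD units before scaling by the planted effect size. The
# cap (inverted-U) pattern rises from control through the intermediate
# groups and falls below baseline at the highest doses; the U pattern is
# its mirror image. Both have a clear quadratic-contrast curvature.
.capPattern <- c(0, 1.0, 1.4, -0.9)
.uPattern <- -.capPattern

.proteomeCategories <- c("dose_only", "age_only", "dose_age", "bmi",
                         "none", "u_shape", "cap_shape")

#' Simulate a protein abundance matrix with planted covariate dependence
#'
#' Models protein expression on the log scale over a simulated cohort
#' and emits raw instrument-scale intensities (the exponential of the
#' modelled log-abundance), leaving the normalizing transform to the
#' analysis pipeline, as with real label-free LC-MS/MS data. Each
#' feature belongs to one planted category: dose-only, age-only,
#' dose-and-age, BMI-dependent, null, or one of the two non-monotone
#' dose-response shapes (U / cap). Linear effects enter the log scale
#' through scaled covariates (dose/1000, (age - mean)/10,
#' (bmi - mean)/5) with coefficients sized so that each active covariate
#' contributes \code{effectSize} residual standard deviations of signal
#' across the cohort; shape features instead receive the fixed
#' group-rank patterns with amplitude \code{effectSize * noiseSd}.
#'
#' @param metadata cohort covariates from \code{\link{simulateCohort}}.
#' @param nFeatures number of proteins (>= 10).
#' @param categoryProportions named numeric vector over the seven
#'   categories; must sum to 1.
#' @param effectSize planted effect in units of residual SD (default 3).
#' @param noiseSd residual standard deviation on the log-abundance scale.
#' @param naFraction fraction of entries set missing completely at random.
#' @param seed integer seed.
#' @return list with elements \code{abundance} (matrix proteins x
#'   samples of positive raw-scale intensities) and \code{truth}
#'   (data.frame: feature_id, true_category, effect_size,
#'   true_direction, and the planted log-scale coefficients beta_dose,
#'   beta_age, beta_bmi).
#' @export
simulateProteome <- function(metadata, nFeatures = 300,
                             categoryProportions = c(
                                 dose_only = 0.25, age_only = 0.12,
                                 dose_age = 0.08, bmi = 0.02, none = 0.45,
                                 u_shape = 0.04, cap_shape = 0.04),
                             effectSize = 3, noiseSd = 1,
                             naFraction = 0, seed = 1L) {
    if (nFeatures < 10L) stop("nFeatures must be at least 10")
    stopifnot(setequal(names(categoryProportions), .proteomeCategories),
              abs(sum(categoryProportions) - 1) < 1e-8,
              all(categoryProportions >= 0))
    n <- nrow(metadata)
    d <- metadata$dose_mGy / 1000
    a <- (metadata$age_years - mean(metadata$age_years)) / 10
    b <- (metadata$bmi - mean(metadata$bmi)) / 5
    rk <- as.integer(metadata$dose_group) - 1L   # group rank 0..3
    withSeed(seed, {
        counts <- floor(nFeatures * categoryProportions[.proteomeCategories])
        rem <- nFeatures - sum(counts)
        if (rem > 0) {
            top <- order(categoryProportions[.proteomeCategories],
                         decreasing = TRUE)[seq_len(rem)]
            counts[top] <- counts[top] + 1L
        }
        category <- sample(rep(.proteomeCategories, counts))
        ids <- sprintf("P%04d", seq_len(nFeatures))
        betaD <- betaA <- betaB <- numeric(nFeatures)
        sgn <- sample(c(-1, 1), nFeatures, replace = TRUE)
        scaleTo <- function(x) if (stats::sd(x) > 0) stats::sd(x) else 1
        sdD <- scaleTo(d); sdA <- scaleTo(a); sdB <- scaleTo(b)
        doseDep <- category %in% c("dose_only", "dose_age")
        ageDep <- category %in% c("age_only", "dose_age")
        betaD[doseDep] <- sgn[doseDep] * effectSize * noiseSd / sdD
        betaA[ageDep] <- sgn[ageDep] * effectSize * noiseSd / sdA
        # dose+age features: independent sign for the age component
        both <- category == "dose_age"
        betaA[both] <- sample(c(-1, 1), sum(both), replace = TRUE) *
            effectSize * noiseSd / sdA
        betaB[category == "bmi"] <- sgn[category == "bmi"] *
            effectSize * noiseSd / sdB
        # natural-log intensity around 25 (raw MS1 intensities of the
        # order 1e10-1e11), spread 2 log units across proteins
        baseline <- stats::rnorm(nFeatures, 25, 2)
        signal <- outer(betaD, d) + outer(betaA, a) + outer(betaB, b)
        isU <- category == "u_shape"
        isCap <- category == "cap_shape"
        if (any(isU))
            signal[isU, ] <- signal[isU, , drop = FALSE] +
                effectSize * noiseSd *
                matrix(.uPattern[rk + 1L], sum(isU), n, byrow = TRUE)
        if (any(isCap))
            signal[isCap, ] <- signal[isCap, , drop = FALSE] +
                effectSize * noiseSd *
                matrix(.capPattern[rk + 1L], sum(isCap), n, byrow = TRUE)
        y <- baseline + signal +
            matrix(stats::rnorm(nFeatures * n, 0, noiseSd), nFeatures, n)
        # emit instrument-scale intensities: the analysis pipeline is
        # responsible for finding the normalizing (log) transform
        y <- exp(y)
        dimnames(y) <- list(ids, metadata$sample_id)
        if (naFraction > 0) {
            drop <- which(stats::runif(length(y)) < naFraction)
            y[drop] <- NA_real_
        }
        direction <- ifelse(doseDep, ifelse(betaD > 0, "up", "down"), "none")
        eff <- ifelse(category == "none", 0, effectSize)
        truth <- data.frame(
            feature_id = ids,
            true_category = category,
            effect_size = eff,
            true_direction = direction,
            beta_dose = betaD, beta_age = betaA, beta_bmi = betaB,
            stringsAsFactors = FALSE)
        list(abundance = y, truth = truth)
    })
}

#' Simulate a paired two-group transcript count matrix
#'
#' Emulates the study's RNA design: two usable control and two usable
#' high-dose samples drawn from the cohort, with negative-binomial counts.
#' Genes mapped (via \code{featureMap}) to dose-affected proteins receive,
#' with probability \code{coherentFraction}, a fold change in the same
#' direction as the planted protein effect; all other genes are null.
#' Library sizes vary uniformly within +/-30 percent of \code{depth}.
#'
#' @param metadata cohort covariates; must contain at least
#'   \code{nPerGroup} control and high-dose samples.
#' @param featureMap data.frame with gene_id, protein_id.
#' @param proteinTruth truth table from \code{\link{simulateProteome}}.
#' @param nGenes total genes in the matrix (mapped genes plus nulls).
#' @param depth expected library size in reads per sample (default 1e6).
#' @param dispersion central NB dispersion alpha (per-gene values scatter
#'   around it log-normally; default 0.05, a typical bulk RNA-seq scale).
#' @param foldChange fold applied to coherent DE genes (default 4).
#' @param coherentFraction probability that a gene paired to a
#'   dose-affected protein is truly differential (default 0.8).
#' @param nPerGroup samples per group (default 2, the study's usable
#'   design).
#' @param seed integer seed.
#' @return list with \code{counts} (genes x samples integer matrix) and
#'   \code{truth} (gene_id, paired_protein, true_fold, true_direction).
#' @export
simulateTranscriptome <- function(metadata, featureMap, proteinTruth,
                                  nGenes = 2000, depth = 1e6,
                                  dispersion = 0.05, foldChange = 4,
                                  coherentFraction = 0.8, nPerGroup = 2L,
                                  seed = 1L) {
    if (depth <= 0) stop("depth must be positive")
    ctrl <- metadata$sample_id[metadata$dose_group == "control"]
    high <- metadata$sample_id[metadata$dose_group == "high"]
    if (length(ctrl) < nPerGroup || length(high) < nPerGroup)
        stop("need at least ", nPerGroup, " control and high-dose samples")
    samples <- c(ctrl[seq_len(nPerGroup)], high[seq_len(nPerGroup)])
    isHigh <- rep(c(0, 1), each = nPerGroup)
    mapped <- unique(featureMap$gene_id)
    if (length(mapped) > nGenes)
        stop("nGenes smaller than the number of mapped genes")
    ids <- c(mapped, sprintf("G%05d", seq_len(nGenes - length(mapped))))
    withSeed(seed, {
        dirOf <- proteinTruth$true_direction[
            match(featureMap$protein_id, proteinTruth$feature_id)]
        pairedDir <- dirOf[match(ids, featureMap$gene_id)]
        pairedDir[is.na(pairedDir)] <- "none"
        de <- pairedDir != "none" &
            stats::runif(length(ids)) < coherentFraction
        fold <- rep(1, length(ids))
        fold[de & pairedDir == "up"] <- foldChange
        fold[de & pairedDir == "down"] <- 1 / foldChange
        q <- stats::rlnorm(length(ids), 0, 1.5)
        q <- q / sum(q * sqrt(fold))          # keep total depth roughly flat
        s <- stats::runif(length(samples), 0.7, 1.3)
        alpha <- dispersion * exp(stats::rnorm(length(ids), 0, 0.25))
        mu <- depth * outer(q, s) * outer(fold, isHigh, function(f, h) f^h)
        counts <- matrix(stats::rnbinom(length(mu), mu = mu,
                                        size = rep(1 / alpha,
                                                   length(samples))),
                         nrow = length(ids))
        dimnames(counts) <- list(ids, samples)
        truth <- data.frame(
            gene_id = ids,
            paired_protein = featureMap$protein_id[
                match(ids, featureMap$gene_id)],
            true_fold = fold,
            true_direction = ifelse(fold > 1, "up",
                             ifelse(fold < 1, "down", "none")),
            stringsAsFactors = FALSE)
        list(counts = counts, truth = truth)
    })
}

# Random gene-to-protein map: a fraction of proteins carries one or two
# transcripts; gene ids are derived from the protein id so paired
# features are recognizable in reports.
.simulateFeatureMap <- function(proteinIds, mappedFraction = 0.6,
                                twoGeneFraction = 0.2) {
    mapped <- proteinIds[stats::runif(length(proteinIds)) < mappedFraction]
    nGenes <- 1L + (stats::runif(length(mapped)) < twoGeneFraction)
    data.frame(
        gene_id = paste0("g.", rep(mapped, nGenes), ".",
                         sequence(nGenes)),
        protein_id = rep(mapped, nGenes),
        stringsAsFactors = FALSE)
}

# Gene-set collection over the simulated universe: one set collecting
# dose-affected genes (a planted pathway) and random sets of nulls.
.simulateGeneSets <- function(geneTruth, nSets = 12L, setSize = c(15L, 50L)) {
    deGenes <- geneTruth$gene_id[geneTruth$true_direction != "none"]
    nullGenes <- geneTruth$gene_id[geneTruth$true_direction == "none"]
    sets <- list()
    if (length(deGenes) >= 5L) {
        s <- deGenes
        attr(s, "description") <- "planted dose-responsive pathway"
        sets[["planted_dose_pathway"]] <- s
    }
    for (i in seq_len(nSets)) {
        k <- sample(seq(setSize[1L], setSize[2L]), 1L)
        s <- sample(nullGenes, min(k, length(nullGenes)))
        attr(s, "description") <- "random background set"
        sets[[sprintf("random_set_%02d", i)]] <- s
    }
    sets
}

#' Simulate a complete paired-omics study
#'
#' Convenience wrapper chaining \code{\link{simulateCohort}},
#' \code{\link{simulateProteome}}, a random gene-protein feature map,
#' \code{\link{simulateTranscriptome}} and synthetic gene sets into a
#' single \linkS4class{RadStudy} with ground truth attached. All stages
#' draw from child seeds derived from \code{seed}, so the full bundle is
#' reproducible and stages can be re-run in isolation.
#'
#' @param seed integer master seed.
#' @param groupSizes,doseAgeRho passed to \code{\link{simulateCohort}}.
#' @param nProteins,effectSize,noiseSd,categoryProportions passed to
#'   \code{\link{simulateProteome}}.
#' @param nGenes,depth,dispersion,foldChange,coherentFraction passed to
#'   \code{\link{simulateTranscriptome}}.
#' @param config a \code{\link{radConfig}}.
#' @return a \linkS4class{RadStudy} whose \code{truthTables} hold the
#'   proteome and transcriptome ground truth.
#' @examples
#' study <- simulateStudy(seed = 1, nProteins = 50, nGenes = 200)
#' study
#' @export
simulateStudy <- function(seed = 1L, groupSizes = c(3L, 6L, 10L, 10L),
                          doseAgeRho = 0.7, nProteins = 300,
                          effectSize = 3, noiseSd = 1,
                          categoryProportions = c(
                              dose_only = 0.25, age_only = 0.12,
                              dose_age = 0.08, bmi = 0.02, none = 0.45,
                              u_shape = 0.04, cap_shape = 0.04),
                          nGenes = 2000, depth = 1e6, dispersion = 0.05,
                          foldChange = 4, coherentFraction = 0.8,
                          config = radConfig(seed = seed)) {
    md <- simulateCohort(groupSizes, doseAgeRho,
                         seed = childSeed(seed, "cohort"))
    prot <- simulateProteome(md, nProteins,
                             categoryProportions = categoryProportions,
                             effectSize = effectSize, noiseSd = noiseSd,
                             seed = childSeed(seed, "proteome"))
    fmap <- withSeed(childSeed(seed, "feature_map"),
                     .simulateFeatureMap(prot$truth$feature_id))
    trans <- simulateTranscriptome(md, fmap, prot$truth, nGenes = nGenes,
                                   depth = depth, dispersion = dispersion,
                                   foldChange = foldChange,
                                   coherentFraction = coherentFraction,
                                   seed = childSeed(seed, "transcriptome"))
    gs <- withSeed(childSeed(seed, "gene_sets"),
                   .simulateGeneSets(trans$truth))
    RadStudy(prot$abundance, md, counts = trans$counts, featureMap = fmap,
             geneSets = gs, config = config,
             truth = list(proteome = prot$truth,
                          transcriptome = trans$truth))
}
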