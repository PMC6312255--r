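test_that("the low-count filter applies the strict-less-than rule", {
    cnt <- rbind(g14 = c(7, 7, 0, 0), g15 = c(5, 5, 5, 0),
                 g16 = c(4, 4, 4, 4), g0 = c(0, 0, 0, 0))
    flt <- filterLowCounts(cnt, 15)
    expect_equal(rownames(flt$counts), c("g15", "g16"))
    expect_equal(sort(flt$removed), c("g0", "g14"))
    # min_total = 0 keeps everything
    expect_equal(nrow(filterLowCounts(cnt, 0)$counts), 4L)
})

test_that("median-of-ratios size factors behave canonically", {
    set.seed(30)
    base <- matrix(rnbinom(400, mu = 50, size = 5) + 1, 100, 4,
                   dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:4)))
    # identical columns: all factors one
    same <- base[, c(1, 1, 1)]
    colnames(same) <- paste0("s", 1:3)
    expect_equal(unname(medianRatioSizeFactors(same)), rep(1, 3))
    # doubling one column doubles its factor relative to the others
    dbl <- base
    dbl[, 2] <- base[, 2] * 2
    sf <- medianRatioSizeFactors(dbl)
    expect_equal(unname(sf[2] / sf[1]),
                 unname(2 * medianRatioSizeFactors(base)[2] /
                        medianRatioSizeFactors(base)[1]),
                 tolerance = 1e-6)
    # invariant to gene reordering
    expect_equal(medianRatioSizeFactors(dbl[sample(100), ]), sf)
    # scaling all counts leaves renormalized factors unchanged
    expect_equal(medianRatioSizeFactors(dbl * 3), sf, tolerance = 1e-12)
    # single sample
    expect_equal(unname(medianRatioSizeFactors(base[, 1, drop = FALSE])), 1)
    zero <- matrix(c(0, 1, 1, 0), 2, 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
    expect_error(medianRatioSizeFactors(zero), "pseudo-reference")
})

test_that("size factors agree with the DESeq2 reference", {
    skip_if_not_installed("DESeq2")
    set.seed(33)
    cnt <- matrix(rnbinom(2000, mu = exp(rnorm(500, 4, 1)), size = 10),
                  500, 4, dimnames = list(sprintf("g%03d", 1:500),
                                          paste0("s", 1:4)))
    cnt[, 3] <- cnt[, 3] * 2
    ref <- DESeq2::estimateSizeFactorsForMatrix(cnt)
    ours <- medianRatioSizeFactors(cnt)
    # same up to overall scaling convention
    expect_equal(ours / ours[1], ref / ref[1], tolerance = 1e-6)
})

test_that("dispersion estimation brackets the generating value", {
    set.seed(34)
    grp <- factor(rep(1:2, each = 2))
    # Poisson data: dispersion near zero
    mu <- exp(rnorm(800, 5, 1))
    pois <- matrix(rpois(800 * 4, rep(mu, 4)), 800)
    rownames(pois) <- sprintf("g%04d", 1:800)
    dP <- estimateNBDispersions(pois, rep(1, 4), grp)
    expect_lte(median(dP), 0.05)
    # NB alpha = 0.2: noisy at 2v2 but the centre is right
    nb <- matrix(rnbinom(800 * 4, mu = rep(mu, 4), size = 5), 800)
    rownames(nb) <- sprintf("g%04d", 1:800)
    dN <- estimateNBDispersions(nb, rep(1, 4), grp)
    expect_gte(median(dN), 0.1)
    expect_lte(median(dN), 0.4)
    # constant gene: floored, never negative
    cc <- rbind(flat = c(50, 50, 50, 50), nb[1:60, ])
    dC <- estimateNBDispersions(cc, rep(1, 4), grp)
    expect_gte(min(dC), 1e-8)
    expect_error(estimateNBDispersions(nb, rep(1, 4), factor(c(1, 1, 1, 2))),
                 ">= 2 samples")
})

test_that("the NB Wald test is symmetric and recovers planted folds", {
    set.seed(35)
    mu <- exp(rnorm(300, 5, 1))
    fold <- rep(c(1, 4), c(250, 50))
    cnt <- cbind(matrix(rnbinom(600, mu = rep(mu, 2), size = 20), 300),
                 matrix(rnbinom(600, mu = rep(mu * fold, 2), size = 20), 300))
    rownames(cnt) <- sprintf("g%03d", 1:300)
    colnames(cnt) <- paste0("s", 1:4)
    sf <- medianRatioSizeFactors(cnt)
    disp <- estimateNBDispersions(cnt, sf, twoGroup22)
    res <- nbWaldTest(cnt, sf, disp, twoGroup22)
    expect_equal(median(res$log2_fold_change[fold == 4], na.rm = TRUE), 2,
                 tolerance = 0.35)
    # swapping group labels negates the fold and keeps p
    swapped <- nbWaldTest(cnt, sf, disp,
                          factor(rep(c("high", "control"), each = 2),
                                 levels = c("control", "high")))
    ok <- res$converged & swapped$converged
    expect_equal(res$log2_fold_change[ok], -swapped$log2_fold_change[ok],
                 tolerance = 1e-6)
    expect_equal(res$wald_p[ok], swapped$wald_p[ok], tolerance = 1e-6)
    # permuting samples within groups changes nothing
    perm <- nbWaldTest(cnt[, c(2, 1, 4, 3)], sf[c(2, 1, 4, 3)], disp,
                       twoGroup22)
    expect_equal(res$wald_p, perm$wald_p, tolerance = 1e-9)
    expect_true(all(res$bh_adjusted_p >= res$wald_p - 1e-12, na.rm = TRUE))
})

test_that("null genes stay near the nominal BH level", {
    set.seed(36)
    hits <- m <- 0
    for (i in 1:8) {
        mu <- exp(rnorm(400, 5, 1))
        cnt <- matrix(rnbinom(1600, mu = rep(mu, 4),
                              size = 1 / 0.05), 400)
        rownames(cnt) <- sprintf("g%03d", 1:400)
        colnames(cnt) <- paste0("s", 1:4)
        flt <- filterLowCounts(cnt)
        sf <- medianRatioSizeFactors(flt$counts)
        disp <- estimateNBDispersions(flt$counts, sf, twoGroup22)
        res <- nbWaldTest(flt$counts, sf, disp, twoGroup22)
        hits <- hits + sum(res$bh_adjusted_p <= 0.05, na.rm = TRUE)
        m <- m + sum(!is.na(res$bh_adjusted_p))
    }
    expect_lte(hits / m, 0.07)
})

test_that("replicate correlation behaves on duplicates, noise and data", {
    set.seed(37)
    cnt <- matrix(rnbinom(600, mu = exp(rnorm(300, 5, 1)), size = 10),
                  300, 2, dimnames = list(NULL, c("a", "b")))
    dup <- cbind(a = cnt[, 1], b = cnt[, 1])
    expect_equal(replicateCorrelation(dup)[1, 2], 1)
    indep <- matrix(rpois(2000, lambda = rep(exp(rnorm(1000, 3, 2)))),
                    1000, 2)
    indep[, 2] <- sample(indep[, 2])     # break the shared mean structure
    colnames(indep) <- c("a", "b")
    expect_lt(abs(replicateCorrelation(indep + 1)[1, 2]), 0.35)
    # spearman variant runs and is bounded
    rs <- replicateCorrelation(cnt, method = "spearman")
    expect_true(all(abs(rs) <= 1))
    expect_error(replicateCorrelation(cnt[, 1, drop = FALSE]), "2 samples")
})

test_that("the end-to-end DE wrapper flags filtered genes correctly", {
    study <- tinyStudy(seed = 40, nProteins = 30, nGenes = 400)
    de <- transcriptDE(study)
    res <- de$results
    expect_equal(nrow(res), 400L)
    expect_true(all(is.na(res$wald_p[res$filtered])))
    expect_true(all(res$gene_id[res$filtered] %in% de$removed))
    tested <- !res$filtered & !is.na(res$wald_p)
    expect_true(all(res$bh_adjusted_p[tested] >= res$wald_p[tested] - 1e-12))
})
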