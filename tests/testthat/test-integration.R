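test_that("the high-vs-control protein test matches rank enumeration", {
    md <- simulateCohort(seed = 1)
    # complete separation, 3 controls vs 10 high: the exact two-sided
    # Mann-Whitney p is 2 / choose(13, 3) by enumeration of rank splits
    ab <- matrix(NA_real_, 2, 29,
                 dimnames = list(c("sep", "same"), md$sample_id))
    ctrl <- md$dose_group == "control"; high <- md$dose_group == "high"
    ab["sep", ctrl] <- 1:3
    ab["sep", high] <- 11:20
    ab["same", ctrl] <- c(5, 6, 7)
    ab["same", high] <- c(5, 6, 7, 5, 6, 7, 5, 6, 7, 5)
    res <- proteinHighVsControlP(ab, md)
    expect_equal(res$p[1], 2 / choose(13, 3), tolerance = 1e-12)
    expect_equal(res$direction[1], 1L)
    # swapping the groups flips the direction, not the p
    ab2 <- ab
    ab2["sep", ctrl] <- 11:13
    ab2["sep", high] <- 1:10
    res2 <- proteinHighVsControlP(ab2, md)
    expect_equal(res2$p[1], res$p[1], tolerance = 1e-12)
    expect_equal(res2$direction[1], -1L)
    # identical distributions with ties only: p = 1 regime
    expect_gt(res$p[2], 0.5)
    allSame <- ab
    allSame["same", ctrl] <- 4
    allSame["same", high] <- 4
    res3 <- proteinHighVsControlP(allSame, md)
    expect_equal(res3$p[2], 1)
    expect_equal(res3$direction[2], 0L)
})

test_that("Fisher combination matches its closed form and is calibrated", {
    fc <- fisherCombine(1, 1)
    expect_equal(fc$stat, 0)
    expect_equal(fc$p, 1)
    expect_equal(fisherCombine(0.05, 0.05)$p, 0.0025 * (1 - log(0.0025)),
                 tolerance = 1e-9)
    expect_equal(fisherCombine(0.01, 0.5)$p, 0.005 * (1 - log(0.005)),
                 tolerance = 1e-9)
    # closed form equals the chi-square-4 survival function
    x <- seq(0.1, 40, by = 0.1)
    expect_equal(exp(-x / 2) * (1 + x / 2),
                 pchisq(x, df = 4, lower.tail = FALSE),
                 tolerance = 1e-10)
    # symmetry and monotonicity
    expect_equal(fisherCombine(0.03, 0.4)$p, fisherCombine(0.4, 0.03)$p)
    ps <- fisherCombine(seq(0.01, 0.99, 0.01), 0.2)$p
    expect_true(all(diff(ps) > 0))
    expect_error(fisherCombine(1.5, 0.2), "0, 1")
    expect_warning(fisherCombine(0, 0.2), "clamped")
})

test_that("BH adjustment follows the step-up rule", {
    expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
                 rep(0.04, 4))
    expect_equal(p.adjust(0.2, "BH"), 0.2)
    p <- runif(30)
    expect_true(all(p.adjust(p, "BH") >= p))
})

test_that("feature mapping picks the minimum-p gene deterministically", {
    pT <- data.frame(protein_id = c("P1", "P2", "P3"),
                     p = c(0.01, 0.02, 0.2), direction = c(1L, -1L, 1L))
    gT <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     p = c(0.01, 0.2, 0.05, 0.05),
                     direction = c(1L, 1L, -1L, 1L))
    fm <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                     protein_id = c("P1", "P1", "P2", "P2"))
    mp <- mapFeatures(pT, gT, fm)
    expect_equal(mp$pairs$gene_id[mp$pairs$protein_id == "P1"], "g1")
    # tie at p = 0.05: lexicographically smaller id wins
    expect_equal(mp$pairs$gene_id[mp$pairs$protein_id == "P2"], "g3")
    expect_equal(mp$unmapped, "P3")
    # NA gene p excludes the gene from consideration
    gT$p[1] <- NA
    mp2 <- mapFeatures(pT, gT, fm)
    expect_equal(mp2$pairs$gene_id[mp2$pairs$protein_id == "P1"], "g2")
})

test_that("integration records carry combined p, BH and coherence", {
    pT <- data.frame(protein_id = paste0("P", 1:4),
                     p = c(0.01, 0.04, 0.5, 0.9),
                     direction = c(1L, -1L, 1L, -1L))
    gT <- data.frame(gene_id = paste0("g", 1:4),
                     p = c(0.005, 0.03, 0.6, 0.8),
                     direction = c(1L, 1L, 1L, -1L))
    fm <- data.frame(gene_id = paste0("g", 1:4),
                     protein_id = paste0("P", 1:4))
    rec <- integrateOmics(pT, gT, fm)
    expect_equal(rec$fisher_stat,
                 -2 * (log(pT$p) + log(gT$p)), tolerance = 1e-12)
    expect_equal(rec$combined_p,
                 exp(-rec$fisher_stat / 2) * (1 + rec$fisher_stat / 2),
                 tolerance = 1e-12)
    expect_equal(rec$bh_adjusted_combined_p,
                 p.adjust(rec$combined_p, "BH"), tolerance = 1e-12)
    expect_equal(rec$coherent, c(TRUE, FALSE, TRUE, TRUE))
    expect_equal(coherenceReport(rec, alpha = 0.05), 0.5)
    expect_true(is.na(coherenceReport(rec, alpha = 1e-9)))
})

test_that("the restrictive intersection buckets by direction", {
    pT <- data.frame(protein_id = paste0("P", 1:3),
                     p = c(0.01, 0.02, 0.5), direction = c(-1L, 1L, 1L))
    gT <- data.frame(gene_id = paste0("g", 1:3),
                     p = c(0.01, 0.04, 0.01), direction = c(-1L, -1L, 1L))
    fm <- data.frame(gene_id = paste0("g", 1:3),
                     protein_id = paste0("P", 1:3))
    ri <- restrictiveIntersection(pT, gT, fm)
    expect_equal(ri$n_pairs, 2L)        # P3 fails the protein side
    expect_equal(sort(ri$pairs$bucket), c("discordant", "down_down"))
    expect_equal(ri$n_proteins, 2L)
    # disjoint significant sets: empty
    ri0 <- restrictiveIntersection(pT[3, ], gT[1:2, ], fm)
    expect_equal(ri0$n_pairs, 0L)
})

test_that("combined p-values of independent uniforms stay uniform", {
    set.seed(71)
    p1 <- runif(20000); p2 <- runif(20000)
    cp <- fisherCombine(p1, p2)$p
    expect_lt(abs(mean(cp <= 0.05) - 0.05), 0.006)
    expect_lt(abs(mean(cp <= 0.5) - 0.5), 0.012)
})

test_that("integrative detection dominates the restrictive comparator", {
    # concordant planted effects; protein-level true positives
    for (s in c(2, 5)) {
        md <- simulateCohort(seed = s)
        sim <- simulateProteome(md, nFeatures = 60,
            categoryProportions = c(dose_only = 0.3, age_only = 0,
                dose_age = 0, bmi = 0, none = 0.7, u_shape = 0,
                cap_shape = 0), effectSize = 3, seed = s + 7000)
        fmap <- identityMap(sim$truth)
        tx <- simulateTranscriptome(md, fmap, sim$truth, nGenes = 300,
                                    coherentFraction = 1, seed = s + 800)
        pT <- proteinHighVsControlP(sim$abundance, md)
        de <- transcriptDE(tx$counts, group = twoGroup22)
        gT <- data.frame(gene_id = de$results$gene_id,
                         p = de$results$wald_p,
                         direction = sign(de$results$log2_fold_change))
        rec <- integrateOmics(pT, gT, fmap)
        ri <- restrictiveIntersection(pT, gT, fmap)
        truePro <- sim$truth$feature_id[sim$truth$true_direction != "none"]
        truePro <- truePro[paste0("g.", truePro) %in%
                           tx$truth$gene_id[tx$truth$true_fold != 1]]
        nInt <- sum(rec$protein_id %in% truePro &
                    rec$bh_adjusted_combined_p <= 0.05)
        nRes <- length(intersect(unique(ri$pairs$protein_id), truePro))
        expect_gte(nInt, nRes)
        expect_gt(nInt, 0)
    }
})
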