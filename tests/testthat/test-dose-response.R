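test_that("Kruskal-Wallis statistic and degenerate cases are exact", {
    kw <- kruskalWallis(1:12, rep(c("a", "b", "c", "d"), each = 3))
    expect_equal(kw$H, 10.3846, tolerance = 1e-4)
    # equal mean ranks across groups
    expect_equal(kruskalWallis(c(1, 4, 2, 3), c("a", "a", "b", "b"))$H, 0)
    # all tied
    deg <- kruskalWallis(rep(5, 8), rep(1:2, each = 4))
    expect_equal(deg$H, 0)
    expect_equal(deg$p, 1)
    expect_error(kruskalWallis(1:5, c(1, 1, 1, 1, 2)), "at least 2")
    # agrees with stats::kruskal.test on larger samples (ties included)
    set.seed(12)
    v <- c(rnorm(10), rnorm(10, 1), round(rnorm(9), 1))
    g <- rep(1:3, c(10, 10, 9))
    ref <- kruskal.test(v, g)
    ours <- kruskalWallis(v, g)
    expect_equal(ours$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("small-sample KW p equals brute-force permutation enumeration", {
    # independent oracle: enumerate label permutations via combn and score
    # each with stats::kruskal.test
    bruteKW <- function(v, g) {
        g <- as.integer(factor(g))
        n1 <- sum(g == 1)
        idx <- combn(seq_along(v), n1, simplify = FALSE)
        H0 <- unname(kruskal.test(v, g)$statistic)
        Hs <- vapply(idx, function(s) {
            lab <- rep(2L, length(v)); lab[s] <- 1L
            unname(kruskal.test(v, lab)$statistic)
        }, numeric(1))
        mean(Hs >= H0 - 1e-12)
    }
    set.seed(9)
    for (i in 1:5) {
        v <- rnorm(8)
        g <- rep(1:2, each = 4)
        expect_equal(kruskalWallis(v, g)$p, bruteKW(v, g),
                     tolerance = 1e-12)
    }
    # with ties
    v <- c(1, 1, 2, 3, 3, 4, 5, 5)
    expect_equal(kruskalWallis(v, rep(1:2, 4))$p,
                 bruteKW(v, rep(1:2, 4)), tolerance = 1e-12)
})

test_that("Storey q-values obey the fixed-lambda estimator", {
    # pi0 caps at 1 here, so q must equal BH exactly
    p <- c(0.001, 0.01, 0.6, 0.8, 0.9)
    st <- storeyQvalues(p, lambda = 0.5)
    expect_equal(st$pi0, 1)
    expect_equal(st$q, p.adjust(p, "BH"), tolerance = 1e-12)

    expect_equal(storeyQvalues(rep(1, 12))$q, rep(1, 12))
    # uncapped pi0: q = pi0 * BH
    p2 <- c(runif(40, 0, 0.01), runif(10, 0.8, 1))
    st2 <- storeyQvalues(p2)
    expect_lt(st2$pi0, 1)
    expect_equal(st2$q, st2$pi0 * p.adjust(p2, "BH"), tolerance = 1e-12)
    # q is non-decreasing in p order
    o <- order(p2)
    expect_true(all(diff(st2$q[o]) >= -1e-15))
    expect_error(storeyQvalues(numeric(0)), "empty")
    expect_error(storeyQvalues(c(0.5, 1.2)))
})

test_that("Dunnett adjusted p has the right degeneracies and bounds", {
    set.seed(14)
    # k = 1 reduces to the pooled two-sample t test
    x <- rnorm(9)
    g <- factor(rep(c("control", "t1"), c(4, 5)))
    d <- dunnettVsControl(x, g)
    ref <- t.test(x[g == "t1"], x[g == "control"], var.equal = TRUE)
    expect_equal(d$p_adj, ref$p.value, tolerance = 1e-3)
    expect_equal(d$direction,
                 as.integer(sign(mean(x[g == "t1"]) -
                                 mean(x[g == "control"]))))

    # multiplicity bounds: unadjusted <= adjusted <= k * unadjusted
    for (i in 1:5) {
        v <- rnorm(20)
        gg <- factor(rep(c("control", "a", "b", "c"), each = 5))
        dn <- dunnettVsControl(v, gg)
        raw <- 2 * pt(-abs(dn$t), df = 16)
        expect_true(all(dn$p_adj >= raw - 2e-3))
        expect_true(all(dn$p_adj <= pmin(1, 3 * raw) + 2e-3))
    }
    expect_error(dunnettVsControl(rep(1, 8), rep(c("control", "a"), 4)),
                 "zero pooled variance")
    # reproducible quasi-Monte-Carlo integration
    v <- rnorm(20)
    gg <- factor(rep(c("control", "a", "b", "c"), each = 5))
    expect_identical(dunnettVsControl(v, gg), dunnettVsControl(v, gg))
})

test_that("Dunnett adjusted p matches a brute-force max-|t| null", {
    # Monte-Carlo oracle: simulate the joint null of the k t statistics
    # and read the tail of max |t| directly
    set.seed(15)
    for (i in 1:6) {
        sizes <- sample(3:6, 4, replace = TRUE)
        v <- rnorm(sum(sizes))
        gg <- factor(rep(c("control", "a", "b", "c"), sizes))
        dn <- dunnettVsControl(v, gg)
        reps <- 40000
        X <- matrix(rnorm(reps * sum(sizes)), reps)
        cuts <- c(0, cumsum(sizes))
        gm <- sapply(1:4, function(j)
            rowMeans(X[, (cuts[j] + 1):cuts[j + 1], drop = FALSE]))
        gv <- sapply(1:4, function(j)
            apply(X[, (cuts[j] + 1):cuts[j + 1], drop = FALSE], 1, var))
        s2 <- rowSums(sweep(gv, 2, sizes - 1, "*")) / (sum(sizes) - 4)
        tmax <- do.call(pmax, lapply(2:4, function(j)
            abs(gm[, j] - gm[, 1]) / sqrt(s2 * (1 / sizes[j] +
                                                1 / sizes[1]))))
        for (j in 1:3) {
            oracle <- mean(tmax >= abs(dn$t[j]))
            expect_lt(abs(dn$p_adj[j] - oracle), 0.012)
        }
    }
})

test_that("Dunnett agrees with the multcomp reference implementation", {
    skip_if_not_installed("multcomp")
    set.seed(77)
    v <- c(rnorm(3), rnorm(6, 0.8), rnorm(10, 1.2), rnorm(10, -0.4))
    gg <- factor(rep(c("control", "low", "medium", "high"),
                     c(3, 6, 10, 10)),
                 levels = c("control", "low", "medium", "high"))
    ours <- dunnettVsControl(v, gg)
    fit <- multcomp::glht(stats::aov(v ~ gg),
                          linfct = multcomp::mcp(gg = "Dunnett"))
    ref <- summary(fit, test = multcomp::adjusted("single-step"))
    expect_equal(ours$p_adj, as.numeric(ref$test$pvalues),
                 tolerance = 5e-3)
})

test_that("shape classification follows the q/posthoc/curvature rules", {
    dn <- function(p, dir) data.frame(group = c("low", "medium", "high"),
                                      estimate = dir, t = dir * 2,
                                      p_adj = p, direction = sign(dir))
    means <- c(control = 0, low = 1, medium = 2, high = 3)
    expect_equal(classifyShape(0.2, dn(c(1, 1, 1), c(1, 1, 1)), means),
                 "flat")
    expect_equal(classifyShape(0.01, dn(c(0.5, 0.01, 0.01), c(1, 1, 1)),
                               means), "up")
    expect_equal(classifyShape(0.01, dn(c(0.5, 0.01, 0.01), c(-1, -1, -1)),
                               means), "down")
    # mixed significant directions with concave means: cap shape
    capMeans <- c(control = 0, low = 1, medium = 1.4, high = -0.9)
    expect_equal(classifyShape(0.01, dn(c(0.01, 0.01, 0.01), c(1, 1, -1)),
                               capMeans), "cap_shape")
    uMeans <- -capMeans
    expect_equal(classifyShape(0.01, dn(c(0.01, 0.01, 0.01), c(-1, -1, 1)),
                               uMeans), "u_shape")
    # significant KW but no significant post-hoc: curvature decides
    expect_equal(classifyShape(0.01, dn(c(0.2, 0.3, 0.4), c(1, 1, -1)),
                               capMeans), "cap_shape")
})

test_that("the dose-response stage is internally consistent", {
    study <- tinyStudy(seed = 13, nProteins = 60, nGenes = 120)
    dr <- doseResponse(study)
    res <- dr$results
    cfg <- radConfig()
    sel <- !is.na(res$q_value) & res$q_value <= cfg$fdr_level
    # every q-selected feature received post-hoc results and a shape
    expect_true(all(!is.na(res$p_high[sel])))
    expect_true(all(res$shape[sel] %in%
                    c("up", "down", "u_shape", "cap_shape")))
    expect_true(all(res$shape[!sel] == "flat"))
    # q is monotone-consistent with the KW p ranking
    tested <- !is.na(res$kw_p)
    o <- order(res$kw_p[tested])
    expect_true(all(diff(res$q_value[tested][o]) >= -1e-12))
})

test_that("set summaries respect set algebra and the planted pattern", {
    res <- data.frame(
        feature_id = c("a", "b", "c", "d"),
        kw_H = 1, kw_p = 0.001, q_value = c(0.01, 0.01, 0.01, 0.5),
        p_low = c(0.01, 0.5, 0.01, NA), dir_low = c(1L, 1L, -1L, NA),
        p_medium = c(0.01, 0.01, 0.01, NA), dir_medium = c(1L, 1L, -1L, NA),
        p_high = c(0.01, 0.01, 0.01, NA), dir_high = c(1L, 1L, -1L, NA),
        shape = c("up", "up", "down", "flat"))
    s <- summarizeDoseSets(res)
    expect_equal(s$group_counts$up, c(1, 2, 2))
    expect_equal(s$group_counts$down, c(1, 1, 1))
    expect_equal(unname(s$venn_up["low&medium&high"]), 1L)
    expect_equal(unname(s$venn_up["medium&high"]), 1L)
    expect_equal(unname(s$venn_down["low&medium&high"]), 1L)
    expect_equal(sum(s$venn_up), 2L)     # cells partition the up set
    expect_equal(sum(s$shape_counts), 4L)

    empty <- summarizeDoseSets(res[res$shape == "flat", ][0, ])
    expect_true(all(empty$venn_up == 0L) && all(empty$venn_down == 0L))
})

test_that("high-dose effects concentrate in the high group counts", {
    md <- simulateCohort(seed = 20)
    sim <- simulateProteome(md, nFeatures = 80, categoryProportions = c(
        dose_only = 0.5, age_only = 0, dose_age = 0, bmi = 0, none = 0.5,
        u_shape = 0, cap_shape = 0), effectSize = 3, seed = 21)
    tr <- transformAbundance(sim$abundance, md)
    dr <- doseResponse(tr$transformed, md, radConfig(seed = 20))
    s <- summarizeDoseSets(dr$results)
    highHits <- s$group_counts$up[3] + s$group_counts$down[3]
    lowHits <- s$group_counts$up[1] + s$group_counts$down[1]
    expect_gt(highHits, lowHits)
})
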