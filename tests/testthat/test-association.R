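test_that("log transform is the documented monotone map", {
    expect_equal(logTransform(0), 0)
    expect_equal(logTransform(3), 2)  # log2(4)
    x <- runif(50) * 100
    expect_equal(2^logTransform(x) - 1, x)
    expect_error(logTransform(-1), "non-negative")
})

test_that("two-group fit matches the closed-form example", {
    f <- fitModels(c(1, 2, 3, 4), c(0, 0, 1, 1))
    r <- f[f$model == "SV_ONLY", ]
    # slope = difference of group means; SE = sqrt(s2 * (1/2 + 1/2)),
    # s2 = SSE / df = 1 / 2
    expect_equal(r$slope, 2)
    expect_equal(r$t, 2 / sqrt(0.5), tolerance = 1e-9)
    expect_equal(r$p, 2 * pt(-2 / sqrt(0.5), 2), tolerance = 1e-9)
    expect_equal(r$p, 0.10557, tolerance = 1e-4)
    # with no covariates the slope is exactly the SV+/SV- mean difference
    set.seed(1)
    y <- rnorm(40); sv <- rep(c(0, 1), each = 20)
    f2 <- fitModels(y, sv)
    expect_equal(f2$slope[1], mean(y[sv == 1]) - mean(y[sv == 0]))
})

test_that("all three models agree with stats::lm on random designs", {
    set.seed(71)
    for (rep in 1:5) {
        n <- 80
        ct <- sample(sprintf("t%d", 1:4), n, TRUE)
        cn <- pmax(0, 2 + rnorm(n))
        sv <- as.numeric(runif(n) < 0.2)
        if (sum(sv) < 3) sv[1:3] <- 1
        y <- rnorm(n) + 0.8 * sv + 0.3 * cn
        f <- fitModels(y, sv, ct, cn)
        co1 <- summary(lm(y ~ sv))$coefficients["sv", ]
        co2 <- summary(lm(y ~ factor(ct) + sv))$coefficients["sv", ]
        co3 <- summary(lm(y ~ factor(ct) + cn + sv))$coefficients["sv", ]
        for (pair in list(list("SV_ONLY", co1), list("SV_TYPE", co2),
                          list("SV_TYPE_CN", co3))) {
            r <- f[f$model == pair[[1]], ]
            expect_equal(r$slope, unname(pair[[2]]["Estimate"]),
                         tolerance = 1e-9)
            expect_equal(r$t, unname(pair[[2]]["t value"]), tolerance = 1e-9)
            expect_equal(r$p, unname(pair[[2]]["Pr(>|t|)"]),
                         tolerance = 1e-9)
        }
        # SV inference is invariant to the cancer-type reference level
        ct2 <- factor(ct, levels = rev(sort(unique(ct))))
        f2 <- fitModels(y, sv, ct2, cn)
        expect_equal(f$t, f2$t, tolerance = 1e-9)
    }
})

test_that("degenerate and confounded designs are flagged", {
    f <- fitModels(rep(2, 10), rep(c(0, 1), 5))
    expect_equal(f$status[1], "degenerate")
    expect_equal(f$slope[1], 0)
    # SV identical to one cancer type -> non-estimable under SV_TYPE
    ct <- rep(c("a", "b"), each = 10)
    sv <- as.numeric(ct == "b")
    f2 <- fitModels(rnorm(20), sv, ct)
    expect_equal(f2$status[f2$model == "SV_TYPE"], "non-estimable")
    expect_equal(f2$status[f2$model == "SV_ONLY"], "ok")
    expect_error(fitModels(rnorm(4), c(0, 1, 2, 1)), "binary")
})

test_that("batch association equals the per-gene fit path", {
    co <- tinyCohort()
    ev <- buildEventMatrix(assignBreakpoints(co$svs, co$genes), co$genes,
                           co$samples, min_sv_samples = 2)
    a <- associateExpression(ev, co$expression, co$samples, co$copy_number)
    ly <- logTransform(co$expression)
    ct <- co$samples[colnames(ev), "cancer_type"]
    for (i in sample(nrow(a), min(10, nrow(a)))) {
        g <- a$gene_id[i]; w <- a$window[i]; m <- a$model[i]
        f <- fitModels(ly[g, colnames(ev)], svEvents(ev, w)[g, ], ct,
                       co$copy_number[g, colnames(ev)])
        r <- f[f$model == m, ]
        if (a$status[i] == "ok") {
            expect_equal(a$t[i], r$t, tolerance = 1e-9)
            expect_equal(a$p[i], r$p, tolerance = 1e-9)
        } else expect_equal(a$status[i], r$status)
    }
})

test_that("Storey q-values behave under the null and strong signal", {
    set.seed(12)
    p <- runif(10000)
    sq <- storeyQvalues(p)
    expect_gte(sq$pi0, 0.9)
    expect_lte(sq$pi0, 1)
    # strong-signal limit
    sq2 <- storeyQvalues(rep(1e-9, 20))
    expect_true(all(sq2$qvalues <= 1e-5))
    # monotone in p
    o <- order(p)
    expect_true(all(diff(sq$qvalues[o]) >= -1e-12))
    # brute-force definition: q_i = min over p_j >= p_i of pi0*m*p_j/rank_j
    set.seed(13)
    ps <- runif(60)^2
    sq3 <- storeyQvalues(ps)
    m <- length(ps); rk <- rank(ps)
    qbf <- vapply(ps, function(pi)
        min(1, min((sq3$pi0 * m * ps / rk)[ps >= pi])), 0)
    expect_equal(sq3$qvalues, qbf, tolerance = 1e-12)
    expect_error(storeyQvalues(numeric()), "empty")
    expect_error(storeyQvalues(runif(5)), "at least 10")
    expect_error(storeyQvalues(c(runif(10), 1.2)), "\\[0, 1\\]")
})

test_that("q-value families are per (window, model)", {
    co <- tinyCohort()
    ev <- buildEventMatrix(assignBreakpoints(co$svs, co$genes), co$genes,
                           co$samples, min_sv_samples = 1)
    a <- associateExpression(ev, co$expression, co$samples, co$copy_number)
    fam <- a[a$window == "UP_0_20" & a$model == "SV_TYPE_CN" &
             a$status == "ok", ]
    if (nrow(fam) >= 10) {
        redo <- storeyQvalues(fam$p)$qvalues
        expect_equal(fam$q, redo, tolerance = 1e-12)
    }
    succeed()
})

test_that("permutation null is deterministic, seed-private and calibrated", {
    co <- tinyCohort()
    ev <- buildEventMatrix(assignBreakpoints(co$svs, co$genes), co$genes,
                           co$samples, min_sv_samples = 2)
    set.seed(4242); before <- .Random.seed
    pn1 <- permutationNull(ev, co$expression, co$samples, co$copy_number,
                           n_perm = 25, seed = 5)
    expect_identical(.Random.seed, before)  # global RNG untouched
    pn2 <- permutationNull(ev, co$expression, co$samples, co$copy_number,
                           n_perm = 25, seed = 5)
    expect_identical(pn1$counts, pn2$counts)
    expect_equal(pn1$mean, mean(pn1$counts))
    expect_equal(pn1$sd, sd(pn1$counts))
    # alpha = 1 -> every testable gene significant in every permutation
    pn3 <- permutationNull(ev, co$expression, co$samples, co$copy_number,
                           n_perm = 5, alpha = 1, seed = 5)
    expect_true(all(pn3$counts == pn3$n_testable))
    expect_error(permutationNull(ev, co$expression, co$samples,
                                 n_perm = 0), "n_perm")
})

test_that("planted effects are recovered with controlled FDR", {
    # ten strong drivers (two per window) so the pooled empirical FDR of
    # q < 0.05 calls is a stable ratio; family sizes ~200 keep the spline
    # pi0 estimate well behaved
    drivers <- data.frame(
        gene_id = sprintf("G%04d", 1:10),
        window = rep(REGION_WINDOWS, 2),
        log2fc = 2, n_sv_samples = 30)
    hits <- 0; false_q <- 0; total_q <- 0
    nseed <- 40
    for (s in seq_len(nseed)) {
        co <- simulateCohort(simConfig(
            nSamples = 200, nGenes = 1000, svRate = 0.05, seed = 100 + s,
            driverGenes = drivers))
        ev <- buildEventMatrix(assignBreakpoints(co$svs, co$genes),
                               co$genes, co$samples)
        a <- associateExpression(ev, co$expression, co$samples,
                                 co$copy_number)
        full <- a[a$model == "SV_TYPE_CN" & a$status == "ok", ]
        key <- paste(full$gene_id, full$window)
        dkey <- paste(drivers$gene_id, drivers$window)
        drv <- full[key %in% dkey, ]
        hits <- hits + sum(drv$p < 0.001)
        called <- full[!is.na(full$q) & full$q < 0.05, ]
        total_q <- total_q + nrow(called)
        false_q <- false_q + sum(!paste(called$gene_id, called$window) %in%
                                 dkey)
    }
    expect_gte(hits / (nseed * nrow(drivers)), 0.95)  # power at p < 0.001
    expect_gt(total_q, 0)
    expect_lte(false_q / total_q, 0.10)               # empirical FDR
})

test_that("alteration grouping follows the documented precedence", {
    g <- makeGenes(100001, 105000, "+")
    samples <- c("s1", "s2", "s3", "s4")
    # s1: UP_0_20 breakend + amplification -> amplified wins
    # s2: breakends in UP_0_20 and UP_50_100 -> nearest window wins
    # s3: extra flag only; s4: unaltered
    bp <- BreakendPairSet(
        chrom1 = rep("chr1", 3), pos1 = c(95001, 95001, 20001),
        orient1 = rep("-", 3),
        chrom2 = c("chr9", "chr9", "chr9"), pos2 = c(1e6, 2e6, 3e6),
        orient2 = rep("+", 3), sampleId = c("s1", "s2", "s2"))
    a <- suppressWarnings(assignBreakpoints(bp, g))
    cn <- matrix(c(6, 2, 2, 2), 1, dimnames = list("G01", samples))
    grp <- alterationGroups("G01", a, g, cn, samples,
                            extra_flags = list(promoter_mut = c(FALSE, FALSE,
                                                                TRUE, FALSE)))
    expect_equal(unname(grp["s1"]), "amplified")
    expect_equal(unname(grp["s2"]), "UP_0_20")
    expect_equal(unname(grp["s3"]), "promoter_mut")
    expect_equal(unname(grp["s4"]), "unaltered")
})

test_that("group tests give extreme and tied p-values correctly", {
    ex <- setNames(c(rnorm(20, 10), rnorm(20)), sprintf("s%d", 1:40))
    grp <- setNames(rep(c("UP_0_20", "unaltered"), each = 20), names(ex))
    gt <- groupTests(ex, grp)
    expect_lt(gt$p, 1e-6)
    # a single shared value in both groups carries no evidence
    ex2 <- setNames(c(5, 5), c("a", "b"))
    gt2 <- groupTests(ex2, setNames(c("grp", "unaltered"), c("a", "b")))
    expect_equal(gt2$p, 1)
    expect_true(gt2$low_n)
    expect_error(groupTests(ex, setNames(rep("x", 40), names(ex))),
                 "empty reference")
})
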