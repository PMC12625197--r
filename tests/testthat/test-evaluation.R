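test_that("confusion metrics satisfy their defining identities", {
    cm <- confusionMetrics(c(1, 1, 1, 0, 0, 0, 1, 0, 0, 0),
                           c(1, 1, 0, 1, 0, 0, 1, 0, 0, 1))
    expect_identical(cm$tp + cm$fp + cm$tn + cm$fn, cm$n)
    expect_equal(cm$concordance, round(100 * (cm$tp + cm$tn) / cm$n, 2))
    expect_equal(cm$ppv, cm$tp / (cm$tp + cm$fp))
    expect_equal(cm$npv, cm$tn / (cm$tn + cm$fn))

    perfect <- confusionMetrics(c(1, 0, 1), c(1, 0, 1))
    expect_equal(perfect$concordance, 100.00)
    expect_equal(perfect$ppv, 1)
    expect_equal(perfect$npv, 1)
})

test_that("direct-arithmetic example: tp 80, fp 20, tn 90, fn 10", {
    pred <- rep(c(1, 1, 0, 0), times = c(80, 20, 90, 10))
    ref <- rep(c(1, 0, 0, 1), times = c(80, 20, 90, 10))
    cm <- confusionMetrics(pred, ref)
    expect_equal(cm$ppv, 0.80)
    expect_equal(cm$npv, 0.90)
    expect_equal(cm$concordance, 85.00)
})

test_that("printed concordance arithmetic: 28 discordant of 325 gives 91.38", {
    pred <- c(rep(1, 150), rep(0, 147), rep(1, 14), rep(0, 14))
    ref <- c(rep(1, 150), rep(0, 147), rep(0, 14), rep(1, 14))
    cm <- confusionMetrics(pred, ref)
    expect_identical(cm$n, 325L)
    expect_equal(cm$concordance, 91.38)
})

test_that("missing pairs are excluded, not dropped silently", {
    cm <- confusionMetrics(c(1, NA, 0, 1), c(1, 1, NA, 0))
    expect_identical(cm$n, 2L)
    expect_identical(cm$n_excluded, 2L)
    expect_error(confusionMetrics(c(NA, NA), c(1, 0)), "no complete pairs")
    expect_error(confusionMetrics(1, c(1, 0)), "paired")
})

test_that("DeLong AUC equals exhaustive pair counting", {
    expect_equal(rocAucDelong(c(1, 2, 3, 10, 11, 12),
                              c(0, 0, 0, 1, 1, 1))$auc, 1.0)
    expect_equal(rocAucDelong(rep(5, 8), rep(c(0, 1), 4))$auc, 0.5)

    set.seed(71)
    for (i in 1:5) {
        n <- sample(8:20, 1)
        scores <- sample(1:6, n, replace = TRUE)    # guarantees ties
        labels <- rbinom(n, 1, 0.5)
        if (length(unique(labels)) < 2) next
        res <- rocAucDelong(scores, labels)
        expect_equal(res$auc, aucOracle(scores, labels), tolerance = 1e-12)
        expect_lte(res$ci_low, res$auc)
        expect_gte(res$ci_high, res$auc)
    }
    expect_error(rocAucDelong(1:5, rep(1, 5)), "both classes")
})

test_that("DeLong variance agrees with pROC", {
    skip_if_not_installed("pROC")
    set.seed(72)
    scores <- c(rnorm(40), rnorm(40, 1))
    labels <- rep(c(0, 1), each = 40)
    res <- rocAucDelong(scores, labels)
    pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    ci <- pROC::ci.auc(pr, method = "delong")
    expect_equal(res$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
    expect_equal(res$ci_low, ci[1], tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(res$ci_high, ci[3], tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("logistic predictor: closed forms, grid oracle, separation", {
    # intercept-only: fitted probability equals prevalence
    set.seed(73)
    y <- rbinom(40, 1, 0.3)
    fit <- logisticPredictor(y, data.frame(x = rep(0, 40)))
    expect_equal(unname(fit$fitted[1]), mean(y), tolerance = 1e-8)

    # 12-row worked fixture vs direct likelihood maximization
    x12 <- c(-2.1, -1.7, -1.2, -0.8, -0.4, -0.1, 0.2, 0.6, 1.1, 1.4, 1.8, 2.3)
    y12 <- c(0, 0, 1, 0, 0, 1, 0, 1, 1, 0, 1, 1)
    fit12 <- logisticPredictor(y12, data.frame(x = x12))
    nll <- function(b) -sum(y12 * (b[1] + b[2] * x12) -
                            log1p(exp(b[1] + b[2] * x12)))
    opt <- optim(c(0, 0), nll, method = "BFGS",
                 control = list(reltol = 1e-14))
    expect_equal(unname(fit12$coefficients), opt$par, tolerance = 1e-4)

    # independent predictor: coefficient within 3 SE of zero
    set.seed(74)
    yy <- rbinom(400, 1, 0.5); xx <- rnorm(400)
    f0 <- logisticPredictor(yy, data.frame(x = xx))
    expect_lt(abs(f0$coefficients[["x"]]), 3 * f0$se[["x"]])

    # complete separation is an error, not silent output
    expect_error(
        logisticPredictor(c(0, 0, 0, 0, 1, 1, 1, 1),
                          data.frame(x = c(1:4, 11:14))),
        "separation")
})

test_that("Kruskal-Wallis H matches the textbook formula and rank-sum link", {
    same <- kruskalDunn(rep(c(5, 7, 9), 3), rep(c("a", "b", "c"), each = 3))
    expect_equal(same$H, 0, tolerance = 1e-12)

    # two groups: H equals the squared standardized rank-sum statistic
    set.seed(75)
    v <- rnorm(24); g <- rep(c("x", "y"), each = 12)
    res <- kruskalDunn(v, g)
    rk <- rank(v); n <- 24; n1 <- 12
    R1 <- sum(rk[g == "x"])
    zz <- (R1 - n1 * (n + 1) / 2) /
        sqrt(n1 * (n - n1) * (n + 1) / 12)
    expect_equal(res$H, zz^2, tolerance = 1e-10)
    expect_equal(res$p, pchisq(zz^2, 1, lower.tail = FALSE),
                 tolerance = 1e-10)

    # three-group fixture, no ties: H = 12/(N(N+1)) sum n_i Rbar_i^2 - 3(N+1)
    v3 <- c(1.1, 2.2, 3.3, 4.4, 5.5, 6.6, 7.7, 8.8, 9.9)
    g3 <- rep(c("a", "b", "c"), each = 3)
    res3 <- kruskalDunn(v3, g3)
    rk3 <- rank(v3)
    manual <- 12 / (9 * 10) *
        sum(tapply(rk3, g3, function(r) length(r) * mean(r)^2)) - 3 * 10
    expect_equal(res3$H, manual, tolerance = 1e-10)
})

test_that("Dunn comparisons are restricted and Bonferroni is exact", {
    set.seed(76)
    v <- rnorm(100)
    g <- sample(c("CO", "AD", "DLB", "FTD", "PD"), 100, replace = TRUE)
    comps <- lapply(c("CO", "DLB", "FTD", "PD"), function(x) c("AD", x))
    res <- kruskalDunn(v, g, comparisons = comps)
    expect_identical(nrow(res$dunn), 4L)
    expect_true(all(res$dunn$group1 == "AD"))
    expect_equal(res$dunn$p_bonf, pmin(1, 4 * res$dunn$p_raw))
    expect_error(kruskalDunn(v, g, comparisons = list(c("AD", "XX"))),
                 "unknown group")
    expect_error(kruskalDunn(1:5, rep("a", 5)), "at least 2 groups")
})

test_that("platform correlation summarises analyte agreement", {
    set.seed(77)
    n <- 60
    x <- matrix(rnorm(5 * n), 5, n, dimnames = list(paste0("p", 1:5), NULL))
    y <- x + matrix(rnorm(5 * n, 0, 0.1), 5, n)   # near-identical
    y[5, ] <- rnorm(n)                            # unrelated analyte
    res <- platformCorrelation(x, y, threshold = 0.7)
    expect_identical(res$n_above, 4L)
    expect_equal(res$pct_above, 80.00)
    expect_true(all(res$per_analyte$r[1:4] > 0.95))

    ident <- platformCorrelation(x[1:2, ], x[1:2, ])
    expect_true(all(ident$per_analyte$r == 1))

    const <- x; const[1, ] <- 5
    res2 <- platformCorrelation(const, y)
    expect_identical(res2$per_analyte$skipped_reason[1], "constant vector")
})

test_that("printed platform fractions: 86/123 and 66/123", {
    expect_equal(NPQtools:::.pctAway(86, 123), 69.92)
    set.seed(78)
    n <- 50
    good <- 86; total <- 123
    x <- matrix(rnorm(total * n), total, n,
                dimnames = list(paste0("p", 1:total), NULL))
    y <- x + matrix(rnorm(total * n, 0, 0.25), total, n)
    y[(good + 1):total, ] <- matrix(rnorm((total - good) * n), total - good, n)
    res <- platformCorrelation(x, y, threshold = 0.7)
    expect_identical(res$n_above, 86L)
    expect_equal(res$pct_above, 69.92)
})

test_that("APOE concordance reproduces printed count arithmetic", {
    # overall: 1,549/1,573 e4+ correct, 2,304/2,319 e4- correct -> 99.00%
    gt <- c(rep("e3e4", 1573), rep("e3e3", 2319))
    calls <- c(rep(1, 1549), rep(0, 24), rep(0, 2304), rep(1, 15))
    res <- apoeConcordance(calls, gt)
    expect_equal(res$overall$concordance, 99.00)

    # 232 e4/e4 with 3 discordant -> 98.71% within the stratum
    gt2 <- rep("e4e4", 232)
    calls2 <- c(rep(1, 229), rep(0, 3))
    res2 <- apoeConcordance(calls2, gt2)
    expect_equal(res2$per_genotype$concordance[
        res2$per_genotype$genotype == "e4e4"], 98.71)

    perfect <- apoeConcordance(c(1, 0, 1, 0),
                               c("e3e4", "e3e3", "e4e4", "e2e2"))
    expect_equal(perfect$overall$concordance, 100.00)
    expect_true(all(perfect$per_genotype$concordance == 100.00))

    # unknown genotype rows are excluded with a log message
    expect_message(res3 <- apoeConcordance(c(1, 0), c("e3e4", "huh")),
                   "unknown genotype")
    expect_identical(res3$n_excluded, 1L)

    # epsilon/slash spellings accepted
    res4 <- apoeConcordance(c(1, 0), c("ε3/ε4", "ε3/ε3"))
    expect_equal(res4$overall$concordance, 100.00)
})

test_that("over-representation test matches hypergeometric enumeration", {
    bg <- paste0("g", 1:100)
    da <- paste0("g", 1:20)
    ann <- list(whole = bg,
                none = paste0("g", 90:95),
                mix = paste0("g", c(1:4, 50:55)))
    res <- overrepresentationTest(da, ann, bg)
    expect_equal(res$fold_enrichment[res$pathway == "whole"], 1)
    fe0 <- res[res$pathway == "none", ]
    expect_equal(fe0$fold_enrichment, 0)
    expect_equal(fe0$p_raw, 1)
    mix <- res[res$pathway == "mix", ]
    expect_equal(mix$fold_enrichment, (4 / 20) / (10 / 100))
    expect_equal(mix$fold_enrichment, 2.0)
    # exhaustive enumeration of P(X >= k) for X ~ Hypergeom(K=10, N=100, n=20)
    enum <- sum(vapply(4:10, function(k)
        choose(10, k) * choose(90, 20 - k), numeric(1))) / choose(100, 20)
    expect_equal(mix$p_raw, enum, tolerance = 1e-12)
    expect_error(overrepresentationTest(c("zz"), ann, bg), "subset")
    expect_error(overrepresentationTest(da, ann, character()), "nonempty")
})

test_that("GMT round trip preserves set membership", {
    sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9"))
    f <- withr::local_tempfile(fileext = ".gmt")
    writeGmt(sets, f)
    back <- readGmt(f)
    expect_identical(back, sets)
})
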