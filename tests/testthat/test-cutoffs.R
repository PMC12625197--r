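test_that("EM recovers a well-separated mixture and keeps logLik monotone", {
    set.seed(61)
    x <- c(rnorm(2500, -2), rnorm(2500, 2))
    fit <- fitTwoComponentGmm(x)
    expect_true(fit@converged)
    expect_lt(abs(fit@means[1] + 2), 0.1)
    expect_lt(abs(fit@means[2] - 2), 0.1)
    expect_lt(abs(fit@weights[1] - 0.5), 0.05)
    expect_true(all(diff(fit@logLik) > -1e-8))
    expect_false(gmmIsDegenerate(fit))
})

test_that("a single tight cluster is flagged as degenerate overlap", {
    set.seed(62)
    fit <- fitTwoComponentGmm(rnorm(500, 3, 0.5))
    expect_true(gmmIsDegenerate(fit))
})

test_that("EM agrees with mclust on a clear mixture", {
    skip_if_not_installed("mclust")
    suppressMessages(library(mclust))   # Mclust needs its namespace attached
    set.seed(63)
    x <- c(rnorm(1500, -1.5, 0.8), rnorm(1000, 1.5, 1.1))
    fit <- fitTwoComponentGmm(x)
    mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
    expect_equal(sort(fit@means), sort(unname(mc$parameters$mean)),
                 tolerance = 0.05)
    expect_equal(fit@weights, mc$parameters$pro[order(mc$parameters$mean)],
                 tolerance = 0.05)
})

test_that("EM input validation and degenerate collapse", {
    expect_error(fitTwoComponentGmm(rnorm(5)), "at least 10")
    expect_error(fitTwoComponentGmm(rep(c(1, 1 + 1e-12), 10)), "degenerate|collapsed")
})

test_that("crossing cutoff solves the equal-likelihood equation", {
    mkfit <- function(w, mu, s)
        new("GMMFit", weights = w, means = mu, sds = s, logLik = 0,
            converged = TRUE, nIter = 1L, varianceFloorActive = FALSE)
    expect_equal(gmmCrossingCutoff(mkfit(c(0.5, 0.5), c(-1, 1), c(1, 1))), 0,
                 tolerance = 1e-12)
    expect_equal(gmmCrossingCutoff(mkfit(c(0.5, 0.5), c(0, 2), c(1, 1))), 1,
                 tolerance = 1e-12)
    expect_equal(gmmCrossingCutoff(mkfit(c(0.7, 0.3), c(0, 2), c(1, 1))),
                 1 + log(7 / 3) / 2, tolerance = 1e-12)

    # unequal variances: the root lies between the means and the
    # posterior there is exactly 1/2
    fit <- mkfit(c(0.6, 0.4), c(-1, 1.5), c(0.7, 1.2))
    cut <- gmmCrossingCutoff(fit)
    expect_gt(cut, -1); expect_lt(cut, 1.5)
    post1 <- fit@weights[1] * dnorm(cut, fit@means[1], fit@sds[1])
    post2 <- fit@weights[2] * dnorm(cut, fit@means[2], fit@sds[2])
    expect_equal(post1 / (post1 + post2), 0.5, tolerance = 1e-8)

    # extreme imbalance: no crossing between the means
    expect_error(gmmCrossingCutoff(mkfit(c(0.9999, 1e-4), c(0, 0.1), c(1, 1))),
                 "no crossing")
})

test_that("Youden cutoff matches the exhaustive scan", {
    perfect <- youdenCutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
    expect_equal(perfect$cutoff, 2.5)
    expect_equal(perfect$J, 1)

    flat <- youdenCutoff(rep(2, 6), c(0, 0, 0, 1, 1, 1))
    expect_equal(flat$J, 0)

    set.seed(64)
    vals <- c(rnorm(30, 0), rnorm(30, 1))
    labs <- rep(c(0, 1), each = 30)
    yc <- youdenCutoff(vals, labs)
    # brute force over a fine grid plus all midpoints
    cands <- sort(c(seq(min(vals), max(vals), length.out = 2000),
                    (sort(unique(vals))[-1] +
                     rev(rev(sort(unique(vals)))[-1])) / 2))
    js <- vapply(cands, function(t)
        mean(vals[labs == 1] > t) + mean(vals[labs == 0] <= t) - 1,
        numeric(1))
    expect_equal(yc$J, max(js), tolerance = 1e-12)
    expect_error(youdenCutoff(1:5, rep(1, 5)), "both classes")
})

test_that("dual cutoffs hit their targets and collapse when separated", {
    set.seed(65)
    vals <- c(rnorm(200, 0), rnorm(200, 1.2))
    labs <- rep(c(0, 1), each = 200)
    dc <- dualCutoffs(vals, labs)
    expect_lt(dc$lower, dc$upper)
    expect_gte(dc$achieved[["sens_at_lower"]], 0.95)
    expect_gte(dc$achieved[["spec_at_upper"]], 0.95)
    # exhaustive verification of the extremal property
    cands <- sort(c(min(vals) - 1,
                    (sort(unique(vals))[-1] +
                     rev(rev(sort(unique(vals)))[-1])) / 2))
    sens <- vapply(cands, function(t) mean(vals[labs == 1] > t), numeric(1))
    spec <- vapply(cands, function(t) mean(vals[labs == 0] <= t), numeric(1))
    expect_equal(dc$lower, max(cands[sens >= 0.95]), tolerance = 1e-12)
    expect_equal(dc$upper, min(cands[spec >= 0.95]), tolerance = 1e-12)

    sep <- suppressMessages(dualCutoffs(c(1:10, 101:110),
                                        rep(c(0, 1), each = 10)))
    expect_true(sep$collapsed)
    expect_gte(sep$lower, sep$upper)
})

test_that("a median-targeted threshold sits near the positive-class median", {
    set.seed(66)
    vals <- c(rnorm(500, 0), rnorm(500, 3))
    labs <- rep(c(0, 1), each = 500)
    dc <- dualCutoffs(vals, labs, sensTarget = 0.501, specTarget = 0.95)
    expect_lt(abs(dc$lower - median(vals[labs == 1])), 0.2)
})

test_that("tri-class labeling partitions every input", {
    res <- classifyThreeWay(c(-1, 0, 1, NA, 0.2, -0.5, 2), -0.3, 0.4)
    expect_identical(unname(as.vector(res$counts)), c(2L, 2L, 2L))
    expect_identical(res$n_missing, 1L)
    expect_identical(as.character(res$labels[1]), "low")
    expect_equal(sum(res$counts) + res$n_missing, 7)
    expect_error(classifyThreeWay(1:3, 2, 1), "must not exceed")
})

test_that("tri-class percentages reproduce printed two-decimal arithmetic", {
    vals <- c(rep(-1, 79), rep(0, 52), rep(1, 194))
    res <- classifyThreeWay(vals, -0.26, 0.35)
    expect_identical(unname(res$percentages),
                     c(24.31, 16.00, 59.69))
})

test_that("deriveCutoffs bundles all strategies with linear equivalents", {
    set.seed(67)
    base <- matrix(rnorm(600, 12, 1), 2, 300,
                   dimnames = list(c("pTau217", "other"), NULL))
    base["pTau217", ] <- c(rnorm(150, 10.5, 0.6), rnorm(150, 13, 0.8))
    colnames(base) <- paste0("s", 1:300)
    z <- normalizeNpq(normalizeNpq(normalizeNpq(am(base), "linear_npq"),
                                   "log10"), "zscore")
    vals <- npq(z)["pTau217", ]
    labs <- as.integer(base["pTau217", ] > 11.5)
    cs <- deriveCutoffs(vals, labs, x = z, analyte = "pTau217")
    expect_s4_class(cs, "CutoffSet")
    expect_false(is.na(cs@gmmCutoff))
    expect_false(is.na(cs@youdenCutoff))
    expect_true(all(c("gmm", "youden") %in% names(cs@linearEquivalents)))
    # inverse-chain consistency
    expect_equal(unname(cs@linearEquivalents[["gmm"]]),
                 unname(zscoreToLinear(cs@gmmCutoff, z, "pTau217")))
    # Youden and GMM crossing agree when classes are the components
    expect_lt(abs(cs@youdenCutoff - cs@gmmCutoff), 0.3)
})

test_that("GMM crossing estimate approaches the analytic root", {
    set.seed(68)
    w <- c(0.6, 0.4); mu <- c(-1, 1.3); s <- c(0.8, 0.9)
    truthFit <- new("GMMFit", weights = w, means = mu, sds = s, logLik = 0,
                    converged = TRUE, nIter = 1L, varianceFloorActive = FALSE)
    analytic <- gmmCrossingCutoff(truthFit)
    comp <- 1 + rbinom(5000, 1, w[2])
    x <- rnorm(5000, mu[comp], s[comp])
    est <- gmmCrossingCutoff(fitTwoComponentGmm(x))
    expect_lt(abs(est - analytic), 0.1)
})
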