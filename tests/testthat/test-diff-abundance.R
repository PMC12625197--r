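test_that("exact linear fit gives beta 2 with zero residual error", {
    x <- am(matrix(2 * (1:8), 1, 8))
    res <- fitProteinRegressions(x, data.frame(pred = 1:8), "pred",
                                 covariates = character())
    expect_equal(res$beta, 2, tolerance = 1e-12)
    expect_equal(res$se, 0, tolerance = 1e-10)
    expect_identical(res$n_used, 8L)
})

test_that("a covariate orthogonal to the predictor leaves beta unchanged", {
    set.seed(41)
    pred <- rep(c(-1, 1), each = 10)
    orth <- rep(c(-1, 1), times = 10)          # orthogonal to pred
    y <- 0.7 * pred + rnorm(20)
    x <- am(matrix(y, 1, 20))
    plain <- fitProteinRegressions(x, data.frame(pred = pred), "pred",
                                   covariates = character())
    withCov <- fitProteinRegressions(x, data.frame(pred = pred, o = orth),
                                     "pred", covariates = "o")
    expect_equal(plain$beta, withCov$beta, tolerance = 1e-10)
})

test_that("coefficients match the normal-equations oracle on a worked fixture", {
    set.seed(42)
    n <- 8
    pred <- c(0, 0, 0, 0, 1, 1, 1, 1)
    age <- c(61, 72, 68, 75, 70, 66, 79, 73)
    y <- 0.5 * pred + 0.02 * age + rnorm(n, 0, 0.3)
    x <- am(matrix(y, 1, n))
    res <- fitProteinRegressions(x, data.frame(dx = pred, age = age), "dx",
                                 covariates = "age")
    X <- cbind(1, pred, age)
    o <- olsOracle(X, y)
    expect_equal(res$beta, unname(o$beta[2]), tolerance = 1e-8)
    expect_equal(res$se, unname(o$se[2]), tolerance = 1e-8)
    expect_equal(res$p_raw,
                 unname(2 * pt(-abs(o$beta[2] / o$se[2]), o$df)),
                 tolerance = 1e-10)
})

test_that("factor predictors, skips and per-analyte complete cases work", {
    set.seed(43)
    v <- matrix(rnorm(40, 0), 2, 20)
    v[2, ] <- NA                                # all-missing analyte
    v[1, 3] <- NA                               # one missing cell
    grp <- factor(rep(c("CO", "AD"), each = 10), levels = c("CO", "AD"))
    res <- fitProteinRegressions(am(v), data.frame(dx = grp), "dx",
                                 covariates = character())
    expect_identical(res$n_used[1], 19L)
    expect_identical(res$skipped_reason[2], "all values missing")
    expect_error(fitProteinRegressions(am(v), data.frame(dx = grp), "nope"),
                 "missing design column")
    const <- fitProteinRegressions(
        am(matrix(rnorm(20), 1, 20)),
        data.frame(dx = grp, dup = as.numeric(grp)), "dx",
        covariates = "dup")
    expect_identical(const$skipped_reason[1], "rank-deficient design")
})

test_that("BH adjustment reproduces the hand step-up trace and its bounds", {
    expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(adjustBH(0.37), 0.37)
    set.seed(44)
    for (i in 1:10) {
        p <- runif(sample(3:40, 1))
        adj <- adjustBH(p)
        expect_equal(adj, bhOracle(p), tolerance = 1e-12)
        expect_true(all(adj >= p - 1e-15) && all(adj <= 1))
    }
    expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("surrogate variables recover a planted batch factor", {
    set.seed(45)
    n <- 300; p <- 60
    batch <- rnorm(n)
    load <- numeric(p); load[1:24] <- runif(24, 0.5, 1.0)  # 40% of analytes
    v <- matrix(rnorm(p * n), p, n) + outer(load, batch)
    grp <- rep(c(0, 1), length.out = n)
    x <- am(v, scaleTag = "zscore")
    sv <- estimateSurrogateVariables(x, data.frame(g = grp), nSv = 2,
                                     seed = 1)
    expect_gt(abs(cor(sv[, 1], batch)), 0.9)
    expect_equal(crossprod(sv), diag(2), tolerance = 1e-8,
                 ignore_attr = TRUE)
    sv2 <- estimateSurrogateVariables(x, data.frame(g = grp), nSv = 2,
                                      seed = 1)
    expect_identical(sv, sv2)
})

test_that("surrogate variables agree with the sva package on planted batch", {
    skip_if_not_installed("sva")
    set.seed(46)
    n <- 200; p <- 50
    batch <- rnorm(n)
    load <- numeric(p); load[1:20] <- runif(20, 0.6, 1.2)
    grp <- rep(c(0, 1), length.out = n)
    v <- matrix(rnorm(p * n), p, n) + outer(load, batch) +
        outer(c(rep(0.5, 5), rep(0, p - 5)), grp)
    sv <- estimateSurrogateVariables(am(v, scaleTag = "zscore"),
                                     data.frame(g = grp), nSv = 1, seed = 2)
    mod <- model.matrix(~ grp)
    svaRes <- suppressMessages(sva::sva(v, mod, n.sv = 1))
    expect_gt(abs(cor(sv[, 1], batch)), 0.9)
    expect_gt(abs(cor(svaRes$sv[, 1], batch)), 0.9)
    expect_gt(abs(cor(sv[, 1], svaRes$sv[, 1])), 0.9)
})

test_that("missing values are imputed reproducibly inside SV estimation", {
    set.seed(47)
    v <- matrix(rnorm(50 * 40), 40, 50)
    v[sample(2000, 100)] <- NA
    x <- am(v, scaleTag = "zscore")
    d <- data.frame(g = rep(c(0, 1), length.out = 50))
    expect_identical(estimateSurrogateVariables(x, d, seed = 3),
                     estimateSurrogateVariables(x, d, seed = 3))
    expect_error(estimateSurrogateVariables(x, d, nSv = 45), "smaller")
})

test_that("an SV-confounded batch inflates null rejections and SVs restore calibration", {
    set.seed(48)
    n <- 200; p <- 40
    grp <- rep(c(0, 1), each = n / 2)
    batch <- 0.8 * grp + rnorm(n, 0, 0.6)       # confounded with group
    load <- runif(p, 0.4, 0.9)
    v <- matrix(rnorm(p * n), p, n) + outer(load, batch)  # no true group effect
    x <- am(v, scaleTag = "zscore")
    naive <- fitProteinRegressions(x, data.frame(dx = grp), "dx",
                                   covariates = character())
    sv <- estimateSurrogateVariables(x, data.frame(g = grp), nSv = 2, seed = 4)
    adj <- fitProteinRegressions(x, data.frame(dx = grp), "dx",
                                 covariates = character(), svs = sv)
    expect_gt(mean(naive$p_raw < 0.05), 0.25)   # clearly inflated
    expect_lt(mean(adj$p_raw < 0.05), 0.12)     # near nominal again
})

test_that("planted positive effects come out with positive signs", {
    set.seed(49)
    hits <- 0; reps <- 20
    for (r in 1:reps) {
        n <- 120
        grp <- rep(c(0, 1), each = n / 2)
        y <- 1.0 * grp + rnorm(n)
        res <- fitProteinRegressions(am(matrix(y, 1, n)),
                                     data.frame(dx = grp), "dx",
                                     covariates = character())
        hits <- hits + (res$beta > 0)
    }
    expect_identical(hits, reps)
})
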