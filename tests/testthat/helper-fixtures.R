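# Shared fixture builders; everything is generated in code.

# Quick AnalyteMatrix from a numeric matrix (analytes x samples).
am <- function(values, scaleTag = "log2_npq") {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        rownames(values) <- paste0("P", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("S", seq_len(ncol(values)))
    AnalyteMatrix(values, scaleTag = scaleTag)
}

# Small deterministic cohort for integration-style tests.
smallCohort <- function(seed = 11, n = 40, p = 12, ...) {
    generateCohort(cohortConfig(n_per_group = n, n_analytes = p,
                                seed = seed, ...))
}

# Hand-rolled OLS via normal equations (independent oracle).
olsOracle <- function(X, y) {
    XtX <- t(X) %*% X
    beta <- solve(XtX, t(X) %*% y)
    res <- y - X %*% beta
    df <- length(y) - ncol(X)
    sigma2 <- sum(res^2) / df
    se <- sqrt(diag(solve(XtX)) * sigma2)
    list(beta = drop(beta), se = se, df = df)
}

# BH step-up by hand (independent oracle).
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(m)
    out[o] <- pmin(1, adj)
    out
}

# AUC by exhaustive pair counting with ties at 1/2 (independent oracle).
aucOracle <- function(scores, labels) {
    xs <- scores[labels == 1]; ys <- scores[labels == 0]
    tot <- 0
    for (x in xs) for (y in ys)
        tot <- tot + (x > y) + 0.5 * (x == y)
    tot / (length(xs) * length(ys))
}

# Newton-Raphson on the Cox partial likelihood, Breslow ties
# (independent oracle for small fixtures, single covariate vector
# or matrix).
coxNewtonOracle <- function(time, event, X, tol = 1e-10, maxIter = 50) {
    X <- as.matrix(X)
    beta <- rep(0, ncol(X))
    ord <- order(time)
    time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
    for (it in seq_len(maxIter)) {
        eta <- drop(X %*% beta)
        w <- exp(eta)
        U <- rep(0, ncol(X)); I <- matrix(0, ncol(X), ncol(X))
        for (t0 in unique(time[event == 1])) {
            risk <- which(time >= t0)
            dead <- which(time == t0 & event == 1)
            sw <- sum(w[risk])
            xb <- colSums(X[risk, , drop = FALSE] * w[risk]) / sw
            x2 <- t(X[risk, , drop = FALSE] * w[risk]) %*%
                X[risk, , drop = FALSE] / sw
            d <- length(dead)
            U <- U + colSums(X[dead, , drop = FALSE]) - d * xb
            I <- I + d * (x2 - outer(xb, xb))
        }
        step <- solve(I, U)
        beta <- beta + step
        if (max(abs(step)) < tol) break
    }
    list(beta = beta, infoInv = solve(I))
}
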