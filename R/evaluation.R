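#' Confusion matrix and agreement metrics for paired binary calls
#'
#' Builds the 2x2 table of predicted vs reference labels and its
#' derived metrics. Pairs where either label is missing (e.g. the
#' intermediate class of a tri-class rule, coded NA) are excluded and
#' counted in \code{n_excluded}. The concordance percentage is
#' reported to two decimals, rounding half away from zero — the
#' convention that reproduces printed study arithmetic such as
#' 297/325 = 91.38\%.
#'
#' @param predicted,reference binary labels (0/1, logical, or 2-level
#'   factors with the positive level second), equal length.
#' @return List: \code{tp}, \code{fp}, \code{tn}, \code{fn},
#'   \code{concordance} (\%), \code{sensitivity}, \code{specificity},
#'   \code{ppv}, \code{npv}, \code{n}, \code{n_excluded}.
#' @examples
#' confusionMetrics(c(1,1,0,0,1), c(1,0,0,0,1))
#' @export
confusionMetrics <- function(predicted, reference) {
    if (length(predicted) != length(reference))
        stop("'predicted' and 'reference' must be paired (equal length)")
    p <- .binLabels(predicted); r <- .binLabels(reference)
    ok <- !is.na(p) & !is.na(r)
    nExcluded <- sum(!ok)
    p <- p[ok]; r <- r[ok]
    if (!length(p)) stop("no complete pairs to evaluate")
    tp <- sum(p == 1 & r == 1); fp <- sum(p == 1 & r == 0)
    tn <- sum(p == 0 & r == 0); fn <- sum(p == 0 & r == 1)
    n <- tp + fp + tn + fn
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         concordance = .pctAway(tp + tn, n),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
         n = n, n_excluded = nExcluded)
}

#' ROC AUC with DeLong 95\% confidence interval
#'
#' The AUC equals the Mann-Whitney statistic \eqn{U/(n_1 n_0)} with
#' ties counted 1/2; the variance comes from DeLong's placement
#' values: \eqn{var = S_{10}/n_1 + S_{01}/n_0} where \eqn{S_{10}} and
#' \eqn{S_{01}} are the sample variances of the per-positive and
#' per-negative placements. The CI is clipped to [0, 1].
#'
#' @param scores numeric predictor (higher = more positive-like).
#' @param labels binary outcome.
#' @return List: \code{auc}, \code{ci_low}, \code{ci_high},
#'   \code{se}, \code{n_pos}, \code{n_neg}.
#' @export
rocAucDelong <- function(scores, labels) {
    lab <- .binLabels(labels)
    ok <- !is.na(scores) & !is.na(lab)
    scores <- scores[ok]; lab <- lab[ok]
    xs <- scores[lab == 1]; ys <- scores[lab == 0]
    n1 <- length(xs); n0 <- length(ys)
    if (n1 == 0 || n0 == 0)
        stop("undefined AUC: both classes must be present")
    psi <- function(x, y) (x > y) + 0.5 * (x == y)
    v10 <- vapply(xs, function(x) mean(psi(x, ys)), numeric(1))
    v01 <- vapply(ys, function(y) mean(psi(xs, y)), numeric(1))
    auc <- mean(v10)
    s10 <- if (n1 > 1) stats::var(v10) else 0
    s01 <- if (n0 > 1) stats::var(v01) else 0
    se <- sqrt(s10 / n1 + s01 / n0)
    z <- stats::qnorm(0.975)
    list(auc = auc,
         ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se),
         se = se, n_pos = n1, n_neg = n0)
}

#' Logistic regression predictor with ROC evaluation
#'
#' Maximum-likelihood logistic fit (IRLS via \code{stats::glm}) of a
#' binary outcome on a marker plus covariates (age and sex by
#' default); the fitted probabilities feed \code{\link{rocAucDelong}}.
#' Complete separation is detected (divergent coefficients /
#' degenerate fitted probabilities) and reported as an error rather
#' than silently returned.
#'
#' @param outcome binary outcome vector.
#' @param predictors data.frame (or matrix) of predictor columns.
#' @return List: \code{coefficients}, \code{fitted} (probabilities),
#'   \code{roc} (the \code{\link{rocAucDelong}} result), \code{n}.
#' @export
logisticPredictor <- function(outcome, predictors) {
    y <- .binLabels(outcome)
    df <- as.data.frame(predictors)
    cc <- !is.na(y) & stats::complete.cases(df)
    y <- y[cc]; df <- df[cc, , drop = FALSE]
    if (!any(y == 1) || !any(y == 0))
        stop("both outcome classes must be present")
    sepWarning <- FALSE
    fit <- withCallingHandlers(
        stats::glm(y ~ ., data = cbind(y = y, df), family = stats::binomial()),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1",
                      conditionMessage(w)))
                sepWarning <<- TRUE
            invokeRestart("muffleWarning")
        })
    pr <- stats::fitted(fit)
    if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
        (sepWarning && all(pr < 1e-5 | pr > 1 - 1e-5)))
        stop("complete (or quasi-complete) separation detected: ",
             "logistic fit diverged")
    list(coefficients = stats::coef(fit),
         se = summary(fit)$coefficients[, "Std. Error"],
         fitted = pr, roc = rocAucDelong(pr, y), n = length(y))
}

#' Kruskal-Wallis test with Dunn's post-hoc comparisons
#'
#' Rank-based one-way comparison across groups (tie-corrected H via
#' \code{stats::kruskal.test}), followed by Dunn's pairwise z tests on
#' mean ranks for the requested comparisons only, with Bonferroni
#' adjustment over exactly those comparisons (e.g. AD against each of
#' the other diagnosis groups).
#'
#' @param values numeric vector.
#' @param groups group labels (factor or character).
#' @param comparisons list of character(2) pairs to test (default:
#'   all pairs).
#' @return List: \code{H}, \code{df}, \code{p}, and \code{dunn} (a
#'   \code{data.frame}: \code{group1}, \code{group2}, \code{z},
#'   \code{p_raw}, \code{p_bonf}).
#' @export
kruskalDunn <- function(values, groups, comparisons = NULL) {
    groups <- factor(groups)
    ok <- !is.na(values) & !is.na(groups)
    values <- values[ok]; groups <- droplevels(groups[ok])
    if (nlevels(groups) < 2) stop("need at least 2 groups")
    if (any(table(groups) == 0)) stop("every group must be nonempty")
    kw <- stats::kruskal.test(values, groups)
    n <- length(values)
    rk <- rank(values)
    meanRank <- tapply(rk, groups, mean)
    ni <- table(groups)
    ties <- table(rk)
    tieCorr <- sum(ties^3 - ties) / (12 * (n - 1))
    if (is.null(comparisons)) {
        lv <- levels(groups)
        comparisons <- utils::combn(lv, 2, simplify = FALSE)
    }
    dunn <- do.call(rbind, lapply(comparisons, function(pr) {
        if (!all(pr %in% levels(groups)))
            stop("unknown group in comparison: ", paste(pr, collapse = " vs "))
        sig <- sqrt((n * (n + 1) / 12 - tieCorr) *
                    (1 / ni[[pr[1]]] + 1 / ni[[pr[2]]]))
        z <- (meanRank[[pr[1]]] - meanRank[[pr[2]]]) / sig
        data.frame(group1 = pr[1], group2 = pr[2], z = z,
                   p_raw = 2 * stats::pnorm(-abs(z)),
                   stringsAsFactors = FALSE)
    }))
    dunn$p_bonf <- pmin(1, length(comparisons) * dunn$p_raw)
    list(H = unname(kw$statistic), df = unname(kw$parameter),
         p = kw$p.value, dunn = dunn)
}

#' Per-analyte correlation between two measurement platforms
#'
#' Pearson correlation of analyte-paired measurements (replicate runs,
#' matrix conditions, or cross-platform matches), one r and p per
#' analyte, with the summary used in panel reproducibility reporting:
#' the mean correlation and the percentage of analytes at or above a
#' threshold (two decimals, half away from zero).
#'
#' @param x,y numeric matrices (analytes x samples) with matching
#'   rownames, or a single list of per-analyte paired data.frames.
#' @param threshold correlation threshold for the summary count.
#' @return List: \code{per_analyte} (\code{data.frame}: analyte, r, p,
#'   n, skipped_reason), \code{mean_r}, \code{n_above},
#'   \code{pct_above}, \code{n_tested}.
#' @export
platformCorrelation <- function(x, y, threshold = 0.7) {
    shared <- intersect(rownames(x), rownames(y))
    if (!length(shared)) stop("no shared analytes between platforms")
    res <- do.call(rbind, lapply(shared, function(an) {
        xv <- x[an, ]; yv <- y[an, ]
        ok <- !is.na(xv) & !is.na(yv)
        if (sum(ok) < 3)
            return(data.frame(analyte = an, r = NA_real_, p = NA_real_,
                              n = sum(ok), skipped_reason = "fewer than 3 pairs"))
        if (stats::sd(xv[ok]) == 0 || stats::sd(yv[ok]) == 0)
            return(data.frame(analyte = an, r = NA_real_, p = NA_real_,
                              n = sum(ok), skipped_reason = "constant vector"))
        ct <- stats::cor.test(xv[ok], yv[ok], method = "pearson")
        data.frame(analyte = an, r = unname(ct$estimate), p = ct$p.value,
                   n = sum(ok), skipped_reason = NA_character_)
    }))
    tested <- res[!is.na(res$r), ]
    nAbove <- sum(tested$r >= threshold)
    list(per_analyte = res, mean_r = mean(tested$r),
         n_above = nAbove, pct_above = .pctAway(nAbove, nrow(res)),
         n_tested = nrow(tested))
}

.APOE_GENOTYPES <- c("e2e2", "e2e3", "e3e3", "e2e4", "e3e4", "e4e4")

#' Concordance of proteoform-based APOE-e4 calls with genotype
#'
#' Compares binary e4-detected calls (e.g. from a GMM crossing on the
#' e4-proteoform analyte) against SNP-derived APOE genotypes, where
#' e4-positive means any genotype containing an e4 allele. Reports the
#' overall 2x2 \code{\link{confusionMetrics}} plus stratified
#' concordance within each genotype subgroup. Rows with an unknown
#' genotype string are excluded and logged.
#'
#' @param calls binary e4-detected calls.
#' @param genotypes character genotypes among
#'   \code{e2e2, e2e3, e3e3, e2e4, e3e4, e4e4} (the common
#'   \code{"e3/e4"} spelling is accepted).
#' @return List: \code{overall} (confusion summary),
#'   \code{per_genotype} (\code{data.frame}: genotype, n, n_concordant,
#'   concordance), \code{n_excluded}.
#' @export
apoeConcordance <- function(calls, genotypes) {
    gt <- tolower(genotypes)
    gt <- gsub("ε", "e", gt)       # accept the epsilon spelling
    gt <- gsub("/", "", gt, fixed = TRUE)
    known <- gt %in% .APOE_GENOTYPES
    if (any(!known))
        message(sum(!known), " row(s) with unknown genotype excluded")
    calls <- .binLabels(calls)[known]
    gt <- gt[known]
    truth <- as.integer(gt %in% c("e2e4", "e3e4", "e4e4"))
    overall <- confusionMetrics(calls, truth)
    per <- do.call(rbind, lapply(.APOE_GENOTYPES, function(g) {
        idx <- gt == g
        if (!any(idx)) return(NULL)
        conc <- sum(calls[idx] == truth[idx])
        data.frame(genotype = g, n = sum(idx), n_concordant = conc,
                   concordance = .pctAway(conc, sum(idx)))
    }))
    list(overall = overall, per_genotype = per, n_excluded = sum(!known))
}

#' Hypergeometric over-representation test with fold enrichment
#'
#' For each annotation set (pathway), tests whether the differentially
#' abundant proteins overlap it more than expected by chance
#' (hypergeometric upper tail) and reports fold enrichment: the
#' proportion of DA proteins in the pathway divided by the proportion
#' of background proteins in it, \eqn{(k/n) / (K/N)}. BH is applied
#' across pathways.
#'
#' @param daSet character vector of differentially abundant protein
#'   ids (must be a subset of \code{background}).
#' @param annotation named list mapping pathway id to member protein
#'   ids (members outside the background are ignored).
#' @param background character vector of all assayed protein ids.
#' @return \code{data.frame}: \code{pathway}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{fold_enrichment}, \code{p_raw},
#'   \code{p_fdr}.
#' @export
overrepresentationTest <- function(daSet, annotation, background) {
    background <- unique(background)
    N <- length(background)
    if (!N) stop("background must be nonempty")
    if (!all(daSet %in% background))
        stop("daSet must be a subset of the background")
    daSet <- unique(daSet)
    n <- length(daSet)
    res <- do.call(rbind, lapply(names(annotation), function(pw) {
        members <- intersect(unique(annotation[[pw]]), background)
        K <- length(members)
        k <- length(intersect(daSet, members))
        fe <- if (n == 0 || K == 0) NA_real_ else (k / n) / (K / N)
        p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(pathway = pw, k = k, K = K, n = n, N = N,
                   fold_enrichment = fe, p_raw = p,
                   stringsAsFactors = FALSE)
    }))
    res$p_fdr <- adjustBH(res$p_raw)
    res
}

#' Read / write annotation maps in GMT format
#'
#' @param path GMT file (set name, description, then member ids,
#'   tab-separated).
#' @return \code{readGmt}: named list of member-id vectors.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- lapply(lines, function(l) {
        f <- strsplit(l, "\t", fixed = TRUE)[[1]]
        f[-(1:2)]
    })
    names(out) <- vapply(lines, function(l)
        strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
    out
}

#' @rdname readGmt
#' @param sets named list of member-id vectors.
#' @param description optional per-set description (recycled).
#' @export
writeGmt <- function(sets, path, description = "na") {
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], rep_len(description, length(sets))[i],
                sets[[i]]), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}
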