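#' Estimate surrogate variables from residual expression structure
#'
#' Estimates latent covariates (surrogate variables) that absorb
#' unmodeled structure such as batch effects, for inclusion alongside
#' age and sex in the per-protein regressions. Missing cells are first
#' imputed by sampling observed values of the same analyte with
#' replacement (seeded); the primary design (intercept + known
#' covariates of interest) is projected out of each analyte and the
#' candidate surrogate variables are the leading left singular vectors
#' of the sample x analyte residual matrix. One reweighting pass then
#' refines them: each analyte is weighted by how much of its residual
#' variance the candidates explain, discounted by how much of its
#' total variance the primary design explains, and the surrogate
#' variables are re-estimated as the leading singular vectors of the
#' weighted centered data. Re-decomposing the data (rather than the
#' residuals) lets a surrogate variable retain the component of a
#' batch factor that is correlated with the design, which is exactly
#' what adjusting for it must remove. The returned vectors are
#' orthonormal.
#'
#' @param x a z-scored \linkS4class{AnalyteMatrix}.
#' @param design data.frame (or model matrix) of the primary design:
#'   the variables whose effects must be kept out of the surrogate
#'   variables (e.g. group, age, sex). Must be full rank.
#' @param nSv number of surrogate variables (default 2).
#' @param seed seed for the imputation draw.
#' @return A samples x \code{nSv} matrix of orthonormal surrogate
#'   variables (rownames = sample ids).
#' @export
estimateSurrogateVariables <- function(x, design, nSv = 2L, seed = 1L) {
    stopifnot(is(x, "AnalyteMatrix"))
    v <- t(npq(x))                      # samples x analytes
    n <- nrow(v); p <- ncol(v)
    if (nSv >= min(n, p))
        stop("nSv must be smaller than both the sample and analyte counts")
    mm <- if (is.matrix(design)) design else
        stats::model.matrix(~ ., data = as.data.frame(design))
    if (nrow(mm) != n)
        stop("design rows must match the number of samples")
    if (qr(mm)$rank < ncol(mm))
        stop("primary design is rank deficient")
    .withSeed(seed, {
        for (j in seq_len(p)) {
            mis <- is.na(v[, j])
            if (any(mis)) {
                obs <- v[!mis, j]
                if (!length(obs))
                    stop("analyte '", colnames(v)[j], "' has no observed values")
                v[mis, j] <- sample(obs, sum(mis), replace = TRUE)
            }
        }
        qrd <- qr(mm)
        resid <- qr.resid(qrd, v)
        sv <- svd(resid, nu = nSv, nv = 0)$u
        # reweighting pass: favor analytes whose residuals the candidate
        # SVs explain, discount analytes driven by the primary design,
        # then re-decompose the weighted centered data
        fitted <- sv %*% crossprod(sv, resid)
        eps <- .Machine$double.eps
        r2sv <- colSums(fitted^2) / pmax(colSums(resid^2), eps)
        vc <- scale(v, center = TRUE, scale = FALSE)
        r2prim <- 1 - colSums(resid^2) / pmax(colSums(vc^2), eps)
        w <- r2sv * pmax(1 - r2prim, 0)
        sv <- svd(vc * rep(w, each = n), nu = nSv, nv = 0)$u
        rownames(sv) <- rownames(v)
        colnames(sv) <- paste0("SV", seq_len(nSv))
        sv
    })
}

#' Per-protein linear regression (differential abundance)
#'
#' Ordinary least squares of each analyte's (z-scored) abundance on a
#' predictor plus covariates, complete cases per analyte. The
#' predictor may be a two-level factor/logical contrast (e.g. disease
#' vs control) or a continuous phenotype. Returns the predictor term's
#' effect size, standard error, two-sided t-test p-value and the BH
#' FDR-adjusted p-value across the analytes of this analysis family.
#'
#' @param x an \linkS4class{AnalyteMatrix} (z-scored for the main
#'   pipeline, but any scale is accepted).
#' @param data data.frame of per-sample variables, rows aligned with
#'   \code{sampleIds(x)}; must contain \code{predictor} and
#'   \code{covariates}.
#' @param predictor name of the predictor column. Factors must have
#'   exactly 2 levels (reference first).
#' @param covariates character vector of covariate column names
#'   (default \code{c("age", "sex")}).
#' @param svs optional samples x k matrix of surrogate variables to
#'   adjust for (rows aligned with samples).
#' @return \code{data.frame} with one row per analyte: \code{analyte},
#'   \code{beta}, \code{se}, \code{p_raw}, \code{p_fdr},
#'   \code{n_used}, and \code{skipped_reason} (NA for fitted
#'   analytes). Analytes with too few complete cases or a
#'   rank-deficient design are skipped with a reason.
#' @examples
#' cohort <- generateCohort(cohortConfig(n_per_group = 30, n_analytes = 8))
#' z <- normalizeNpq(cohort$matrix, "zscore")
#' keep <- cohort$annotation$group %in% c("CO", "AD")
#' res <- fitProteinRegressions(z[, keep],
#'     data.frame(dx = droplevels(cohort$annotation$group[keep]),
#'                age = cohort$annotation$age[keep],
#'                sex = cohort$annotation$sex[keep]),
#'     predictor = "dx")
#' head(res)
#' @export
fitProteinRegressions <- function(x, data, predictor,
                                  covariates = c("age", "sex"),
                                  svs = NULL) {
    stopifnot(is(x, "AnalyteMatrix"))
    data <- as.data.frame(data)
    if (nrow(data) != ncol(x))
        stop("'data' must have one row per sample of 'x'")
    need <- c(predictor, covariates)
    miss <- setdiff(need, colnames(data))
    if (length(miss))
        stop("missing design column(s): ", paste(miss, collapse = ", "))
    pv <- data[[predictor]]
    if (is.character(pv)) pv <- factor(pv)
    if (is.factor(pv)) {
        if (nlevels(droplevels(pv)) != 2L)
            stop("factor predictor must have exactly 2 levels")
        pv <- as.numeric(droplevels(pv)) - 1
    } else if (is.logical(pv)) pv <- as.numeric(pv)
    X <- cbind(`(Intercept)` = 1, predictor = pv)
    for (cv in covariates) {
        col <- data[[cv]]
        if (is.character(col)) col <- factor(col)
        if (is.factor(col))
            X <- cbind(X, stats::model.matrix(~ col)[, -1, drop = FALSE])
        else X <- cbind(X, stats::setNames(data.frame(col), cv))
    }
    X <- as.matrix(X)
    if (!is.null(svs)) {
        svs <- as.matrix(svs)
        if (nrow(svs) != ncol(x))
            stop("'svs' must have one row per sample of 'x'")
        colnames(svs) <- paste0("SV", seq_len(ncol(svs)))
        X <- cbind(X, svs)
    }
    v <- npq(x)
    k <- ncol(X)
    out <- data.frame(analyte = rownames(v), beta = NA_real_, se = NA_real_,
                      p_raw = NA_real_, p_fdr = NA_real_, n_used = NA_integer_,
                      skipped_reason = NA_character_,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(v))) {
        y <- v[i, ]
        cc <- !is.na(y) & stats::complete.cases(X)
        nUsed <- sum(cc)
        if (nUsed < k + 2L) {
            out$skipped_reason[i] <- if (nUsed == 0L) "all values missing" else
                "too few complete cases"
            next
        }
        Xi <- X[cc, , drop = FALSE]
        qrd <- qr(Xi)
        if (qrd$rank < k) {
            out$skipped_reason[i] <- "rank-deficient design"
            next
        }
        fit <- stats::lm.fit(Xi, y[cc])
        rss <- sum(fit$residuals^2)
        dfres <- nUsed - k
        sigma2 <- rss / dfres
        XtXinv <- chol2inv(chol(crossprod(Xi)))
        j <- match("predictor", colnames(Xi))
        beta <- fit$coefficients[j]
        se <- sqrt(sigma2 * XtXinv[j, j])
        out$beta[i] <- beta
        out$se[i] <- se
        out$p_raw[i] <- if (se == 0) (if (beta == 0) 1 else 0) else
            2 * stats::pt(-abs(beta / se), dfres)
        out$n_used[i] <- nUsed
    }
    fitted <- !is.na(out$p_raw)
    out$p_fdr[fitted] <- adjustBH(out$p_raw[fitted])
    out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH adjusted p-values (monotone in the input ranks, capped
#' at 1), the adjustment used for every analysis family in this
#' pipeline. Thin validated wrapper over
#' \code{stats::p.adjust(method = "BH")}.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
adjustBH <- function(p) {
    if (!is.numeric(p) || any(!is.na(p) & (p < 0 | p > 1)))
        stop("p-values must be numeric in [0, 1]")
    stats::p.adjust(p, method = "BH")
}
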