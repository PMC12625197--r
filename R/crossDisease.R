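#' Two-tailed z-test comparing two estimated effect sizes
#'
#' The z statistic is the difference in estimated effects divided by
#' the square root of the summed squared standard errors,
#' \eqn{z = (b_1 - b_2) / \sqrt{se_1^2 + se_2^2}}, with a two-sided
#' p-value from the standard normal distribution. Vectorized over
#' analytes; apply \code{\link{adjustBH}} across analytes per contrast
#' pair downstream.
#'
#' @param b1,b2 effect estimates.
#' @param se1,se2 their standard errors (not both zero).
#' @return \code{data.frame} with columns \code{z}, \code{p}.
#' @examples
#' effectSizeZTest(1.4, 0.3, 0.7, 0.4)  # z = 1.4, p ~ 0.1615
#' @export
effectSizeZTest <- function(b1, se1, b2, se2) {
    if (any(se1 < 0 | se2 < 0, na.rm = TRUE))
        stop("standard errors must be nonnegative")
    denom <- sqrt(se1^2 + se2^2)
    if (any(!is.na(denom) & denom == 0))
        stop("undefined statistic: both standard errors are zero")
    z <- (b1 - b2) / denom
    data.frame(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare effect sizes of two contrasts across all shared analytes
#'
#' Runs \code{\link{effectSizeZTest}} analyte-wise on two differential
#' abundance result tables, applies BH across analytes, and assigns
#' the discordance category used in cross-disease scatter displays:
#' \code{fdr_significant} (FDR p < 0.05), \code{nominal} (raw p < 0.05
#' only), else \code{ns}.
#'
#' @param res1,res2 \code{data.frame}s from
#'   \code{\link{fitProteinRegressions}} (columns \code{analyte},
#'   \code{beta}, \code{se}).
#' @return \code{data.frame} with \code{analyte}, \code{beta1},
#'   \code{beta2}, \code{z}, \code{p_raw}, \code{p_fdr},
#'   \code{category}.
#' @export
compareContrasts <- function(res1, res2) {
    shared <- intersect(res1$analyte, res2$analyte)
    if (!length(shared)) stop("no shared analytes between the two contrasts")
    a <- res1[match(shared, res1$analyte), ]
    b <- res2[match(shared, res2$analyte), ]
    ok <- !is.na(a$beta) & !is.na(b$beta)
    zt <- effectSizeZTest(a$beta[ok], a$se[ok], b$beta[ok], b$se[ok])
    out <- data.frame(analyte = shared, beta1 = a$beta, beta2 = b$beta,
                      z = NA_real_, p_raw = NA_real_, p_fdr = NA_real_,
                      category = "ns", stringsAsFactors = FALSE)
    out$z[ok] <- zt$z
    out$p_raw[ok] <- zt$p
    out$p_fdr[ok] <- adjustBH(zt$p)
    out$category <- ifelse(!is.na(out$p_fdr) & out$p_fdr < 0.05,
                           "fdr_significant",
                    ifelse(!is.na(out$p_raw) & out$p_raw < 0.05,
                           "nominal", "ns"))
    out
}

#' Assemble an effect-size table across contrasts
#'
#' @param results named list of \code{\link{fitProteinRegressions}}
#'   outputs, one per contrast (e.g.
#'   \code{list(AD = ..., DLB = ...)}).
#' @return List of analyte x contrast matrices \code{beta}, \code{se},
#'   \code{p_raw}, \code{p_fdr} over the shared analyte universe.
#' @export
effectSizeTable <- function(results) {
    stopifnot(is.list(results), !is.null(names(results)))
    analytes <- Reduce(intersect, lapply(results, `[[`, "analyte"))
    pull <- function(col) {
        m <- vapply(results, function(r) r[[col]][match(analytes, r$analyte)],
                    numeric(length(analytes)))
        m <- matrix(m, nrow = length(analytes),
                    dimnames = list(analytes, names(results)))
        m
    }
    list(beta = pull("beta"), se = pull("se"),
         p_raw = pull("p_raw"), p_fdr = pull("p_fdr"))
}

#' Pearson correlation of two contrasts' effect-size vectors
#'
#' @param table an \code{\link{effectSizeTable}}.
#' @param pair character(2) of contrast names to compare.
#' @return List: \code{r}, \code{p} (t-transform of r), \code{n}.
#' @export
correlateEffectSizes <- function(table, pair) {
    b <- table$beta
    stopifnot(all(pair %in% colnames(b)))
    x <- b[, pair[1]]; y <- b[, pair[2]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) stop("need >= 3 shared analytes with estimates")
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        stop("undefined correlation: zero variance in an effect vector")
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Hierarchically cluster the effect-size matrix
#'
#' Complete-linkage agglomerative clustering with Euclidean distance
#' on both rows (analytes) and columns (contrasts). Rows and columns
#' are sorted lexicographically by label before clustering so that
#' results are deterministic under input permutation even in the
#' presence of tied merge heights.
#'
#' @param table an \code{\link{effectSizeTable}} (or a plain numeric
#'   matrix of effect sizes).
#' @param pairwiseComplete if TRUE, rows with missing values are
#'   allowed and distances use pairwise-complete coordinates;
#'   otherwise missing betas are an error.
#' @return List with \code{rows} and \code{cols}: \code{hclust} trees
#'   (single-leaf axes return NULL with a warning).
#' @export
clusterEffectMatrix <- function(table, pairwiseComplete = FALSE) {
    b <- if (is.list(table)) table$beta else as.matrix(table)
    if (anyNA(b) && !pairwiseComplete)
        stop("missing effect sizes; set pairwiseComplete = TRUE to allow")
    clusterAxis <- function(m) {
        if (nrow(m) < 2) {
            warning("fewer than 2 items on this axis: trivial tree")
            return(NULL)
        }
        if (is.null(rownames(m)))
            rownames(m) <- paste0("item", seq_len(nrow(m)))
        m <- m[order(rownames(m)), , drop = FALSE]
        d <- if (pairwiseComplete) .pairwiseEuclid(m) else stats::dist(m)
        stats::hclust(d, method = "complete")
    }
    list(rows = clusterAxis(b), cols = clusterAxis(t(b)))
}

.pairwiseEuclid <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        ok <- !is.na(m[i, ]) & !is.na(m[j, ])
        out[i, j] <- out[j, i] <-
            sqrt(sum((m[i, ok] - m[j, ok])^2) * ncol(m) / max(sum(ok), 1))
    }
    stats::as.dist(out)
}

#' Export a dendrogram as Newick
#'
#' @param hc an \code{hclust} tree.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeDendrogramNewick <- function(hc, path) {
    ape::write.tree(ape::as.phylo(hc), file = path)
    invisible(path)
}

#' Scorecard ranking of proteins across diseases
#'
#' Per protein and disease: +2 if the association is positive and
#' FDR-significant (FDR p < 0.05), +1 if positive and nominally
#' significant only (raw p < 0.05), -1/-2 mirrored for negative
#' associations, 0 otherwise. The total is the sum of per-disease
#' scores (consistent cross-disease direction scores high); the
#' absolute total sums the magnitudes (direction ignored). Proteins
#' are ranked by absolute total, then total.
#'
#' @param table an \code{\link{effectSizeTable}} whose contrasts are
#'   the diseases.
#' @param diseases contrast names to score (default: all).
#' @return \code{data.frame}: \code{analyte}, one score column per
#'   disease, \code{total}, \code{absolute_total}, \code{complete}
#'   (FALSE if any cell was missing and scored 0), sorted by rank.
#' @export
buildScorecard <- function(table, diseases = colnames(table$beta)) {
    b <- table$beta[, diseases, drop = FALSE]
    praw <- table$p_raw[, diseases, drop = FALSE]
    pfdr <- table$p_fdr[, diseases, drop = FALSE]
    sc <- sign(b) * ((!is.na(pfdr) & pfdr < 0.05) * 2 +
                     (!is.na(praw) & praw < 0.05 &
                      (is.na(pfdr) | pfdr >= 0.05)) * 1)
    incomplete <- is.na(b) | is.na(praw)
    sc[incomplete] <- 0
    out <- data.frame(analyte = rownames(b), sc, check.names = FALSE,
                      stringsAsFactors = FALSE)
    out$total <- rowSums(sc)
    out$absolute_total <- rowSums(abs(sc))
    out$complete <- !apply(incomplete, 1, any)
    out[order(-out$absolute_total, -out$total, out$analyte), ]
}
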