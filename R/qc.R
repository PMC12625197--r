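#' Mask per-analyte IQR outliers
#'
#' For each analyte (row), values strictly outside the Tukey fences
#' \eqn{[Q1 - 1.5\,IQR,\; Q3 + 1.5\,IQR]} are flagged as outliers and
#' replaced with \code{NA}; all other values are untouched. Quartiles
#' use linear interpolation between order statistics
#' (\code{quantile(type = 7)}), recorded in the report so results are
#' reproducible bit-for-bit. Values exactly on a fence are retained.
#'
#' Analytes with fewer than 4 non-missing values have undefined fences:
#' they are flagged in the report and left unmasked.
#'
#' @param x an \linkS4class{AnalyteMatrix} on the \code{log2_npq} scale.
#' @return A list with elements \code{matrix} (the masked
#'   \linkS4class{AnalyteMatrix}) and \code{report} (a
#'   \linkS4class{QCReport} carrying the fences and outlier counts).
#' @examples
#' m <- matrix(c(1:9, 100), nrow = 1,
#'             dimnames = list("P1", paste0("S", 1:10)))
#' out <- flagIqrOutliers(AnalyteMatrix(m))
#' sum(is.na(npq(out$matrix)))  # the value 100 is masked
#' @export
flagIqrOutliers <- function(x) {
    stopifnot(is(x, "AnalyteMatrix"))
    if (scaleTag(x) != "log2_npq")
        stop("IQR outlier masking is defined on the log2_npq scale; got '",
             scaleTag(x), "'")
    v <- npq(x)
    nAn <- nrow(v)
    fenceLo <- fenceHi <- rep(NA_real_, nAn)
    defined <- rep(FALSE, nAn)
    nOut <- integer(nAn)
    for (i in seq_len(nAn)) {
        row <- v[i, ]
        obs <- row[!is.na(row)]
        if (length(obs) < 4L) next
        q <- stats::quantile(obs, c(0.25, 0.75), type = 7, names = FALSE)
        iqr <- q[2] - q[1]
        fenceLo[i] <- q[1] - 1.5 * iqr
        fenceHi[i] <- q[2] + 1.5 * iqr
        defined[i] <- TRUE
        bad <- !is.na(row) & (row < fenceLo[i] | row > fenceHi[i])
        nOut[i] <- sum(bad)
        v[i, bad] <- NA_real_
    }
    out <- x
    SummarizedExperiment::assay(out, "npq") <- v
    report <- new("QCReport",
        analyteStats = S4Vectors::DataFrame(
            call_rate = rowMeans(!is.na(v)),
            fence_lo = fenceLo, fence_hi = fenceHi,
            n_outliers = nOut, fences_defined = defined,
            row.names = rownames(v)),
        sampleStats = S4Vectors::DataFrame(
            call_rate = colMeans(!is.na(v)), row.names = colnames(v)),
        removedAnalytes = data.frame(id = character(), step = character(),
                                     call_rate = numeric()),
        removedSamples = data.frame(id = character(), step = character(),
                                    call_rate = numeric()),
        thresholds = numeric(), quantileType = 7L)
    list(matrix = out, report = report)
}

#' Call rates per analyte and per sample
#'
#' The call rate is the proportion of successful (non-missing)
#' measurements along the respective axis.
#'
#' @param x an \linkS4class{AnalyteMatrix}.
#' @return List with numeric vectors \code{analyte} and \code{sample},
#'   both in \code{[0, 1]}, named by id.
#' @export
computeCallRates <- function(x) {
    stopifnot(is(x, "AnalyteMatrix"))
    v <- npq(x)
    if (nrow(v) == 0L || ncol(v) == 0L)
        stop("cannot compute call rates on an empty matrix")
    list(analyte = rowMeans(!is.na(v)), sample = colMeans(!is.na(v)))
}

#' Two-step call-rate threshold filter
#'
#' Removes low-quality analytes and samples in two passes: first all
#' analytes, then all samples, with call rate below the first threshold
#' (default 65\%); call rates are then recomputed on the reduced matrix
#' and the second threshold (default 85\%) is applied the same way.
#' Recomputing between the steps retains borderline analytes and
#' samples whose rates rise once grossly incomplete rows/columns are
#' gone. Within a step, analytes are filtered first and sample rates
#' are recomputed on the analyte-reduced matrix before the sample
#' filter, so every survivor meets the step's threshold at the moment
#' it is applied.
#'
#' @param x an \linkS4class{AnalyteMatrix}, typically after
#'   \code{\link{flagIqrOutliers}}.
#' @param thresholds increasing numeric(2) of call-rate thresholds in
#'   (0, 1].
#' @return List with \code{matrix} (the filtered
#'   \linkS4class{AnalyteMatrix}) and \code{report}
#'   (\linkS4class{QCReport} listing removals per step).
#' @export
twoStepCallRateFilter <- function(x, thresholds = c(0.65, 0.85)) {
    stopifnot(is(x, "AnalyteMatrix"))
    if (length(thresholds) != 2L || any(thresholds <= 0) ||
        any(thresholds > 1) || diff(thresholds) <= 0)
        stop("'thresholds' must be two increasing call rates in (0, 1]")
    stepLabels <- paste0("step", round(100 * thresholds))
    v <- npq(x)
    remA <- data.frame(id = character(), step = character(), call_rate = numeric())
    remS <- data.frame(id = character(), step = character(), call_rate = numeric())
    for (k in 1:2) {
        thr <- thresholds[k]
        ra <- rowMeans(!is.na(v))
        dropA <- ra < thr
        if (any(dropA)) {
            remA <- rbind(remA, data.frame(id = rownames(v)[dropA],
                                           step = stepLabels[k],
                                           call_rate = unname(ra[dropA])))
            v <- v[!dropA, , drop = FALSE]
        }
        rs <- colMeans(!is.na(v))
        dropS <- rs < thr
        if (any(dropS)) {
            remS <- rbind(remS, data.frame(id = colnames(v)[dropS],
                                           step = stepLabels[k],
                                           call_rate = unname(rs[dropS])))
            v <- v[, !dropS, drop = FALSE]
        }
    }
    out <- x[rownames(v), colnames(v)]
    report <- new("QCReport",
        analyteStats = S4Vectors::DataFrame(
            call_rate = rowMeans(!is.na(v)), row.names = rownames(v)),
        sampleStats = S4Vectors::DataFrame(
            call_rate = colMeans(!is.na(v)), row.names = colnames(v)),
        removedAnalytes = remA, removedSamples = remS,
        thresholds = thresholds, quantileType = 7L)
    list(matrix = out, report = report)
}

#' Limit of detection and coefficient of variation per analyte
#'
#' Reported for information only, never used as a filter. CV is
#' computed on the linear scale over replicate groups as
#' \eqn{100 \cdot SD/mean}, averaged across groups with >= 2 observed
#' replicates. LOD is \code{mean + 3 SD} of the designated
#' negative-control samples on the linear scale (a working definition,
#' flagged as an assumption in the output).
#'
#' @param x an \linkS4class{AnalyteMatrix} on the \code{log2_npq} or
#'   \code{linear_npq} scale (log2 values are back-transformed).
#' @param controlIds character vector of negative-control sample ids
#'   (may be empty: LOD reported as \code{NA}).
#' @param replicateGroups optional list of character vectors of sample
#'   ids, each a replicate group (\code{NULL}: CV reported as
#'   \code{NA}).
#' @return \code{data.frame} with columns \code{analyte}, \code{lod},
#'   \code{cv_pct} and attribute \code{lod_definition}.
#' @export
computeLodCv <- function(x, controlIds = character(), replicateGroups = NULL) {
    stopifnot(is(x, "AnalyteMatrix"))
    v <- npq(x)
    if (scaleTag(x) == "log2_npq") v <- 2^v
    else if (scaleTag(x) != "linear_npq")
        stop("LOD/CV need linear-scale values (scale_tag log2_npq or linear_npq)")
    lod <- rep(NA_real_, nrow(v))
    if (length(controlIds)) {
        miss <- setdiff(controlIds, colnames(v))
        if (length(miss))
            stop("unknown control sample ids: ", paste(miss, collapse = ", "))
        ctl <- v[, controlIds, drop = FALSE]
        mu <- rowMeans(ctl, na.rm = TRUE)
        sdv <- apply(ctl, 1, stats::sd, na.rm = TRUE)
        sdv[is.na(sdv)] <- 0  # single control: SD undefined -> 0
        lod <- mu + 3 * sdv
    }
    cv <- rep(NA_real_, nrow(v))
    if (!is.null(replicateGroups) && length(replicateGroups)) {
        perGroup <- vapply(replicateGroups, function(ids) {
            g <- v[, ids, drop = FALSE]
            m <- rowMeans(g, na.rm = TRUE)
            s <- apply(g, 1, stats::sd, na.rm = TRUE)
            n <- rowSums(!is.na(g))
            out <- 100 * s / m
            out[n < 2] <- NA_real_
            out
        }, numeric(nrow(v)))
        perGroup <- matrix(perGroup, nrow = nrow(v))
        cv <- rowMeans(perGroup, na.rm = TRUE)
        cv[is.nan(cv)] <- NA_real_
    }
    out <- data.frame(analyte = rownames(v), lod = unname(lod),
                      cv_pct = unname(cv))
    attr(out, "lod_definition") <-
        "mean + 3*SD of negative-control samples, linear NPQ scale (assumed)"
    out
}

#' Normalize along the NPQ scale chain
#'
#' Moves an \linkS4class{AnalyteMatrix} forward along the chain
#' \code{log2_npq -> linear_npq -> log10 -> zscore}, applying each
#' elementwise step in turn: back-transform \code{linear = 2^log2},
#' elementwise \code{log10}, then a per-analyte z-score over the
#' non-missing retained samples (mean 0, SD 1, sample SD). Missing
#' cells stay missing. The z-score step stores per-analyte means and
#' SDs (and the chain) in \code{metadata(x)$normalization}, which
#' \code{\link{deriveCutoffs}} inverts to report linear-NPQ cutoff
#' equivalents.
#'
#' Moving backwards is also supported stage by stage (e.g.
#' \code{linear_npq -> log2_npq} recovers the input to numerical
#' precision; \code{zscore -> log10} requires the stored constants), so
#' the chain can be inverted without leaving the class.
#'
#' @param x an \linkS4class{AnalyteMatrix}.
#' @param target the destination scale tag; any other tag on the chain.
#' @param ... unused.
#' @return The transformed \linkS4class{AnalyteMatrix} with its
#'   \code{scale_tag} updated.
#' @examples
#' m <- matrix(c(10, 11, 12), 1, 3,
#'             dimnames = list("P1", c("a", "b", "c")))
#' z <- normalizeNpq(AnalyteMatrix(m), "zscore")
#' npq(z)
#' @export
setMethod("normalizeNpq", "AnalyteMatrix", function(x, target, ...) {
    from <- match(scaleTag(x), .SCALE_TAGS)
    to <- match(target, .SCALE_TAGS)
    if (is.na(to)) stop("unknown target scale '", target, "'")
    if (to == from)
        stop("matrix is already on scale '", target, "'")
    v <- npq(x)
    norm <- metadata(x)$normalization
    if (is.null(norm)) norm <- list(chain = scaleTag(x))
    if (to < from) {
        # inverse direction, one stage at a time
        for (step in seq(from, to + 1L)) {
            stage <- .SCALE_TAGS[step]
            if (stage == "zscore") {
                if (is.null(norm$zscore_mean))
                    stop("cannot invert z-score: no stored normalization constants")
                v <- v * norm$zscore_sd + norm$zscore_mean
            } else if (stage == "log10") {
                v <- 10^v
            } else if (stage == "linear_npq") {
                bad <- which(!is.na(v) & v <= 0)
                if (length(bad))
                    stop("nonpositive linear value(s) cannot be log2-transformed")
                v <- log2(v)
            }
            norm$chain <- c(norm$chain, .SCALE_TAGS[step - 1L])
        }
        out <- x
        SummarizedExperiment::assay(out, "npq") <- v
        metadata(out)$scale_tag <- target
        metadata(out)$normalization <- norm
        return(out)
    }
    for (step in seq(from, to - 1L)) {
        stage <- .SCALE_TAGS[step + 1L]
        if (stage == "linear_npq") {
            v <- 2^v
        } else if (stage == "log10") {
            bad <- which(!is.na(v) & v <= 0)
            if (length(bad))
                stop(sprintf(
                    "%d nonpositive linear value(s) cannot be log10-transformed (first at cell %d)",
                    length(bad), bad[1]))
            v <- log10(v)
        } else if (stage == "zscore") {
            mu <- rowMeans(v, na.rm = TRUE)
            sdv <- apply(v, 1, stats::sd, na.rm = TRUE)
            if (any(!is.na(sdv) & sdv == 0))
                warning("constant analyte(s): z-score undefined, returned as NA")
            v <- (v - mu) / sdv
            norm$zscore_mean <- mu
            norm$zscore_sd <- sdv
        }
        norm$chain <- c(norm$chain, stage)
    }
    out <- x
    SummarizedExperiment::assay(out, "npq") <- v
    metadata(out)$scale_tag <- target
    metadata(out)$normalization <- norm
    out
})

#' Invert the z-score + log10 normalization for one analyte
#'
#' Maps a z-score back to the linear NPQ scale using the per-analyte
#' normalization constants stored by \code{\link{normalizeNpq}}.
#'
#' @param z numeric z-score(s).
#' @param x the z-scored \linkS4class{AnalyteMatrix} holding the
#'   normalization metadata.
#' @param analyte analyte id.
#' @return Linear NPQ value(s).
#' @export
zscoreToLinear <- function(z, x, analyte) {
    norm <- metadata(x)$normalization
    if (is.null(norm$zscore_mean))
        stop("no z-score normalization constants stored on this matrix")
    if (!analyte %in% names(norm$zscore_mean))
        stop("unknown analyte '", analyte, "'")
    10^(z * norm$zscore_sd[[analyte]] + norm$zscore_mean[[analyte]])
}
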