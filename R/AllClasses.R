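#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

.SCALE_TAGS <- c("log2_npq", "linear_npq", "log10", "zscore")

#' AnalyteMatrix: sample x analyte abundance container
#'
#' The central carrier of the pipeline: a
#' \linkS4class{SummarizedExperiment} whose single assay \code{"npq"}
#' holds analyte abundances (rows = analytes, columns = samples;
#' \code{NA} encodes a missing/failed measurement) plus a scale tag
#' recording where the matrix sits on the NPQ normalization chain
#' \code{log2_npq -> linear_npq -> log10 -> zscore}. Sample annotation
#' (diagnosis group, age at draw, sex, APOE genotype, imaging and CSF
#' phenotypes, follow-up ages) lives in \code{colData}.
#'
#' Use \code{\link{AnalyteMatrix}} to construct, \code{\link{npq}} and
#' \code{\link{scaleTag}} to access, and \code{\link{normalizeNpq}} to
#' move along the scale chain (the only sanctioned way to change the
#' tag).
#'
#' @aliases AnalyteMatrix-class
#' @exportClass AnalyteMatrix
setClass("AnalyteMatrix", contains = "SummarizedExperiment")

setValidity("AnalyteMatrix", function(object) {
    msg <- character()
    if (!("npq" %in% names(assays(object))))
        msg <- c(msg, "assay 'npq' is required")
    tag <- metadata(object)$scale_tag
    if (is.null(tag) || !is.character(tag) || length(tag) != 1L ||
        !(tag %in% .SCALE_TAGS))
        msg <- c(msg, sprintf("metadata scale_tag must be one of %s",
                              paste(.SCALE_TAGS, collapse = ", ")))
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "analyte ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids (colnames) must be present and unique")
    if (length(msg)) msg else TRUE
})

#' QCReport: record of the QC chain applied to an AnalyteMatrix
#'
#' Holds per-analyte call rates, IQR fences and outlier counts,
#' per-sample call rates, and the analytes/samples removed at each step
#' of the two-step call-rate filter (step labels \code{"step65"},
#' \code{"step85"} for the default 0.65/0.85 thresholds).
#'
#' @slot analyteStats \code{DataFrame} with one row per analyte of the
#'   input matrix: \code{call_rate}, \code{fence_lo}, \code{fence_hi},
#'   \code{n_outliers}, \code{fences_defined}.
#' @slot sampleStats \code{DataFrame} with one row per sample:
#'   \code{call_rate}.
#' @slot removedAnalytes,removedSamples \code{data.frame}s with columns
#'   \code{id}, \code{step}, \code{call_rate}.
#' @slot thresholds numeric(2), the two call-rate thresholds.
#' @slot quantileType integer, the quantile convention used for fences
#'   (7 = linear interpolation between order statistics).
#' @exportClass QCReport
setClass("QCReport", representation(
    analyteStats = "DataFrame",
    sampleStats = "DataFrame",
    removedAnalytes = "data.frame",
    removedSamples = "data.frame",
    thresholds = "numeric",
    quantileType = "integer"))

setValidity("QCReport", function(object) {
    msg <- character()
    cr <- object@analyteStats$call_rate
    if (length(cr) && (any(cr < 0, na.rm = TRUE) || any(cr > 1, na.rm = TRUE)))
        msg <- c(msg, "analyte call rates must lie in [0, 1]")
    cs <- object@sampleStats$call_rate
    if (length(cs) && (any(cs < 0, na.rm = TRUE) || any(cs > 1, na.rm = TRUE)))
        msg <- c(msg, "sample call rates must lie in [0, 1]")
    for (df in list(object@removedAnalytes, object@removedSamples))
        if (nrow(df) && !all(grepl("^step[0-9]+$", df$step)))
            msg <- c(msg, "removal step labels must look like 'step65'")
    if (length(msg)) msg else TRUE
})

#' GMMFit: two-component univariate Gaussian mixture fit
#'
#' Result of \code{\link{fitTwoComponentGmm}}: EM estimates with
#' components relabeled so that \code{means[1] < means[2]}, plus the
#' log-likelihood trace (nondecreasing by the EM guarantee).
#'
#' @slot weights numeric(2) mixing proportions, sum to 1.
#' @slot means numeric(2), ordered increasing.
#' @slot sds numeric(2), strictly positive.
#' @slot logLik numeric, per-iteration observed-data log-likelihood.
#' @slot converged logical.
#' @slot nIter integer.
#' @slot varianceFloorActive logical, TRUE if the variance floor was hit.
#' @exportClass GMMFit
setClass("GMMFit", representation(
    weights = "numeric", means = "numeric", sds = "numeric",
    logLik = "numeric", converged = "logical", nIter = "integer",
    varianceFloorActive = "logical"))

setValidity("GMMFit", function(object) {
    msg <- character()
    if (length(object@weights) != 2L || abs(sum(object@weights) - 1) > 1e-8 ||
        any(object@weights <= 0) || any(object@weights >= 1))
        msg <- c(msg, "weights must be two proportions in (0,1) summing to 1")
    if (length(object@means) != 2L || object@means[1] > object@means[2])
        msg <- c(msg, "means must be length 2 with means[1] <= means[2]")
    if (length(object@sds) != 2L || any(object@sds <= 0))
        msg <- c(msg, "sds must be length 2 and positive")
    if (length(msg)) msg else TRUE
})

#' CutoffSet: data-driven positivity cutoffs for a z-scored biomarker
#'
#' Bundles the Gaussian-mixture equal-likelihood crossing cutoff, the
#' Youden-index cutoff, and the dual cutoffs (largest threshold with
#' sensitivity >= the target = lower; smallest threshold with
#' specificity >= the target = upper) on the z-score scale, with their
#' linear-NPQ equivalents obtained by inverting the stored
#' normalization chain when available.
#'
#' @slot gmmCutoff,youdenCutoff,lowerCutoff,upperCutoff numeric(1)
#'   cutoffs on the z-score scale (may be NA when not derived).
#' @slot linearEquivalents named numeric, linear-NPQ values of the
#'   cutoffs (empty when normalization constants are unknown).
#' @slot achieved named numeric, achieved sensitivity/specificity and
#'   Youden J on the derivation set.
#' @slot gmm the \linkS4class{GMMFit} behind the crossing cutoff, or NULL.
#' @exportClass CutoffSet
setClass("CutoffSet", representation(
    gmmCutoff = "numeric", youdenCutoff = "numeric",
    lowerCutoff = "numeric", upperCutoff = "numeric",
    linearEquivalents = "numeric", achieved = "numeric",
    gmm = "ANY"))
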