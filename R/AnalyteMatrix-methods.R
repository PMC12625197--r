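#' Construct an AnalyteMatrix
#'
#' @param values numeric matrix of abundances, analytes in rows and
#'   samples in columns, with unique dimnames. \code{NA} marks a
#'   missing or failed measurement.
#' @param sampleData optional \code{data.frame}/\code{DataFrame} of
#'   per-sample annotation (one row per column of \code{values}).
#' @param scaleTag scale of \code{values}; one of \code{"log2_npq"}
#'   (assay default), \code{"linear_npq"}, \code{"log10"},
#'   \code{"zscore"}.
#'
#' @return An \linkS4class{AnalyteMatrix}.
#' @examples
#' m <- matrix(rnorm(12, 10), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("S", 1:4)))
#' am <- AnalyteMatrix(m)
#' scaleTag(am)
#' @export
AnalyteMatrix <- function(values, sampleData = NULL, scaleTag = "log2_npq") {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        rownames(values) <- paste0("analyte", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("sample", seq_len(ncol(values)))
    if (is.null(sampleData))
        sampleData <- S4Vectors::DataFrame(row.names = colnames(values))
    se <- SummarizedExperiment(assays = list(npq = values),
                               colData = sampleData)
    metadata(se)$scale_tag <- scaleTag
    new("AnalyteMatrix", se)
}

#' Abundance values of an AnalyteMatrix
#'
#' @param x an \linkS4class{AnalyteMatrix}.
#' @param ... unused.
#' @return The analyte x sample numeric matrix (assay \code{"npq"}).
#' @export
setMethod("npq", "AnalyteMatrix", function(x, ...) assay(x, "npq"))

#' Scale tag of an AnalyteMatrix
#'
#' @param x an \linkS4class{AnalyteMatrix}.
#' @return Character scalar: where \code{x} sits on the normalization
#'   chain \code{log2_npq -> linear_npq -> log10 -> zscore}.
#' @export
setMethod("scaleTag", "AnalyteMatrix", function(x) metadata(x)$scale_tag)

#' Analyte and sample identifiers
#'
#' @param x an \linkS4class{AnalyteMatrix}.
#' @return Character vector of ids.
#' @export
setMethod("analyteIds", "AnalyteMatrix", function(x) rownames(x))

#' @rdname analyteIds
#' @export
setMethod("sampleIds", "AnalyteMatrix", function(x) colnames(x))

setMethod("show", "AnalyteMatrix", function(object) {
    callNextMethod()
    cat("scale_tag:", scaleTag(object), "\n")
})

setMethod("show", "GMMFit", function(object) {
    cat("Two-component Gaussian mixture fit\n")
    cat(sprintf("  weights: %.4f / %.4f\n", object@weights[1], object@weights[2]))
    cat(sprintf("  means:   %.4f / %.4f\n", object@means[1], object@means[2]))
    cat(sprintf("  sds:     %.4f / %.4f\n", object@sds[1], object@sds[2]))
    cat(sprintf("  %s after %d EM iterations (logLik %.4f)\n",
                if (object@converged) "converged" else "NOT converged",
                object@nIter, object@logLik[length(object@logLik)]))
    if (object@varianceFloorActive)
        cat("  note: variance floor was active\n")
})

setMethod("show", "CutoffSet", function(object) {
    cat("Biomarker cutoff set (z-score scale)\n")
    cat(sprintf("  GMM crossing: %s\n", format(object@gmmCutoff)))
    cat(sprintf("  Youden:       %s\n", format(object@youdenCutoff)))
    cat(sprintf("  dual lower (sens target): %s\n", format(object@lowerCutoff)))
    cat(sprintf("  dual upper (spec target): %s\n", format(object@upperCutoff)))
    if (length(object@linearEquivalents)) {
        cat("  linear NPQ equivalents:\n")
        for (nm in names(object@linearEquivalents))
            cat(sprintf("    %s: %.2f\n", nm, object@linearEquivalents[[nm]]))
    }
})

setMethod("show", "QCReport", function(object) {
    cat("QC report\n")
    cat(sprintf("  analytes tracked: %d; samples tracked: %d\n",
                nrow(object@analyteStats), nrow(object@sampleStats)))
    cat(sprintf("  removed analytes: %d; removed samples: %d\n",
                nrow(object@removedAnalytes), nrow(object@removedSamples)))
    if (length(object@thresholds))
        cat(sprintf("  call-rate thresholds: %s\n",
                    paste(object@thresholds, collapse = ", ")))
})

#' Accessors for QCReport contents
#'
#' @param report a \linkS4class{QCReport}.
#' @return \code{qcAnalyteStats}/\code{qcSampleStats}: per-id
#'   \code{DataFrame}s; \code{qcRemoved}: a \code{data.frame} of removed
#'   ids with the step at which each was removed.
#' @export
qcAnalyteStats <- function(report) report@analyteStats

#' @rdname qcAnalyteStats
#' @export
qcSampleStats <- function(report) report@sampleStats

#' @rdname qcAnalyteStats
#' @param axis \code{"analytes"} or \code{"samples"}.
#' @export
qcRemoved <- function(report, axis = c("analytes", "samples")) {
    axis <- match.arg(axis)
    if (axis == "analytes") report@removedAnalytes else report@removedSamples
}

#' Read / write the tab-separated AnalyteMatrix dialect
#'
#' The on-disk layout is samples in rows and analytes in columns: a
#' header row of analyte ids, first column \code{sample_id}, empty cell
#' = missing. \code{readAnalyteMatrix} transposes into the internal
#' analytes x samples orientation.
#'
#' @param path file path.
#' @param scaleTag scale tag to stamp on the matrix read.
#' @return \code{readAnalyteMatrix}: an \linkS4class{AnalyteMatrix}.
#' @export
readAnalyteMatrix <- function(path, scaleTag = "log2_npq") {
    df <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
    if (colnames(df)[1] != "sample_id")
        stop("first column of an analyte matrix file must be 'sample_id'")
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    AnalyteMatrix(t(m), scaleTag = scaleTag)
}

#' @rdname readAnalyteMatrix
#' @param x an \linkS4class{AnalyteMatrix} to write.
#' @export
writeAnalyteMatrix <- function(x, path) {
    m <- t(npq(x))
    df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    invisible(path)
}
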