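#' @rdname npq
#' @export
setGeneric("npq", function(x, ...) standardGeneric("npq"))

#' @rdname scaleTag
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' @rdname analyteIds
#' @export
setGeneric("analyteIds", function(x) standardGeneric("analyteIds"))

#' @rdname analyteIds
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname normalizeNpq
#' @export
setGeneric("normalizeNpq", function(x, target, ...) standardGeneric("normalizeNpq"))
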