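#' @rdname tokenLabels
#' @export
setGeneric("tokenLabels", function(x) standardGeneric("tokenLabels"))

#' @rdname tokenLabels
#' @export
setGeneric("tokenTable", function(x) standardGeneric("tokenTable"))

#' @rdname tokenLabels
#' @export
setGeneric("nTokens", function(x) standardGeneric("nTokens"))

#' @rdname phonemeOf
#' @export
setGeneric("phonemeOf", function(x, token) standardGeneric("phonemeOf"))

#' @rdname accessors
#' @export
setGeneric("design", function(x) standardGeneric("design"))

#' @rdname accessors
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' @rdname accessors
#' @export
setGeneric("unitMeta", function(x) standardGeneric("unitMeta"))

#' @rdname accessors
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x, unit, token, repetition)
  standardGeneric("spikeTimes"))

#' @rdname accessors
#' @export
setGeneric("meanRate", function(x, unit) standardGeneric("meanRate"))

#' @rdname percentCorrect
#' @export
setGeneric("percentCorrect", function(x) standardGeneric("percentCorrect"))

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))

#' @rdname accessors
#' @export
setGeneric("ngMatrix", function(x) standardGeneric("ngMatrix"))

#' @rdname accessors
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))

#' @rdname accessors
#' @export
setGeneric("optimum", function(x) standardGeneric("optimum"))
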