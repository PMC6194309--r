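#' Accessors for the package's S4 containers
#'
#' Small read-only accessors: \code{design} returns the embedded
#' \linkS4class{StimulusDesign}; \code{unitIds}/\code{unitMeta}/\code{nUnits}
#' expose the unit table; \code{spikeTimes} returns one spike train;
#' \code{meanRate} the unit's mean evoked rate (spikes/s over the response
#' window, all tokens and repetitions); \code{counts} the confusion counts;
#' \code{ngMatrix} the neurogram matrix; \code{sweepTable}/\code{optimum}
#' the sweep results.
#'
#' @param x the object.
#' @param unit unit id.
#' @param token token label.
#' @param repetition repetition index, 1-based.
#' @name accessors
NULL

#' @rdname accessors
setMethod("design", "SpikeDataset", function(x) x@design)

#' @rdname accessors
setMethod("design", "RateField", function(x) x@params@design)

#' @rdname accessors
setMethod("unitIds", "SpikeDataset", function(x) as.character(x@units$unit_id))

#' @rdname accessors
setMethod("unitMeta", "SpikeDataset", function(x) x@units)

#' @rdname accessors
setMethod("nUnits", "SpikeDataset", function(x) nrow(x@units))

#' @rdname accessors
setMethod("spikeTimes", "SpikeDataset", function(x, unit, token, repetition) {
  su <- x@spikes[[as.character(unit)]]
  if (is.null(su)) stop("unknown unit: ", unit)
  st <- su[[token]]
  if (is.null(st)) stop("unknown token: ", token)
  if (repetition < 1L || repetition > x@design@nRepetitions)
    stop("repetition out of range: ", repetition)
  st[[repetition]]
})

#' @rdname accessors
setMethod("meanRate", "SpikeDataset", function(x, unit) {
  su <- x@spikes[[as.character(unit)]]
  if (is.null(su)) stop("unknown unit: ", unit)
  win <- x@design@responseWindow
  n <- sum(vapply(su, function(tok) sum(vapply(tok, function(r)
    sum(r < win), numeric(1))), numeric(1)))
  trials <- nTokens(x@design) * x@design@nRepetitions
  n / trials / (win / 1000)
})

#' @rdname accessors
setMethod("counts", "ConfusionMatrix", function(x) x@counts)

#' @rdname accessors
setMethod("ngMatrix", "Neurogram", function(x) x@mat)

#' @rdname accessors
setMethod("sweepTable", "SweepResult", function(x) x@results)

#' @rdname accessors
setMethod("optimum", "SweepResult", function(x) x@optimum)

## ---- show methods -------------------------------------------------------

setMethod("show", "StimulusDesign", function(object) {
  cat(sprintf(
    "StimulusDesign: %d phonemes x %d talkers (%d tokens), %d repetitions\n",
    length(object@phonemes), length(object@talkers), nTokens(object),
    object@nRepetitions))
  cat(sprintf("  stimulus %g ms, response window %g ms, %g-ms bins\n",
              object@stimulusDuration, object@responseWindow, object@binWidth))
})

setMethod("show", "SpikeDataset", function(object) {
  cat(sprintf("SpikeDataset: %d units, %d tokens x %d repetitions\n",
              nUnits(object), nTokens(object@design), object@design@nRepetitions))
  rg <- unique(object@units$region)
  cat("  regions:", paste(rg[!is.na(rg)], collapse = ", "), "\n")
})

setMethod("show", "Neurogram", function(object) {
  cat(sprintf("Neurogram: %d units x %d bins (%g-ms bins, %g-ms smoothing)\n",
              nrow(object@mat), ncol(object@mat), object@binWidth,
              object@smoothingLength))
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat(sprintf("ConfusionMatrix (%s mode): %d classes, %d trials, %.2f%% correct\n",
              object@mode, length(object@labels), sum(object@counts),
              percentCorrect(object)))
})

setMethod("show", "ClassifierResult", function(object) {
  cat(sprintf(
    "ClassifierResult (%s mode, %g-ms window, +/-%g-ms lag): %.2f%% correct\n",
    object@mode, object@smoothingLength, object@maxLag, object@percentCorrect))
  cat(sprintf("  chance level: %.2f%%\n", 100 / length(object@confusion@labels)))
})

setMethod("show", "SweepResult", function(object) {
  cat(sprintf("SweepResult over %s (%s mode): %d evaluations\n",
              object@parameter, object@mode, nrow(object@results)))
  if (!is.na(object@optimum))
    cat(sprintf("  optimum: %g\n", object@optimum))
})

setMethod("show", "GeneratorParams", function(object) {
  cat(sprintf(
    "GeneratorParams ('%s'): %d units, base %g sp/s, selectivity %.2f,\n",
    object@preset, object@nUnits, object@baseRate, object@selectivity))
  cat(sprintf("  talkerSd %g ms, jitterSd %g ms, onsetOnly %s, seed %d\n",
              object@talkerSd, object@jitterSd, object@onsetOnly, object@seed))
})

setMethod("show", "RateField", function(object) {
  d <- dim(object@rates)
  cat(sprintf("RateField: %d units x %d tokens x %d bins ('%s' preset)\n",
              d[1], d[2], d[3], object@params@preset))
})

setMethod("show", "RawTrace", function(object) {
  cat(sprintf("RawTrace: %d samples at %g Hz (%.1f ms)\n",
              length(object@samples), object@sampleRate,
              1000 * length(object@samples) / object@sampleRate))
})
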