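## Central S4 containers. All times are in milliseconds; bins are half-open
## [t, t + binWidth) with 0-based bin origins at stimulus onset.

#' Stimulus design: the phoneme x talker x repetition labelling scheme
#'
#' Describes the stimulus set and the analysis timing constants. Every
#' (phoneme, talker) pair is one distinct *token* class. The defaults match
#' the standard VCV design: 16 phonemes x 3 talkers x 10 repetitions,
#' 700-ms stimuli analysed over the first 650 ms in 1-ms bins.
#'
#' @slot phonemes character vector of phoneme labels.
#' @slot talkers character vector of talker labels.
#' @slot nRepetitions number of repetitions per token.
#' @slot stimulusDuration stimulus length, ms.
#' @slot responseWindow analysis window from stimulus onset, ms; must not
#'   exceed \code{stimulusDuration} and must be a multiple of \code{binWidth}.
#' @slot binWidth PSTH bin width, ms.
#'
#' @export
setClass("StimulusDesign",
  representation(
    phonemes = "character",
    talkers = "character",
    nRepetitions = "integer",
    stimulusDuration = "numeric",
    responseWindow = "numeric",
    binWidth = "numeric"
  )
)

setValidity("StimulusDesign", function(object) {
  msg <- character()
  if (length(object@phonemes) < 1L) msg <- c(msg, "at least one phoneme is required")
  if (length(object@talkers) < 1L) msg <- c(msg, "at least one talker is required")
  if (anyDuplicated(object@phonemes)) msg <- c(msg, "phoneme labels must be unique")
  if (anyDuplicated(object@talkers)) msg <- c(msg, "talker labels must be unique")
  if (length(object@nRepetitions) != 1L || object@nRepetitions < 1L)
    msg <- c(msg, "nRepetitions must be a single positive integer")
  if (object@stimulusDuration <= 0) msg <- c(msg, "stimulusDuration must be positive")
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be positive")
  if (object@responseWindow > object@stimulusDuration)
    msg <- c(msg, "responseWindow must not exceed stimulusDuration")
  if (object@responseWindow <= 0) msg <- c(msg, "responseWindow must be positive")
  if (abs(object@responseWindow / object@binWidth -
          round(object@responseWindow / object@binWidth)) > 1e-9)
    msg <- c(msg, "binWidth must divide responseWindow")
  if (length(msg)) msg else TRUE
})

#' @describeIn StimulusDesign-class Constructor with the default VCV design.
#'
#' @param phonemes,talkers,nRepetitions,stimulusDuration,responseWindow,binWidth
#'   see slots.
#' @return A validated \code{StimulusDesign}.
#' @examples
#' d <- StimulusDesign()
#' nTokens(d) # 48
#' @export
StimulusDesign <- function(phonemes = defaultPhonemes(),
                           talkers = c("M2", "M3", "M5"),
                           nRepetitions = 10,
                           stimulusDuration = 700,
                           responseWindow = 650,
                           binWidth = 1) {
  new("StimulusDesign",
    phonemes = as.character(phonemes), talkers = as.character(talkers),
    nRepetitions = as.integer(nRepetitions),
    stimulusDuration = as.numeric(stimulusDuration),
    responseWindow = as.numeric(responseWindow),
    binWidth = as.numeric(binWidth)
  )
}

#' Default phoneme labels: 16 medial consonants in /a/-C-/a/ context
#' @return character vector of 16 VCV labels.
#' @export
defaultPhonemes <- function() {
  c("aba", "ada", "adha", "afa", "aga", "aja", "aka", "ala",
    "ama", "ana", "apa", "asa", "asha", "ata", "ava", "aza")
}

#' Labelled spike-time dataset for one recorded or simulated population
#'
#' Spike times (ms from stimulus onset) indexed by (unit, token, repetition),
#' with per-unit metadata. The spike slot is a nested list:
#' \code{spikes[[unit_id]][[token_label]][[repetition]]} is a sorted numeric
#' vector (possibly empty) of spike times in \code{[0, stimulusDuration)}.
#'
#' @slot design a \linkS4class{StimulusDesign}.
#' @slot units data.frame with columns \code{unit_id} (unique character),
#'   \code{region} (character) and \code{cf} (characteristic frequency, Hz;
#'   \code{NA} allowed).
#' @slot spikes nested list as described above.
#' @export
setClass("SpikeDataset",
  representation(design = "StimulusDesign", units = "data.frame", spikes = "list")
)

setValidity("SpikeDataset", function(object) {
  msg <- character()
  u <- object@units
  need <- c("unit_id", "region", "cf")
  if (!all(need %in% names(u)))
    return(paste("units must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(u$unit_id)) msg <- c(msg, "unit_id must be unique")
  if (any(!is.na(u$cf) & u$cf <= 0)) msg <- c(msg, "cf must be positive when present")
  toks <- tokenLabels(object@design)
  R <- object@design@nRepetitions
  dur <- object@design@stimulusDuration
  if (!identical(sort(names(object@spikes)), sort(as.character(u$unit_id))))
    return("spike list names must match unit_id")
  for (uid in names(object@spikes)) {
    su <- object@spikes[[uid]]
    if (!identical(sort(names(su)), sort(toks)))
      return(sprintf("unit '%s': spike list must cover every token class", uid))
    for (tok in names(su)) {
      st <- su[[tok]]
      if (length(st) != R)
        return(sprintf("unit '%s', token '%s': expected %d repetitions", uid, tok, R))
      for (r in seq_len(R)) {
        x <- st[[r]]
        if (length(x)) {
          if (is.unsorted(x)) msg <- c(msg, sprintf(
            "unit '%s', token '%s', rep %d: spike times must be sorted", uid, tok, r))
          if (min(x) < 0 || max(x) >= dur) msg <- c(msg, sprintf(
            "unit '%s', token '%s', rep %d: spike times must lie in [0, %g)",
            uid, tok, r, dur))
        }
      }
    }
  }
  if (length(msg)) head(msg, 3L) else TRUE
})

#' @describeIn SpikeDataset-class Constructor.
#' @param design,units,spikes see slots.
#' @export
SpikeDataset <- function(design, units, spikes) {
  units$unit_id <- as.character(units$unit_id)
  if (is.null(units$region)) units$region <- NA_character_
  if (is.null(units$cf)) units$cf <- NA_real_
  new("SpikeDataset", design = design, units = units, spikes = spikes)
}

#' Neurogram: a units x time-bins response matrix
#'
#' Rows are units ordered by characteristic frequency (units lacking a CF
#' follow, in unit_id order); columns are PSTH time bins, optionally smoothed
#' by a unit-sum Hamming window.
#'
#' @slot mat numeric matrix, units x bins, non-negative.
#' @slot unitOrder character vector of unit ids, one per row.
#' @slot binWidth bin width, ms.
#' @slot smoothingLength Hamming window length, ms (1 = unsmoothed).
#' @export
setClass("Neurogram",
  representation(mat = "matrix", unitOrder = "character",
                 binWidth = "numeric", smoothingLength = "numeric")
)

setValidity("Neurogram", function(object) {
  if (nrow(object@mat) != length(object@unitOrder))
    return("row count must equal length(unitOrder)")
  if (any(object@mat < -1e-9)) return("neurogram values must be non-negative")
  if (object@binWidth <= 0) return("binWidth must be positive")
  if (object@smoothingLength < 1) return("smoothingLength must be >= 1 ms")
  TRUE
})

#' Confusion matrix from leave-one-repetition-out classification
#'
#' @slot labels class labels (token labels, or phoneme labels for the
#'   phoneme / hierarchical modes).
#' @slot counts integer matrix, rows = true class, columns = predicted.
#' @slot mode one of \code{"token"}, \code{"phoneme"}, \code{"hierarchical"}.
#' @export
setClass("ConfusionMatrix",
  representation(labels = "character", counts = "matrix", mode = "character")
)

setValidity("ConfusionMatrix", function(object) {
  k <- length(object@labels)
  if (!all(dim(object@counts) == c(k, k))) return("counts must be labels x labels")
  if (any(object@counts < 0)) return("counts must be non-negative")
  if (!object@mode %in% c("token", "phoneme", "hierarchical"))
    return("mode must be token, phoneme or hierarchical")
  TRUE
})

#' @describeIn ConfusionMatrix-class Constructor.
#' @param labels,counts,mode see slots.
#' @export
ConfusionMatrix <- function(labels, counts, mode = "token") {
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(true = labels, predicted = labels))
  new("ConfusionMatrix", labels = as.character(labels), counts = counts, mode = mode)
}

#' Result of one classifier evaluation
#'
#' @slot confusion a \linkS4class{ConfusionMatrix}.
#' @slot percentCorrect overall percent correct (100 x trace / total).
#' @slot perTrial data.frame with one row per held-out trial: \code{token},
#'   \code{repetition}, \code{true}, \code{predicted}, \code{bestLag} (ms),
#'   \code{minDistance}, \code{correct}.
#' @slot mode classifier mode.
#' @slot smoothingLength Hamming window, ms.
#' @slot maxLag lag-search half-range, ms.
#' @export
setClass("ClassifierResult",
  representation(confusion = "ConfusionMatrix", percentCorrect = "numeric",
                 perTrial = "data.frame", mode = "character",
                 smoothingLength = "numeric", maxLag = "numeric")
)

#' Sweep experiment result
#'
#' @slot parameter name of the swept parameter.
#' @slot results long-format data.frame; always has columns \code{value}
#'   (the swept value) and \code{percentCorrect}, plus \code{draw} for
#'   random-subpopulation sweeps.
#' @slot mode classifier mode used.
#' @slot seed RNG seed (NA for deterministic sweeps).
#' @slot optimum the best swept value (argmax percent correct; ties go to
#'   the smallest value), NA when not applicable.
#' @export
setClass("SweepResult",
  representation(parameter = "character", results = "data.frame",
                 mode = "character", seed = "integer", optimum = "numeric")
)

#' Parameters of the synthetic population generator
#'
#' Presets map onto the qualitative codes seen along the ascending auditory
#' pathway: \code{"dense"} (auditory-nerve-like: high rates, unselective,
#' sub-millisecond precision), \code{"intermediate"} (midbrain-like) and
#' \code{"sparse"} (cortex-like: low rates, highly selective, transient,
#' 10-20 ms jitter).
#'
#' @slot design a \linkS4class{StimulusDesign}.
#' @slot nUnits number of units.
#' @slot preset preset name.
#' @slot baseRate driven firing rate scale, spikes/s.
#' @slot eventRateGain gain on the density of latent envelope events.
#' @slot selectivity fraction of phoneme classes driving each unit, in (0, 1].
#' @slot talkerSd temporal shift scale between talker variants of one
#'   phoneme, ms.
#' @slot jitterSd trial-to-trial Gaussian spike-time jitter, ms.
#' @slot onsetOnly if TRUE responses are transient (onset-weighted).
#' @slot seed master seed; all stages draw from named substreams of it.
#' @export
setClass("GeneratorParams",
  representation(design = "StimulusDesign", nUnits = "integer",
                 preset = "character", baseRate = "numeric",
                 eventRateGain = "numeric", selectivity = "numeric",
                 talkerSd = "numeric", jitterSd = "numeric",
                 onsetOnly = "logical", seed = "integer")
)

setValidity("GeneratorParams", function(object) {
  msg <- character()
  if (object@nUnits < 1L) msg <- c(msg, "nUnits must be >= 1")
  if (object@baseRate < 0) msg <- c(msg, "baseRate must be >= 0")
  if (object@selectivity <= 0 || object@selectivity > 1)
    msg <- c(msg, "selectivity must lie in (0, 1]")
  if (object@talkerSd < 0 || object@jitterSd < 0)
    msg <- c(msg, "temporal scales must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Latent firing-rate field underlying a synthetic population
#'
#' @slot rates array units x tokens x time-bins of intensities (spikes/s)
#'   over the full stimulus duration at the design bin width.
#' @slot unitIds,tokenLabels dimension labels.
#' @slot params the \linkS4class{GeneratorParams} that produced it.
#' @export
setClass("RateField",
  representation(rates = "array", unitIds = "character",
                 tokenLabels = "character", params = "GeneratorParams")
)

setValidity("RateField", function(object) {
  d <- dim(object@rates)
  if (length(d) != 3L) return("rates must be a 3-d array")
  if (d[1] != length(object@unitIds) || d[2] != length(object@tokenLabels))
    return("rates dimensions must match unitIds and tokenLabels")
  if (any(!is.finite(object@rates)) || any(object@rates < 0))
    return("rates must be finite and non-negative")
  TRUE
})

#' Raw extracellular voltage trace
#'
#' @slot samples numeric vector of voltages (arbitrary units).
#' @slot sampleRate sampling rate, Hz.
#' @export
setClass("RawTrace", representation(samples = "numeric", sampleRate = "numeric"))

setValidity("RawTrace", function(object) {
  if (object@sampleRate <= 0) return("sampleRate must be positive")
  if (any(!is.finite(object@samples))) return("samples must be finite")
  TRUE
})

#' @describeIn RawTrace-class Constructor.
#' @param samples,sampleRate see slots.
#' @export
RawTrace <- function(samples, sampleRate) {
  new("RawTrace", samples = as.numeric(samples), sampleRate = as.numeric(sampleRate))
}

#' Spike-detection parameters
#'
#' Houses the bandpass corner frequencies (default 0.3-6 kHz, fourth-order
#' Butterworth applied forward-backward for zero phase), the robust threshold
#' multiplier (default 4) with its 0.6745 median-absolute-deviation
#' normaliser, and the detector dead time.
#'
#' @slot bandLow,bandHigh passband corners, Hz.
#' @slot filterOrder designed Butterworth order (the forward-backward pass
#'   doubles the effective order).
#' @slot thresholdMultiplier multiple of the estimated noise SD.
#' @slot deadTime minimum inter-spike interval, ms.
#' @export
setClass("DetectionParams",
  representation(bandLow = "numeric", bandHigh = "numeric",
                 filterOrder = "integer", thresholdMultiplier = "numeric",
                 deadTime = "numeric")
)

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (object@bandLow <= 0 || object@bandHigh <= object@bandLow)
    msg <- c(msg, "need 0 < bandLow < bandHigh")
  if (object@thresholdMultiplier <= 0) msg <- c(msg, "thresholdMultiplier must be > 0")
  if (object@deadTime < 0) msg <- c(msg, "deadTime must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn DetectionParams-class Constructor with the standard defaults.
#' @param bandLow,bandHigh,filterOrder,thresholdMultiplier,deadTime see slots.
#' @export
DetectionParams <- function(bandLow = 300, bandHigh = 6000, filterOrder = 4,
                            thresholdMultiplier = 4, deadTime = 1) {
  new("DetectionParams", bandLow = as.numeric(bandLow),
      bandHigh = as.numeric(bandHigh), filterOrder = as.integer(filterOrder),
      thresholdMultiplier = as.numeric(thresholdMultiplier),
      deadTime = as.numeric(deadTime))
}
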