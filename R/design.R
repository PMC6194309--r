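## Token vocabulary. Tokens are structured (phoneme, talker) pairs held in a
## lookup table; the printable label is derived for display and file I/O, and
## phonemeOf() resolves labels through the table rather than parsing text.

.tokenLabel <- function(phoneme, talker) paste(phoneme, talker, sep = ".")

#' Token classes of a stimulus design
#'
#' Every (phoneme, talker) pair is one token class. Enumeration order is
#' deterministic: phoneme-major, then talker, in the order the design lists
#' them. \code{tokenTable} returns the structured pairs, \code{tokenLabels}
#' the corresponding printable labels, and \code{nTokens} their count
#' (48 for the default 16-phoneme x 3-talker design).
#'
#' @param x a \linkS4class{StimulusDesign} (or an object carrying one).
#' @return \code{tokenTable}: data.frame with columns \code{token},
#'   \code{phoneme}, \code{talker}; \code{tokenLabels}: character vector;
#'   \code{nTokens}: integer.
#' @examples
#' tokenLabels(StimulusDesign(phonemes = c("aba", "ada"), talkers = c("T1", "T2")))
#' @name tokenLabels
NULL

#' @rdname tokenLabels
setMethod("tokenTable", "StimulusDesign", function(x) {
  ph <- rep(x@phonemes, each = length(x@talkers))
  tk <- rep(x@talkers, times = length(x@phonemes))
  data.frame(token = .tokenLabel(ph, tk), phoneme = ph, talker = tk,
             stringsAsFactors = FALSE)
})

#' @rdname tokenLabels
setMethod("tokenLabels", "StimulusDesign", function(x) tokenTable(x)$token)

#' @rdname tokenLabels
setMethod("nTokens", "StimulusDesign",
          function(x) length(x@phonemes) * length(x@talkers))

#' Phoneme component of a token class
#'
#' Projects token labels onto their phoneme class through the design's token
#' table; the map is many-to-one with one token per talker.
#'
#' @param x a \linkS4class{StimulusDesign}.
#' @param token character vector of token labels.
#' @return character vector of phoneme labels.
#' @examples
#' d <- StimulusDesign()
#' phonemeOf(d, "aba.M2")
#' @name phonemeOf
NULL

#' @rdname phonemeOf
setMethod("phonemeOf", "StimulusDesign", function(x, token) {
  tt <- tokenTable(x)
  i <- match(token, tt$token)
  if (anyNA(i))
    stop("unknown token label(s): ",
         paste(unique(token[is.na(i)]), collapse = ", "))
  tt$phoneme[i]
})

#' Number of time bins in the analysis window
#' @param design a \linkS4class{StimulusDesign}.
#' @return integer bin count (\code{responseWindow / binWidth}).
#' @export
nBins <- function(design) as.integer(round(design@responseWindow / design@binWidth))

#' Log-spaced characteristic-frequency grid
#'
#' Assigns characteristic frequencies evenly spaced on a logarithmic scale,
#' the convention used for simulated auditory-nerve fibre banks (default
#' 100 CFs over 0.1-5 kHz).
#'
#' @param n number of frequencies.
#' @param cfMin,cfMax range, Hz.
#' @return numeric vector of length \code{n}.
#' @export
cfGrid <- function(n = 100, cfMin = 100, cfMax = 5000) {
  stopifnot(n >= 1, cfMin > 0, cfMax > cfMin)
  if (n == 1L) return(sqrt(cfMin * cfMax))
  exp(seq(log(cfMin), log(cfMax), length.out = n))
}
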