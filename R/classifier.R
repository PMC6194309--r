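## Time-shifted nearest-neighbour classifier.
##
## Distances between a template X and a test x are Euclidean, evaluated at
## every relative lag within +/- maxLag: the template is trimmed by maxLag
## bins at both ends (only its fully overlapping core enters the sum) and
## the squared difference to each contiguous test slice is minimised over
## slice offsets. A single shared lag applies across all unit rows of a
## comparison.

.lagBins <- function(maxLag, binWidth) {
  L <- as.integer(round(maxLag / binWidth))
  if (L < 0L) stop("maxLag must be >= 0")
  L
}

.coreOf <- function(mat, L) {
  nb <- ncol(mat)
  if (2L * L >= nb)
    stop("2 * maxLag must be smaller than the number of bins")
  mat[, (L + 1L):(nb - L), drop = FALSE]
}

#' Minimum lagged Euclidean distance between two neurograms
#'
#' Trims the first and last \code{maxLag} ms from the template, slides the
#' trimmed core across the test neurogram over all relative lags in
#' \code{[-maxLag, +maxLag]} in one-bin steps, and returns the minimum
#' sum-of-squared-differences and the lag attaining it (ties resolve to the
#' most negative lag).
#'
#' @param template,test \linkS4class{Neurogram}s sharing unit order and bin
#'   width.
#' @param maxLag lag half-range, ms (default 100).
#' @return list with \code{distance}, \code{lag} (ms) and the full
#'   \code{distances} vector indexed by slice offset.
#' @export
laggedDistance <- function(template, test, maxLag = 100) {
  if (!identical(template@unitOrder, test@unitOrder))
    stop("template and test must share unitOrder")
  if (template@binWidth != test@binWidth)
    stop("template and test must share binWidth")
  L <- .lagBins(maxLag, template@binWidth)
  d <- .cppLagDistances(.coreOf(ngMatrix(template), L), ngMatrix(test))
  i <- which.min(d)
  list(distance = d[i], lag = (i - 1L - L) * template@binWidth, distances = d)
}

#' Classify one test neurogram against a set of class templates
#'
#' Argmin of \code{\link{laggedDistance}} over classes. Exact distance ties
#' resolve to the first class in the supplied (canonical) order, with a
#' warning.
#'
#' @param templates named list of template \linkS4class{Neurogram}s in
#'   canonical class order.
#' @param test the held-out single-trial \linkS4class{Neurogram}.
#' @param maxLag lag half-range, ms.
#' @return list with \code{predicted} (class label), \code{bestLag} (ms) and
#'   \code{distance}.
#' @export
classifyTrial <- function(templates, test, maxLag = 100) {
  if (length(templates) < 1L) stop("at least one template is required")
  dmin <- rep(Inf, length(templates))
  lag <- numeric(length(templates))
  for (j in seq_along(templates)) {
    r <- laggedDistance(templates[[j]], test, maxLag)
    dmin[j] <- r$distance
    lag[j] <- r$lag
  }
  best <- which.min(dmin)
  if (sum(dmin == dmin[best]) > 1L)
    warning("distance tie between classes; resolved to canonical order")
  list(predicted = names(templates)[best], bestLag = lag[best],
       distance = dmin[best])
}

## Merge full template matrices across talkers: align each to the first
## (canonical reference) by its best lag, then average element-wise over the
## aligned supports (bins covered by fewer talkers average over those only).
.mergeMats <- function(mats, L) {
  if (length(mats) == 1L) return(mats[[1L]])
  ref <- mats[[1L]]
  nb <- ncol(ref)
  core <- .coreOf(ref, L)
  acc <- ref
  cnt <- matrix(1, nrow(ref), nb)
  for (j in seq_along(mats)[-1L]) {
    other <- mats[[j]]
    if (!all(dim(other) == dim(ref))) stop("template shape mismatch")
    d <- .cppLagDistances(core, other)
    lag <- which.min(d) - 1L - L
    n <- max(1L, 1L - lag):min(nb, nb - lag)
    acc[, n] <- acc[, n] + other[, n + lag, drop = FALSE]
    cnt[, n] <- cnt[, n] + 1
  }
  acc / cnt
}

#' Merge per-talker templates into one phoneme template
#'
#' The first talker in canonical order is the reference; every other
#' talker's template is time-shifted by the lag minimising its distance to
#' the reference (the same lag-search kernel the classifier uses) and the
#' aligned templates are averaged element-wise over their common support.
#'
#' @param templates named list of per-talker \linkS4class{Neurogram}s for
#'   one phoneme, canonical talker order.
#' @param maxLag lag half-range, ms.
#' @return a \linkS4class{Neurogram}.
#' @export
mergeTalkerTemplates <- function(templates, maxLag = 100) {
  if (length(templates) < 1L) stop("at least one talker template is required")
  ref <- templates[[1L]]
  L <- .lagBins(maxLag, ref@binWidth)
  merged <- .mergeMats(lapply(templates, ngMatrix), L)
  new("Neurogram", mat = merged, unitOrder = ref@unitOrder,
      binWidth = ref@binWidth, smoothingLength = ref@smoothingLength)
}

#' Percent correct of a confusion matrix
#'
#' @param x a \linkS4class{ConfusionMatrix} or \linkS4class{ClassifierResult}.
#' @return 100 x trace / total.
#' @name percentCorrect
NULL

#' @rdname percentCorrect
setMethod("percentCorrect", "ConfusionMatrix", function(x) {
  tot <- sum(x@counts)
  if (tot == 0) stop("empty confusion matrix")
  100 * sum(diag(x@counts)) / tot
})

#' @rdname percentCorrect
setMethod("percentCorrect", "ClassifierResult", function(x) x@percentCorrect)

#' Chance level for a classifier mode
#'
#' 100 divided by the number of classes the mode discriminates: token
#' classes for \code{"token"}, phoneme classes for \code{"phoneme"} and
#' \code{"hierarchical"} (~2.08\% and ~6.25\% under the default design).
#'
#' @param design a \linkS4class{StimulusDesign}.
#' @param mode classifier mode.
#' @return percent.
#' @export
chanceLevel <- function(design, mode = c("token", "phoneme", "hierarchical")) {
  mode <- match.arg(mode)
  k <- if (mode == "token") nTokens(design) else length(design@phonemes)
  100 / k
}

#' Leave-one-repetition-out classifier evaluation
#'
#' For every repetition fold, that repetition of \emph{every} token is
#' removed, templates are averaged over the remaining repetitions, and each
#' held-out trial is classified by minimum time-shifted Euclidean distance.
#' Modes: \code{"token"} scores identity over all token classes;
#' \code{"phoneme"} classifies against talker-merged phoneme templates (see
#' \code{\link{mergeTalkerTemplates}}) and scores phoneme identity;
#' \code{"hierarchical"} runs token classification but disregards confusions
#' between talker variants of the same phoneme, i.e. scores
#' \code{phonemeOf(predicted) == phonemeOf(true)}.
#'
#' @param dataset a complete \linkS4class{SpikeDataset}.
#' @param mode classifier mode.
#' @param length Hamming smoothing window, ms (1 = unsmoothed).
#' @param maxLag lag-search half-range, ms (default 100).
#' @return a \linkS4class{ClassifierResult}.
#' @export
evaluateClassifier <- function(dataset,
                               mode = c("token", "phoneme", "hierarchical"),
                               length = 1, maxLag = 100) {
  mode <- match.arg(mode)
  des <- design(dataset)
  bw <- des@binWidth
  L <- .lagBins(maxLag, bw)
  nb <- nBins(des)
  if (2L * L >= nb) stop("2 * maxLag must be smaller than the response window")
  toks <- tokenLabels(des)
  tt <- tokenTable(des)
  R <- des@nRepetitions
  if (R < 2L) stop("leave-one-out needs at least 2 repetitions")
  U <- nUnits(dataset)

  arrs <- .trialArrays(dataset, length)
  sums <- lapply(arrs, function(a) rowSums(a, dims = 2L))

  classLabels <- if (mode == "token") toks else unique(tt$phoneme)
  k <- base::length(classLabels)
  conf <- matrix(0L, k, k, dimnames = list(true = classLabels,
                                           predicted = classLabels))
  perTrial <- vector("list", base::length(toks) * R)
  ti <- 0L
  anyTie <- FALSE

  for (r in seq_len(R)) {
    tmplFull <- lapply(toks, function(tok)
      (sums[[tok]] - matrix(arrs[[tok]][, , r], nrow = U)) / (R - 1))
    names(tmplFull) <- toks
    if (mode == "phoneme") {
      cores <- lapply(unique(tt$phoneme), function(ph)
        .coreOf(.mergeMats(tmplFull[tt$token[tt$phoneme == ph]], L), L))
      names(cores) <- unique(tt$phoneme)
    } else {
      cores <- lapply(tmplFull, .coreOf, L = L)
    }
    for (tok in toks) {
      test <- matrix(arrs[[tok]][, , r], nrow = U)
      dmin <- rep(Inf, base::length(cores))
      lags <- integer(base::length(cores))
      for (j in seq_along(cores)) {
        d <- .cppLagDistances(cores[[j]], test)
        i <- which.min(d)
        dmin[j] <- d[i]
        lags[j] <- i - 1L - L
      }
      best <- which.min(dmin)
      if (sum(dmin == dmin[best]) > 1L) anyTie <- TRUE
      predRaw <- names(cores)[best]
      trueLab <- if (mode == "token") tok else phonemeOf(des, tok)
      predLab <- if (mode == "hierarchical") phonemeOf(des, predRaw) else predRaw
      conf[trueLab, predLab] <- conf[trueLab, predLab] + 1L
      ti <- ti + 1L
      perTrial[[ti]] <- data.frame(
        token = tok, repetition = r, true = trueLab, predicted = predLab,
        bestLag = lags[best] * bw, minDistance = dmin[best],
        correct = trueLab == predLab, stringsAsFactors = FALSE)
    }
  }
  if (anyTie)
    warning("distance ties occurred; resolved to canonical class order")
  cm <- new("ConfusionMatrix", labels = classLabels, counts = conf, mode = mode)
  new("ClassifierResult", confusion = cm,
      percentCorrect = percentCorrect(cm),
      perTrial = do.call(rbind, perTrial), mode = mode,
      smoothingLength = as.numeric(length), maxLag = as.numeric(maxLag))
}
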