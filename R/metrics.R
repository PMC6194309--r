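## Response statistics: sparseness, d-prime, discrimination specificity and
## CF-neighbourhood PSTH correlations.

#' Normalised sparseness of a non-negative response vector
#'
#' \deqn{S = \frac{1 - (\sum r_i / n)^2 / (\sum r_i^2 / n)}{1 - 1/n}}
#'
#' 0 for a uniform vector, 1 for a one-hot vector; invariant to positive
#' rescaling. The \code{r_i} are per-stimulus mean firing rates (lifetime
#' sparseness), per-unit rates for one presentation (population
#' sparseness), or clipped per-class d-prime values (discrimination
#' specificity).
#'
#' @param values non-negative numeric vector, length >= 2, not all zero.
#' @return S in [0, 1].
#' @examples
#' sparseness(c(1, 1, 1, 1)) # 0
#' sparseness(c(1, 0, 0, 0)) # 1
#' @export
sparseness <- function(values) {
  n <- length(values)
  if (n < 2L) stop("at least 2 values are required")
  if (any(!is.finite(values)) || any(values < 0))
    stop("values must be finite and non-negative")
  s2 <- sum(values^2) / n
  if (s2 == 0) stop("sparseness is undefined for an all-zero vector")
  (1 - (sum(values) / n)^2 / s2) / (1 - 1 / n)
}

## Mean evoked rate (spikes/s over the response window) per token for one
## unit, averaged over repetitions.
.ratesByToken <- function(dataset, unit) {
  des <- design(dataset)
  win <- des@responseWindow
  su <- dataset@spikes[[as.character(unit)]]
  if (is.null(su)) stop("unknown unit: ", unit)
  vapply(tokenLabels(des), function(tok)
    mean(vapply(su[[tok]], function(x) sum(x < win), numeric(1))) / (win / 1000),
    numeric(1))
}

#' Lifetime sparseness of one unit
#'
#' Sparseness of the unit's per-token mean firing rates (rates averaged over
#' repetitions and time within the response window): near 0 for a unit that
#' fires equally to every token, near 1 for a unit responsive to a single
#' token.
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param unit unit id.
#' @return S in [0, 1]; errors for a silent unit (undefined).
#' @export
lifetimeSparseness <- function(dataset, unit) {
  r <- .ratesByToken(dataset, unit)
  if (all(r == 0)) stop("lifetime sparseness undefined: unit '", unit, "' is silent")
  sparseness(r)
}

#' Population sparseness for one stimulus presentation
#'
#' Sparseness of the per-unit firing rates in response to a single (token,
#' repetition): near 0 when the whole population responds alike, near 1 when
#' a single unit carries the response. Summaries across repetitions should
#' report dispersion across repetitions.
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param token token label.
#' @param repetition repetition index, 1-based.
#' @return S in [0, 1]; errors when no unit fired (undefined).
#' @export
populationSparseness <- function(dataset, token, repetition) {
  des <- design(dataset)
  win <- des@responseWindow
  r <- vapply(unitIds(dataset), function(u)
    sum(spikeTimes(dataset, u, token, repetition) < win) / (win / 1000),
    numeric(1))
  if (all(r == 0))
    stop("population sparseness undefined: no unit fired for ", token,
         " rep ", repetition)
  sparseness(r)
}

#' Per-class sensitivity index d' from a confusion matrix
#'
#' For each class s: the hit rate is the fraction of class-s trials
#' predicted s, the false-alarm rate the fraction of other-class trials
#' predicted s, and \eqn{d' = Z(P_{HIT}) - Z(P_{FA})} with Z the inverse
#' normal. Rates are clipped to \code{[1/(2n), 1 - 1/(2n)]} (n = the
#' relevant trial count) so saturated rates stay finite.
#'
#' @param confusion a \linkS4class{ConfusionMatrix} with >= 1 trial per class.
#' @return named numeric vector of d' values.
#' @export
dprimePerClass <- function(confusion) {
  cts <- counts(confusion)
  nS <- rowSums(cts)
  if (any(nS == 0)) stop("every class needs at least one test trial")
  tot <- sum(cts)
  hits <- diag(cts)
  fa <- colSums(cts) - hits
  nO <- tot - nS
  clip <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  pHit <- clip(hits / nS, nS)
  pFa <- clip(fa / nO, nO)
  setNames(qnorm(pHit) - qnorm(pFa), confusion@labels)
}

#' Discrimination specificity of a d-prime profile
#'
#' The sparseness statistic applied to per-class d' values (negative values
#' clipped to 0 first): 0 indicates a generalist that discriminates all
#' classes equally, 1 a specialist recognising a single class.
#'
#' @param dprimes numeric vector of per-class d' values (>= 2 classes),
#'   e.g. from \code{\link{dprimePerClass}}.
#' @return value in [0, 1]; errors if all values clip to zero (undefined).
#' @export
discriminationSpecificity <- function(dprimes) {
  if (length(dprimes) < 2L) stop("at least 2 classes are required")
  if (any(dprimes < 0)) {
    warning("negative d' values clipped to 0")
    dprimes <- pmax(dprimes, 0)
  }
  if (all(dprimes == 0))
    stop("discrimination specificity undefined: all d' values are <= 0")
  sparseness(dprimes)
}

#' Mean PSTH correlation between CF neighbours
#'
#' For every unordered pair of units whose characteristic frequencies lie
#' within \code{halfOctaveLimit} octaves of one another, computes the
#' Pearson correlation between their trial-averaged, unsmoothed PSTHs for
#' each phoneme stimulus (averaging repetitions and talker variants),
#' averages over stimuli, then over pairs. High values indicate that
#' neighbouring CF channels carry redundant response patterns.
#'
#' @param dataset a \linkS4class{SpikeDataset}; at least 2 units need CFs.
#' @param halfOctaveLimit maximum |log2(cf_a / cf_b)| for a pair to count
#'   (default 0.5).
#' @param binWidth correlation bin width, ms (default 1).
#' @return list with \code{mean} (the pair-averaged correlation) and
#'   \code{pairs} (a data.frame of per-pair means); errors when no pair is
#'   eligible.
#' @export
cfNeighborhoodCorrelation <- function(dataset, halfOctaveLimit = 0.5,
                                      binWidth = 1) {
  des <- design(dataset)
  corDesign <- StimulusDesign(
    phonemes = des@phonemes, talkers = des@talkers,
    nRepetitions = des@nRepetitions, stimulusDuration = des@stimulusDuration,
    responseWindow = des@responseWindow, binWidth = binWidth)
  u <- unitMeta(dataset)
  u <- u[!is.na(u$cf), , drop = FALSE]
  if (nrow(u) < 2L) stop("need at least 2 units with CFs")
  tt <- tokenTable(des)
  phon <- unique(tt$phoneme)
  # phoneme-averaged PSTH per unit: mean over talkers and repetitions
  psth <- lapply(u$unit_id, function(uid) {
    vapply(phon, function(ph) {
      toks <- tt$token[tt$phoneme == ph]
      rows <- unlist(lapply(toks, function(tok) lapply(
        seq_len(des@nRepetitions), function(r)
          binSpikes(spikeTimes(dataset, uid, tok, r), corDesign))),
        recursive = FALSE)
      Reduce(`+`, rows) / length(rows)
    }, numeric(nBins(corDesign)))
  })
  names(psth) <- u$unit_id
  prs <- which(upper.tri(matrix(0, nrow(u), nrow(u))), arr.ind = TRUE)
  keep <- abs(log2(u$cf[prs[, 1]] / u$cf[prs[, 2]])) <= halfOctaveLimit
  prs <- prs[keep, , drop = FALSE]
  if (nrow(prs) == 0L) stop("no unit pair within the CF limit")
  pairMean <- vapply(seq_len(nrow(prs)), function(k) {
    a <- psth[[prs[k, 1]]]
    b <- psth[[prs[k, 2]]]
    rho <- vapply(seq_along(phon), function(j) {
      if (sd(a[, j]) == 0 || sd(b[, j]) == 0) NA_real_
      else cor(a[, j], b[, j])
    }, numeric(1))
    mean(rho, na.rm = TRUE)
  }, numeric(1))
  df <- data.frame(unit_a = u$unit_id[prs[, 1]], unit_b = u$unit_id[prs[, 2]],
                   correlation = pairMean, stringsAsFactors = FALSE)
  list(mean = mean(pairMean, na.rm = TRUE), pairs = df)
}
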