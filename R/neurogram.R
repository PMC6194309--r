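## PSTH construction, Hamming smoothing and neurogram assembly.

#' Bin a spike train into a PSTH row
#'
#' Counts spikes in half-open \code{[t, t + binWidth)} bins over the response
#' window only; spikes at or after the window end are dropped (the analysis
#' deliberately excludes the stimulus tail).
#'
#' @param spikeTimes numeric vector of spike times, ms from stimulus onset.
#' @param design a \linkS4class{StimulusDesign}.
#' @return integer vector of length \code{nBins(design)}.
#' @examples
#' d <- StimulusDesign(phonemes = "aba", talkers = "T1", nRepetitions = 2,
#'                     stimulusDuration = 3, responseWindow = 3)
#' binSpikes(c(0.5, 1.5, 1.7), d) # 1 2 0
#' @export
binSpikes <- function(spikeTimes, design) {
  if (length(spikeTimes) && min(spikeTimes) < 0)
    stop("negative spike times are not allowed")
  nb <- nBins(design)
  st <- spikeTimes[spikeTimes < design@responseWindow]
  tabulate(floor(st / design@binWidth) + 1L, nbins = nb)
}

#' Log-spaced grid of Hamming smoothing window lengths
#'
#' The default grid has 10 lengths evenly spaced on a logarithmic scale from
#' 1 to 400 ms, rounded to integer milliseconds; a length of 1 means no
#' smoothing and 400 approaches an average-rate code.
#'
#' @param n number of lengths (>= 2).
#' @param minMs,maxMs endpoints, ms; reproduced exactly in the grid.
#' @return strictly increasing integer vector of window lengths, ms.
#' @examples
#' makeSmoothingGrid() # 1 2 4 7 14 28 54 106 206 400
#' @export
makeSmoothingGrid <- function(n = 10, minMs = 1, maxMs = 400) {
  if (n < 2) stop("n must be >= 2")
  if (minMs <= 0 || maxMs <= minMs) stop("need 0 < minMs < maxMs")
  g <- round(10^seq(log10(minMs), log10(maxMs), length.out = n))
  g[1] <- round(minMs); g[n] <- round(maxMs)
  g <- as.numeric(g)
  if (is.unsorted(g, strictly = TRUE))
    stop("grid is not strictly increasing; use fewer points or a wider range")
  g
}

## Unit-sum Hamming window of w bins (w = 1 collapses to identity).
.hammingWindow <- function(w) {
  if (w == 1L) return(1)
  h <- 0.54 - 0.46 * cos(2 * pi * (0:(w - 1)) / (w - 1))
  h / sum(h)
}

#' Smooth a PSTH row with a unit-sum Hamming window
#'
#' Zero-padded "same" convolution: the output has the input's length, and a
#' constant row is preserved away from the edges. The unit-sum normalisation
#' keeps smoothed values on the spike-count scale. Length 1 returns the
#' input unchanged.
#'
#' @param x numeric PSTH row.
#' @param length window length in bins (= ms at 1-ms bins).
#' @return numeric vector, same length as \code{x}.
#' @export
smoothPSTH <- function(x, length) {
  w <- as.integer(round(length))
  if (w < 1L) stop("window length must be >= 1")
  if (w > base::length(x)) stop("window length exceeds row length")
  if (w == 1L) return(as.numeric(x))
  .smoothRows(matrix(as.numeric(x), nrow = 1L), w)[1L, ]
}

## Row-wise "same" convolution with a unit-sum Hamming window of w bins:
## the full zero-padded convolution restricted to its centred N columns,
## realised as a shift-and-add over the w taps.
.smoothRows <- function(mat, w) {
  if (w == 1L) return(mat)
  h <- .hammingWindow(w)
  N <- ncol(mat)
  s <- (w - 1L) %/% 2L
  out <- matrix(0, nrow(mat), N)
  for (k in seq_len(w)) {
    d <- s - k + 1L                       # source offset: out[, n] += h[k] mat[, n + d]
    nlo <- max(1L, 1L - d)
    nhi <- min(N, N - d)
    if (nlo <= nhi)
      out[, nlo:nhi] <- out[, nlo:nhi] + h[k] * mat[, (nlo + d):(nhi + d), drop = FALSE]
  }
  out
}

## CF-ascending unit order; units lacking a CF follow, in unit_id order.
.unitOrder <- function(units) {
  cf <- units$cf
  ids <- as.character(units$unit_id)
  ids[order(is.na(cf), cf, ids)]
}

#' Assemble a single-trial population neurogram
#'
#' Stacks the (optionally smoothed) single-trial PSTHs of every unit into a
#' units x bins matrix, rows ordered by characteristic frequency ascending
#' (units without a CF appended in unit_id order).
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param token token label.
#' @param repetition repetition index, 1-based.
#' @param length Hamming window length, ms (1 = unsmoothed).
#' @return a \linkS4class{Neurogram}.
#' @export
buildNeurogram <- function(dataset, token, repetition, length = 1) {
  des <- design(dataset)
  if (!token %in% tokenLabels(des)) stop("unknown token: ", token)
  if (repetition < 1L || repetition > des@nRepetitions)
    stop("missing (token, repetition): ", token, ", rep ", repetition)
  ord <- .unitOrder(unitMeta(dataset))
  mat <- t(vapply(ord, function(u)
    as.numeric(binSpikes(spikeTimes(dataset, u, token, repetition), des)),
    numeric(nBins(des))))
  w <- as.integer(round(length / des@binWidth))
  new("Neurogram", mat = .smoothRows(mat, max(w, 1L)), unitOrder = ord,
      binWidth = des@binWidth, smoothingLength = as.numeric(length))
}

#' Leave-one-out trial-average template neurogram
#'
#' Element-wise mean of the single-trial neurograms of all repetitions of a
#' token except the held-out one (for the default design: the mean over the
#' remaining nine repetitions).
#'
#' @inheritParams buildNeurogram
#' @param heldOutRepetition repetition excluded from the average, 1-based.
#' @return a \linkS4class{Neurogram}.
#' @export
averageTemplate <- function(dataset, token, heldOutRepetition, length = 1) {
  des <- design(dataset)
  R <- des@nRepetitions
  if (R < 2L) stop("at least 2 repetitions are required")
  if (heldOutRepetition < 1L || heldOutRepetition > R)
    stop("held-out repetition out of range: ", heldOutRepetition)
  keep <- setdiff(seq_len(R), heldOutRepetition)
  ngs <- lapply(keep, function(r) buildNeurogram(dataset, token, r, length))
  mat <- Reduce(`+`, lapply(ngs, ngMatrix)) / length(keep)
  new("Neurogram", mat = mat, unitOrder = ngs[[1]]@unitOrder,
      binWidth = des@binWidth, smoothingLength = as.numeric(length))
}

## Precompute smoothed single-trial PSTH arrays for fast cross-validation:
## a list over tokens of arrays (units x bins x repetitions), rows CF-ordered.
.trialArrays <- function(dataset, length) {
  des <- design(dataset)
  ord <- .unitOrder(unitMeta(dataset))
  nb <- nBins(des)
  R <- des@nRepetitions
  w <- max(as.integer(round(length / des@binWidth)), 1L)
  toks <- tokenLabels(des)
  out <- vector("list", base::length(toks))
  names(out) <- toks
  for (tok in toks) {
    a <- array(0, dim = c(base::length(ord), nb, R))
    for (r in seq_len(R)) {
      m <- t(vapply(ord, function(u)
        as.numeric(binSpikes(dataset@spikes[[u]][[tok]][[r]], des)),
        numeric(nb)))
      a[, , r] <- .smoothRows(m, w)
    }
    out[[tok]] <- a
  }
  attr(out, "unitOrder") <- ord
  out
}

#' Write / read a neurogram as labelled delimited text
#'
#' The container is a TSV whose first lines are \code{#}-prefixed metadata
#' (bin width, smoothing length) followed by a header row of bin indices;
#' the first column holds unit ids. \code{readNeurogram} inverts it.
#'
#' @param ng a \linkS4class{Neurogram}.
#' @param path file path.
#' @return \code{readNeurogram}: a \linkS4class{Neurogram}.
#' @export
writeNeurogram <- function(ng, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# binWidth\t%g", ng@binWidth),
               sprintf("# smoothingLength\t%g", ng@smoothingLength)), con)
  df <- data.frame(unit_id = ng@unitOrder, ng@mat, check.names = FALSE)
  names(df) <- c("unit_id", sprintf("bin%d", seq_len(ncol(ng@mat)) - 1L))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNeurogram
#' @export
readNeurogram <- function(path) {
  hdr <- readLines(path, n = 10L)
  meta <- hdr[startsWith(hdr, "# ")]
  kv <- do.call(rbind, strsplit(sub("^# ", "", meta), "\t"))
  df <- read.delim(path, comment.char = "#", check.names = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  dimnames(mat) <- NULL
  new("Neurogram", mat = mat, unitOrder = as.character(df[[1L]]),
      binWidth = as.numeric(kv[kv[, 1] == "binWidth", 2]),
      smoothingLength = as.numeric(kv[kv[, 1] == "smoothingLength", 2]))
}
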