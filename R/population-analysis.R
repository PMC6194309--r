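## Sweep experiments: classifier performance as a function of the smoothing
## window (per unit and per population) and of population size (random,
## best-first and worst-first sampling).

.optimalValue <- function(values, pc) {
  # argmax; ties resolve to the smallest swept value
  values[which.max(pc)]
}

#' Smoothing-window sweep for a single unit
#'
#' Runs the single-unit classifier (a one-row neurogram) at every window of
#' the grid and reports the optimal window (argmax percent correct; ties go
#' to the shortest window). Units whose class differences live in precise
#' spike timing peak at short windows; rate-coded units are flat.
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param unit unit id.
#' @param mode classifier mode.
#' @param grid smoothing window lengths, ms (default
#'   \code{\link{makeSmoothingGrid}()}).
#' @param maxLag lag half-range, ms.
#' @return a \linkS4class{SweepResult}; \code{optimum(x)} is the best window.
#' @export
unitWindowSweep <- function(dataset, unit, mode = "token",
                            grid = makeSmoothingGrid(), maxLag = 100) {
  sub <- subsetUnits(dataset, unit)
  pc <- vapply(grid, function(w)
    percentCorrect(evaluateClassifier(sub, mode, length = w, maxLag = maxLag)),
    numeric(1))
  new("SweepResult", parameter = "smoothingLength",
      results = data.frame(value = grid, percentCorrect = pc),
      mode = mode, seed = NA_integer_, optimum = .optimalValue(grid, pc))
}

#' Smoothing-window sweep for a population
#'
#' Full leave-one-out evaluation at every grid length over a population (or
#' subpopulation) neurogram; reports the optimal window.
#'
#' @inheritParams unitWindowSweep
#' @param subpopulation unit ids to use (default: all units).
#' @export
populationWindowSweep <- function(dataset, mode = "token",
                                  grid = makeSmoothingGrid(),
                                  subpopulation = unitIds(dataset),
                                  maxLag = 100) {
  if (length(subpopulation) == 0L) stop("subpopulation must not be empty")
  sub <- subsetUnits(dataset, subpopulation)
  pc <- vapply(grid, function(w)
    percentCorrect(evaluateClassifier(sub, mode, length = w, maxLag = maxLag)),
    numeric(1))
  new("SweepResult", parameter = "smoothingLength",
      results = data.frame(value = grid, percentCorrect = pc),
      mode = mode, seed = NA_integer_, optimum = .optimalValue(grid, pc))
}

#' Default population-size ladder
#'
#' Roughly logarithmic sizes 1, 2, 3, 5, 10, 20, 50, 100, ... capped at the
#' population size (which is always included).
#'
#' @param nTotal population size.
#' @return increasing integer vector.
#' @export
defaultSizes <- function(nTotal) {
  ladder <- c(1, 2, 3, 5, 10, 20, 50, 100, 200, 500, 1000)
  sort(unique(c(ladder[ladder < nTotal], nTotal)))
}

#' Classifier performance vs population size, random subpopulations
#'
#' For each size, draws \code{nDraws} seeded subpopulations uniformly
#' without replacement (a fresh, independent draw per size) and runs the
#' full leave-one-out evaluation on each.
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param sizes population sizes (default \code{\link{defaultSizes}}).
#' @param nDraws subpopulations per size (default 20).
#' @param mode classifier mode.
#' @param length smoothing window, ms.
#' @param seed RNG seed for the draws.
#' @param maxLag lag half-range, ms.
#' @return a \linkS4class{SweepResult}; the results table has one row per
#'   (size, draw).
#' @export
randomPopulationSweep <- function(dataset, sizes = defaultSizes(nUnits(dataset)),
                                  nDraws = 20, mode = "token", length = 1,
                                  seed = 1, maxLag = 100) {
  U <- nUnits(dataset)
  if (any(sizes > U)) stop("sizes must not exceed the population size")
  if (nDraws < 1) stop("nDraws must be >= 1")
  ids <- unitIds(dataset)
  rows <- .withSeed(.substreamSeed(seed, "popdraws"), {
    out <- list()
    for (s in sort(sizes)) {
      for (dr in seq_len(nDraws)) {
        pick <- ids[sample.int(U, s)]
        pc <- percentCorrect(evaluateClassifier(
          subsetUnits(dataset, pick), mode, length = length, maxLag = maxLag))
        out[[base::length(out) + 1L]] <-
          data.frame(value = s, draw = dr, percentCorrect = pc)
      }
    }
    out
  })
  new("SweepResult", parameter = "populationSize",
      results = do.call(rbind, rows), mode = mode,
      seed = as.integer(seed), optimum = NA_real_)
}

#' Rank units by single-unit token discriminability
#'
#' Percent correct of the single-unit token classifier at a given window,
#' with ties broken by higher mean firing rate (informative sites tend to
#' fire more) and then by unit id.
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param length smoothing window, ms.
#' @param maxLag lag half-range, ms.
#' @return data.frame of \code{unit_id}, \code{percentCorrect},
#'   \code{meanRate}, sorted best first.
#' @export
rankUnits <- function(dataset, length = 1, maxLag = 100) {
  ids <- unitIds(dataset)
  pc <- vapply(ids, function(u) percentCorrect(evaluateClassifier(
    subsetUnits(dataset, u), "token", length = length, maxLag = maxLag)),
    numeric(1))
  mr <- vapply(ids, function(u) meanRate(dataset, u), numeric(1))
  df <- data.frame(unit_id = ids, percentCorrect = pc, meanRate = mr,
                   stringsAsFactors = FALSE)
  df[order(-df$percentCorrect, -df$meanRate, df$unit_id), , drop = FALSE]
}

#' Classifier performance vs population size, ordered sampling
#'
#' Units are ranked by single-unit token discriminability at the
#' population-optimal smoothing window (found with
#' \code{\link{populationWindowSweep}} unless \code{length} is given), then
#' the first k units in descending ("best" first) or ascending ("worst"
#' first) rank order are evaluated cumulatively for each size k.
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param order \code{"best"} or \code{"worst"}.
#' @param mode classifier mode.
#' @param sizes cumulative sizes (default \code{\link{defaultSizes}}).
#' @param length smoothing window, ms; \code{NULL} means use the
#'   population-optimal window.
#' @param maxLag lag half-range, ms.
#' @return a \linkS4class{SweepResult}.
#' @export
orderedPopulationSweep <- function(dataset, order = c("best", "worst"),
                                   mode = "token",
                                   sizes = defaultSizes(nUnits(dataset)),
                                   length = NULL, maxLag = 100) {
  order <- match.arg(order)
  if (is.null(length))
    length <- optimum(populationWindowSweep(dataset, mode, maxLag = maxLag))
  rk <- rankUnits(dataset, length = length, maxLag = maxLag)
  ids <- rk$unit_id
  if (order == "worst") ids <- rev(ids)
  pc <- vapply(sort(sizes), function(s) percentCorrect(evaluateClassifier(
    subsetUnits(dataset, ids[seq_len(s)]), mode, length = length,
    maxLag = maxLag)), numeric(1))
  new("SweepResult", parameter = "populationSize",
      results = data.frame(value = sort(sizes), percentCorrect = pc,
                           order = order),
      mode = mode, seed = NA_integer_, optimum = NA_real_)
}
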