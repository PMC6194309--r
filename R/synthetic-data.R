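## Seeded synthetic population generator. The latent structure mirrors what
## the decoding pipeline assumes of real data: each phoneme owns a smooth
## rate envelope built from brief events, talker variants are time-shifted
## and gain-jittered deformations of it, and units differ in gain, temporal
## profile and class selectivity. Spikes are drawn from an inhomogeneous
## Poisson process and jittered trial-to-trial.

## Deterministic substream seed from a master seed and a stage name, kept
## within 32-bit integer range so set.seed() accepts it.
.substreamSeed <- function(master, name) {
  v <- utf8ToInt(name)
  h <- sum(v * seq_along(v))
  as.integer((as.numeric(master) %% 2147483647 * 48271 + h * 10007) %% 2147483647)
}

## Evaluate expr under a given seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Construct generator parameters, optionally from a preset
#'
#' Presets bundle the qualitative response regimes of the ascending
#' auditory pathway: \describe{
#'   \item{dense}{auditory-nerve-like: high sustained rates, every unit
#'     driven by every class, sub-millisecond trial-to-trial precision.}
#'   \item{intermediate}{midbrain-like: moderate rates, partial
#'     selectivity, a few ms of jitter.}
#'   \item{sparse}{cortex-like: low-rate, transient (onset-weighted)
#'     responses from a small fraction of classes, 15-ms jitter and strong
#'     across-talker warping.}
#' }
#' Any named argument overrides its preset value.
#'
#' @param preset preset name.
#' @param design a \linkS4class{StimulusDesign}.
#' @param nUnits population size.
#' @param seed master seed; envelopes, selectivity masks, unit profiles and
#'   spike sampling each draw from a named substream of it.
#' @param baseRate,eventRateGain,selectivity,talkerSd,jitterSd,onsetOnly
#'   see \linkS4class{GeneratorParams}; defaults come from the preset.
#' @return a \linkS4class{GeneratorParams}.
#' @export
generatorParams <- function(preset = c("intermediate", "dense", "sparse"),
                            design = StimulusDesign(), nUnits = 100,
                            seed = 1, baseRate = NULL, eventRateGain = NULL,
                            selectivity = NULL, talkerSd = NULL,
                            jitterSd = NULL, onsetOnly = NULL) {
  preset <- match.arg(preset)
  p <- switch(preset,
    dense = list(baseRate = 120, eventRateGain = 1.5, selectivity = 1,
                 talkerSd = 5, jitterSd = 0.5, onsetOnly = FALSE),
    intermediate = list(baseRate = 50, eventRateGain = 1, selectivity = 0.5,
                        talkerSd = 10, jitterSd = 5, onsetOnly = FALSE),
    sparse = list(baseRate = 30, eventRateGain = 0.6, selectivity = 0.15,
                  talkerSd = 20, jitterSd = 15, onsetOnly = TRUE))
  ov <- list(baseRate = baseRate, eventRateGain = eventRateGain,
             selectivity = selectivity, talkerSd = talkerSd,
             jitterSd = jitterSd, onsetOnly = onsetOnly)
  for (nm in names(ov)) if (!is.null(ov[[nm]])) p[[nm]] <- ov[[nm]]
  new("GeneratorParams", design = design, nUnits = as.integer(nUnits),
      preset = preset, baseRate = as.numeric(p$baseRate),
      eventRateGain = as.numeric(p$eventRateGain),
      selectivity = as.numeric(p$selectivity),
      talkerSd = as.numeric(p$talkerSd), jitterSd = as.numeric(p$jitterSd),
      onsetOnly = as.logical(p$onsetOnly), seed = as.integer(seed))
}

## Gaussian-bump envelope over bin centres; mean normalised to 1.
.drawEnvelope <- function(tms, eventRate, durMs, onsetOnly) {
  nEv <- rpois(1, eventRate * durMs / 1000)
  e <- rep(0.05, length(tms))
  if (nEv > 0) {
    # brief, tall events: instantaneous rates well above the mean, as in
    # phase-locked / pitch-period-driven auditory responses
    ctr <- runif(nEv, 0, durMs)
    wid <- runif(nEv, 0.5, 2)
    amp <- exp(rnorm(nEv, 0, 0.5))
    for (j in seq_len(nEv))
      e <- e + amp[j] * exp(-(tms - ctr[j])^2 / (2 * wid[j]^2))
  }
  e <- e + 2 * exp(-(tms - 12)^2 / (2 * 3^2))  # onset component
  e <- e / mean(e)
  if (onsetOnly) e <- e * exp(-tms / 60)       # transient truncation
  e
}

## Shift a vector by d bins, padding with its own minimum (baseline).
.shiftPad <- function(x, d) {
  n <- length(x)
  out <- rep(min(x), n)
  src <- (max(1, 1 + d)):(min(n, n + d))
  out[src - d] <- x[src]
  out
}

#' Build the latent firing-rate field of a synthetic population
#'
#' Per phoneme, draws a latent envelope (brief Gaussian events plus an
#' onset component over the stimulus duration); per talker, applies a
#' seeded time shift of scale \code{talkerSd} and a gain jitter; per unit,
#' gates classes by a seeded phoneme-selectivity mask (a unit driven by a
#' phoneme is driven by all of its talker variants), applies a unit gain
#' and a smooth unit-specific temporal profile, and scales to
#' \code{baseRate}. Non-driven classes receive a flat spontaneous rate of
#' 5\% of \code{baseRate}. With \code{onsetOnly} the envelopes decay with a
#' 60-ms time constant, leaving transient responses.
#'
#' @param params a \linkS4class{GeneratorParams}.
#' @return a \linkS4class{RateField} (spikes/s over the full stimulus
#'   duration). Units carry log-spaced CFs over 0.1-5 kHz.
#' @export
makeRateField <- function(params) {
  des <- params@design
  bw <- des@binWidth
  nbFull <- as.integer(round(des@stimulusDuration / bw))
  tms <- (seq_len(nbFull) - 0.5) * bw
  tt <- tokenTable(des)
  nP <- length(des@phonemes)
  nT <- length(des@talkers)
  U <- params@nUnits

  env <- .withSeed(.substreamSeed(params@seed, "envelopes"), {
    perPhoneme <- lapply(seq_len(nP), function(p)
      .drawEnvelope(tms, 20 * params@eventRateGain, des@stimulusDuration,
                    params@onsetOnly))
    out <- matrix(0, nrow(tt), nbFull)
    for (i in seq_len(nrow(tt))) {
      p <- match(tt$phoneme[i], des@phonemes)
      k <- match(tt$talker[i], des@talkers)
      if (k == 1L) {
        out[i, ] <- perPhoneme[[p]]
      } else {
        # both deformations scale with talkerSd: at 0 the variants coincide
        d <- as.integer(round(rnorm(1, 0, params@talkerSd) / bw))
        g <- exp(rnorm(1, 0, 0.005 * params@talkerSd))
        out[i, ] <- g * .shiftPad(perPhoneme[[p]], d)
      }
    }
    out
  })

  mask <- .withSeed(.substreamSeed(params@seed, "masks"), {
    nDriven <- max(1L, as.integer(round(params@selectivity * nP)))
    m <- matrix(FALSE, U, nP)
    for (u in seq_len(U)) m[u, sample.int(nP, nDriven)] <- TRUE
    m
  })

  prof <- .withSeed(.substreamSeed(params@seed, "units"), {
    gain <- exp(rnorm(U, 0, 0.3))
    gmat <- matrix(0, U, nbFull)
    w <- max(3L, as.integer(round(50 / bw)))
    for (u in seq_len(U)) {
      z <- .smoothRows(matrix(rnorm(nbFull), 1L), w)[1L, ]
      z <- z / max(sd(z), 1e-12)
      g <- exp(0.5 * z)
      gmat[u, ] <- gain[u] * g / mean(g)
    }
    gmat
  })

  spont <- 0.05 * params@baseRate
  rates <- array(0, dim = c(U, nrow(tt), nbFull))
  phIdx <- match(tt$phoneme, des@phonemes)
  for (u in seq_len(U)) {
    for (i in seq_len(nrow(tt))) {
      rates[u, i, ] <- if (mask[u, phIdx[i]])
        params@baseRate * prof[u, ] * env[i, ] else rep(spont, nbFull)
    }
  }
  new("RateField", rates = rates,
      unitIds = sprintf("u%03d", seq_len(U)), tokenLabels = tt$token,
      params = params)
}

#' Sample a labelled spike dataset from a rate field
#'
#' For every (unit, token, repetition), bin-wise Poisson counts are drawn
#' from the unit/class intensity, spike times are placed uniformly within
#' their bin and jittered by Gaussian noise of SD \code{jitterSd}; jittered
#' times falling outside the stimulus window are dropped. Fully seeded: the
#' same field and seed give an identical dataset.
#'
#' @param field a \linkS4class{RateField}.
#' @param params generator parameters (defaults to the field's own).
#' @return a \linkS4class{SpikeDataset} with CF-bearing unit metadata
#'   (region = preset name).
#' @export
sampleDataset <- function(field, params = field@params) {
  des <- params@design
  bw <- des@binWidth
  nbFull <- dim(field@rates)[3]
  R <- des@nRepetitions
  U <- length(field@unitIds)
  dur <- des@stimulusDuration
  spikes <- .withSeed(.substreamSeed(params@seed, "spikes"), {
    sp <- vector("list", U)
    names(sp) <- field@unitIds
    for (u in seq_len(U)) {
      su <- vector("list", length(field@tokenLabels))
      names(su) <- field@tokenLabels
      for (i in seq_along(field@tokenLabels)) {
        lam <- field@rates[u, i, ] * bw / 1000
        st <- vector("list", R)
        for (r in seq_len(R)) {
          cnt <- rpois(nbFull, lam)
          tot <- sum(cnt)
          if (tot == 0L) { st[[r]] <- numeric(0); next }
          tsp <- rep((seq_len(nbFull) - 1L) * bw, cnt) + runif(tot, 0, bw)
          if (params@jitterSd > 0) {
            tsp <- tsp + rnorm(tot, 0, params@jitterSd)
            # spikes jittered outside the stimulus window are lost, not
            # piled on the boundary
            tsp <- tsp[tsp >= 0 & tsp < dur]
          }
          st[[r]] <- sort(tsp)
        }
        su[[i]] <- st
      }
      sp[[u]] <- su
    }
    sp
  })
  units <- data.frame(unit_id = field@unitIds,
                      region = params@preset,
                      cf = cfGrid(U), stringsAsFactors = FALSE)
  SpikeDataset(des, units, spikes)
}

#' Generate a synthetic population dataset in one call
#'
#' @inheritParams generatorParams
#' @param ... further overrides passed to \code{\link{generatorParams}}.
#' @return a \linkS4class{SpikeDataset}.
#' @export
simulatePopulation <- function(preset = "intermediate",
                               design = StimulusDesign(), nUnits = 100,
                               seed = 1, ...) {
  p <- generatorParams(preset = preset, design = design, nUnits = nUnits,
                       seed = seed, ...)
  sampleDataset(makeRateField(p))
}

#' Information-free (chance-level) dataset
#'
#' Every token class shares one homogeneous Poisson rate, so no response
#' feature distinguishes the classes and leave-one-out classification can
#' only perform at chance (100 / number of classes).
#'
#' @param design a \linkS4class{StimulusDesign}.
#' @param nUnits population size.
#' @param rate the common firing rate, spikes/s.
#' @param seed master seed.
#' @return a \linkS4class{SpikeDataset}.
#' @export
makeChanceDataset <- function(design = StimulusDesign(), nUnits = 8,
                              rate = 50, seed = 1) {
  p <- generatorParams("intermediate", design = design, nUnits = nUnits,
                       seed = seed, baseRate = rate, selectivity = 1,
                       jitterSd = 0, talkerSd = 0)
  nbFull <- as.integer(round(design@stimulusDuration / design@binWidth))
  rates <- array(rate, dim = c(nUnits, nTokens(design), nbFull))
  field <- new("RateField", rates = rates,
               unitIds = sprintf("u%03d", seq_len(nUnits)),
               tokenLabels = tokenLabels(design), params = p)
  sampleDataset(field)
}

#' Synthesise a raw extracellular trace from spike times
#'
#' Unit-variance Gaussian background noise plus a stereotyped biphasic
#' (negative-leading) spike waveform at each spike time, scaled so the
#' waveform trough is \code{amplitude} noise SDs deep. Overlapping
#' waveforms sum.
#'
#' @param spikeTimes spike times, ms.
#' @param amplitude trough depth as a multiple of the noise SD.
#' @param sampleRate Hz (default 24400).
#' @param durationMs trace duration, ms.
#' @param seed noise seed.
#' @return a \linkS4class{RawTrace}.
#' @export
makeRawTrace <- function(spikeTimes, amplitude = 6, sampleRate = 24400,
                         durationMs = 1000, seed = 1) {
  if (length(spikeTimes) && (min(spikeTimes) < 0 || max(spikeTimes) >= durationMs))
    stop("spike times must lie within the trace duration")
  n <- as.integer(round(durationMs / 1000 * sampleRate))
  x <- .withSeed(.substreamSeed(seed, "noise"), rnorm(n))
  if (length(spikeTimes)) {
    wt <- seq(0, 1.5, by = 1000 / sampleRate)           # waveform support, ms
    w <- -exp(-(wt - 0.3)^2 / (2 * 0.1^2)) +
      0.45 * exp(-(wt - 0.75)^2 / (2 * 0.18^2))
    w <- w / abs(min(w)) * amplitude
    troughAt <- which.min(w) - 1L
    for (st in spikeTimes) {
      i0 <- as.integer(round(st / 1000 * sampleRate)) - troughAt
      idx <- i0 + seq_along(w)
      ok <- idx >= 1L & idx <= n
      x[idx[ok]] <- x[idx[ok]] + w[ok]
    }
  }
  RawTrace(x, sampleRate)
}
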