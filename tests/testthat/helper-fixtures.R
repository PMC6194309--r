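# Shared fixtures and independent oracles, built in code at test time.

# Reduced stimulus design for fast end-to-end runs.
tinyDesign <- function(nPhonemes = 4, nTalkers = 2, nReps = 4,
                       stimulusDuration = 700, responseWindow = 650,
                       binWidth = 1) {
  StimulusDesign(phonemes = defaultPhonemes()[seq_len(nPhonemes)],
                 talkers = paste0("T", seq_len(nTalkers)),
                 nRepetitions = nReps, stimulusDuration = stimulusDuration,
                 responseWindow = responseWindow, binWidth = binWidth)
}

# Independent oracle for the lag-search distance: a plain double loop over
# slice offsets, never touching the compiled kernel.
bruteLagDistances <- function(core, test) {
  nOff <- ncol(test) - ncol(core) + 1
  vapply(seq_len(nOff), function(i) {
    sl <- test[, i:(i + ncol(core) - 1), drop = FALSE]
    sum((core - sl)^2)
  }, numeric(1))
}

# Brute-force nearest-template classification over (class, offset).
bruteClassify <- function(coreList, test) {
  d <- vapply(coreList, function(core) min(bruteLagDistances(core, test)),
              numeric(1))
  names(coreList)[which.min(d)]
}

# SpikeDataset with explicitly given spike times.
# spikeFun(unit_index, token_label, repetition) -> numeric vector of times.
manualDataset <- function(design, nUnits, spikeFun, cfs = NULL) {
  ids <- sprintf("m%02d", seq_len(nUnits))
  if (is.null(cfs)) cfs <- cfGrid(nUnits, 200, 4000)
  toks <- tokenLabels(design)
  spikes <- lapply(seq_len(nUnits), function(u) {
    su <- lapply(toks, function(tok)
      lapply(seq_len(design@nRepetitions), function(r)
        sort(spikeFun(u, tok, r))))
    names(su) <- toks
    su
  })
  names(spikes) <- ids
  SpikeDataset(design, data.frame(unit_id = ids, region = "manual", cf = cfs,
                                  stringsAsFactors = FALSE), spikes)
}

# Rate field whose classes carry independent trains of brief (1-ms) rate
# events: class information exists at every timescale, and trial-to-trial
# jitter sets the finest usable one.
makeEventField <- function(design, nUnits, baseRate = 150, seed = 1,
                           eventsPerS = 20, width = 1, jitterSd = 0) {
  p <- generatorParams("intermediate", design = design, nUnits = nUnits,
                       seed = seed, baseRate = baseRate, selectivity = 1,
                       talkerSd = 0, jitterSd = jitterSd)
  bw <- design@binWidth
  nb <- as.integer(round(design@stimulusDuration / bw))
  tms <- (seq_len(nb) - 0.5) * bw
  nt <- nTokens(design)
  rates <- array(0, dim = c(nUnits, nt, nb))
  set.seed(seed * 1000 + 7)
  for (u in seq_len(nUnits)) {
    for (i in seq_len(nt)) {
      ev <- runif(round(eventsPerS * design@stimulusDuration / 1000),
                  0, design@stimulusDuration)
      e <- rep(0.02, nb)
      for (t0 in ev) e <- e + exp(-(tms - t0)^2 / (2 * width^2))
      rates[u, i, ] <- baseRate * e / mean(e)
    }
  }
  new("RateField", rates = rates, unitIds = sprintf("u%03d", seq_len(nUnits)),
      tokenLabels = tokenLabels(design), params = p)
}

# Blend class-specific rates toward the across-class mean: alpha = 0 removes
# all between-class structure, alpha = 1 leaves the field unchanged.
mixToward <- function(field, alpha) {
  r <- field@rates
  avg <- apply(r, c(1, 3), mean)
  for (i in seq_len(dim(r)[2])) r[, i, ] <- (1 - alpha) * avg + alpha * r[, i, ]
  new("RateField", rates = r, unitIds = field@unitIds,
      tokenLabels = field@tokenLabels, params = field@params)
}
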