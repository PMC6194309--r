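## Interchange formats and the end-to-end pipeline driver. The spike table
## is tab-separated UTF-8 with a mandatory header, one row per spike:
##   unit_id  region  cf_hz  phoneme  talker  repetition  spike_time_ms
## (repetition is 0-based in the file). A YAML sidecar (<path>.meta.yaml)
## records the stimulus design and the full unit table so that silent units
## and empty trials survive a round trip.

.spikeTableColumns <- c("unit_id", "region", "cf_hz", "phoneme", "talker",
                        "repetition", "spike_time_ms")

#' Write a spike dataset as a tabular spike file
#'
#' @param dataset a \linkS4class{SpikeDataset}.
#' @param path output TSV path; a \code{<path>.meta.yaml} sidecar is written
#'   alongside unless \code{sidecar = FALSE}.
#' @param sidecar write the design/units sidecar (default TRUE).
#' @return the path, invisibly.
#' @export
writeSpikeTable <- function(dataset, path, sidecar = TRUE) {
  des <- design(dataset)
  tt <- tokenTable(des)
  u <- unitMeta(dataset)
  rows <- list()
  for (uid in u$unit_id) {
    for (i in seq_len(nrow(tt))) {
      st <- dataset@spikes[[uid]][[tt$token[i]]]
      for (r in seq_along(st)) {
        if (length(st[[r]]) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          unit_id = uid, region = u$region[match(uid, u$unit_id)],
          cf_hz = u$cf[match(uid, u$unit_id)], phoneme = tt$phoneme[i],
          talker = tt$talker[i], repetition = r - 1L,
          spike_time_ms = st[[r]], stringsAsFactors = FALSE)
      }
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    setNames(data.frame(matrix(nrow = 0, ncol = 7)), .spikeTableColumns)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecar) {
    yaml::write_yaml(list(
      design = list(phonemes = des@phonemes, talkers = des@talkers,
                    n_repetitions = des@nRepetitions,
                    stimulus_duration = des@stimulusDuration,
                    response_window = des@responseWindow,
                    bin_width = des@binWidth),
      units = lapply(seq_len(nrow(u)), function(i) list(
        unit_id = u$unit_id[i], region = u$region[i],
        cf = if (is.na(u$cf[i])) NULL else u$cf[i]))),
      paste0(path, ".meta.yaml"))
  }
  invisible(path)
}

.designFromList <- function(d) {
  StimulusDesign(phonemes = unlist(d$phonemes), talkers = unlist(d$talkers),
                 nRepetitions = d$n_repetitions,
                 stimulusDuration = d$stimulus_duration,
                 responseWindow = d$response_window, binWidth = d$bin_width)
}

#' Read a tabular spike file into a SpikeDataset
#'
#' The design and the unit table come from the \code{<path>.meta.yaml}
#' sidecar when present, from the \code{design} argument otherwise, and are
#' inferred from the rows as a last resort (phonemes, talkers and
#' repetition count from the data; default timing constants). Exactly
#' duplicated rows are collapsed with a warning; rows with out-of-range
#' times or a design mismatch raise an error naming the row numbers.
#'
#' @param path TSV path.
#' @param design optional \linkS4class{StimulusDesign} to validate against.
#' @return a \linkS4class{SpikeDataset}.
#' @export
readSpikeTable <- function(path, design = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missingCols <- setdiff(.spikeTableColumns, names(df))
  if (length(missingCols))
    stop("spike table is missing column(s): ", paste(missingCols, collapse = ", "))
  sidecarPath <- paste0(path, ".meta.yaml")
  unitTab <- NULL
  if (file.exists(sidecarPath)) {
    meta <- yaml::read_yaml(sidecarPath)
    scDesign <- .designFromList(meta$design)
    if (is.null(design)) design <- scDesign
    else if (!identical(tokenLabels(design), tokenLabels(scDesign)))
      stop("design argument conflicts with the sidecar design")
    unitTab <- data.frame(
      unit_id = vapply(meta$units, `[[`, "", "unit_id"),
      region = vapply(meta$units, function(x)
        if (is.null(x$region)) NA_character_ else as.character(x$region), ""),
      cf = vapply(meta$units, function(x)
        if (is.null(x$cf)) NA_real_ else as.numeric(x$cf), numeric(1)),
      stringsAsFactors = FALSE)
  }
  if (is.null(design)) {
    design <- StimulusDesign(
      phonemes = unique(df$phoneme), talkers = unique(df$talker),
      nRepetitions = max(df$repetition) + 1L,
      stimulusDuration = max(700, ceiling(max(df$spike_time_ms)) + 1),
      responseWindow = min(650, max(700, ceiling(max(df$spike_time_ms)) + 1)))
  }
  dup <- duplicated(df)
  if (any(dup)) {
    warning(sum(dup), " duplicate spike row(s) collapsed")
    df <- df[!dup, , drop = FALSE]
  }
  bad <- which(df$spike_time_ms < 0 | df$spike_time_ms >= design@stimulusDuration)
  if (length(bad))
    stop("spike times out of [0, ", design@stimulusDuration, ") at row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  badTok <- which(!(df$phoneme %in% design@phonemes) |
                    !(df$talker %in% design@talkers))
  if (length(badTok))
    stop("phoneme/talker not in the design at row(s): ",
         paste(head(badTok, 5L), collapse = ", "))
  badRep <- which(df$repetition < 0 | df$repetition >= design@nRepetitions)
  if (length(badRep))
    stop("repetition out of [0, ", design@nRepetitions, ") at row(s): ",
         paste(head(badRep, 5L), collapse = ", "))
  if (is.null(unitTab)) {
    first <- !duplicated(df$unit_id)
    unitTab <- data.frame(unit_id = as.character(df$unit_id[first]),
                          region = as.character(df$region[first]),
                          cf = as.numeric(df$cf_hz[first]),
                          stringsAsFactors = FALSE)
    unitTab <- unitTab[order(unitTab$unit_id), , drop = FALSE]
  }
  spikes <- .emptySpikeList(unitTab$unit_id, design)
  if (nrow(df)) {
    tok <- .tokenLabel(df$phoneme, df$talker)
    key <- split(seq_len(nrow(df)),
                 list(u = df$unit_id, t = tok, r = df$repetition), drop = TRUE)
    for (nm in names(key)) {
      i <- key[[nm]]
      uid <- as.character(df$unit_id[i[1]])
      spikes[[uid]][[tok[i[1]]]][[df$repetition[i[1]] + 1L]] <-
        sort(df$spike_time_ms[i])
    }
  }
  SpikeDataset(design, unitTab, spikes)
}

#' Default run configuration
#'
#' Nested list mirroring the standard analysis settings: the default VCV
#' design, 0.3-6 kHz fourth-order detection with a 4-SD robust threshold,
#' token-mode classification with a 650-ms window, 1-ms bins and 100-ms
#' maximum lag, the 10-window 1-400 ms smoothing grid, and 20 random draws
#' per population size.
#'
#' @return named list, serialisable with \code{yaml::write_yaml}.
#' @export
defaultRunConfig <- function() {
  des <- StimulusDesign()
  list(
    seed = 1L,
    design = list(phonemes = des@phonemes, talkers = des@talkers,
                  n_repetitions = des@nRepetitions,
                  stimulus_duration = des@stimulusDuration,
                  response_window = des@responseWindow,
                  bin_width = des@binWidth),
    detection = list(band_low = 300, band_high = 6000, filter_order = 4,
                     threshold_multiplier = 4, dead_time = 1),
    classifier = list(mode = "token", window = 1, max_lag = 100),
    smoothing_grid = list(n = 10, min_ms = 1, max_ms = 400),
    sweep = list(enabled = FALSE, n_draws = 20),
    generator = list(preset = "intermediate", n_units = 100)
  )
}

#' Read and validate a YAML run configuration
#'
#' Missing keys fall back to \code{\link{defaultRunConfig}}; structural
#' errors (e.g. a maximum lag of half the response window or more) are
#' raised before any computation.
#'
#' @param path YAML file.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(utils::modifyList(defaultRunConfig(), cfg))
}

#' @rdname readRunConfig
#' @param config a config list.
#' @export
validateRunConfig <- function(config) {
  des <- .designFromList(config$design)   # validity checks the design block
  if (2 * config$classifier$max_lag >= des@responseWindow)
    stop("classifier max_lag must be below half the response window")
  if (!config$classifier$mode %in% c("token", "phoneme", "hierarchical"))
    stop("unknown classifier mode: ", config$classifier$mode)
  if (config$classifier$window < 1)
    stop("classifier window must be >= 1 ms")
  config
}

#' Run the full pipeline from a configuration
#'
#' Simulate (or ingest) a population spike dataset, evaluate the classifier,
#' compute the response metrics, optionally run the sweep experiments, and
#' write every result plus a provenance log to \code{outDir}. Deterministic
#' under a fixed config and seed.
#'
#' @param config config list (see \code{\link{defaultRunConfig}} /
#'   \code{\link{readRunConfig}}).
#' @param outDir output directory, created if needed.
#' @param dataset optionally, a pre-built \linkS4class{SpikeDataset}
#'   (overrides the generator/input blocks).
#' @return invisibly, a list with the dataset, the
#'   \linkS4class{ClassifierResult}, the metric tables and any sweeps.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempfile("run"),
                        dataset = NULL) {
  config <- validateRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  des <- .designFromList(config$design)
  t0 <- Sys.time()
  if (is.null(dataset)) {
    dataset <- if (!is.null(config$input$spike_table))
      readSpikeTable(config$input$spike_table, design = des)
    else simulatePopulation(preset = config$generator$preset, design = des,
                            nUnits = config$generator$n_units,
                            seed = config$seed)
  }
  message(sprintf("[pipeline] dataset: %d units, %d tokens x %d reps",
                  nUnits(dataset), nTokens(des), des@nRepetitions))

  res <- evaluateClassifier(dataset, config$classifier$mode,
                            length = config$classifier$window,
                            maxLag = config$classifier$max_lag)
  message(sprintf("[pipeline] classifier: %.2f%% correct (chance %.2f%%)",
                  percentCorrect(res), 100 / length(res@confusion@labels)))
  cm <- counts(res@confusion)
  write.table(data.frame(true = rownames(cm), cm, check.names = FALSE),
              file.path(outDir, "confusion.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(res@perTrial, file.path(outDir, "per_trial.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  dp <- dprimePerClass(res@confusion)
  spec <- tryCatch(discriminationSpecificity(dp), error = function(e) NA_real_)
  lifeS <- vapply(unitIds(dataset), function(u)
    tryCatch(lifetimeSparseness(dataset, u), error = function(e) NA_real_),
    numeric(1))
  metrics <- list(
    dprime = data.frame(class = names(dp), dprime = as.numeric(dp)),
    specificity = spec,
    lifetime = data.frame(unit_id = unitIds(dataset), sparseness = lifeS))
  write.table(metrics$dprime, file.path(outDir, "dprime.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(metrics$lifetime, file.path(outDir, "lifetime_sparseness.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sweeps <- NULL
  if (isTRUE(config$sweep$enabled)) {
    grid <- makeSmoothingGrid(config$smoothing_grid$n,
                              config$smoothing_grid$min_ms,
                              config$smoothing_grid$max_ms)
    sweeps <- list(
      window = populationWindowSweep(dataset, config$classifier$mode, grid,
                                     maxLag = config$classifier$max_lag),
      size = randomPopulationSweep(dataset, nDraws = config$sweep$n_draws,
                                   mode = config$classifier$mode,
                                   length = config$classifier$window,
                                   seed = config$seed,
                                   maxLag = config$classifier$max_lag))
    write.table(sweepTable(sweeps$window), file.path(outDir, "window_sweep.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sweepTable(sweeps$size), file.path(outDir, "size_sweep.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(config, cfgPath)
  prov <- c(
    sprintf("config_md5: %s", unname(tools::md5sum(cfgPath))),
    sprintf("seed: %d", config$seed),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("neurogram"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("percent_correct: %.6f", percentCorrect(res)),
    sprintf("elapsed_s: %.2f", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(prov, file.path(outDir, "provenance.txt"))
  invisible(list(dataset = dataset, classifier = res, metrics = metrics,
                 sweeps = sweeps, outDir = outDir))
}
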