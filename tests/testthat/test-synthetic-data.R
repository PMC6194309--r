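test_that("generation is deterministic under the master seed", {
  des <- tinyDesign(2, 2, 2)
  a <- simulatePopulation("sparse", design = des, nUnits = 3, seed = 17)
  b <- simulatePopulation("sparse", design = des, nUnits = 3, seed = 17)
  expect_identical(a@spikes, b@spikes)
  c <- simulatePopulation("sparse", design = des, nUnits = 3, seed = 18)
  expect_false(identical(a@spikes, c@spikes))
})

test_that("talkerSd = 0 collapses talker variants onto the phoneme template", {
  des <- tinyDesign(2, 3, 2)
  p <- generatorParams("intermediate", design = des, nUnits = 2, seed = 5,
                       talkerSd = 0)
  f <- makeRateField(p)
  tt <- tokenTable(des)
  for (ph in des@phonemes) {
    idx <- which(tt$phoneme == ph)
    for (j in idx[-1])
      expect_equal(f@rates[, j, ], f@rates[, idx[1], ])
  }
})

test_that("zero intensity yields empty trains; constant rate hits its mean", {
  des <- tinyDesign(1, 1, 5)
  p <- generatorParams("dense", design = des, nUnits = 1, seed = 2,
                       jitterSd = 0)
  zero <- new("RateField",
              rates = array(0, dim = c(1, 1, 700)),
              unitIds = "u001", tokenLabels = tokenLabels(des), params = p)
  dz <- sampleDataset(zero)
  expect_true(all(vapply(dz@spikes[["u001"]][[1]], length, integer(1)) == 0L))

  # 100 spikes/s: expected 65 spikes in the 650-ms window
  ch <- makeChanceDataset(tinyDesign(4, 2, 10), nUnits = 1, rate = 100,
                          seed = 12)
  counts <- unlist(lapply(ch@spikes[["u001"]], function(tok)
    vapply(tok, function(x) sum(x < 650), numeric(1))))
  expect_length(counts, 80L)
  expect_equal(mean(counts), 65, tolerance = 0.05)
})

test_that("presets order sparseness the way the ascending pathway does", {
  des <- tinyDesign(4, 2, 3)
  for (seed in 1:2) {
    dense <- simulatePopulation("dense", design = des, nUnits = 6, seed = seed)
    sparse <- simulatePopulation("sparse", design = des, nUnits = 6,
                                 seed = seed)
    lf <- function(ds) mean(vapply(unitIds(ds), function(u)
      tryCatch(lifetimeSparseness(ds, u), error = function(e) NA_real_),
      numeric(1)), na.rm = TRUE)
    expect_gt(lf(sparse), lf(dense))
  }
})

test_that("lower selectivity raises lifetime sparseness", {
  des <- tinyDesign(6, 2, 3)
  meanLS <- vapply(c(1, 0.5, 0.15), function(sel) {
    v <- vapply(1:3, function(seed) {
      ds <- simulatePopulation("intermediate", design = des, nUnits = 5,
                               seed = seed, selectivity = sel)
      mean(vapply(unitIds(ds), function(u)
        tryCatch(lifetimeSparseness(ds, u), error = function(e) NA_real_),
        numeric(1)), na.rm = TRUE)
    }, numeric(1))
    mean(v)
  }, numeric(1))
  expect_true(all(diff(meanLS) > 0))
})

test_that("class separation and temporal jitter steer classifier accuracy", {
  des <- tinyDesign(4, 2, 4)
  # between-class separation: blending class rates toward their mean
  # degrades accuracy monotonically (perfect rank agreement on means)
  alphas <- c(0, 0.5, 1)
  accSep <- vapply(alphas, function(a) {
    mean(vapply(1:4, function(seed) {
      f <- mixToward(makeEventField(des, 2, baseRate = 60, seed = seed), a)
      percentCorrect(evaluateClassifier(sampleDataset(f), "token",
                                        length = 7))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cor(alphas, accSep, method = "spearman"), 1)

  # trial-to-trial jitter degrades accuracy monotonically
  jits <- c(0.5, 5, 20, 60)
  accJit <- vapply(jits, function(j) {
    mean(vapply(1:4, function(seed) {
      f <- makeEventField(des, 2, baseRate = 60, seed = seed, jitterSd = j)
      percentCorrect(evaluateClassifier(sampleDataset(f), "token",
                                        length = 7))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cor(jits, accJit, method = "spearman"), -1)
})

test_that("talker variability erodes phoneme-mode accuracy", {
  des <- tinyDesign(4, 3, 3)
  tsds <- c(0, 15, 40)
  acc <- vapply(tsds, function(tsd) {
    mean(vapply(1:4, function(seed) {
      ds <- simulatePopulation("intermediate", design = des, nUnits = 5,
                               seed = seed, baseRate = 60, selectivity = 1,
                               talkerSd = tsd, jitterSd = 3)
      percentCorrect(evaluateClassifier(ds, "phoneme", length = 14))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(cor(tsds, acc, method = "spearman"), -1)
})

test_that("optimal smoothing windows track the trial-to-trial jitter scale", {
  des <- tinyDesign(8, 1, 6)
  grid <- makeSmoothingGrid()
  opts <- function(j) vapply(1:5, function(seed) {
    ds <- sampleDataset(makeEventField(des, 1, baseRate = 150, seed = seed,
                                       jitterSd = j))
    optimum(populationWindowSweep(ds, grid = grid))
  }, numeric(1))
  precise <- opts(0.5)
  coarse <- suppressWarnings(opts(15))
  expect_lte(median(precise), 4)
  expect_gte(median(coarse), 14)
  expect_lte(median(coarse), 106)
})

test_that("synthetic raw traces carry the requested spikes and noise floor", {
  tr <- makeRawTrace(numeric(0), durationMs = 500, seed = 7)
  expect_equal(length(tr@samples), 12200L)
  expect_equal(sd(tr@samples), 1, tolerance = 0.05)
  expect_equal(mean(tr@samples), 0, tolerance = 0.05)
  expect_error(makeRawTrace(c(100, 600), durationMs = 500), "duration")
})
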