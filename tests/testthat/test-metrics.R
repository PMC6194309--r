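test_that("sparseness hits its closed-form anchors", {
  expect_equal(sparseness(c(1, 1, 1, 1)), 0)
  expect_equal(sparseness(c(1, 0, 0, 0)), 1)
  expect_equal(sparseness(c(2, 1, 1, 0)), 4 / 9)
  expect_error(sparseness(c(0, 0, 0)), "all-zero")
  expect_error(sparseness(3), "at least 2")
  expect_error(sparseness(c(1, -1)), "non-negative")
})

test_that("sparseness is bounded, scale-invariant and monotone under mixing", {
  set.seed(13)
  for (k in 1:10) {
    v <- rexp(sample(3:20, 1))
    s <- sparseness(v)
    expect_gte(s, 0)
    expect_lte(s, 1 + 1e-12)
    expect_equal(sparseness(3.7 * v), s)
  }
  # mixing a one-hot vector toward uniform decreases sparseness monotonically
  oneHot <- c(1, 0, 0, 0, 0)
  unif <- rep(0.2, 5)
  path <- vapply(seq(0, 1, by = 0.1), function(a)
    sparseness((1 - a) * oneHot + a * unif), numeric(1))
  expect_true(all(diff(path) < 0))
})

test_that("lifetime sparseness separates selective from uniform units", {
  des <- tinyDesign(4, 2, 3, stimulusDuration = 100, responseWindow = 100)
  toks <- tokenLabels(des)
  flat <- manualDataset(des, 1, function(u, tok, r) seq(5, 95, by = 10))
  expect_equal(lifetimeSparseness(flat, "m01"), 0)

  onehot <- manualDataset(des, 1, function(u, tok, r)
    if (tok == toks[1]) seq(5, 95, by = 5) else numeric(0))
  expect_equal(lifetimeSparseness(onehot, "m01"), 1)

  # geometric rate profile: matches the direct formula evaluation
  geo <- manualDataset(des, 1, function(u, tok, r) {
    n <- 2^(match(tok, toks) - 1)
    if (n == 0) numeric(0) else seq(1, 99, length.out = n)
  })
  r <- 2^(seq_along(toks) - 1) * 10  # spikes/s: count / 0.1 s
  expect_equal(lifetimeSparseness(geo, "m01"), sparseness(r))

  silent <- manualDataset(des, 1, function(u, tok, r) numeric(0))
  expect_error(lifetimeSparseness(silent, "m01"), "silent")
})

test_that("population sparseness separates homogeneous from one-unit codes", {
  des <- tinyDesign(1, 1, 2, stimulusDuration = 100, responseWindow = 100)
  tok <- tokenLabels(des)
  hom <- manualDataset(des, 5, function(u, tk, r) seq(10, 90, by = 10))
  expect_equal(populationSparseness(hom, tok, 1), 0)
  solo <- manualDataset(des, 5, function(u, tk, r)
    if (u == 3) seq(10, 90, by = 10) else numeric(0))
  expect_equal(populationSparseness(solo, tok, 1), 1)
  none <- manualDataset(des, 5, function(u, tk, r) numeric(0))
  expect_error(populationSparseness(none, tok, 1), "undefined")
})

test_that("d-prime anchors: no sensitivity at equal rates, 1.989 at .84/.16", {
  # two classes, 100 trials each, engineered hit/false-alarm rates
  cm <- ConfusionMatrix(c("a", "b"),
                        matrix(c(84L, 16L, 16L, 84L), 2, byrow = TRUE))
  dp <- dprimePerClass(cm)
  expect_equal(unname(dp["a"]), qnorm(0.84) - qnorm(0.16), tolerance = 1e-12)
  expect_equal(unname(dp["a"]), 1.989, tolerance = 1e-3)

  # uniform (chance) confusion: d' = 0 everywhere, no clipping involved
  unif <- ConfusionMatrix(paste0("c", 1:6), matrix(5L, 6, 6))
  expect_equal(unname(dprimePerClass(unif)), rep(0, 6))

  # identity confusion, 10 trials x 48 classes: clipping keeps d' finite
  ident <- ConfusionMatrix(paste0("c", 1:48), diag(rep(10L, 48)))
  dpi <- dprimePerClass(ident)
  expect_true(all(is.finite(dpi)))
  expect_true(all(dpi > 0))
  expect_equal(max(dpi) - min(dpi), 0)
  expect_equal(unname(dpi[1]), qnorm(1 - 1 / 20) - qnorm(1 / (2 * 470)))

  bad <- new("ConfusionMatrix", labels = c("a", "b"),
             counts = matrix(c(3L, 0L, 1L, 0L), 2), mode = "token")
  expect_error(dprimePerClass(bad), "at least one test trial")
})

test_that("discrimination specificity shares the sparseness kernel", {
  expect_equal(discriminationSpecificity(c(1.5, 1.5, 1.5)), 0)
  expect_equal(discriminationSpecificity(c(2, 0, 0, 0)), 1)
  expect_equal(discriminationSpecificity(c(2, 1, 1, 0)), sparseness(c(2, 1, 1, 0)))
  expect_warning(s <- discriminationSpecificity(c(2, -0.5, 1, 0)), "clipped")
  expect_equal(s, sparseness(c(2, 0, 1, 0)))
  expect_error(suppressWarnings(discriminationSpecificity(c(-1, -2))),
               "undefined")
})

test_that("CF-neighbourhood correlations: duplicates 1, independents ~0", {
  des <- tinyDesign(4, 1, 3)
  base <- simulatePopulation("dense", design = des, nUnits = 1, seed = 6)
  # two units with identical spikes and the same CF
  spikes <- list(a = base@spikes[[1]], b = base@spikes[[1]])
  dup <- SpikeDataset(des, data.frame(unit_id = c("a", "b"), region = "x",
                                      cf = c(1000, 1000)), spikes)
  expect_equal(cfNeighborhoodCorrelation(dup)$mean, 1)

  # independent homogeneous-Poisson units at the same CF decorrelate
  ch <- makeChanceDataset(des, nUnits = 2, rate = 80, seed = 3)
  ch@units$cf <- c(1000, 1000)
  cc <- cfNeighborhoodCorrelation(ch)
  expect_lt(abs(cc$mean), 0.05)

  # units a full octave apart are not eligible neighbours
  far <- dup
  far@units$cf <- c(500, 1000)
  expect_error(cfNeighborhoodCorrelation(far), "no unit pair")
  # ... unless the limit is widened
  expect_equal(cfNeighborhoodCorrelation(far, halfOctaveLimit = 1)$mean, 1)
})
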