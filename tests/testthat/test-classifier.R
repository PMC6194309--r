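# Neurogram object from a bare matrix, for kernel-level tests.
ngFrom <- function(mat, sm = 1) {
  new("Neurogram", mat = mat, unitOrder = sprintf("u%d", seq_len(nrow(mat))),
      binWidth = 1, smoothingLength = sm)
}

test_that("lagged distance recovers identity, pure shifts and hand arithmetic", {
  set.seed(7)
  m <- matrix(runif(3 * 40), 3, 40)
  r <- laggedDistance(ngFrom(m), ngFrom(m), maxLag = 5)
  expect_equal(r$distance, 0)
  expect_equal(r$lag, 0)

  # test delayed by +6 bins: zero distance at lag +6
  shifted <- cbind(matrix(0, 3, 6), m[, 1:34])
  r2 <- laggedDistance(ngFrom(m), ngFrom(shifted), maxLag = 10)
  expect_equal(r2$distance, 0, tolerance = 1e-12)
  expect_equal(r2$lag, 6)

  # hand-computed M = 1 case: template [?,2,3,?], test [0,2,3,0], maxLag 1
  tpl <- matrix(c(9, 2, 3, 9), 1)   # trimmed core is [2, 3]
  tst <- matrix(c(0, 2, 3, 0), 1)
  r3 <- laggedDistance(ngFrom(tpl), ngFrom(tst), maxLag = 1)
  expect_equal(r3$distances, c(5, 0, 10))
  expect_equal(r3$distance, 0)
  expect_equal(r3$lag, 0)

  expect_error(laggedDistance(ngFrom(m), ngFrom(m[1:2, ])), "unitOrder")
  expect_error(laggedDistance(ngFrom(tpl), ngFrom(tst), maxLag = 2), "bins")
})

test_that("the compiled kernel matches a brute-force oracle exactly", {
  set.seed(42)
  for (rep in 1:20) {
    M <- sample(1:3, 1)
    nb <- sample(8:20, 1)
    L <- sample(1:3, 1)
    tpl <- matrix(rpois(M * nb, 1), M, nb)
    tst <- matrix(rpois(M * nb, 1), M, nb)
    core <- tpl[, (L + 1):(nb - L), drop = FALSE]
    got <- laggedDistance(ngFrom(tpl), ngFrom(tst), maxLag = L)
    want <- bruteLagDistances(core, tst)
    expect_identical(got$distances, want)
    expect_identical(got$distance, min(want))
    expect_identical(got$lag, which.min(want) - 1 - L)
  }
})

test_that("trial classification is argmin with canonical tie-breaking", {
  set.seed(8)
  tplA <- matrix(rpois(30, 2), 1)
  tplB <- matrix(rpois(30, 2), 1)
  tplC <- matrix(rpois(30, 2), 1)
  tmpl <- list(a = ngFrom(tplA), b = ngFrom(tplB), c = ngFrom(tplC))
  test <- ngFrom(tplB)
  out <- classifyTrial(tmpl, test, maxLag = 3)
  expect_equal(out$predicted, "b")
  expect_equal(out$distance, 0)

  # brute-force agreement over random instances
  for (k in 1:10) {
    tl <- lapply(1:4, function(i) matrix(rpois(2 * 16, 1), 2))
    names(tl) <- paste0("c", 1:4)
    tst <- matrix(rpois(2 * 16, 1), 2)
    got <- classifyTrial(lapply(tl, ngFrom), ngFrom(tst), maxLag = 2)
    want <- bruteClassify(lapply(tl, function(m)
      m[, 3:14, drop = FALSE]), tst)
    expect_equal(got$predicted, want)
  }

  # exact tie: both templates identical -> first class, with a warning
  tie <- list(x = ngFrom(tplA), y = ngFrom(tplA))
  expect_warning(res <- classifyTrial(tie, ngFrom(tplC), maxLag = 2), "tie")
  expect_equal(res$predicted, "x")

  expect_error(classifyTrial(list(), test), "at least one")
})

test_that("lag equivariance: delaying the test shifts the best lag only", {
  set.seed(9)
  tpl <- matrix(rpois(2 * 60, 1.5), 2)
  tst <- matrix(rpois(2 * 60, 1.5), 2)
  base <- laggedDistance(ngFrom(tpl), ngFrom(tst), maxLag = 15)
  # delay (or advance) the test so the shifted optimum stays in range and
  # the template core never meets the zero padding
  d <- if (base$lag <= 5) 5 else -5
  delayed <- if (d > 0) cbind(matrix(0, 2, d), tst[, 1:(60 - d)])
             else cbind(tst[, (1 - d):60], matrix(0, 2, -d))
  shift <- laggedDistance(ngFrom(tpl), ngFrom(delayed), maxLag = 15)
  expect_equal(shift$lag, base$lag + d)
  expect_equal(shift$distance, base$distance)
})

test_that("talker-template merging aligns before averaging", {
  set.seed(10)
  m <- matrix(runif(2 * 50), 2, 50)
  # identical templates: merged equals the template
  same <- mergeTalkerTemplates(list(t1 = ngFrom(m), t2 = ngFrom(m)),
                               maxLag = 8)
  expect_equal(ngMatrix(same), m)

  # one talker: unchanged
  one <- mergeTalkerTemplates(list(t1 = ngFrom(m)), maxLag = 8)
  expect_equal(ngMatrix(one), m)

  # second talker delayed by +6 bins: merged equals the reference wherever
  # the shifted copy is defined
  shifted <- cbind(matrix(0, 2, 6), m[, 1:44])
  merged <- mergeTalkerTemplates(list(t1 = ngFrom(m), t2 = ngFrom(shifted)),
                                 maxLag = 10)
  expect_equal(ngMatrix(merged)[, 1:44], m[, 1:44], tolerance = 1e-12)
})

test_that("noiseless separable classes are classified perfectly in all modes", {
  des <- tinyDesign(3, 2, 3)
  toks <- tokenLabels(des)
  # deterministic, token-specific spike patterns, identical across reps
  # class-specific inter-spike spacing so no class is a time-shifted copy
  # of another (the lag search would absorb a pure shift)
  ds <- manualDataset(des, 2, function(u, tok, r) {
    i <- match(tok, toks)
    seq(150 + 10 * i, 500, by = 40 + 7 * i) + 3 * u
  })
  for (mode in c("token", "phoneme", "hierarchical"))
    expect_equal(percentCorrect(evaluateClassifier(ds, mode, length = 1)), 100)
})

test_that("chance-only datasets score near chance in token mode", {
  des <- tinyDesign(4, 2, 5)
  ds <- sampleDataset(mixToward(makeEventField(des, 3, seed = 1), 0))
  pc <- percentCorrect(evaluateClassifier(ds, "token", length = 1))
  # 8 classes -> chance 12.5%; 40 trials, binomial 3 SD ~ 16
  expect_lt(abs(pc - 12.5), 16)
})

test_that("phoneme-structured confusions: hierarchical rescues token errors", {
  des <- tinyDesign(3, 3, 3)
  toks <- tokenLabels(des)
  # responses depend only on the phoneme: talker variants indistinguishable
  ds <- manualDataset(des, 2, function(u, tok, r) {
    i <- match(phonemeOf(des, tok), des@phonemes)
    seq(120 + 13 * i, 520, by = 45 + 11 * i) + 2 * u
  })
  hier <- suppressWarnings(evaluateClassifier(ds, "hierarchical", length = 1))
  tokn <- suppressWarnings(evaluateClassifier(ds, "token", length = 1))
  expect_equal(percentCorrect(hier), 100)
  expect_lt(percentCorrect(tokn), 100)
})

test_that("hierarchical accuracy never falls below token accuracy", {
  for (seed in 1:3) {
    ds <- simulatePopulation("intermediate", design = tinyDesign(3, 2, 4),
                             nUnits = 4, seed = seed)
    tok <- evaluateClassifier(ds, "token", length = 7)
    hier <- evaluateClassifier(ds, "hierarchical", length = 7)
    expect_gte(percentCorrect(hier), percentCorrect(tok))
  }
})

test_that("percent correct follows the confusion-matrix trace", {
  ident <- ConfusionMatrix(c("a", "b"), diag(c(5L, 5L)))
  expect_equal(percentCorrect(ident), 100)
  unif <- ConfusionMatrix(paste0("c", 1:48),
                          matrix(1L, 48, 48), mode = "token")
  expect_equal(percentCorrect(unif), 100 / 48)
  expect_equal(percentCorrect(ConfusionMatrix(c("a", "b"),
                                              matrix(c(3, 2, 1, 4), 2))), 70)
  expect_error(percentCorrect(ConfusionMatrix("a", matrix(0L, 1, 1))),
               "empty")
})

test_that("chance level reflects the class count of the mode", {
  d <- StimulusDesign()
  expect_equal(chanceLevel(d, "token"), 100 / 48)
  expect_equal(chanceLevel(d, "phoneme"), 100 / 16)
  expect_equal(chanceLevel(d, "hierarchical"), 100 / 16)
})
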