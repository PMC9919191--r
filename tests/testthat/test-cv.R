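# Random hyperparameter search, nested CV protocol, model ranking.

test_that("random search is deterministic and returns the single draw when nDraws = 1", {
  fps <- easyFingerprints(c(30, 30))
  g <- tinyGrid(lr = c(2e-3, 1e-5))
  one <- randomSearch(fps, g, nDraws = 1, kInner = 2, seed = 5, nSteps = 8)
  expect_s3_class(one, "hyperParamPoint")
  expect_equal(nrow(attr(one, "searchLog")), 1L)
  again <- randomSearch(fps, g, nDraws = 1, kInner = 2, seed = 5, nSteps = 8)
  expect_identical(unclass(one)[names(unclass(one))],
                   unclass(again)[names(unclass(again))])
  expect_identical(attr(one, "searchLog"), attr(again, "searchLog"))
  expect_error(randomSearch(fps, tinyGrid(lr = numeric(0)), nDraws = 2,
                            seed = 1), "empty grid")
})

test_that("exhaustive draws find the clearly superior configuration", {
  # learnable task; one grid axis contrasts a working learning rate with a
  # uselessly small one, so enough draws must select the working config
  fps <- syntheticFingerprints(nPerClass = c(40, 40), nBits = 32,
                               nInformative = 16, pOnActive = 0.9,
                               pBackground = 0.15, seed = 3)
  g <- tinyGrid(nHidden = 24L, lr = c(2e-3, 1e-9), epochs = 10L)
  best <- randomSearch(fps, g, nDraws = 12, kInner = 2, seed = 11,
                       nSteps = 15)
  expect_equal(best$lr, 2e-3)
  log <- attr(best, "searchLog")
  expect_true(all(c("draw", "lr", "meanInnerBA") %in% names(log)))
  expect_identical(max(log$meanInnerBA),
                   max(log$meanInnerBA[log$lr == 2e-3]))
})

test_that("nested CV accounting: repetitions x outer folds rows, zero std under forced seeds", {
  fps <- easyFingerprints(c(30, 30))
  g <- tinyGrid()
  cv <- nestedCV(fps, g, kOuter = 2, kInner = 2, nRepeats = 1, nDraws = 1,
                 seed = 13, nSteps = 8)
  expect_s4_class(cv, "CVSummary")
  expect_equal(nrow(cvResults(cv)), 2L)   # 1 repetition x 2 outer folds
  expect_true(all(cvResults(cv)$ba >= 0 & cvResults(cv)$ba <= 100))
  expect_true(all(cvResults(cv)$auc >= 0 & cvResults(cv)$auc <= 1))

  # identical per-repetition seeds collapse the repetition variance to zero
  cv2 <- nestedCV(fps, g, kOuter = 2, kInner = 2, nRepeats = 2, nDraws = 1,
                  seed = 13, nSteps = 8, repeatSeeds = c(99L, 99L))
  expect_equal(cv2@stdBA, 0)
  expect_equal(cv2@stdAUC, 0)
  expect_error(nestedCV(fps, g, kOuter = 1, seed = 1), "kOuter")
})

test_that("no outer-test sample ever enters its own inner search or refit", {
  fps <- easyFingerprints(c(25, 25))
  for (mode in c("none", "safe")) {
    cv <- nestedCV(fps, tinyGrid(), kOuter = 3, kInner = 2, nRepeats = 2,
                   nDraws = 2, seed = 7, nSteps = 8, balance = mode)
    for (bk in cv@bookkeeping) {
      expect_length(intersect(bk$outerTest, bk$innerTrain), 0)
      expect_length(intersect(bk$outerTest, bk$outerTrain), 0)
      expect_setequal(c(bk$outerTest, bk$outerTrain),
                      seq_along(fpLabels(fps)))
    }
  }
})

test_that("paper-style pre-balancing lets duplicated minority records straddle folds", {
  fps <- syntheticFingerprints(nPerClass = c(40, 8), nBits = 24,
                               nInformative = 6, seed = 15)
  cv <- nestedCV(fps, tinyGrid(), kOuter = 2, kInner = 2, nRepeats = 1,
                 nDraws = 1, seed = 21, nSteps = 8, balance = "paper")
  orig <- cv@config$origIdx
  expect_length(orig, 80L)   # 40 + 40 after equalization
  straddle <- vapply(cv@bookkeeping, function(bk)
    length(intersect(orig[bk$outerTest], orig[bk$outerTrain])) > 0,
    logical(1))
  expect_true(any(straddle))  # same original molecule on both sides

  # leakage-safe mode keeps original indices disjoint by construction
  cvSafe <- nestedCV(fps, tinyGrid(), kOuter = 2, kInner = 2, nRepeats = 1,
                     nDraws = 1, seed = 21, nSteps = 8, balance = "safe")
  origSafe <- cvSafe@config$origIdx
  safe <- vapply(cvSafe@bookkeeping, function(bk)
    length(intersect(origSafe[bk$outerTest], origSafe[bk$outerTrain])) == 0,
    logical(1))
  expect_true(all(safe))
})

test_that("model ranking truncates, sorts and breaks ties stably", {
  rec <- data.frame(nHidden = 1:7, meanBA = c(90, 95, 95, 80, 99, 70, 60),
                    stdBA = 1)
  top <- rankModels(rec)
  expect_equal(nrow(top), 5L)
  expect_equal(top$meanBA, c(99, 95, 95, 90, 80))
  # equal means keep insertion order
  expect_equal(top$nHidden[top$meanBA == 95], c(2L, 3L))
  expect_equal(rankModels(rec, topK = 2)$meanBA, c(99, 95))
  expect_error(rankModels(rec[0, ]), "no records")
})
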