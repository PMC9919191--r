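#' Default hyperparameter search grid
#'
#' The grid the random search draws from. Defaults follow the published
#' search ranges for this architecture: hidden width between 500 and 2000
#' (the level set includes the intermediate widths 800/1200/1500 that the
#' ranked result tables contain), six regularly spaced membrane decays on
#' \[0.6, 0.95\], surrogate slopes \{25, 50, 75\}, the seven-optimizer menu,
#' fifteen learning-rate levels on \[1e-5, 0.5\] built from the commonly
#' selected values padded log-uniformly, weight decay \{0\} plus four
#' log-spaced levels on \[1e-4, 0.05\], gradient clipping on/off, and epoch
#' counts \{10, 25, 50, 100\}.
#'
#' @param ... named elements overriding individual grid axes, e.g.
#'   `hyperGrid(nHidden = c(16, 32), epochs = 2)`.
#' @return named list of grid axes.
#' @examples
#' str(hyperGrid(epochs = c(5, 10)))
#' @export
hyperGrid <- function(...) {
  grid <- list(
    nHidden = c(500L, 800L, 1000L, 1200L, 1500L, 2000L),
    beta = seq(0.6, 0.95, length.out = 6),
    slope = c(25, 50, 75),
    optimizer = c("Adam", "Adamax", "SGO", "Adagrad", "Adadelta", "AdamW",
                  "RMSProp"),
    lr = sort(unique(c(1e-5, 5e-5, 1e-4, 1e-3, 2e-3, 5e-3, 1e-2,
                       exp(seq(log(0.02), log(0.5), length.out = 8))))),
    wd = c(0, 10^seq(log10(1e-4), log10(0.05), length.out = 4)),
    gc = c(TRUE, FALSE),
    epochs = c(10L, 25L, 50L, 100L))
  over <- list(...)
  for (nm in names(over)) {
    if (!nm %in% names(grid))
      stop("unknown grid axis '", nm, "'", call. = FALSE)
    grid[[nm]] <- over[[nm]]
  }
  grid
}

# One uniform draw per axis from the grid.
.drawPoint <- function(grid) {
  pick <- function(v) v[[sample.int(length(v), 1L)]]
  hyperParamPoint(nHidden = pick(grid$nHidden), beta = pick(grid$beta),
                  slope = pick(grid$slope), optimizer = pick(grid$optimizer),
                  lr = pick(grid$lr), wd = pick(grid$wd), gc = pick(grid$gc),
                  epochs = pick(grid$epochs))
}

# Train on trainIdx, score balanced accuracy on testIdx.
.fitScore <- function(fpset, point, trainIdx, testIdx, seed, nSteps,
                      balance = "none") {
  trainSet <- fpset[trainIdx]
  if (balance == "safe")
    trainSet <- oversampleMinority(trainSet, .deriveSeed(seed, "balance"))
  model <- trainNetwork(trainSet, point, seed = seed, nSteps = nSteps)
  fwd <- snnForward(model, fpMatrix(fpset)[testIdx, , drop = FALSE])
  yTest <- fpLabels(fpset)[testIdx]
  list(ba = balancedAccuracy(yTest, snnPredict(fwd)),
       auc = aucROC(yTest, fwd$score), model = model)
}

#' Random hyperparameter search with inner cross-validation
#'
#' Draws `nDraws` configurations uniformly from the grid and scores each by
#' its mean balanced accuracy over `kInner` stratified folds of the given
#' data; the best-scoring draw wins (ties go to the earlier draw).
#'
#' @param fpset a [FingerprintSet-class] (the search's training data only —
#'   callers are responsible for keeping evaluation data out).
#' @param grid a [hyperGrid()].
#' @param nDraws number of random draws (>= 1).
#' @param kInner inner folds (>= 2).
#' @param seed integer seed driving draws, folds and training.
#' @param nSteps simulation steps per forward pass.
#' @param balance `"none"` or `"safe"` (oversample minority inside each
#'   inner training portion).
#' @return the winning [hyperParamPoint()]; attribute `"searchLog"` is a
#'   data.frame with one row per draw (configuration + mean inner BA).
#' @export
randomSearch <- function(fpset, grid, nDraws, kInner = 3, seed = 1,
                         nSteps = 25, balance = "none") {
  if (nDraws < 1) stop("nDraws must be >= 1", call. = FALSE)
  if (any(vapply(grid, length, integer(1)) == 0L))
    stop("empty grid axis", call. = FALSE)
  points <- .withSeed(.deriveSeed(seed, "draws"),
                      lapply(seq_len(nDraws), function(i) .drawPoint(grid)))
  folds <- .stratifiedFolds(fpLabels(fpset), kInner,
                            .deriveSeed(seed, "innerfolds"))
  scores <- numeric(nDraws)
  for (d in seq_len(nDraws)) {
    bas <- vapply(seq_len(kInner), function(f) {
      .fitScore(fpset, points[[d]], trainIdx = which(folds != f),
                testIdx = which(folds == f),
                seed = .deriveSeed(seed, "innerfit", d, f),
                nSteps = nSteps, balance = balance)$ba
    }, numeric(1))
    scores[d] <- mean(bas)
  }
  best <- points[[which.max(scores)]]   # which.max: first max wins ties
  log <- do.call(rbind, lapply(seq_len(nDraws), function(d)
    data.frame(draw = d, as.data.frame(unclass(points[[d]])),
               meanInnerBA = scores[d])))
  attr(best, "searchLog") <- log
  best
}

#' Repeated nested cross-validation of the spiking classifier
#'
#' The evaluation protocol: hyperparameters are selected in an inner
#' cross-validated random search run only on each outer-training portion,
#' the winning configuration is refit on that whole portion, and balanced
#' accuracy plus ROC AUC are measured on the held-out outer fold. The whole
#' procedure is repeated `nRepeats` times with reshuffled folds to expose
#' model variability; the summary aggregates the per-repetition means.
#'
#' Class balancing has two modes. `"paper"` equalizes class counts by
#' oversampling the minority class once, before the folds are drawn — the
#' historical protocol, in which duplicated minority records may straddle a
#' fold boundary. `"safe"` (recommended) oversamples inside each training
#' portion only, so no test fold ever contains a duplicate of a training
#' record. `"none"` leaves the data as provided.
#'
#' @param fpset a [FingerprintSet-class].
#' @param grid a [hyperGrid()].
#' @param kOuter,kInner outer/inner fold counts (defaults 5 and 3).
#' @param nRepeats repetitions of the whole CV (default 10).
#' @param nDraws random-search draws per outer fold.
#' @param seed master seed; every stochastic component derives from it.
#' @param balance `"none"`, `"paper"` or `"safe"`.
#' @param nSteps simulation steps per forward pass.
#' @param repeatSeeds optional integer vector (length `nRepeats`) of
#'   per-repetition seeds, overriding the derived ones (identical entries
#'   force identical repetitions).
#' @return a [CVSummary-class].
#' @export
nestedCV <- function(fpset, grid, kOuter = 5, kInner = 3, nRepeats = 10,
                     nDraws = 10, seed = 1, balance = c("none", "paper",
                                                        "safe"),
                     nSteps = 25, repeatSeeds = NULL) {
  balance <- match.arg(balance)
  if (kOuter < 2 || kInner < 2)
    stop("kOuter and kInner must be >= 2", call. = FALSE)
  origIdx <- seq_along(fpLabels(fpset))
  if (balance == "paper") {
    fpset <- oversampleMinority(fpset, .deriveSeed(seed, "prebalance"))
    origIdx <- attr(fpset, "oversampleIdx")  # maps rows back to originals
  }
  y <- fpLabels(fpset)
  if (is.null(repeatSeeds))
    repeatSeeds <- vapply(seq_len(nRepeats),
                          function(r) .deriveSeed(seed, "rep", r),
                          integer(1))
  stopifnot(length(repeatSeeds) == nRepeats)
  rows <- list(); book <- list()
  for (r in seq_len(nRepeats)) {
    rs <- repeatSeeds[r]
    folds <- .stratifiedFolds(y, kOuter, .deriveSeed(rs, "outerfolds"))
    for (f in seq_len(kOuter)) {
      outerTest <- which(folds == f)
      outerTrain <- which(folds != f)
      best <- randomSearch(fpset[outerTrain], grid, nDraws = nDraws,
                           kInner = kInner,
                           seed = .deriveSeed(rs, "search", f),
                           nSteps = nSteps,
                           balance = if (balance == "safe") "safe"
                                     else "none")
      fit <- .fitScore(fpset, best, trainIdx = outerTrain,
                       testIdx = outerTest,
                       seed = .deriveSeed(rs, "refit", f),
                       nSteps = nSteps, balance = balance)
      rows[[length(rows) + 1L]] <-
        data.frame(rep = r, fold = f, ba = fit$ba, auc = fit$auc,
                   as.data.frame(unclass(best)))
      book[[length(book) + 1L]] <-
        list(rep = r, fold = f, outerTest = outerTest,
             outerTrain = outerTrain, innerTrain = outerTrain)
    }
  }
  results <- do.call(rbind, rows)
  perRep <- tapply(results$ba, results$rep, mean)
  perRepAUC <- tapply(results$auc, results$rep, mean)
  new("CVSummary", results = results,
      meanBA = mean(perRep), stdBA = stats::sd(c(perRep)),
      meanAUC = mean(perRepAUC), stdAUC = stats::sd(c(perRepAUC)),
      bookkeeping = book,
      config = list(kOuter = kOuter, kInner = kInner, nRepeats = nRepeats,
                    nDraws = nDraws, seed = seed, balance = balance,
                    nSteps = nSteps, repeatSeeds = repeatSeeds,
                    origIdx = origIdx))
}

#' Rank hyperparameter configurations
#'
#' Sorts search records by mean balanced accuracy (descending, stable — ties
#' keep insertion order) and keeps the top `topK`, mirroring the layout of a
#' leaderboard table: hidden width, decay, slope, optimizer, learning rate,
#' weight decay, clipping flag, mean and sd.
#'
#' @param records data.frame with at least a `meanBA` column (e.g. the
#'   per-configuration aggregation of [nestedCV()] results or a
#'   [randomSearch()] log with `meanInnerBA` renamed).
#' @param topK rows to keep (default 5).
#' @return the sorted, truncated data.frame.
#' @export
rankModels <- function(records, topK = 5) {
  if (nrow(records) < 1L) stop("no records to rank", call. = FALSE)
  ord <- order(-records$meanBA)          # stable in base R
  out <- records[ord, , drop = FALSE][seq_len(min(topK, nrow(records))), ,
                                      drop = FALSE]
  rownames(out) <- NULL
  out
}
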