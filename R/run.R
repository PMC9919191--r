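# Pipeline entry points wrapped by the command-line script in
# inst/scripts/spikescreen.R. Each returns its outputs invisibly and writes
# files only where asked, so they are equally usable from R.

#' Encode a SMILES CSV into a fingerprint matrix file
#'
#' @param csvIn input CSV with SMILES and binary labels.
#' @param out output CSV path: label column followed by one 0/1 column per
#'   bit.
#' @param fingerprint `"maccs"` or `"ecfp"`.
#' @param radius,nBits ECFP settings.
#' @param smilesColumn,labelColumn input column names.
#' @param reportOut optional path for a JSON encode report (skip counts and
#'   skipped SMILES).
#' @return the [FingerprintSet-class], invisibly.
#' @export
runEncode <- function(csvIn, out, fingerprint = c("maccs", "ecfp"),
                      radius = 2, nBits = 1024, smilesColumn = "smiles",
                      labelColumn = "label", reportOut = NULL) {
  fingerprint <- match.arg(fingerprint)
  records <- loadSmilesTable(csvIn, smilesColumn = smilesColumn,
                             labelColumn = labelColumn)
  fps <- encodeDataset(records, fingerprint = fingerprint, radius = radius,
                       nBits = nBits)
  m <- fpMatrix(fps)
  colnames(m) <- sprintf("bit%03d", seq_len(ncol(m)))
  utils::write.csv(data.frame(label = fpLabels(fps), m), out,
                   row.names = FALSE, quote = FALSE)
  if (!is.null(reportOut)) {
    rep <- c(attr(records, "report"), attr(fps, "report"))
    jsonlite::write_json(rep, reportOut, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(fps)
}

#' Simulate one LIF neuron and export the voltage trace
#'
#' @param beta membrane decay.
#' @param threshold firing threshold.
#' @param current constant input current.
#' @param steps number of simulation steps.
#' @param out optional CSV path (`step,V,spike`).
#' @return the trace data.frame, invisibly.
#' @export
runNeuron <- function(beta = 0.95, threshold = 1, current = 0.1,
                      steps = 100, out = NULL) {
  tr <- simulateConstantInput(lifParams(beta = beta, threshold = threshold),
                              current, steps)
  if (!is.null(out))
    utils::write.csv(tr, out, row.names = FALSE, quote = FALSE)
  invisible(tr)
}

# Validate a screening configuration, filling defaults.
.validateScreenConfig <- function(config) {
  defaults <- list(dataset = NULL, synthetic = NULL,
                   fingerprint = "maccs", radius = 2, nBits = 1024,
                   smilesColumn = "smiles", labelColumn = "label",
                   grid = hyperGrid(), kOuter = 5, kInner = 3,
                   nRepeats = 10, nDraws = 10, balance = "paper",
                   nSteps = 25, seed = 1, outDir = NULL, force = FALSE,
                   topK = 5)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  config <- utils::modifyList(defaults, config)
  if (is.null(config$dataset) && is.null(config$synthetic))
    stop("config must provide either a dataset path or a synthetic spec",
         call. = FALSE)
  if (!config$balance %in% c("none", "paper", "safe"))
    stop("balance must be none, paper or safe", call. = FALSE)
  config
}

#' Run the full screening pipeline
#'
#' Load (or generate) the data, balance, run repeated nested
#' cross-validation with random hyperparameter search, and rank the winning
#' configurations. When `outDir` is set, writes `results.csv` (per
#' repetition x fold), `top_models.csv` (leaderboard of the chosen
#' configurations aggregated over folds) and `manifest.json` (the full
#' configuration and seeds needed to replay the run bit-identically).
#'
#' @param config named list; see [`.validateScreenConfig`] fields: one of
#'   `dataset` (CSV path) or `synthetic` (argument list for
#'   [syntheticFingerprints()]), plus `fingerprint`, `grid`, `kOuter`,
#'   `kInner`, `nRepeats`, `nDraws`, `balance`, `nSteps`, `seed`, `outDir`,
#'   `force`, `topK`.
#' @return list with the [CVSummary-class] (`cv`) and the leaderboard
#'   (`top`), invisibly.
#' @export
runScreen <- function(config) {
  config <- .validateScreenConfig(config)
  fps <- if (!is.null(config$dataset)) {
    records <- loadSmilesTable(config$dataset,
                               smilesColumn = config$smilesColumn,
                               labelColumn = config$labelColumn)
    encodeDataset(records, fingerprint = config$fingerprint,
                  radius = config$radius, nBits = config$nBits)
  } else {
    do.call(syntheticFingerprints, config$synthetic)
  }
  cv <- nestedCV(fps, config$grid, kOuter = config$kOuter,
                 kInner = config$kInner, nRepeats = config$nRepeats,
                 nDraws = config$nDraws, seed = config$seed,
                 balance = config$balance, nSteps = config$nSteps)
  res <- cvResults(cv)
  key <- c("nHidden", "beta", "slope", "optimizer", "lr", "wd", "gc")
  agg <- stats::aggregate(res$ba, by = res[key], FUN = function(v)
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0))
  agg <- cbind(agg[key], meanBA = agg$x[, "mean"], stdBA = agg$x[, "sd"])
  top <- rankModels(agg, topK = config$topK)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(config$outDir,
                       c("results.csv", "top_models.csv", "manifest.json"))
    if (!config$force && any(file.exists(paths)))
      stop("output files exist in ", config$outDir,
           " (use force = TRUE to overwrite)", call. = FALSE)
    utils::write.csv(res, paths[1], row.names = FALSE)
    utils::write.csv(top, paths[2], row.names = FALSE)
    manifest <- config[setdiff(names(config), "grid")]
    manifest$grid <- lapply(config$grid, unname)
    manifest$summary <- list(meanBA = cv@meanBA, stdBA = cv@stdBA,
                             meanAUC = cv@meanAUC, stdAUC = cv@stdAUC)
    manifest$rVersion <- as.character(getRversion())
    jsonlite::write_json(manifest, paths[3], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
  }
  invisible(list(cv = cv, top = top))
}
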