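#' Read a SMILES table with binary activity labels
#'
#' Loads a MoleculeNet-style CSV (comma-separated, header row, UTF-8) holding
#' one molecule per row: a SMILES string column and a single binary label
#' column. Rows whose label is missing or not interpretable as 0/1 are
#' skipped and counted; SMILES validity is *not* checked here (that happens
#' at standardization/encoding time, so a load report and an encode report
#' stay separate).
#'
#' @param path path to the CSV file.
#' @param smilesColumn,labelColumn column names (defaults `"smiles"`,
#'   `"label"`).
#' @return data.frame with columns `smiles` (character) and `label`
#'   (integer 0/1), rows in file order; attribute `"report"` is a list with
#'   `nRead`, `nKept` and `nSkippedLabel`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(smiles = c("CCO", "c1ccccc1"), label = c(1, 0)),
#'           f, row.names = FALSE)
#' d <- loadSmilesTable(f)
#' attr(d, "report")
#' @export
loadSmilesTable <- function(path, smilesColumn = "smiles",
                            labelColumn = "label") {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", check.names = FALSE)
  for (col in c(smilesColumn, labelColumn))
    if (!col %in% names(tab))
      stop("column '", col, "' not present in ", path, call. = FALSE)
  smiles <- as.character(tab[[smilesColumn]])
  rawLab <- trimws(as.character(tab[[labelColumn]]))
  lab <- suppressWarnings(as.numeric(rawLab))
  ok <- !is.na(lab) & lab %in% c(0, 1) & !is.na(smiles) & nzchar(smiles)
  out <- data.frame(smiles = smiles[ok], label = as.integer(lab[ok]),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L)
    stop("no usable rows in ", path, " after label filtering", call. = FALSE)
  attr(out, "report") <- list(nRead = nrow(tab), nKept = nrow(out),
                              nSkippedLabel = nrow(tab) - nrow(out))
  out
}

# Canonicalize one SMILES through OpenBabel; NA_character_ on parse failure.
.canonicalizeOne <- function(s) {
  out <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", s),
                  error = function(e) "")
  out <- sub("[\t ].*$", "", sub("\n$", "", out))
  if (!nzchar(out)) NA_character_ else out
}

#' Standardize and canonicalize SMILES strings
#'
#' Normalizes each molecule (aromaticity perception, functional-group
#' normalization as performed by the OpenBabel canonicalizer) and returns its
#' canonical SMILES, so that different spellings of the same structure — for
#' instance `"C(C)O"` and `"CCO"` — map to one string. The operation is
#' idempotent: standardizing an already standardized SMILES returns it
#' unchanged.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @section Errors: an unparseable SMILES raises an error of class
#'   `smilesParseError` whose `offending` field carries the bad string(s).
#' @examples
#' standardizeSmiles(c("C(C)O", "CCO"))  # both "CCO"
#' @export
standardizeSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) == 0L || any(!nzchar(smiles)))
    stop("smiles must be one or more non-empty strings", call. = FALSE)
  out <- vapply(smiles, .canonicalizeOne, character(1), USE.NAMES = FALSE)
  if (anyNA(out)) {
    bad <- smiles[is.na(out)]
    cond <- structure(
      class = c("smilesParseError", "error", "condition"),
      list(message = paste0("unparseable SMILES: ",
                            paste(bad, collapse = ", ")),
           call = sys.call(-1), offending = bad))
    stop(cond)
  }
  out
}

# OpenBabel fingerprint for a vector of (already canonical) SMILES.
# Returns a 0/1 matrix, one row per molecule.
.fingerprintOB <- function(smiles, obType) {
  mols <- ChemmineOB::forEachMol("SMILES",
                                 paste0(paste(smiles, collapse = "\n"),
                                        "\n"),
                                 identity)
  m <- ChemmineOB::fingerprint_OB(mols, obType)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  if (nrow(m) != length(smiles))
    stop("fingerprint backend returned ", nrow(m), " rows for ",
         length(smiles), " molecules", call. = FALSE)
  m
}

#' Encode a molecule as 166-bit MACCS keys
#'
#' Standardizes the SMILES and computes the public 166-key MACCS
#' substructure fingerprint (SMARTS-based, via the OpenBabel backend, whose
#' key numbering agrees with the RDKit implementation).
#'
#' @param smiles character vector of SMILES strings.
#' @return if one SMILES is given, an integer 0/1 vector of length 166;
#'   otherwise an `n x 166` 0/1 matrix.
#' @examples
#' sum(encodeMACCS("CCO"))  # a handful of keys set for ethanol
#' @export
encodeMACCS <- function(smiles) {
  std <- standardizeSmiles(smiles)
  m <- .fingerprintOB(std, "MACCS")[, 1:166, drop = FALSE]
  storage.mode(m) <- "integer"
  if (length(smiles) == 1L) drop(m) else m
}

#' Encode a molecule as a hashed extended-connectivity fingerprint
#'
#' Computes circular (Morgan-style) substructure fingerprints of the given
#' radius and folds the hashed bit vector down to `nBits` positions by OR-ing
#' bits with equal index modulo `nBits` (the usual fingerprint folding).
#'
#' @param smiles character vector of SMILES strings.
#' @param radius integer atom-environment radius (0–5); default 2 (ECFP4).
#' @param nBits requested fingerprint length; default 1024.
#' @return 0/1 vector of length `nBits` (single SMILES) or an `n x nBits`
#'   matrix.
#' @examples
#' length(encodeECFP("CCO"))  # 1024
#' @export
encodeECFP <- function(smiles, radius = 2, nBits = 1024) {
  if (length(radius) != 1L || radius < 0 || radius > 5 || radius %% 1 != 0)
    stop("radius must be an integer in 0..5", call. = FALSE)
  if (length(nBits) != 1L || nBits < 1 || nBits %% 1 != 0)
    stop("nBits must be a positive integer", call. = FALSE)
  std <- standardizeSmiles(smiles)
  m <- .foldFingerprint(.fingerprintOB(std, sprintf("ECFP%d", 2 * radius)),
                        nBits)
  if (length(smiles) == 1L) drop(m) else m
}

# OR-fold a hashed fingerprint matrix down to nBits columns (bit i of the
# raw vector lands on position i mod nBits).
.foldFingerprint <- function(raw, nBits) {
  m <- matrix(0L, nrow(raw), nBits)
  for (start in seq(1L, ncol(raw), by = nBits)) {
    end <- min(start + nBits - 1L, ncol(raw))
    w <- end - start + 1L
    m[, seq_len(w)] <- as.integer(m[, seq_len(w)] |
                                  raw[, start:end, drop = FALSE])
  }
  m
}

#' Encode a SMILES table into a FingerprintSet
#'
#' Standardizes and fingerprints every molecule of a loaded SMILES table
#' (see [loadSmilesTable()]). Molecules whose SMILES fail to parse are
#' dropped and listed in the encode report instead of aborting the whole
#' dataset.
#'
#' @param records data.frame with `smiles` and `label` columns.
#' @param fingerprint `"maccs"` (166 bits) or `"ecfp"`.
#' @param radius,nBits ECFP parameters, ignored for MACCS.
#' @return a [FingerprintSet-class]; attribute `"report"` lists `nInput`,
#'   `nEncoded`, `nSkippedParse` and the `skippedSmiles`.
#' @export
encodeDataset <- function(records, fingerprint = c("maccs", "ecfp"),
                          radius = 2, nBits = 1024) {
  fingerprint <- match.arg(fingerprint)
  smiles <- as.character(records$smiles)
  std <- vapply(smiles, .canonicalizeOne, character(1), USE.NAMES = FALSE)
  ok <- !is.na(std)
  if (!any(ok))
    stop("no molecule could be parsed", call. = FALSE)
  bits <- if (fingerprint == "maccs") {
    .fingerprintOB(std[ok], "MACCS")[, 1:166, drop = FALSE]
  } else {
    .foldFingerprint(.fingerprintOB(std[ok], sprintf("ECFP%d", 2 * radius)),
                     nBits)
  }
  bits <- matrix(as.integer(bits), nrow = sum(ok))
  fps <- FingerprintSet(bits, labels = records$label[ok],
                        fpType = if (fingerprint == "maccs") "MACCS"
                                 else sprintf("ECFP%d", 2 * radius))
  attr(fps, "report") <- list(nInput = length(smiles), nEncoded = sum(ok),
                              nSkippedParse = sum(!ok),
                              skippedSmiles = smiles[!ok])
  fps
}

#' Jaccard–Tanimoto similarity of two fingerprints
#'
#' `|a AND b| / |a OR b|`: the fraction of bits set in either fingerprint
#' that are set in both. Symmetric, bounded in \[0, 1\], and equal to 1
#' exactly when the two non-empty bit supports coincide. Two all-zero
#' fingerprints share no substructure evidence at all, so their similarity
#' is defined as 0 (with a warning) rather than the indeterminate 0/0.
#'
#' @param a,b 0/1 vectors of equal length.
#' @return numeric scalar in \[0, 1\].
#' @examples
#' tanimoto(c(1,1,0,0), c(0,1,1,0))  # 1/3
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop("fingerprints have different lengths (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  .assertBinary(a, "fingerprint a"); .assertBinary(b, "fingerprint b")
  union <- sum(a == 1 | b == 1)
  if (union == 0) {
    warning("both fingerprints are all-zero; Tanimoto defined as 0")
    return(0)
  }
  sum(a == 1 & b == 1) / union
}

#' @rdname meanPairwiseTanimoto
#' @export
setMethod("meanPairwiseTanimoto", "matrix", function(x) {
  if (nrow(x) < 2)
    stop("need at least 2 fingerprints", call. = FALSE)
  .assertBinary(x, "fingerprint matrix")
  inter <- tcrossprod(x)            # pairwise |a AND b|
  s <- rowSums(x)
  union <- outer(s, s, "+") - inter # |a| + |b| - |a AND b|
  ut <- upper.tri(inter)
  i <- inter[ut]; u <- union[ut]
  if (any(u == 0))
    warning("all-zero fingerprint pair(s); their Tanimoto counted as 0")
  vals <- ifelse(u == 0, 0, i / u)
  mean(vals)
})

#' @rdname meanPairwiseTanimoto
#' @export
setMethod("meanPairwiseTanimoto", "FingerprintSet",
          function(x) meanPairwiseTanimoto(fpMatrix(x)))

# Oversampling core: indices making a class-balanced resample of `labels`.
.oversampleIdx <- function(labels, seed) {
  tab <- table(factor(labels, levels = c(0, 1)))
  if (any(tab == 0))
    stop("both classes must be present to oversample", call. = FALSE)
  minority <- if (tab[["0"]] < tab[["1"]]) 0L else 1L
  need <- abs(tab[["0"]] - tab[["1"]])
  minIdx <- which(labels == minority)
  extra <- if (need > 0)
    .withSeed(seed,
              minIdx[sample.int(length(minIdx), need, replace = TRUE)])
  else integer(0)
  c(seq_along(labels), extra)
}

#' @rdname oversampleMinority
#' @export
setMethod("oversampleMinority", "data.frame",
  function(x, seed, labelColumn = "label") {
    idx <- .oversampleIdx(x[[labelColumn]], seed)
    out <- x[idx, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "oversampleIdx") <- idx
    out
  })

#' @rdname oversampleMinority
#' @export
setMethod("oversampleMinority", "FingerprintSet", function(x, seed) {
  idx <- .oversampleIdx(fpLabels(x), seed)
  out <- x[idx]
  attr(out, "oversampleIdx") <- idx
  out
})
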