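# SMILES loading, standardization, fingerprints, similarity, oversampling.

test_that("loadSmilesTable reads rows in order and skips bad labels", {
  f <- writeSmilesCSV(c("CCO", "c1ccccc1", "CC(=O)O"), c(1, 0, 1))
  d <- loadSmilesTable(f)
  expect_equal(d$smiles, c("CCO", "c1ccccc1", "CC(=O)O"))
  expect_equal(d$label, c(1L, 0L, 1L))
  expect_equal(attr(d, "report")$nSkippedLabel, 0L)

  # empty and non-binary label cells are skipped and counted
  f2 <- writeSmilesCSV(c("CCO", "CCN", "CCC", "CCCl"), c("1", "", "2", "0"))
  d2 <- loadSmilesTable(f2)
  expect_equal(nrow(d2), 2L)
  expect_equal(attr(d2, "report")$nSkippedLabel, 2L)

  # labels written as strings round-trip to integer 0/1
  fps <- easyFingerprints(c(5, 5))
  f3 <- tempfile(fileext = ".csv")
  writeFingerprintCSV(fps, f3)
  d3 <- loadSmilesTable(f3)
  expect_type(d3$label, "integer")
  expect_equal(d3$label, fpLabels(fps))

  expect_error(loadSmilesTable(tempfile()), "not found")
  expect_error(loadSmilesTable(f, labelColumn = "missing"), "missing")
})

test_that("standardization canonicalizes, is idempotent, rejects garbage", {
  expect_identical(standardizeSmiles("C(C)O"), standardizeSmiles("CCO"))
  for (s in c("CCO", "c1ccccc1O", "CC(=O)Oc1ccccc1C(=O)O")) {
    std <- standardizeSmiles(s)
    expect_identical(standardizeSmiles(std), std)
  }
  err <- tryCatch(standardizeSmiles("not_a_molecule"), error = identity)
  expect_s3_class(err, "smilesParseError")
  expect_identical(err$offending, "not_a_molecule")
  expect_error(standardizeSmiles(""), "non-empty")
})

test_that("MACCS encoding is 166 bits, deterministic, matches reference keys", {
  v <- encodeMACCS("CCO")
  expect_length(v, 166L)
  expect_true(all(v %in% c(0L, 1L)))
  # reference on-bit positions for ethanol from an independent MACCS-keys
  # implementation (RDKit's SMARTS set, 1-based key numbering)
  expect_equal(which(v == 1L), c(82, 109, 114, 139, 153, 155, 157, 160, 164))
  expect_identical(encodeMACCS("CCO"), v)
  m <- encodeMACCS(c("CCO", "c1ccccc1"))
  expect_equal(dim(m), c(2L, 166L))
  expect_error(encodeMACCS("not_a_molecule"), "unparseable")
})

test_that("ECFP encoding honours radius and length contracts", {
  e <- encodeECFP("CCO")
  expect_length(e, 1024L)
  expect_true(all(e %in% c(0L, 1L)))
  expect_gt(sum(e), 0)
  # single-atom molecule at radius 0 still sets at least one bit
  expect_gt(sum(encodeECFP("C", radius = 0)), 0)
  expect_length(encodeECFP("CCO", nBits = 512), 512L)
  expect_length(encodeECFP("CCO", nBits = 2048), 2048L)
  expect_identical(encodeECFP("c1ccccc1"), encodeECFP("c1ccccc1"))
  expect_error(encodeECFP("CCO", radius = 9), "radius")
})

test_that("Tanimoto index follows set arithmetic", {
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 1, 1, 0)), 1 / 3)
  expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_warning(z <- tanimoto(c(0, 0), c(0, 0)), "all-zero")
  expect_equal(z, 0)
  expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length")
  # symmetry and bounds on random pairs
  set.seed(42)
  for (i in 1:20) {
    a <- rbinom(32, 1, 0.3); b <- rbinom(32, 1, 0.3)
    if (sum(a | b) == 0) next
    expect_identical(tanimoto(a, b), tanimoto(b, a))
    expect_gte(tanimoto(a, b), 0); expect_lte(tanimoto(a, b), 1)
    expect_equal(tanimoto(a, b) == 1,
                 identical(which(a == 1), which(b == 1)) && sum(a) > 0)
  }
})

test_that("mean pairwise Tanimoto averages all unordered pairs", {
  m <- rbind(c(1, 1, 0, 0), c(0, 1, 1, 0), c(1, 1, 1, 0))
  expect_equal(meanPairwiseTanimoto(m), mean(c(1 / 3, 2 / 3, 2 / 3)))
  # k identical non-zero rows give exactly 1 for any k
  for (k in c(2, 5)) {
    dup <- matrix(rep(c(1, 0, 1, 1), each = k), k, 4)
    expect_equal(meanPairwiseTanimoto(dup), 1)
  }
  expect_equal(meanPairwiseTanimoto(rbind(c(1, 0), c(0, 1))), 0)
  expect_error(meanPairwiseTanimoto(matrix(1, 1, 4)), "at least 2")
  # matches brute force over tanimoto() on a random matrix
  set.seed(1)
  r <- matrix(rbinom(60, 1, 0.4), 10, 6)
  pairs <- utils::combn(10, 2)
  bf <- mean(apply(pairs, 2, function(p) tanimoto(r[p[1], ], r[p[2], ])))
  expect_equal(meanPairwiseTanimoto(r), bf)
  expect_equal(meanPairwiseTanimoto(FingerprintSet(r, rep(0:1, 5))), bf)
})

test_that("oversampling equalizes to the majority count without inventing records", {
  d <- data.frame(smiles = letters[1:4], label = c(0, 0, 0, 1))
  out <- oversampleMinority(d, seed = 1)
  expect_equal(as.integer(table(out$label)), c(3L, 3L))
  # the single minority record is simply repeated
  expect_true(all(out$smiles[out$label == 1] == "d"))
  expect_setequal(unique(out$smiles), d$smiles)

  # already balanced input is a fixed point (in counts and content)
  b <- data.frame(smiles = letters[1:4], label = c(0, 1, 0, 1))
  expect_equal(oversampleMinority(b, seed = 3)$smiles, b$smiles)

  # FingerprintSet method conserves the majority class exactly
  fps <- syntheticFingerprints(nPerClass = c(30, 7), nBits = 16,
                               nInformative = 4, seed = 2)
  bal <- oversampleMinority(fps, seed = 9)
  expect_equal(as.integer(table(fpLabels(bal))), c(30L, 30L))
  idx <- attr(bal, "oversampleIdx")
  expect_identical(fpMatrix(bal), fpMatrix(fps)[idx, ])
  # appended rows are duplicates of existing minority rows
  expect_true(all(idx[-seq_len(37)] %in% which(fpLabels(fps) == 1L)))
  # same seed, same draws
  expect_identical(attr(oversampleMinority(fps, seed = 9), "oversampleIdx"),
                   idx)
  expect_error(oversampleMinority(fps[1:30], seed = 1), "both classes")
})

test_that("encodeDataset drops unparseable molecules with a report", {
  d <- data.frame(smiles = c("CCO", "not_a_molecule", "c1ccccc1"),
                  label = c(1, 0, 0))
  fps <- encodeDataset(d, "maccs")
  expect_equal(dim(fpMatrix(fps)), c(2L, 166L))
  expect_equal(fpLabels(fps), c(1L, 0L))
  rep <- attr(fps, "report")
  expect_equal(rep$nSkippedParse, 1L)
  expect_equal(rep$skippedSmiles, "not_a_molecule")
})
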