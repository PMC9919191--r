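# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a string tag, so
# every stochastic component (fold shuffles, search draws, weight init,
# oversampling) gets its own stream while the whole pipeline is driven by a
# single user-facing seed. Kept strictly below 2^31 - 1.
.deriveSeed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h) %% 2147483647)
}

# Evaluate an expression under a local RNG state.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.assertBinary <- function(x, what = "vector") {
  if (!all(x %in% c(0, 1)))
    stop(what, " must contain only 0/1 entries", call. = FALSE)
  invisible(x)
}

# Stratified k-fold assignment: returns an integer fold id per sample,
# shuffled within each class so every fold holds (near-)proportional counts
# of both classes.
.stratifiedFolds <- function(labels, k, seed) {
  if (k < 2) stop("need at least 2 folds", call. = FALSE)
  fold <- integer(length(labels))
  .withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop("class ", cl, " has fewer samples (", length(idx),
             ") than folds (", k, ")", call. = FALSE)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}
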