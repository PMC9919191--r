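#' Construct an optimizer
#'
#' The seven first-order optimizers surveyed for training the spiking
#' classifier: Adam, Adamax, plain stochastic gradient descent (SGO),
#' Adagrad, Adadelta, AdamW and RMSProp, with the conventional default
#' moments/epsilons of each. Weight decay `wd` is coupled (added to the
#' gradient) for all of them except AdamW, where it is decoupled and applied
#' directly to the weights.
#'
#' @param name one of `"Adam"`, `"Adamax"`, `"SGO"`, `"Adagrad"`,
#'   `"Adadelta"`, `"AdamW"`, `"RMSProp"`.
#' @param lr positive learning rate.
#' @param wd weight decay, >= 0.
#' @return an optimizer object; `step(params, grads)` maps a named list of
#'   weight matrices and a matching list of gradients to updated weights,
#'   keeping internal state (moments, accumulators) across calls.
#' @examples
#' opt <- makeOptimizer("Adam", lr = 1e-4)
#' w <- list(W = matrix(1, 2, 2))
#' g <- list(W = matrix(0.5, 2, 2))
#' opt$step(w, g)$W
#' @export
makeOptimizer <- function(name, lr, wd = 0) {
  valid <- c("Adam", "Adamax", "SGO", "Adagrad", "Adadelta", "AdamW",
             "RMSProp")
  if (!name %in% valid)
    stop("unknown optimizer '", name, "'; choose one of ",
         paste(valid, collapse = ", "), call. = FALSE)
  if (lr < 0) stop("lr must be non-negative", call. = FALSE)
  if (wd < 0) stop("wd must be >= 0", call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  zeroLike <- function(params) lapply(params, function(p) p * 0)
  step <- function(params, grads) {
    st$t <- st$t + 1L
    if (name != "AdamW" && wd > 0)
      grads <- Map(function(g, p) g + wd * p, grads, params)
    out <- switch(name,
      SGO = Map(function(p, g) p - lr * g, params, grads),
      Adam = , AdamW = {
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        if (is.null(st$m)) { st$m <- zeroLike(params); st$v <- zeroLike(params) }
        st$m <- Map(function(m, g) b1 * m + (1 - b1) * g, st$m, grads)
        st$v <- Map(function(v, g) b2 * v + (1 - b2) * g^2, st$v, grads)
        bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
        upd <- Map(function(m, v) (m / bc1) / (sqrt(v / bc2) + eps),
                   st$m, st$v)
        if (name == "AdamW" && wd > 0)
          Map(function(p, u) p - lr * (u + wd * p), params, upd)
        else
          Map(function(p, u) p - lr * u, params, upd)
      },
      Adamax = {
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        if (is.null(st$m)) { st$m <- zeroLike(params); st$u <- zeroLike(params) }
        st$m <- Map(function(m, g) b1 * m + (1 - b1) * g, st$m, grads)
        st$u <- Map(function(u, g) pmax(b2 * u, abs(g)), st$u, grads)
        bc1 <- 1 - b1^st$t
        Map(function(p, m, u) p - (lr / bc1) * m / (u + eps),
            params, st$m, st$u)
      },
      Adagrad = {
        eps <- 1e-10
        if (is.null(st$acc)) st$acc <- zeroLike(params)
        st$acc <- Map(function(a, g) a + g^2, st$acc, grads)
        Map(function(p, g, a) p - lr * g / (sqrt(a) + eps),
            params, grads, st$acc)
      },
      Adadelta = {
        rho <- 0.9; eps <- 1e-6
        if (is.null(st$acc)) { st$acc <- zeroLike(params)
                               st$accD <- zeroLike(params) }
        st$acc <- Map(function(a, g) rho * a + (1 - rho) * g^2,
                      st$acc, grads)
        delta <- Map(function(g, a, d) sqrt(d + eps) / sqrt(a + eps) * g,
                     grads, st$acc, st$accD)
        st$accD <- Map(function(d, dl) rho * d + (1 - rho) * dl^2,
                       st$accD, delta)
        Map(function(p, dl) p - lr * dl, params, delta)
      },
      RMSProp = {
        alpha <- 0.99; eps <- 1e-8
        if (is.null(st$acc)) st$acc <- zeroLike(params)
        st$acc <- Map(function(a, g) alpha * a + (1 - alpha) * g^2,
                      st$acc, grads)
        Map(function(p, g, a) p - lr * g / (sqrt(a) + eps),
            params, grads, st$acc)
      })
    out
  }
  structure(list(name = name, lr = lr, wd = wd, step = step,
                 state = st), class = "snnOptimizer")
}

#' @export
print.snnOptimizer <- function(x, ...) {
  cat(sprintf("<%s optimizer: lr = %g, wd = %g, steps taken = %d>\n",
              x$name, x$lr, x$wd, x$state$t))
  invisible(x)
}
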