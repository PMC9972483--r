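# Internal numeric helpers shared across modules.

# 32-bit unsigned arithmetic on doubles (R has no native uint32).
.u32 <- function(x) x %% 4294967296

.mul32 <- function(a, b) {
  a <- .u32(a); b <- .u32(b)
  ah <- a %/% 65536; al <- a %% 65536
  .u32(((ah * b) %% 4294967296 %/% 1) %% 65536 * 65536 + al * b)
}

.xor32 <- function(a, b) {
  ai <- if (a >= 2147483648) as.integer(a - 4294967296) else as.integer(a)
  bi <- if (b >= 2147483648) as.integer(b - 4294967296) else as.integer(b)
  r <- bitwXor(ai, bi)
  if (r < 0) r + 4294967296 else r
}

.shr32 <- function(x, n) floor(.u32(x) / 2^n)

#' Counter-based seed derivation (splitmix32 finalizer)
#'
#' Derives an independent child seed from a global seed and a counter, so
#' that every simulated patient (or run) has its own reproducible random
#' stream regardless of how many patients precede it.
#'
#' @param seed Integer global seed.
#' @param counter Integer counter (e.g. patient index).
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, counter) {
  x <- .u32(.u32(seed) + .mul32(.u32(counter) + 1, 2654435769))
  x <- .u32(x + 2654435769)
  x <- .mul32(.xor32(x, .shr32(x, 16)), 2246822519)
  x <- .mul32(.xor32(x, .shr32(x, 13)), 3266489917)
  x <- .xor32(x, .shr32(x, 16))
  as.integer(x %% 2147483645) + 1L
}

# Evaluate expr with a temporary RNG state; restores the caller's stream.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Row-wise softmax with max-shift for numerical stability.
.softmaxRows <- function(x) {
  mx <- x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
  e <- exp(x - mx)
  e / rowSums(e)
}

# Row entropy of a probability matrix, natural log, 0*log0 := 0.
.rowEntropy <- function(p) {
  lp <- log(p)
  lp[p <= 0] <- 0
  -rowSums(p * lp)
}

.relu <- function(x) (x > 0) * x

# fast row-broadcast bias add (avoids sweep's aperm overhead)
.addBias <- function(X, b) X + rep(b, each = nrow(X))

# Adam optimizer state over a flat named list of parameter matrices.
.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weightDecay = 0) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    # decoupled weight decay on weight matrices, never on bias rows
    if (weightDecay > 0 && nrow(params[[nm]]) > 1)
      step <- step + lr * weightDecay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

# Glorot-style init.
.initMat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.assertThat <- function(cond, ...) if (!isTRUE(cond)) .stopf(...)
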