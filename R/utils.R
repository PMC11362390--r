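## Internal helpers.

## Run expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single integer 'seed' is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Truncated-normal sampler (lower bound 0) by inverse-CDF; exact and
## vectorized, no rejection loop.
rtruncnorm0 <- function(n, mean, sd) {
  plo <- stats::pnorm(0, mean, sd)
  u <- stats::runif(n, plo, 1)
  ## guard u == 1 from fp rounding
  u <- pmin(u, 1 - 1e-16)
  stats::qnorm(u, mean, sd)
}

## Sliding-window box sums via separable cumulative sums.  Returns an
## (nr - w + 1) x (nc - w + 1) matrix of window sums.
boxSums <- function(m, w) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- matrix(apply(m, 2, cumsum), nrow = nr, ncol = nc)
  top <- if (nr == w) cs[w, , drop = FALSE]
         else rbind(cs[w, , drop = FALSE],
                    cs[(w + 1):nr, , drop = FALSE] -
                      cs[seq_len(nr - w), , drop = FALSE])
  cs2 <- matrix(t(apply(top, 1, cumsum)), nrow = nrow(top), ncol = nc)
  if (nc == w) return(cs2[, w, drop = FALSE])
  cbind(cs2[, w, drop = FALSE],
        cs2[, (w + 1):nc, drop = FALSE] -
          cs2[, seq_len(nc - w), drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
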