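## Independent oracles used to validate the package implementations.
## These deliberately use naive loops, not the vectorized code paths.

## sliding-window sigma/mu by explicit double loop (population SD)
naiveContrastMap <- function(frame, window) {
  half <- (window - 1L) %/% 2L
  out <- matrix(NA_real_, nrow(frame), ncol(frame))
  for (i in (half + 1L):(nrow(frame) - half)) {
    for (j in (half + 1L):(ncol(frame) - half)) {
      w <- frame[(i - half):(i + half), (j - half):(j + half)]
      mu <- mean(w)
      if (mu > 0)
        out[i, j] <- sqrt(mean((w - mu)^2)) / mu
    }
  }
  out
}

## exhaustive Youden scan: evaluate every candidate threshold by direct
## counting and return the smallest threshold attaining the best J
bruteCutoff <- function(values, labels, direction) {
  sv <- sort(unique(values))
  mids <- (sv[-1] + sv[-length(sv)]) / 2
  cand <- c(sv[1] - 1, mids, sv[length(sv)] + 1)
  pos <- values[labels == "ischemic"]
  neg <- values[labels == "well"]
  best <- NULL
  for (t in cand) {
    if (direction == "below_positive") {
      sens <- sum(pos < t) / length(pos)
      spec <- sum(neg >= t) / length(neg)
    } else {
      sens <- sum(pos > t) / length(pos)
      spec <- sum(neg <= t) / length(neg)
    }
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12)
      best <- list(threshold = t, sens = sens, spec = spec, j = j)
  }
  best
}

## Cohen's kappa from a hand-built contingency table
bruteKappa <- function(a, b) {
  cats <- sort(unique(c(a, b)))
  n <- length(a)
  tab <- matrix(0, length(cats), length(cats),
                dimnames = list(cats, cats))
  for (i in seq_len(n)) tab[a[i], b[i]] <- tab[a[i], b[i]] + 1
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

## Mann-Whitney U by pair counting (ties count 1/2)
bruteU <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

## uniform-flow phantom covering the whole frame
uniformPhantom <- function(n, x, exposure = 5) {
  tau <- if (x == 0) matrix(Inf, n, n) else matrix(exposure / x, n, n)
  flowPhantom(tau, matrix("well", n, n), exposure = exposure)
}

measuredContrast <- function(stack, frame = 1) {
  f <- frames(stack)[, , frame]
  sqrt(mean((f - mean(f))^2)) / mean(f)
}
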