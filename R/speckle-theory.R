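#' Closed-form spatial contrast of time-integrated speckle
#'
#' For dynamic speckle with a negative-exponential field correlation
#' \eqn{g_1(t) = \exp(-t/\tau_c)} integrated over an exposure T, the
#' expected squared spatial contrast is
#' \deqn{K^2 = \beta \frac{e^{-2x} - 1 + 2x}{2 x^2}, \quad x = T/\tau_c,}
#' with the zero-motion limit \eqn{K^2 \to \beta} as \eqn{x \to 0}.  This
#' is the validation oracle for \code{\link{generateSpeckleStack}}: the
#' measured window contrast of a uniform-flow region must follow this
#' curve.
#'
#' @param x dimensionless exposure-to-decorrelation ratio \eqn{T/\tau_c};
#'   nonnegative, vectorized.
#' @param beta coherence factor \eqn{\beta \in (0, 1]}.
#'
#' @return numeric vector of expected contrast values \eqn{K \in [0, 1]},
#'   strictly decreasing in \code{x}.
#'
#' @examples
#' expectedContrast(0)            # 1: fully developed static speckle
#' expectedContrast(c(0.5, 1, 5)) # blurring with increasing flow
#'
#' @export
expectedContrast <- function(x, beta = 1) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite and >= 0")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1)
    stop("'beta' must lie in (0, 1]")
  k2 <- numeric(length(x))
  ## below x ~ 1e-3 the closed form cancels catastrophically (numerator
  ## ~ 2x^2 assembled from O(1) terms); the series is exact to ~1e-10
  ## there and keeps the curve continuous and monotone through 0
  small <- x < 1e-3
  xs <- x[small]
  k2[small] <- 1 - 2 * xs / 3 + xs^2 / 3 - 2 * xs^3 / 15
  xl <- x[!small]
  k2[!small] <- (exp(-2 * xl) - 1 + 2 * xl) / (2 * xl^2)
  sqrt(beta * k2)
}

## Expected contrast of the discrete M-sub-step integration actually
## performed by the simulator (rectangle rule).  Used internally to choose
## the automatic sub-step count.
discreteContrast <- function(x, M, beta = 1) {
  vapply(x, function(xi) {
    if (xi == 0) return(sqrt(beta))
    m <- seq_len(M - 1)
    s <- M + 2 * sum((M - m) * exp(-2 * xi * m / M))
    sqrt(beta * s / M^2)
  }, numeric(1))
}
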