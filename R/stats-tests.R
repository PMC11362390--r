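#' Two-group comparison with a normality-driven test choice
#'
#' Compares two groups of perfusion or lactate values the way the study's
#' analysis plan prescribes: each group is screened with a Shapiro-Wilk
#' normality test; if both pass at \code{alphaNormality} a two-sided Welch
#' t test is used, otherwise a two-sided Mann-Whitney U test.  A group
#' with zero variance cannot be normal and routes to the Mann-Whitney
#' branch; if both groups are identical constants no test can separate
#' them and p = 1 is returned with a warning.
#'
#' @param a,b numeric vectors, each of length >= 3.
#' @param alphaNormality significance level of the normality screen.
#' @param test \code{"auto"} (default) applies the normality-driven
#'   choice; \code{"t"} or \code{"mann_whitney"} force a branch.
#'
#' @return a \linkS4class{GroupTestResult}.  For the Mann-Whitney branch
#'   the statistic is the U statistic (ties counted 1/2).
#'
#' @examples
#' compareGroups(rnorm(20), rnorm(20, 2))
#'
#' @export
compareGroups <- function(a, b, alphaNormality = 0.05,
                          test = c("auto", "t", "mann_whitney")) {
  test <- match.arg(test)
  if (!is.numeric(a) || !is.numeric(b))
    stop("'a' and 'b' must be numeric")
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 values")

  shapP <- function(v) {
    if (stats::sd(v) == 0 || length(v) > 5000) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }
  np <- c(shapP(a), shapP(b))

  if (stats::sd(a) == 0 && stats::sd(b) == 0 && a[1] == b[1]) {
    warning("both groups are the same constant; returning p = 1")
    return(new("GroupTestResult", testUsed = "degenerate",
               statistic = NA_real_, pValue = 1, normalityP = np))
  }

  if (test == "auto") {
    bothNormal <- !anyNA(np) && all(np > alphaNormality)
    test <- if (bothNormal) "t" else "mann_whitney"
  }

  if (test == "t") {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    new("GroupTestResult", testUsed = "t",
        statistic = unname(tt$statistic), pValue = tt$p.value,
        normalityP = np)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    new("GroupTestResult", testUsed = "mann_whitney",
        statistic = unname(wt$statistic), pValue = wt$p.value,
        normalityP = np)
  }
}
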