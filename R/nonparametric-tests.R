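# Nonparametric group comparisons with explicit small-sample policies:
# mid-ranks for ties, zero differences dropped, exact null enumeration at
# the sample sizes of the phantom study, normal approximation with tie
# correction beyond.

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test with mid-ranks for ties. The null distribution
#' is enumerated exactly (all assignments of the pooled ranks to the two
#' groups) when `min(nA, nB) <= 12` and the number of assignments is at
#' most 2e5; otherwise the normal approximation with tie correction and
#' continuity correction is used. The exact two-sided p is the null
#' probability of a U at least as far from its expectation as observed.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @return A list with `U` (the smaller of the two group statistics),
#'   `p` (two-sided) and `method` (`"exact"` or `"normal"`).
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mannWhitneyU <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty")
  n <- na + nb
  r <- rank(c(a, b))                      # mid-ranks
  ra <- sum(r[seq_len(na)])
  ua <- na * nb + na * (na + 1) / 2 - ra
  ub <- na * nb - ua
  u <- min(ua, ub)
  e <- na * nb / 2
  if (min(na, nb) <= 12 && choose(n, na) <= 2e5) {
    cmb <- utils::combn(n, na)
    rsums <- colSums(matrix(r[cmb], nrow = na))
    uall <- na * nb + na * (na + 1) / 2 - rsums
    p <- mean(abs(uall - e) >= abs(ua - e) - 1e-9)
    list(U = u, p = p, method = "exact")
  } else {
    ties <- table(r)
    s2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(ua - e) - 0.5) / sqrt(s2)
    list(U = u, p = min(1, 2 * stats::pnorm(-max(z, 0))), method = "normal")
  }
}

#' Wilcoxon signed-rank test
#'
#' Two-sided test on paired differences. Zero differences are dropped;
#' absolute values are mid-ranked. For up to 25 non-zero differences the
#' null distribution of the positive-rank sum is enumerated exactly over
#' all 2^n sign patterns (via a generating-function convolution on
#' doubled ranks, exact for ties); beyond that the normal approximation
#' with tie correction is used.
#'
#' @param diffs Numeric vector of paired differences.
#' @return A list with `W` (the smaller signed-rank sum), `p`
#'   (two-sided), `n` (non-zero differences) and `method`.
#' @examples
#' wilcoxonSignedRank(c(1, 2, 3))  # W = 0, p = 0.25
#' @export
wilcoxonSignedRank <- function(diffs) {
  d <- diffs[is.finite(diffs) & diffs != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  r <- rank(abs(d))
  wpos <- sum(r[d > 0])
  wneg <- sum(r[d < 0])
  w <- min(wpos, wneg)
  e <- n * (n + 1) / 4
  if (n <= 25) {
    r2 <- as.integer(round(2 * r))        # doubled mid-ranks are integers
    # counts[k+1] = number of sign patterns with doubled rank sum k
    counts <- numeric(sum(r2) + 1)
    counts[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
      counts <- counts + shifted
    }
    wall <- (seq_along(counts) - 1) / 2   # back to original scale
    p <- sum(counts[abs(wall - e) >= abs(wpos - e) - 1e-9]) / 2^n
    list(W = w, p = p, n = n, method = "exact")
  } else {
    ties <- table(r)
    s2 <- (n * (n + 1) * (2 * n + 1) - sum(ties^3 - ties) / 2) / 24
    z <- (abs(wpos - e) - 0.5) / sqrt(s2)
    list(W = w, p = min(1, 2 * stats::pnorm(-max(z, 0))), n = n,
         method = "normal")
  }
}

#' Levene test for equality of variances (two groups)
#'
#' Classic Levene statistic: a one-way F test on absolute deviations from
#' the group centers (mean by default; `center = "median"` gives the
#' Brown-Forsythe variant).
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @param center `"mean"` or `"median"`.
#' @return A list with `statistic` (F), `df` (numerator, denominator),
#'   `p` and `center`.
#' @export
leveneVarTest <- function(a, b, center = c("mean", "median")) {
  center <- match.arg(center)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  cf <- if (center == "mean") mean else stats::median
  z <- c(abs(a - cf(a)), abs(b - cf(b)))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  fit <- stats::aov(z ~ g)
  tab <- stats::anova(fit)
  list(statistic = tab[["F value"]][1],
       df = c(tab[["Df"]][1], tab[["Df"]][2]),
       p = tab[["Pr(>F)"]][1], center = center)
}
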