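## Exact nonparametric tests. Small samples get exact p-values by counting
## over the full permutation/sign distribution (a subset-sum DP equivalent to
## exhaustive enumeration, including under ties via mid-ranks); larger
## samples fall back to the usual normal approximations with tie and
## continuity corrections. The branch taken is always reported.

.mwu_exact_limit <- 2e5   # max C(nx+ny, nx) labelings for the exact branch
.wsr_exact_limit <- 20L   # max non-zero pairs for the exact sign branch

## Distribution of the x-group rank sum over all C(N, nx) labelings, exactly,
## with mid-ranks doubled so sums are integers even under ties.
## Returns counts indexed by doubled rank sum (offset by minimum possible).
.ranksum_distribution <- function(ranks2, nx) {
  N <- length(ranks2)
  maxsum <- sum(sort(ranks2, decreasing = TRUE)[seq_len(nx)])
  ## dp[k + 1, s + 1] = number of k-subsets with doubled-rank sum s
  dp <- matrix(0, nrow = nx + 1L, ncol = maxsum + 1L)
  dp[1L, 1L] <- 1
  for (r in ranks2) {
    kmax <- nx
    for (k in kmax:1L) {
      shifted <- c(rep(0, r), dp[k, seq_len(maxsum + 1L - r)])
      dp[k + 1L, ] <- dp[k + 1L, ] + shifted
    }
  }
  dp[nx + 1L, ]
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples.  When the number of group
#' labelings \code{choose(nx + ny, nx)} is at most \code{2e5} the p-value is
#' exact: the full labeling distribution of the rank sum is counted (ties
#' handled exactly through mid-ranks).  Otherwise the normal approximation
#' with tie and continuity corrections is used.  The two-sided p-value is
#' \code{min(1, 2 * one-sided)}.
#'
#' @param x,y numeric vectors, one per group.
#' @return A list of class \code{"nichemech_test"}: \code{test},
#'   \code{statistic} (U for the first sample), \code{p.value}, \code{n}
#'   (per-group sizes) and \code{method} (\code{"exact"} or
#'   \code{"normal-approximation"}).
#' @examples
#' mannWhitneyTwoTailed(c(1, 2), c(3, 4))$p.value  # exact 1/3
#' @export
mannWhitneyTwoTailed <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  rx <- sum(r[seq_len(nx)])
  U <- rx - nx * (nx + 1) / 2

  if (choose(N, nx) <= .mwu_exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    counts <- .ranksum_distribution(ranks2, nx)
    total <- sum(counts)
    s_obs <- as.integer(round(2 * rx))
    idx <- seq_along(counts) - 1L          # doubled rank sums
    p_le <- sum(counts[idx <= s_obs]) / total
    p_ge <- sum(counts[idx >= s_obs]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tie <- table(r)
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal-approximation"
  }
  structure(list(test = "Mann-Whitney U (two-tailed)", statistic = U,
                 p.value = p, n = c(nx = nx, ny = ny), method = method),
            class = "nichemech_test")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Sums the hypergeometric probabilities of every table with the observed
#' margins whose probability does not exceed that of the observed table
#' (within a relative tolerance of 1e-7 on the comparison) — the standard
#' probability-ordering definition of the two-sided exact test.
#'
#' @param a,b,c,d non-negative integer cell counts, row-wise:
#'   \code{rbind(c(a, b), c(c, d))}.
#' @return A list of class \code{"nichemech_test"} with the odds-ratio-free
#'   \code{statistic} (probability of the observed table), \code{p.value},
#'   \code{n} and \code{method = "exact"}.
#' @examples
#' fisherExactTwoSided(2, 0, 0, 2)$p.value  # 1/3
#' @export
fisherExactTwoSided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    stop("every margin of the 2x2 table must be positive")
  N <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  pmf <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  p <- min(1, sum(pmf[pmf <= p_obs * (1 + 1e-7)]))
  structure(list(test = "Fisher exact (two-sided)", statistic = p_obs,
                 p.value = p, n = c(n = N), method = "exact"),
            class = "nichemech_test")
}

#' Two-tailed Wilcoxon matched-pairs signed-rank test
#'
#' Differences of zero are dropped; with at most 20 non-zero pairs the exact
#' distribution of the positive-rank sum over all sign assignments is
#' counted (ties handled exactly through mid-ranks), otherwise the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y equal-length numeric vectors of paired observations.
#' @return A list of class \code{"nichemech_test"} with \code{statistic}
#'   (positive-rank sum W), \code{p.value}, \code{n} (non-zero pairs) and
#'   \code{method}.
#' @examples
#' wilcoxonSignedRankTwoTailed(6:10, c(1, 2, 3, 4, 5))$p.value  # 2/32
#' @export
wilcoxonSignedRankTwoTailed <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!length(x)) stop("samples must be non-empty")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(structure(list(test = "Wilcoxon signed-rank (two-tailed)",
                          statistic = 0, p.value = 1, n = c(n = 0L),
                          method = "exact"), class = "nichemech_test"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])

  if (n <= .wsr_exact_limit) {
    ranks2 <- as.integer(round(2 * r))
    maxsum <- sum(ranks2)
    ## counts over all 2^n sign assignments of the doubled positive-rank sum
    dp <- numeric(maxsum + 1L); dp[1L] <- 1
    for (rr in ranks2)
      dp <- dp + c(rep(0, rr), dp[seq_len(maxsum + 1L - rr)])
    total <- sum(dp)
    w_obs <- as.integer(round(2 * W))
    idx <- seq_along(dp) - 1L
    p_le <- sum(dp[idx <= w_obs]) / total
    p_ge <- sum(dp[idx >= w_obs]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  structure(list(test = "Wilcoxon signed-rank (two-tailed)", statistic = W,
                 p.value = p, n = c(n = n), method = method),
            class = "nichemech_test")
}

#' @export
print.nichemech_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.6g (%s; n = %s)\n", x$test,
              x$statistic, x$p.value, x$method,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Normalize values to the mean of a reference group, per experiment block
#'
#' Divides every value by the mean of the reference group's values, computed
#' separately within each experiment block — the convention used to express
#' per-cell fluorescence relative to the mean of a reference age group in
#' each independent experiment.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @param reference label of the reference group.
#' @param block optional experiment/block label per value; each block is
#'   normalized independently.  Default: one block.
#' @return numeric vector of normalized values (reference group mean = 1 in
#'   every block).
#' @examples
#' normalizeToReferenceMean(c(2, 4, 6), c("young", "young", "old"), "young")
#' @export
normalizeToReferenceMean <- function(values, groups, reference,
                                     block = NULL) {
  values <- as.numeric(values)
  if (length(groups) != length(values))
    stop("groups must match values in length")
  if (is.null(block)) block <- rep("all", length(values))
  if (length(block) != length(values))
    stop("block must match values in length")
  out <- values
  for (b in unique(block)) {
    in_b <- block == b
    ref <- values[in_b & groups == reference]
    if (!length(ref))
      stop(sprintf("reference group '%s' empty in block '%s'", reference, b))
    m <- mean(ref)
    if (!is.finite(m) || m == 0)
      stop(sprintf("reference mean in block '%s' is zero or non-finite", b))
    out[in_b] <- values[in_b] / m
  }
  out
}
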