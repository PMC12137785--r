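## CV-space reproducibility statistics and paired nonparametric testing.
##
## A CVTable holds CV_{v,s} (percent) for V subjects across S scan groups.
## The cluster statistics are: inertia ICV (dispersion around the per-group
## centroid), centroid norm |xbar| (overall CV magnitude), and the
## perpendicular distance d_perp from the centroid to the identity line
## (inter-session consistency).

#' Inertia of a CV cluster
#'
#' ICV = (1 / (V*S)) * sum_v sum_s (CV_{v,s} - xbar_s)^2 with xbar_s the
#' per-scan-group mean. Reported on the squared-percent scale exactly as
#' defined; the square root is available via [clusterSummary()].
#'
#' @param table A [CVTable-class].
#' @return numeric, squared-percent scale.
#' @examples
#' cvInertia(cvTable(rbind(c(10, 20), c(20, 30))))  # 25
#' @export
cvInertia <- function(table) {
  v <- table@values
  if (length(v) == 0L) stop("CV table is empty")
  ctr <- colMeans(v)
  mean(sweep(v, 2, ctr, "-")^2)
}

#' Norm of the CV-cluster centroid
#'
#' |xbar| = sqrt(sum_s xbar_s^2): distance of the centroid from the origin
#' of the CV space.
#'
#' @param table A [CVTable-class].
#' @return numeric, percent.
#' @export
centroidNorm <- function(table) {
  v <- table@values
  if (length(v) == 0L) stop("CV table is empty")
  sqrt(sum(colMeans(v)^2))
}

#' Perpendicular distance from the centroid to the identity line
#'
#' d_perp = sqrt(sum_s (m - xbar_s)^2) with m the mean of the centroid
#' components; equals the Euclidean distance from the centroid to the
#' identity line in S-space, and is 0 iff all centroid components are equal.
#'
#' @param table A [CVTable-class].
#' @return numeric, percent.
#' @export
perpDistance <- function(table) {
  v <- table@values
  if (length(v) == 0L) stop("CV table is empty")
  ctr <- colMeans(v)
  m <- mean(ctr)
  sqrt(sum((m - ctr)^2))
}

#' Summarize a CV cluster
#'
#' @param table A [CVTable-class].
#' @return A [ClusterSummary-class]: centroid, inertia (and its square
#'   root), centroid norm, perpendicular distance, and the componentwise
#'   median point (for plotting parity with per-subject CV scatter).
#' @export
clusterSummary <- function(table) {
  icv <- cvInertia(table)
  new("ClusterSummary", method = table@method,
      centroid = colMeans(table@values), icv = icv, icvRoot = sqrt(icv),
      centroidNorm = centroidNorm(table),
      perpDistance = perpDistance(table),
      medianPoint = apply(table@values, 2, median))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided p-value from the signed-rank statistic of the paired
#' differences. Zero differences are dropped (Wilcoxon's rule). For n <= 12
#' remaining pairs the exact null distribution is used (all 2^n sign
#' assignments, valid under ties via average ranks); otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric vectors of equal length, paired by subject.
#' @param exactMax integer, largest n for which the exact null is
#'   enumerated.
#' @return numeric p-value in (0, 1], with attributes `statistic` (W, the
#'   sum of ranks of positive differences) and `exact`.
#' @examples
#' pairedRankTest(c(2, 4, 6, 8, 10, 12), c(1, 2, 3, 4, 5, 6))  # 0.03125
#' @export
pairedRankTest <- function(x, y, exactMax = 12L) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; p = 1")
    return(structure(1, statistic = NA_real_, exact = TRUE))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exactMax) {
    Wall <- .signedRankNull(r)
    eps <- 1e-9
    p <- 2 * min(mean(Wall <= W + eps), mean(Wall >= W - eps))
    p <- min(1, p)
    return(structure(p, statistic = W, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
  p <- min(1, 2 * pnorm(-abs(z)))
  structure(p, statistic = W, exact = FALSE)
}

## all 2^n values of the signed-rank statistic for rank vector r
.signedRankNull <- function(r) {
  n <- length(r)
  masks <- seq_len(2^n) - 1L
  vapply(masks, function(m)
    sum(r[bitwAnd(bitwShiftR(m, seq_len(n) - 1L), 1L) == 1L]), numeric(1))
}

#' Bonferroni significance flags
#'
#' Flags a comparison "S" iff p < alpha / m, with m the number of
#' comparisons in the family.
#'
#' @param pvals numeric p-values (one family).
#' @param alpha family-wise level.
#' @param m family size; defaults to `length(pvals)`.
#' @return character vector of "S"/"NS" with attributes `threshold` and `m`.
#' @export
bonferroniFlags <- function(pvals, alpha = 0.05, m = length(pvals)) {
  if (length(pvals) == 0L) stop("no p-values supplied")
  thr <- alpha / m
  structure(ifelse(pvals < thr, "S", "NS"), threshold = thr, m = m)
}

#' Pairwise signed-rank tests between methods
#'
#' For every pair of CV tables (one per excitation method, identical
#' subject/scan layout), performs the paired signed-rank test on the
#' flattened (subject, scan group) CV values and applies the Bonferroni
#' correction with family size equal to the number of pairs.
#'
#' @param tables named list of [CVTable-class] objects with identical
#'   dimensions.
#' @param alpha family-wise level.
#' @return data.frame: methodA, methodB, statistic, p, flag, m.
#' @export
pairwiseRankTests <- function(tables, alpha = 0.05) {
  stopifnot(length(tables) >= 2L)
  nm <- names(tables)
  if (is.null(nm)) nm <- vapply(tables, function(t) t@method, character(1))
  pairs <- utils::combn(length(tables), 2)
  res <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    p <- suppressWarnings(
      pairedRankTest(as.vector(tables[[a]]@values),
                     as.vector(tables[[b]]@values)))
    data.frame(methodA = nm[a], methodB = nm[b],
               statistic = as.numeric(attr(p, "statistic")),
               p = as.numeric(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  fl <- bonferroniFlags(out$p, alpha = alpha, m = nrow(out))
  out$flag <- as.character(fl)
  out$m <- nrow(out)
  out
}
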