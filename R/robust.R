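#' Trimmed mean
#'
#' Mean after removing the \code{floor(gamma * n)} smallest and largest
#' observations (the base-R trimming convention).
#'
#' @param x numeric vector.
#' @param gamma trim fraction per side, in [0, 0.5).
#' @return numeric scalar.
#' @export
trimmedMean <- function(x, gamma = 0.2) {
  stopifnot(gamma >= 0, gamma < 0.5)
  n <- length(x)
  if (n <= 2 * floor(gamma * n))
    stop("trimming removes every observation")
  mean(x, trim = gamma)
}

# Yuen-style ingredients for a trimmed-mean comparison: trimmed mean and
# the winsorized-variance squared standard error d = (n-1) s_w^2 / (h (h-1))
# with h = n - 2 g effective observations.
.yuenParts <- function(x, gamma) {
  n <- length(x)
  g <- floor(gamma * n)
  h <- n - 2L * g
  xs <- sort(x)
  tm <- mean(xs[(g + 1L):(n - g)])
  w <- xs
  if (g > 0) {
    w[seq_len(g)] <- xs[g + 1L]
    w[(n - g + 1L):n] <- xs[n - g]
  }
  swsq <- sum((w - mean(w))^2) / (n - 1L)
  list(tm = tm, d = (n - 1L) * swsq / (h * (h - 1L)), h = h)
}

# Vectorised Yuen parts over the columns of a matrix (each column one
# bootstrap resample). Returns tm and d vectors.
.yuenPartsMat <- function(m, gamma) {
  n <- nrow(m)
  g <- floor(gamma * n)
  h <- n - 2L * g
  ms <- apply(m, 2L, sort, method = "radix")
  tm <- colMeans(ms[(g + 1L):(n - g), , drop = FALSE])
  if (g > 0) {
    ms[seq_len(g), ] <- rep(ms[g + 1L, ], each = g)
    ms[(n - g + 1L):n, ] <- rep(ms[n - g, ], each = g)
  }
  wbar <- colMeans(ms)
  swsq <- (colSums(ms^2) - n * wbar^2) / (n - 1L)
  list(tm = tm, d = (n - 1L) * swsq / (h * (h - 1L)))
}

#' Percentile-t bootstrap test for equality of trimmed means
#'
#' Two-sample test of H0: the gamma-trimmed means of two groups are equal.
#' The observed statistic is the Yuen-studentized trimmed-mean difference.
#' Each group is centred at its own trimmed mean, resampled with
#' replacement within groups, and the studentized statistic recomputed;
#' the two-sided p-value locates the observed statistic in this bootstrap
#' distribution by symmetric tail counting, p = 2 min(tails), capped at 1.
#' Bootstrapping the studentized statistic (rather than the raw estimator)
#' gives second-order accuracy without a normality assumption.
#'
#' @param a,b numeric vectors (the two groups).
#' @param B number of bootstrap resamples (default 2000).
#' @param gamma trim fraction per side (default 0.2; 0 gives the ordinary
#'   bootstrap-t mean comparison).
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @return list with \code{p.value}, \code{statistic} (observed
#'   studentized difference), \code{estimate} (trimmed-mean difference
#'   a - b), \code{B}, \code{gamma}, \code{seed}.
#' @export
percentileTBootstrap <- function(a, b, B = 2000L, gamma = 0.2, seed = 1L) {
  stopifnot(B >= 1L)
  pa <- .yuenParts(a, gamma)
  pb <- .yuenParts(b, gamma)
  diff <- pa$tm - pb$tm
  se <- sqrt(pa$d + pb$d)
  if (se == 0) {
    if (diff == 0)
      return(list(p.value = 1, statistic = 0, estimate = 0, B = B,
                  gamma = gamma, seed = seed))
    stop("degenerate input: zero standard error with nonzero difference")
  }
  tObs <- diff / se
  ac <- a - pa$tm
  bc <- b - pb$tm
  tBoot <- .withSeed(seed, {
    am <- matrix(ac[sample.int(length(a), length(a) * B, replace = TRUE)],
                 nrow = length(a))
    bm <- matrix(bc[sample.int(length(b), length(b) * B, replace = TRUE)],
                 nrow = length(b))
    ya <- .yuenPartsMat(am, gamma)
    yb <- .yuenPartsMat(bm, gamma)
    seB <- sqrt(ya$d + yb$d)
    tb <- (ya$tm - yb$tm) / seB
    tb[seB == 0] <- 0
    tb
  })
  pLo <- mean(tBoot <= tObs)
  pHi <- mean(tBoot >= tObs)
  list(p.value = min(1, 2 * min(pLo, pHi)),
       statistic = tObs, estimate = diff, B = B, gamma = gamma, seed = seed)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-controlling adjustment; monotone, capped at 1, returned in
#' the input order.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return numeric vector of adjusted p-values.
#' @export
bhAdjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value sums the probabilities
#' of all tables no more likely than the observed one.
#'
#' @param tab 2x2 matrix, or c(a, b, c, d) filled by row.
#' @return the p-value.
#' @export
fisherExact2x2 <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  stopifnot(all(tab >= 0), sum(tab) > 0)
  stats::fisher.test(tab)$p.value
}

#' Region-wise robust two-group comparison sweep
#'
#' For every region, tests whether the trimmed means of the two probe
#' groups' region-mean energies differ (percentile-t bootstrap), adjusts
#' across regions by Benjamini-Hochberg, and flags regions with adjusted
#' p below \code{alpha}. Regions with fewer than 3 probes in either group
#' are skipped with a warning.
#'
#' @param groupA,groupB numeric matrices of per-probe region means
#'   (probes x regions, identical region columns).
#' @param alpha adjusted-p significance cutoff (default 0.25).
#' @param B bootstrap resamples per region (default 2000).
#' @param gamma trim fraction (default 0.2).
#' @param seed integer seed; each region uses an offset sub-seed.
#' @return data.frame with one row per region: region, nA, nB, statistic,
#'   estimate, p, pAdj, significant, direction ("A>B"/"B>A").
#' @export
regionSweep <- function(groupA, groupB, alpha = 0.25, B = 2000L,
                        gamma = 0.2, seed = 1L) {
  stopifnot(ncol(groupA) == ncol(groupB))
  regions <- colnames(groupA)
  if (is.null(regions)) regions <- as.character(seq_len(ncol(groupA)))
  rows <- lapply(seq_len(ncol(groupA)), function(j) {
    xa <- groupA[, j]; xb <- groupB[, j]
    if (length(xa) < 3L || length(xb) < 3L) {
      warning("region ", regions[j], " skipped: fewer than 3 probes")
      return(NULL)
    }
    bt <- percentileTBootstrap(xa, xb, B = B, gamma = gamma,
                               seed = seed + j)
    data.frame(region = regions[j], nA = length(xa), nB = length(xb),
               statistic = bt$statistic, estimate = bt$estimate,
               p = bt$p.value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no region had enough probes")
  res$pAdj <- bhAdjust(res$p)
  res$significant <- res$pAdj < alpha
  res$direction <- ifelse(res$estimate > 0, "A>B",
                          ifelse(res$estimate < 0, "B>A", "none"))
  res
}

#' Fisher category enrichment
#'
#' Tests whether membership in a category (e.g. a curated protein list) is
#' associated with a binary probe property (e.g. having a structured UTR).
#'
#' @param inCategory,property logical vectors of equal length.
#' @return list with the 2x2 \code{table} and the Fisher \code{p.value}.
#' @export
categoryEnrichment <- function(inCategory, property) {
  stopifnot(length(inCategory) == length(property))
  tab <- matrix(c(sum(inCategory & property), sum(inCategory & !property),
                  sum(!inCategory & property), sum(!inCategory & !property)),
                2, 2, byrow = TRUE)
  list(table = tab, p.value = fisherExact2x2(tab))
}
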