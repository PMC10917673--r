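## Generic 1D/2D cluster-based permutation engine. Used for ripple-locked
## firing/power contrasts, object-cell tuning windows, ripple-rate PSTHs
## and the coactivity-map group tests.

## bin-wise t statistics from precomputed sums; returns list(t, n) where n
## is the per-bin observation count (first group count for two-sample).
binwiseT <- function(sums, sumsqs, ns, sums2 = NULL, sumsqs2 = NULL,
                     ns2 = NULL) {
  if (is.null(sums2)) {
    m <- sums / ns
    v <- (sumsqs - ns * m^2) / (ns - 1)
    t <- m / sqrt(v / ns)
    t[!is.finite(t) | v <= 0] <- NA_real_
    list(t = t, df = ns - 1)
  } else {
    m1 <- sums / ns; m2 <- sums2 / ns2
    vp <- (sumsqs - ns * m1^2 + sumsqs2 - ns2 * m2^2) / (ns + ns2 - 2)
    t <- (m1 - m2) / sqrt(vp * (1 / ns + 1 / ns2))
    t[!is.finite(t) | vp <= 0] <- NA_real_
    list(t = t, df = ns + ns2 - 2)
  }
}

## critical t values with caching over the (few) unique df values
critT <- function(df, alpha) {
  out <- rep(NA_real_, length(df))
  ok <- is.finite(df) & df >= 1
  if (any(ok)) {
    u <- unique(df[ok])
    cv <- qt(1 - alpha, u)
    out[ok] <- cv[match(df[ok], u)]
  }
  out
}

## cluster sums for one t map; returns list(labels, sums) for positive
## clusters (and negative if twoSided)
clusterSums <- function(tvec, tcrit, dims, connectivity, negative = FALSE) {
  mask <- if (negative) (!is.na(tvec)) & (tvec < -tcrit) else
    (!is.na(tvec)) & (tvec > tcrit)
  if (!any(mask)) return(list(labels = integer(length(tvec)),
                              sums = numeric(0)))
  if (is.null(dims)) {
    lab <- labelComponents(mask)
  } else {
    lab <- as.integer(labelComponents(matrix(mask, dims[1L], dims[2L]),
                                      connectivity))
  }
  sums <- as.numeric(rowsum(tvec[lab > 0L], lab[lab > 0L]))
  list(labels = lab, sums = sums)
}

#' Cluster-based permutation test (1D or 2D)
#'
#' Bin-wise t-tests (one-sample against zero, or pooled-variance
#' two-sample) are thresholded at the first-level alpha; contiguous
#' suprathreshold bins form clusters whose summed t value is compared to
#' the distribution of maximum cluster statistics obtained from surrogate
#' data. Surrogates invert the sign of a random subset of observations
#' ("sign_flip", one-sample), swap a random subset of paired observations
#' between the two sets ("set_swap"), or randomly reassign observations to
#' the two sets ("label_reassign"). One-sided tests use a first-level
#' alpha of 0.05 and the 95th percentile of surrogate maxima; two-sided
#' tests use 0.025 at both levels and additionally compare negative
#' clusters to the 2.5th percentile of surrogate minima. Missing values
#' are allowed; bins with fewer than \code{minValid} valid observations
#' (per set) are excluded from cluster formation.
#'
#' @param x observations x bins matrix (set A). For 2D data pass the
#'   flattened matrix plus \code{dims = c(nrow, ncol)}, or a 3D array
#'   observations x d1 x d2.
#' @param y optional set B matrix for two-sample tests.
#' @param test "one_sample" or "two_sample".
#' @param alternative "greater" (one-sided positive) or "two_sided".
#' @param scheme surrogate scheme; defaults to "sign_flip" for one-sample
#'   and "label_reassign" for two-sample tests.
#' @param nSurrogates number of surrogate iterations (default 1001).
#' @param firstLevelAlpha bin-level alpha; default 0.05 one-sided, 0.025
#'   two-sided.
#' @param connectivity 4 or 8 (2D data).
#' @param dims c(d1, d2) when bins form a 2D grid.
#' @param minValid minimum valid observations per bin (default 5).
#' @param seed integer seed for the surrogate draws.
#' @return list with clusters (data.frame: id, sign, nBins, sumT, p,
#'   pPlusOne, significant), labels (integer per bin, positive clusters),
#'   t (bin-wise t), surrogateMax (and surrogateMin for two-sided),
#'   threshold(s).
#' @export
clusterTest <- function(x, y = NULL, test = c("one_sample", "two_sample"),
                        alternative = c("greater", "two_sided"),
                        scheme = NULL, nSurrogates = 1001L,
                        firstLevelAlpha = NULL, connectivity = 4,
                        dims = NULL, minValid = 5L, seed = NULL) {
  test <- match.arg(test)
  alternative <- match.arg(alternative)
  if (length(dim(x)) == 3L) {
    dims <- dim(x)[2:3]
    x <- matrix(x, nrow = dim(x)[1L])
  }
  if (!is.null(y) && length(dim(y)) == 3L) y <- matrix(y, nrow = dim(y)[1L])
  if (is.null(scheme))
    scheme <- if (test == "one_sample") "sign_flip" else "label_reassign"
  stopifnot(scheme %in% c("sign_flip", "set_swap", "label_reassign"))
  if (is.null(firstLevelAlpha))
    firstLevelAlpha <- if (alternative == "two_sided") 0.025 else 0.05
  twoSided <- alternative == "two_sided"
  if (!is.null(seed)) set.seed(seed)
  if (nrow(x) < 5L) stop("need at least 5 observations")

  B <- ncol(x)
  Vx <- !is.na(x); X0 <- ifelse(Vx, x, 0); X2 <- X0^2
  nsX <- colSums(Vx)
  if (test == "one_sample") {
    computeT <- function(signs) {
      s <- as.numeric(crossprod(signs, X0))
      tt <- binwiseT(s, colSums(X2), nsX)
      tt$t[nsX < minValid] <- NA_real_
      tt
    }
    tEmp <- computeT(rep(1, nrow(x)))
    drawSurrogate <- function()
      computeT(sample(c(-1, 1), nrow(x), replace = TRUE))
  } else {
    stopifnot(!is.null(y), nrow(y) >= 5L, ncol(y) == B)
    Z <- rbind(x, y)
    Vz <- !is.na(Z); Z0 <- ifelse(Vz, Z, 0); Z2 <- Z0^2
    nTot <- nrow(Z); nA <- nrow(x)
    computeT <- function(inA) {
      G <- cbind(as.numeric(inA), as.numeric(!inA))
      S <- crossprod(G, Z0); SQ <- crossprod(G, Z2); N <- crossprod(G, Vz)
      tt <- binwiseT(S[1L, ], SQ[1L, ], N[1L, ], S[2L, ], SQ[2L, ],
                     N[2L, ])
      tt$t[N[1L, ] < minValid | N[2L, ] < minValid] <- NA_real_
      tt
    }
    inA0 <- c(rep(TRUE, nA), rep(FALSE, nTot - nA))
    tEmp <- computeT(inA0)
    drawSurrogate <- if (scheme == "set_swap") {
      if (nA != nTot - nA)
        stop("set_swap requires paired sets of equal size")
      function() {
        sw <- runif(nA) < 0.5
        computeT(c(!sw, sw))
      }
    } else function() computeT(sample(inA0))
  }

  tcritEmp <- critT(tEmp$df, firstLevelAlpha)
  empPos <- clusterSums(tEmp$t, tcritEmp, dims, connectivity)
  empNeg <- if (twoSided)
    clusterSums(tEmp$t, tcritEmp, dims, connectivity, negative = TRUE)
  else list(labels = integer(B), sums = numeric(0))

  surMax <- surMin <- numeric(nSurrogates)
  for (i in seq_len(nSurrogates)) {
    tt <- drawSurrogate()
    tc <- critT(tt$df, firstLevelAlpha)
    sp <- clusterSums(tt$t, tc, dims, connectivity)
    surMax[i] <- if (length(sp$sums)) max(sp$sums) else 0
    if (twoSided) {
      sn <- clusterSums(tt$t, tc, dims, connectivity, negative = TRUE)
      surMin[i] <- if (length(sn$sums)) min(sn$sums) else 0
    }
  }

  thrPos <- quantile(surMax, if (twoSided) 0.975 else 0.95, names = FALSE)
  rows <- list()
  addRows <- function(sums, labels, sign) {
    for (k in seq_along(sums)) {
      s <- sums[k]
      if (sign > 0) {
        p <- mean(surMax >= s)
        pp <- (1 + sum(surMax >= s)) / (1 + nSurrogates)
        sig <- s > thrPos
      } else {
        p <- mean(surMin <= s)
        pp <- (1 + sum(surMin <= s)) / (1 + nSurrogates)
        sig <- s < quantile(surMin, 0.025, names = FALSE)
      }
      rows[[length(rows) + 1L]] <<- data.frame(
        id = k, sign = sign, nBins = sum(labels == k), sumT = s, p = p,
        pPlusOne = pp, significant = sig)
    }
  }
  addRows(empPos$sums, empPos$labels, 1L)
  if (twoSided) addRows(empNeg$sums, empNeg$labels, -1L)
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), sign = integer(0), nBins = integer(0),
               sumT = numeric(0), p = numeric(0), pPlusOne = numeric(0),
               significant = logical(0))
  res <- list(clusters = clusters, labels = empPos$labels,
              negLabels = if (twoSided) empNeg$labels else NULL,
              t = tEmp$t, dims = dims, surrogateMax = surMax,
              surrogateMin = if (twoSided) surMin else NULL,
              threshold = thrPos)
  class(res) <- "clusterResult"
  res
}

#' @export
print.clusterResult <- function(x, ...) {
  cat("Cluster-based permutation test:",
      nrow(x$clusters), "cluster(s);",
      sum(x$clusters$significant), "significant\n")
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Rayleigh test for circular non-uniformity
#'
#' Tests whether phases cluster around a common direction. The statistic
#' is \eqn{z = n \bar{R}^2} with \eqn{\bar{R}} the mean resultant length;
#' the p value uses the standard series approximation
#' \eqn{p = \exp(\sqrt{1 + 4n + 4(n^2 - R^2)} - (1 + 2n))} with
#' \eqn{R = n \bar{R}}.
#'
#' @param phases angles in radians.
#' @return list with n, meanDirection (radians), rBar, z, p.
#' @export
rayleighTest <- function(phases) {
  phases <- phases[is.finite(phases)]
  n <- length(phases)
  stopifnot(n >= 3L)
  rBar <- circR(phases)
  R <- n * rBar
  z <- n * rBar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  list(n = n, meanDirection = circMean(phases), rBar = rBar, z = z,
       p = min(1, p))
}

#' Two-sample Kuiper test on circular data
#'
#' Rotation-invariant two-sample comparison of circular distributions. The
#' raw statistic is \eqn{V = D^+ + D^-}, the sum of the maximal positive
#' and negative deviations between the two empirical CDFs; \code{k}
#' rescales it by \eqn{n_1 n_2} for compatibility with common circular
#' statistics toolboxes. The p value uses the asymptotic Kuiper series
#' with the effective sample size \eqn{n_e = n_1 n_2 / (n_1 + n_2)}.
#'
#' @param a,b angles in radians.
#' @return list with V, k, p, n1, n2.
#' @export
kuiperTwoSample <- function(a, b) {
  a <- sort(a %% (2 * pi)); b <- sort(b %% (2 * pi))
  n1 <- length(a); n2 <- length(b)
  stopifnot(n1 >= 3L, n2 >= 3L)
  pts <- sort(unique(c(a, b)))
  Fa <- findInterval(pts, a) / n1
  Fb <- findInterval(pts, b) / n2
  d <- Fa - Fb
  V <- max(d) - min(d)
  ne <- n1 * n2 / (n1 + n2)
  lam <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * V
  ## the asymptotic series is only valid for lam away from zero
  p <- if (lam < 0.4) 1 else {
    j <- 1:50
    2 * sum((4 * j^2 * lam^2 - 1) * exp(-2 * j^2 * lam^2))
  }
  list(V = V, k = n1 * n2 * V, p = min(1, max(0, p)), n1 = n1, n2 = n2)
}
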