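## Low-level signal helpers shared across modules. FFT-based convolution is
## used throughout so that long FIR kernels (delta-band filtering, Morlet
## wavelets) stay affordable on multi-minute 2 kHz recordings.

nextFastLen <- function(n) stats::nextn(n, c(2L, 3L, 5L))

## Linear convolution of x with kernel h, returning the "same" segment
## aligned on the kernel centre (h is assumed odd-length, centre at
## (length(h)+1)/2). Complex h supported.
fftConvSame <- function(x, h) {
  n <- length(x); m <- length(h)
  L <- nextFastLen(n + m - 1L)
  X <- fft(c(x, rep(0, L - n)))
  H <- fft(c(h, rep(0, L - m)))
  y <- fft(X * H, inverse = TRUE) / L
  if (!is.complex(x) && !is.complex(h)) y <- Re(y)
  half <- (m - 1L) %/% 2L
  y[(half + 1L):(half + n)]
}

## Analytic signal via the FFT (Marple); x must be free of NA.
hilbertAnalytic <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

## Zero-phase (forward-backward) IIR filtering with reflect padding to
## suppress transients at the session edges.
filtfiltPad <- function(filt, x, fs, padS = 1) {
  np <- min(length(x) - 1L, round(padS * fs))
  if (np > 0) {
    pre <- 2 * x[1L] - x[(np + 1L):2L]
    post <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - np)]
    y <- signal::filtfilt(filt, c(pre, x, post))
    y[(np + 1L):(np + length(x))]
  } else signal::filtfilt(filt, x)
}

## Two-pass FIR band-pass via FFT convolution (kernel from signal::fir1).
## The kernel is symmetric, so each pass is already zero-phase; two passes
## square the magnitude response as in forward-backward filtering.
firBandpass <- function(x, fs, low, high, order = 8000) {
  order <- min(order, 2L * (length(x) %/% 2L) - 2L)
  h <- signal::fir1(order, c(low, high) / (fs / 2), type = "pass")
  np <- min(length(x) - 1L, order %/% 2L)
  pre <- 2 * x[1L] - x[(np + 1L):2L]
  post <- 2 * x[length(x)] - x[(length(x) - 1L):(length(x) - np)]
  xp <- c(pre, x, post)
  y <- fftConvSame(fftConvSame(xp, h), h)
  y[(np + 1L):(np + length(x))]
}

## Centered moving average with window shrinking at the edges.
movingAverage <- function(x, k) {
  if (k <= 1L) return(x)
  n <- length(x)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + (k - 1L - half), n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Gaussian kernel with total support lengthS seconds and sd = lengthS / 5
## (the conventional reading of a "kernel length"; documented constant).
gaussKernel <- function(lengthS, fs, sigmaS = lengthS / 5) {
  half <- max(1L, round(lengthS * fs / 2))
  t <- (-half:half) / fs
  k <- exp(-t^2 / (2 * sigmaS^2))
  k / sum(k)
}

## NA-aware Gaussian smoothing (normalised convolution); NA runs remain NA.
smoothGaussian <- function(x, lengthS, fs) {
  k <- gaussKernel(lengthS, fs)
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  num <- fftConvSame(x0, k)
  den <- fftConvSame(as.numeric(ok), k)
  y <- num / den
  y[!ok] <- NA_real_
  y
}

## Morlet wavelet power (nCycles cycles) for a set of frequencies.
## Returns a freq x time matrix; samples whose wavelet support extends past
## the recording edge are NA (invalid, never zero-filled).
morletPower <- function(x, fs, freqs, nCycles = 7) {
  n <- length(x)
  L <- nextFastLen(2L * n)
  X <- fft(c(x, rep(0, L - n)))
  out <- matrix(NA_real_, length(freqs), n)
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sigmaT <- nCycles / (2 * pi * f)
    half <- min(n - 1L, ceiling(3 * sigmaT * fs))
    t <- (-half:half) / fs
    w <- exp(-t^2 / (2 * sigmaT^2)) * exp(2i * pi * f * t)
    w <- w / sum(abs(w))
    m <- length(w)
    W <- fft(c(w, rep(0+0i, L - m)))
    y <- fft(X * W, inverse = TRUE) / L
    coefs <- y[(half + 1L):(half + n)]
    p <- Mod(coefs)^2
    edge <- half
    if (edge > 0) p[c(seq_len(min(edge, n)),
                      seq.int(max(1L, n - edge + 1L), n))] <- NA_real_
    out[i, ] <- p
  }
  out
}

## TRUE-run extraction: data.frame(start, end) of maximal runs (indices).
runsFromLogical <- function(flags) {
  flags[is.na(flags)] <- FALSE
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

## Connected-component labelling. For a logical vector (1D) uses run-length
## encoding; for a logical matrix a two-pass union-find over the TRUE cells
## with 4- or 8-connectivity. Returns integer labels (0 = background).
labelComponents <- function(mask, connectivity = 4) {
  mask[is.na(mask)] <- FALSE
  if (is.null(dim(mask))) {
    lab <- integer(length(mask))
    runs <- runsFromLogical(mask)
    if (nrow(runs)) for (i in seq_len(nrow(runs)))
      lab[runs$start[i]:runs$end[i]] <- i
    return(lab)
  }
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, nr, nc)
  if (!length(idx)) return(lab)
  k <- length(idx)
  pos <- integer(nr * nc)
  pos[idx] <- seq_len(k)
  parent <- seq_len(k)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  offs <- list(c(-1L, 0L), c(0L, -1L))
  if (connectivity == 8) offs <- c(offs, list(c(-1L, -1L), c(1L, -1L)))
  for (i in seq_len(k)) {
    for (o in offs) {
      rr <- r[i] + o[1L]; ccn <- cc[i] + o[2L]
      if (rr < 1L || rr > nr || ccn < 1L || ccn > nc) next
      j <- pos[rr + (ccn - 1L) * nr]
      if (j > 0L) {
        ri <- findRoot(i); rj <- findRoot(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(k), findRoot, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

## Circular statistics on radians.
circMean <- function(phases) Arg(sum(exp(1i * phases)))
circR <- function(phases) Mod(mean(exp(1i * phases)))

## z-score a vector over its valid samples.
zscoreVec <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(x * NA_real_)
  (x - m) / s
}

## Partial Pearson correlation of x and y controlling for the columns of Z.
partialCor <- function(x, y, Z) {
  Z <- as.matrix(Z)
  ok <- complete.cases(x, y, Z)
  if (sum(ok) < 4L) return(NA_real_)
  x <- x[ok]; y <- y[ok]; Z <- Z[ok, , drop = FALSE]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  M <- cbind(1, Z)
  rx <- residuals(stats::lm.fit(M, x))
  ry <- residuals(stats::lm.fit(M, y))
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

## Pooled-variance (equal-variance) two-sample t statistic, oriented as
## mean(x) - mean(y).
pooledT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) return(NA_real_)
  vp <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (vp == 0) return(NA_real_)
  (mean(x) - mean(y)) / sqrt(vp * (1 / nx + 1 / ny))
}
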