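# Internal numerical helpers: quadrature, FFT convolution, interpolation,
# seeded RNG scopes. Nothing here is exported.

#' @importFrom stats fft approx runmed nextn rnorm rpois runif median var sd quantile dist coef
#' @importFrom methods new validObject is slot
NULL

# Simpson weights on n+1 equispaced nodes (n even), integrating step h.
simpsonWeights <- function(n, h) {
  if (n %% 2L != 0L) stop("Simpson rule needs an even number of intervals")
  w <- rep(c(2, 4), length.out = n - 1)
  h / 3 * c(1, w, 1)
}

# 2-D linear convolution via FFT, "same" output, explicit kernel origin.
# out[i,j] = sum_{m,n} ker[m,n] * img[i - (m - cy), j - (n - cx)]
# center = c(cy, cx) is the kernel sample treated as the origin.
fftConv2Same <- function(img, ker, center = (dim(ker) + 1) / 2) {
  ni <- dim(img); nk <- dim(ker)
  np <- ni + nk - 1L
  # pad to fast FFT sizes
  nf <- c(nextn(np[1], c(2, 3, 5)), nextn(np[2], c(2, 3, 5)))
  A <- matrix(0, nf[1], nf[2]); A[seq_len(ni[1]), seq_len(ni[2])] <- img
  B <- matrix(0, nf[1], nf[2]); B[seq_len(nk[1]), seq_len(nk[2])] <- ker
  full <- Re(fft(fft(A) * fft(B), inverse = TRUE)) / prod(nf)
  full[center[1] + seq_len(ni[1]) - 1L, center[2] + seq_len(ni[2]) - 1L, drop = FALSE]
}

# Correlation (matched filtering) with the same geometry as fftConv2Same:
# out[i,j] = sum_{m,n} ker[m,n] * img[i + (m - cy), j + (n - cx)]
fftCorr2Same <- function(img, ker, center = (dim(ker) + 1) / 2) {
  nk <- dim(ker)
  kerF <- ker[nk[1]:1, nk[2]:1, drop = FALSE]
  fftConv2Same(img, kerF, center = nk - center + 1)
}

# Subpixel shift of a 2-D array by (dy, dx) samples via Fourier phase ramp.
# Periodic wrap-around; callers must ensure content is compactly supported.
fourierShift2 <- function(x, dy, dx) {
  n <- dim(x)
  ky <- c(0:floor(n[1] / 2), -(ceiling(n[1] / 2) - 1):-1)[seq_len(n[1])] / n[1]
  kx <- c(0:floor(n[2] / 2), -(ceiling(n[2] / 2) - 1):-1)[seq_len(n[2])] / n[2]
  ph <- outer(exp(-2i * pi * ky * dy), exp(-2i * pi * kx * dx))
  Re(fft(fft(x) * ph, inverse = TRUE)) / prod(n)
}

# Phase-correlation displacement of b relative to a (b ~ shift(a, dy, dx)),
# with 3-point parabolic sub-sample refinement. Returns c(dy, dx) in samples.
phaseCorrShift <- function(a, b, eps = 1e-12) {
  n <- dim(a)
  Fa <- fft(a); Fb <- fft(b)
  R <- Fa * Conj(Fb)
  R <- R / (Mod(R) + eps * max(Mod(R), eps))
  r <- Re(fft(R, inverse = TRUE)) / prod(n)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  refine <- function(rm, r0, rp) {
    den <- rm - 2 * r0 + rp
    if (abs(den) < .Machine$double.eps) return(0)
    d <- 0.5 * (rm - rp) / den
    max(min(d, 0.5), -0.5)
  }
  idx <- function(i, n) ((i - 1) %% n) + 1
  dy <- refine(r[idx(pk[1] - 1, n[1]), pk[2]], r[pk[1], pk[2]], r[idx(pk[1] + 1, n[1]), pk[2]])
  dx <- refine(r[pk[1], idx(pk[2] - 1, n[2])], r[pk[1], pk[2]], r[pk[1], idx(pk[2] + 1, n[2])])
  shift <- c(pk[1] - 1 + dy, pk[2] - 1 + dx)
  # unwrap to the symmetric interval
  shift - n * (shift > n / 2)
}

# 1-D 4-point Lagrange cubic interpolation at arbitrary positions (in units of
# the input sample index). Clamped to quadratic/linear near the boundaries.
lagrangeCubic1 <- function(y, at) {
  n <- length(y)
  out <- numeric(length(at))
  for (ii in seq_along(at)) {
    t <- at[ii]
    i1 <- floor(t)
    if (i1 < 2) i1 <- 2
    if (i1 > n - 2) i1 <- n - 2
    xs <- (i1 - 1):(i1 + 2)
    if (n < 4) { out[ii] <- approx(seq_len(n), y, xout = min(max(t, 1), n), rule = 2)$y; next }
    w <- vapply(seq_len(4), function(j) {
      xj <- xs[j]
      prod((t - xs[-j]) / (xj - xs[-j]))
    }, numeric(1))
    out[ii] <- sum(w * y[xs])
  }
  out
}

# Evaluate an expression under a fixed RNG state, restoring the caller's state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Normalized 1-D Gaussian taps on (-half:half)
gaussKernel1 <- function(sigma, half = 5L) {
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable 3-D convolution with a 1-D kernel applied along each axis,
# zero-padded but renormalized by the local kernel mass (so interior voxels see
# the plain Gaussian weighting and edges a truncated, renormalized one).
sepConv3 <- function(x, k1) {
  convAxis <- function(a, k1, axis) {
    d <- dim(a)
    half <- (length(k1) - 1L) / 2L
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    n <- dp[1]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k1)) {
      off <- j - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k1[j] * m[src[ok], ]
    }
    dim(out) <- dp
    aperm(out, order(perm))
  }
  wt <- array(1, dim(x))
  for (ax in 1:3) {
    x <- convAxis(x, k1, ax)
    wt <- convAxis(wt, k1, ax)
  }
  x / wt
}

# strictly-local maxima with leftmost-of-plateau convention
localMaxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) idx <- c(idx, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  idx
}
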