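# Image-quality and clustering metrics: SBR, SNR, 3-D SSIM, FWHM, Fourier
# ring correlation, Calinski-Harabasz score and class-distance matrices.

#' Signal-to-background ratio, dB
#'
#' \code{10*log10(max(signal area) / mean(background area))}. Equal signal
#' and background give 0 dB; the value is invariant to global scaling.
#'
#' @param image numeric array.
#' @param signalMask,backgroundMask logical masks (disjoint, nonempty).
#' @export
sbr <- function(image, signalMask, backgroundMask) {
  if (!any(signalMask) || !any(backgroundMask)) stop("masks must be nonempty")
  if (any(signalMask & backgroundMask)) stop("masks must be disjoint")
  bg <- mean(image[backgroundMask])
  if (bg <= 0) stop("background mean must be positive")
  10 * log10(max(image[signalMask]) / bg)
}

#' Signal-to-noise ratio of a reconstruction against a reference, dB
#'
#' \code{10*log10(||X||^2 / ||X - Y||^2)}; identical inputs return Inf.
#'
#' @param reference,estimate equal-shape numeric arrays.
#' @export
snr <- function(reference, estimate) {
  if (!identical(dim(reference), dim(estimate))) stop("shapes differ")
  if (all(reference == 0)) stop("all-zero reference")
  err <- sum((reference - estimate)^2)
  if (err == 0) return(Inf)
  10 * log10(sum(reference^2) / err)
}

#' 3-D structural similarity index
#'
#' SSIM with 3-D Gaussian local windows (sigma 1.5 voxels, 11-voxel
#' support), constants (0.01 L)^2 and (0.03 L)^2. Both volumes are
#' normalized by their own maximum first, so L = 1; the mean SSIM over all
#' voxels is returned.
#'
#' @param reference,estimate equal-shape 3-D arrays.
#' @param sigma,half Gaussian window parameters (support 2*half+1).
#' @export
ssim3d <- function(reference, estimate, sigma = 1.5, half = 5L) {
  if (!identical(dim(reference), dim(estimate))) stop("shapes differ")
  if (max(reference) <= 0) stop("all-zero reference")
  X <- reference / max(reference)
  Y <- estimate / max(estimate)
  L <- max(X)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  k <- gaussKernel1(sigma, half)
  muX <- sepConv3(X, k); muY <- sepConv3(Y, k)
  sXX <- sepConv3(X * X, k) - muX^2
  sYY <- sepConv3(Y * Y, k) - muY^2
  sXY <- sepConv3(X * Y, k) - muX * muY
  s <- ((2 * muX * muY + c1) * (2 * sXY + c2)) /
    ((muX^2 + muY^2 + c1) * (sXX + sYY + c2))
  mean(s)
}

#' Full width at half maximum of a 1-D profile
#'
#' Linear-interpolated half-maximum crossing width, or a Gaussian-fit mode
#' (\code{2*sqrt(2*log(2))*sigma}) for noisy sub-resolution structures.
#'
#' @param x sample positions (um); defaults to unit spacing.
#' @param y intensity profile (unimodal, >= 5 samples).
#' @param method "interp" or "gaussfit".
#' @return width in the units of \code{x}.
#' @export
fwhm <- function(y, x = seq_along(y), method = c("interp", "gaussfit")) {
  method <- match.arg(method)
  if (length(y) < 5) stop("need at least 5 samples")
  if (method == "gaussfit") {
    df <- data.frame(x = x, y = y)
    st <- list(A = max(y) - min(y), mu = x[which.max(y)],
               sig = (max(x) - min(x)) / 6, b = min(y))
    fit <- minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * sig^2)) + b,
                             data = df, start = st,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    return(2 * sqrt(2 * log(2)) * abs(stats::coef(fit)[["sig"]]))
  }
  pk <- which.max(y)
  half <- y[pk] / 2
  iL <- NULL; if (pk > 1) for (i in (pk - 1):1) if (y[i] < half) { iL <- i; break }
  iR <- NULL; if (pk < length(y)) for (i in (pk + 1):length(y)) if (y[i] < half) { iR <- i; break }
  if (is.null(iL) || is.null(iR)) stop("no half-maximum crossing within the profile support")
  xL <- x[iL] + (x[iL + 1] - x[iL]) * (half - y[iL]) / (y[iL + 1] - y[iL])
  xR <- x[iR - 1] + (x[iR] - x[iR - 1]) * (half - y[iR - 1]) / (y[iR] - y[iR - 1])
  xR - xL
}

#' Fourier ring correlation resolution
#'
#' Correlates two independent-noise images ring-by-ring in frequency space
#' and reads the resolution at the fixed-threshold crossing (1/7 by
#' default). Identical inputs are flagged and return the sampling limit.
#'
#' @param imageA,imageB equal-shape 2-D images.
#' @param pixelSize sample spacing, um.
#' @param threshold FRC threshold.
#' @return list: \code{frc} (data.frame freq, frc), \code{resolution} (um),
#'   \code{limited} (TRUE when no crossing / identical inputs).
#' @export
frcResolution <- function(imageA, imageB, pixelSize = 1, threshold = 1 / 7) {
  if (!identical(dim(imageA), dim(imageB))) stop("shapes differ")
  n <- dim(imageA)
  Fa <- fft(imageA - mean(imageA)); Fb <- fft(imageB - mean(imageB))
  fy <- c(0:floor(n[1] / 2), -(ceiling(n[1] / 2) - 1):-1)[seq_len(n[1])] / n[1]
  fx <- c(0:floor(n[2] / 2), -(ceiling(n[2] / 2) - 1):-1)[seq_len(n[2])] / n[2]
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  nR <- floor(min(n) / 2)
  ring <- pmin(1L + as.integer(round(fr * min(n))), nR)
  num <- as.vector(rowsum(as.vector(Re(Fa * Conj(Fb))), as.vector(ring)))
  dA <- as.vector(rowsum(as.vector(Mod(Fa)^2), as.vector(ring)))
  dB <- as.vector(rowsum(as.vector(Mod(Fb)^2), as.vector(ring)))
  frc <- num / sqrt(pmax(dA * dB, .Machine$double.xmin))
  freq <- (seq_len(nR) - 1) / (min(n) * pixelSize)   # cycles / um
  identicalIn <- isTRUE(all.equal(imageA, imageB))
  cross <- which(frc < threshold)
  cross <- cross[cross > 1]
  if (identicalIn || !length(cross)) {
    return(list(frc = data.frame(freq = freq, frc = frc[seq_len(nR)]),
                resolution = 2 * pixelSize, limited = TRUE))
  }
  i <- cross[1]
  f0 <- freq[i - 1] + (freq[i] - freq[i - 1]) *
    (frc[i - 1] - threshold) / (frc[i - 1] - frc[i])
  list(frc = data.frame(freq = freq, frc = frc[seq_len(nR)]),
       resolution = 1 / f0, limited = FALSE)
}

#' Calinski-Harabasz score
#'
#' \code{(SSB / SSW) * (N - k) / (k - 1)} with centroid-based between- and
#' within-class squared-distance sums. Degenerate zero within-class scatter
#' returns Inf.
#'
#' @param features numeric matrix [sample, feature].
#' @param labels class labels, length nrow(features).
#' @export
chScore <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  k <- nlevels(labels); N <- nrow(features)
  if (k < 2) stop("need at least 2 classes")
  if (k >= N) stop("need more samples than classes")
  cE <- colMeans(features)
  ssb <- 0; ssw <- 0
  for (lv in levels(labels)) {
    Xq <- features[labels == lv, , drop = FALSE]
    cq <- colMeans(Xq)
    ssb <- ssb + nrow(Xq) * sum((cq - cE)^2)
    ssw <- ssw + sum(sweep(Xq, 2, cq)^2)
  }
  if (ssw == 0) return(Inf)
  (ssb / ssw) * (N - k) / (k - 1)
}

#' Intra-/inter-class Euclidean distance matrix
#'
#' Entry (q, p) is the mean pairwise Euclidean distance between samples of
#' class q and class p (intra-class on the diagonal, including zero
#' self-distances, per the 1/Nq^2 normalization).
#'
#' @inheritParams chScore
#' @return symmetric k x k matrix with class levels as dimnames.
#' @export
classDistances <- function(features, labels) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  lv <- levels(labels)
  k <- length(lv)
  D <- as.matrix(stats::dist(features))
  out <- matrix(0, k, k, dimnames = list(lv, lv))
  for (q in seq_len(k)) for (p in seq_len(k)) {
    iq <- which(labels == lv[q]); ip <- which(labels == lv[p])
    out[q, p] <- sum(D[iq, ip, drop = FALSE]) / (length(iq) * length(ip))
  }
  out
}
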