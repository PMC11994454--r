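# Fluorescence time-series analysis: dF/F0 normalization, spike detection
# for calcium and voltage indicators, and orientation-tuning analysis of
# 8-direction moving-grating responses.

#' dF/F0 traces
#'
#' \code{(F - F0) / F0} per ROI, with F0 the time-mean fluorescence of the
#' ROI over the entire series (recomputed, never cached).
#'
#' @param traces a \code{TraceSet}.
#' @return matrix [roi, t] of dF/F0 values (each row has exact zero mean).
#' @export
dff <- function(traces) {
  stopifnot(is(traces, "TraceSet"))
  f0 <- baselineF0(traces)
  bad <- which(f0 <= 0)
  if (length(bad))
    stop("nonpositive baseline F0 for ROI(s): ", paste(bad, collapse = ", "))
  sweep(sweep(traces@f, 1, f0), 1, f0, "/")
}

#' Detect spikes in a dF/F0 trace
#'
#' Calcium mode: strict local maxima of the trace exceeding 0.40 (40%
#' dF/F0). Voltage mode: the trace minus its running-median over a 130-ms
#' window (length in frames \code{round(0.130/frameInterval)}, forced odd),
#' then strict local maxima exceeding 0.02. Spike amplitude is the (absolute)
#' peak value of the detected trace.
#'
#' @param trace numeric dF/F0 vector for one ROI.
#' @param modality "calcium" or "voltage".
#' @param frameInterval frame interval, s (needed for the voltage median
#'   window).
#' @param threshold override the modality default (0.40 / 0.02).
#' @param medianWindowS voltage median-filter window, s.
#' @return data.frame with columns \code{index}, \code{time}, \code{amplitude}.
#' @export
detectSpikes <- function(trace, modality = c("calcium", "voltage"),
                         frameInterval = 0.05, threshold = NULL,
                         medianWindowS = 0.130) {
  modality <- match.arg(modality)
  if (frameInterval <= 0) stop("frameInterval must be positive")
  if (is.null(threshold)) threshold <- if (modality == "calcium") 0.40 else 0.02
  x <- trace
  if (modality == "voltage") {
    k <- as.integer(round(medianWindowS / frameInterval))
    if (k %% 2L == 0L) k <- k + 1L
    k <- max(k, 1L)
    if (k > length(trace)) stop("median window longer than the trace")
    x <- trace - runmed(trace, k)
  }
  pk <- localMaxima(x)
  pk <- pk[x[pk] > threshold]
  data.frame(index = pk, time = (pk - 1) * frameInterval,
             amplitude = abs(x[pk]))
}

#' Orientation-tuning analysis of 8-direction grating responses
#'
#' Per ROI: mean dF/F0 during the stimulus bins of each direction, referred
#' to the blank-period baseline; visual response ratio R = mean
#' stimulus-period response over mean blank-period response (floored at its
#' standard error); ROIs with R > 3 are "responsive". R_pref is the maximum direction response, R_orth
#' the mean response of the two directions orthogonal to the preferred one,
#' and OSI = (R_pref - R_orth) / (R_pref + R_orth). The fraction of
#' responsive ROIs with OSI > 0.8 is also reported.
#'
#' @param traces a \code{TraceSet} whose stimulus schedule labels each frame
#'   with a direction (degrees, as character) or "blank". All blank bins are
#'   pooled for R.
#' @return a \code{TuningResult}.
#' @export
tuningAnalysis <- function(traces) {
  stopifnot(is(traces, "TraceSet"))
  if (!length(traces@stimulus)) stop("stimulus schedule is required")
  stim <- traces@stimulus
  if (!any(stim == "blank")) stop("missing blank periods; R is undefined")
  dirs <- sort(as.numeric(unique(stim[stim != "blank"])))
  if (length(dirs) != 8L)
    stop("expected 8 stimulus directions, got ", length(dirs))
  # All tuning quantities are referred to the blank-period baseline: with
  # the whole-series mean the dF/F0 series sums to zero, which makes the
  # stim/blank response ratio degenerate and pushes sharply tuned OSIs
  # beyond 1. (dff() itself keeps the whole-series-mean definition.)
  f0b <- rowMeans(traces@f[, stim == "blank", drop = FALSE])
  if (any(f0b <= 0)) stop("nonpositive blank-period baseline")
  dmat <- sweep(sweep(traces@f, 1, f0b), 1, f0b, "/")
  nR <- nrow(dmat)
  resp <- matrix(0, nR, 8, dimnames = list(NULL, as.character(dirs)))
  for (j in seq_len(8))
    resp[, j] <- rowMeans(dmat[, stim == as.character(dirs)[j], drop = FALSE])
  stimMean <- rowMeans(dmat[, stim != "blank", drop = FALSE])
  blank <- dmat[, stim == "blank", drop = FALSE]
  blankMean <- rowMeans(blank)
  # a blank-period response cannot be resolved below its standard error;
  # floor the denominator there so noise around zero does not flip R
  blankSe <- apply(blank, 1, sd) / sqrt(ncol(blank))
  r <- stimMean / pmax(blankMean, blankSe, .Machine$double.eps)
  prefIdx <- apply(resp, 1, which.max)
  rPref <- resp[cbind(seq_len(nR), prefIdx)]
  orthOf <- function(j) {
    a <- dirs[j]
    which(((dirs - a) %% 180) == 90)
  }
  rOrth <- vapply(seq_len(nR), function(i) mean(resp[i, orthOf(prefIdx[i])]),
                  numeric(1))
  osi <- (rPref - rOrth) / (rPref + rOrth)
  responsive <- is.finite(r) & r > 3
  hi <- if (any(responsive)) mean(osi[responsive] > 0.8) else NA_real_
  new("TuningResult", responses = resp, directions = dirs, r = r,
      rPref = rPref, rOrth = rOrth, osi = osi, responsive = responsive,
      highOsiFraction = hi)
}

#' Simulate a stimulus-locked neuron population trace set
#'
#' Generates dF/F0-style fluorescence traces for a population of neurons
#' with von-Mises orientation tuning, an 8-direction moving-grating protocol
#' (stimulus blocks separated by blank periods) and calcium-like transients
#' plus Gaussian noise. Part of the synthetic-data module; deterministic
#' under the seed.
#'
#' @param nRoi number of neurons.
#' @param kappa von-Mises concentration of the tuning curves.
#' @param stimS,blankS stimulus and blank durations per trial, s.
#' @param nTrials trials per direction.
#' @param frameInterval frame interval, s.
#' @param baseline baseline fluorescence.
#' @param amplitude peak stimulus-driven fluorescence increment.
#' @param noiseSd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return a \code{TraceSet} with stimulus schedule.
#' @export
simulateTuningTraces <- function(nRoi = 20L, kappa = 4, stimS = 3, blankS = 6,
                                 nTrials = 2L, frameInterval = 0.05,
                                 baseline = 100, amplitude = 500,
                                 noiseSd = 0.5, seed = 1L) {
  dirs <- seq(0, 315, by = 45)
  stimF <- round(stimS / frameInterval); blankF <- round(blankS / frameInterval)
  sched <- character(0)
  for (d in dirs) for (t in seq_len(nTrials))
    sched <- c(sched, rep("blank", blankF), rep(as.character(d), stimF))
  nT <- length(sched)
  withSeed(seed, {
    pref <- runif(nRoi, 0, 360)
    gain <- runif(nRoi, 0.6, 1.4)
    f <- matrix(0, nRoi, nT)
    for (i in seq_len(nRoi)) {
      drive <- numeric(nT)
      for (d in dirs) {
        tun <- exp(kappa * (cos((d - pref[i]) * pi / 180) - 1))
        drive[sched == as.character(d)] <- tun
      }
      # simple calcium impulse response (fast rise, slow decay)
      kern <- exp(-(0:60) * frameInterval / 0.6)
      conv <- stats::filter(drive, kern, sides = 1)
      conv[is.na(conv)] <- 0
      conv <- conv / max(conv)
      f[i, ] <- baseline + amplitude * gain[i] * conv +
        rnorm(nT, sd = noiseSd)
    }
    TraceSet(f, frameInterval, sched)
  })
}
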