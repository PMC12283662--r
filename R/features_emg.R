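#' Root-mean-square amplitude
#'
#' `sqrt(mean(x^2))`: the quadratic-mean amplitude of the window, an index of
#' the electrical energy produced by the muscle during the movement.
#'
#' @param x Numeric sample vector (non-empty).
#' @return RMS amplitude (same units as `x`).
#' @export
compute_rms <- function(x) {
  if (length(x) == 0L) stopf("RMS of an empty vector is undefined")
  sqrt(mean(x^2))
}

#' Mean absolute value
#'
#' `mean(abs(x))`: the rectified mean amplitude, commonly read as contraction
#' intensity.
#'
#' @inheritParams compute_rms
#' @return MAV (same units as `x`).
#' @export
compute_mav <- function(x) {
  if (length(x) == 0L) stopf("MAV of an empty vector is undefined")
  mean(abs(x))
}

#' Integrated EMG
#'
#' Rectangular-rule integral of the rectified signal over the analysis
#' window: `sum(abs(x)) / fs`, in amplitude-seconds. By construction
#' `iemg = mav * duration`; it indexes total motor-unit discharge over the
#' window.
#'
#' @inheritParams compute_rms
#' @param fs Sampling rate, Hz.
#' @return iEMG in amplitude-seconds.
#' @export
compute_iemg <- function(x, fs) {
  if (length(x) == 0L) stopf("iEMG of an empty vector is undefined")
  if (!is.numeric(fs) || fs <= 0) stopf("fs must be positive")
  sum(abs(x)) / fs
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: the signal is cut into 50%-overlapping
#' Hann-tapered segments of `nperseg` samples, each segment's periodogram is
#' computed and the one-sided densities are averaged.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate, Hz.
#' @param nperseg Segment length (default `min(length(x), 4096)`).
#' @return List with `freq` (Hz) and `psd` (power per Hz), one-sided.
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), 4096L)) {
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  if (nperseg < 8L) stopf("segment too short for a PSD estimate")
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nperseg - 1L)) / (nperseg - 1L))
  acc <- numeric(nperseg)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nperseg - 1L)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  P <- acc / length(starts)
  half <- nperseg %/% 2L
  psd <- P[1:(half + 1L)] * 2 / (fs * sum(w^2))
  psd[1L] <- psd[1L] / 2
  if (nperseg %% 2L == 0L) psd[half + 1L] <- psd[half + 1L] / 2
  list(freq = (0:half) * fs / nperseg, psd = psd)
}

#' Median frequency
#'
#' The frequency that splits the power spectrum into two equal-power halves
#' -- the central value of the muscle's discharge-frequency distribution,
#' which drops with fatigue. The PSD is estimated by [welch_psd()]; the
#' half-power crossing is located on the cumulative spectrum with each bin's
#' mass centred on its frequency and linear interpolation between bin
#' centres (an edge-based cumulative biases a pure tone by up to one bin).
#'
#' @inheritParams compute_iemg
#' @param nperseg Welch segment length (default `min(length(x), 4096)`).
#' @return Median frequency in Hz, in `[0, fs/2]`.
#' @export
compute_mf <- function(x, fs, nperseg = min(length(x), 4096L)) {
  if (length(x) < 16L) stopf("median frequency needs at least 16 samples")
  if (!is.numeric(fs) || fs <= 0) stopf("fs must be positive")
  W <- welch_psd(x, fs, nperseg)
  tot <- sum(W$psd)
  if (tot <= 0 || !is.finite(tot))
    stopf("all-zero signal: median frequency undefined")
  cum <- cumsum(W$psd) - W$psd / 2
  j <- which(cum >= tot / 2)[1L]
  if (is.na(j)) return(W$freq[length(W$freq)])
  if (j == 1L) return(W$freq[1L])
  df <- W$freq[2L] - W$freq[1L]
  W$freq[j - 1L] + (tot / 2 - cum[j - 1L]) / (cum[j] - cum[j - 1L]) * df
}

#' Per-channel sEMG feature set of a trial
#'
#' Computes the four features -- RMS, iEMG, MAV, median frequency -- for each
#' of the three deltoid channels over the full (aligned) trial window, one
#' scalar per feature per channel.
#'
#' @param trial An [emg_trial()] (typically denoised via [sg_denoise()]).
#' @return Named numeric vector of length 12, names
#'   `<channel>_{rms,iemg,mav,mf}` in channel order.
#' @export
emg_features <- function(trial) {
  stopifnot(inherits(trial, "emg_trial"))
  out <- lapply(seq_len(3L), function(j) {
    x <- trial$samples[, j]
    v <- c(rms = compute_rms(x),
           iemg = compute_iemg(x, trial$fs_emg),
           mav = compute_mav(x),
           mf = compute_mf(x, trial$fs_emg))
    names(v) <- paste(trial$channels[j], names(v), sep = "_")
    v
  })
  unlist(out)
}
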