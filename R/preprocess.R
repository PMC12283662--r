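sg_smooth_vector <- function(x, window_length, polyorder) {
  n <- length(x)
  m <- (window_length - 1L) %/% 2L
  # mirror-pad (no edge-sample repetition) so output length equals input
  pad <- c(x[(m + 1L):2L], x, x[(n - 1L):(n - m)])
  h <- signal::sgolay(p = polyorder, n = window_length)[m + 1L, ]
  y <- stats::filter(pad, h, sides = 2)
  as.numeric(y[(m + 1L):(m + n)])
}

#' Savitzky-Golay denoising of an sEMG trial
#'
#' Per-channel least-squares polynomial smoothing: within each sliding window
#' of `window_length` samples a degree-`polyorder` polynomial is fitted and
#' evaluated at the window centre. The signal is mirror-padded by
#' `(window_length - 1)/2` samples on each side so the output has the input's
#' length without edge blow-up. Defaults (window 51, cubic) trade noise
#' suppression against preservation of burst morphology.
#'
#' @param trial An [emg_trial()].
#' @param window_length Odd window length in samples (default 51).
#' @param polyorder Polynomial degree, `< window_length` (default 3).
#' @return The denoised [emg_trial()].
#' @export
sg_denoise <- function(trial, window_length = 51L, polyorder = 3L) {
  stopifnot(inherits(trial, "emg_trial"))
  window_length <- as.integer(window_length)
  if (window_length %% 2L == 0L) stopf("window_length must be odd")
  if (polyorder >= window_length)
    stopf("polyorder must be smaller than window_length")
  if (nrow(trial$samples) < window_length)
    stopf("signal (%d samples) shorter than the %d-sample window",
          nrow(trial$samples), window_length)
  out <- trial
  out$samples <- apply(trial$samples, 2, sg_smooth_vector,
                       window_length = window_length, polyorder = polyorder)
  colnames(out$samples) <- trial$channels
  out
}

# 1 Hz low-pass trend, computed on a ~100 Hz bin-averaged copy of the channel
# for numerical stability of the Butterworth filter at very low normalized
# cutoffs.
baseline_trend_range <- function(x, fs) {
  target <- 100
  dec <- max(1L, floor(fs / target))
  nb <- floor(length(x) / dec)
  xb <- colMeans(matrix(x[seq_len(nb * dec)], nrow = dec))
  fsd <- fs / dec
  bf <- signal::butter(2, min(0.99, 1 / (fsd / 2)), type = "low")
  tr <- signal::filtfilt(bf, xb)
  diff(range(tr))
}

powerline_band_ratio <- function(x, fs, mains, half_width = 1) {
  W <- welch_psd(x, fs)
  band <- W$freq >= mains - half_width & W$freq <= mains + half_width
  tot <- sum(W$psd)
  if (tot <= 0) return(0)
  sum(W$psd[band]) / tot
}

#' Rule-based sEMG channel quality control
#'
#' Screens each channel for the two failure modes excluded at acquisition
#' time: unstable baseline (range of a 1 Hz low-pass trend) and powerline
#' interference (fraction of spectral power within `mains` +/- 1 Hz). The
#' report is informational; [run_pipeline()] drops failed channels' trials.
#' Thresholds are artifact defaults (the acquisition rules are qualitative):
#' drift below `d_max_frac` of the channel RMS, powerline ratio below `r_max`.
#'
#' @param trial An [emg_trial()] of at least 1 s.
#' @param d_max_frac Maximum baseline drift as a fraction of channel RMS.
#' @param r_max Maximum powerline power fraction.
#' @param mains Mains frequency in Hz (default 50; set 60 where applicable).
#' @return A data.frame of class `qc_report`: one row per channel with
#'   `baseline_drift`, `powerline_ratio`, `passed`.
#' @export
qc_channels <- function(trial, d_max_frac = 0.2, r_max = 0.2, mains = 50) {
  stopifnot(inherits(trial, "emg_trial"))
  if (nrow(trial$samples) < trial$fs_emg)
    stopf("QC requires at least 1 s of signal")
  res <- lapply(seq_len(3L), function(j) {
    x <- trial$samples[, j]
    drift <- baseline_trend_range(x, trial$fs_emg)
    ratio <- powerline_band_ratio(x, trial$fs_emg, mains)
    d_max <- d_max_frac * compute_rms(x)
    data.frame(channel = trial$channels[j], baseline_drift = drift,
               powerline_ratio = ratio,
               passed = drift < d_max && ratio < r_max)
  })
  out <- do.call(rbind, res)
  class(out) <- c("qc_report", "data.frame")
  out
}
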