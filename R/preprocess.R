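# Per-lead noise suppression chain: power-line cancellation, baseline-drift
# removal, and EMG smoothing with a cutoff that adapts to the local wave
# content. All stages are zero-phase so fiducial latencies are preserved.

#' Remove power-line interference
#'
#' Zero-phase second-order Butterworth band-stop centred on the mains
#' frequency (+-1.5 Hz), applied forward-backward.
#'
#' @param x Numeric signal in mV.
#' @param fs Sampling rate in Hz; must be at least 4x the mains frequency.
#' @param mains_freq 50 or 60 Hz.
#' @return Filtered signal.
#' @export
remove_powerline <- function(x, fs = 500, mains_freq = 50) {
  stopifnot(fs >= 4 * mains_freq)
  if (!length(x) || all(x == 0)) return(x)
  w <- c(mains_freq - 1.5, mains_freq + 1.5) / (fs / 2)
  bt <- signal::butter(2, w, type = "stop")
  as.numeric(signal::filtfilt(bt, x))
}

#' Remove baseline drift
#'
#' First-order recursive (IIR) high-pass run forward-backward. The design
#' cutoff is pre-warped so the combined two-pass response has its -3 dB
#' point at `cutoff`: the two-pass amplitude of a first-order Butterworth
#' high-pass is x^2/(1+x^2) with x = f/f_design, which equals 1/sqrt(2) at
#' x = sqrt(1+sqrt(2)) ~ 1.554.
#'
#' @param x Numeric signal in mV.
#' @param fs Sampling rate in Hz.
#' @param cutoff Half-power frequency in Hz (default 0.64).
#' @return Filtered signal with the DC component and slow drift removed.
#' @export
remove_baseline <- function(x, fs = 500, cutoff = 0.64) {
  if (!length(x) || all(x == 0)) return(x)
  design_cutoff <- cutoff / sqrt(1 + sqrt(2))
  bt <- signal::butter(1, design_cutoff / (fs / 2), type = "high")
  as.numeric(signal::filtfilt(bt, x))
}

# Savitzky-Golay -3 dB cutoff ~ (order+1) * fs / (3.2 m - 4.6) for window
# 2m+1; solve for the window half-width at a target cutoff.
.sg_window <- function(fs, cutoff, order = 3) {
  m <- ((order + 1) * fs / cutoff + 4.6) / 3.2
  w <- 2L * as.integer(round(m)) + 1L
  max(w, order + 3L - ((order + 3L) %% 2L == 0L))  # odd, > order
}

#' Adaptive low-pass smoothing for EMG noise
#'
#' Savitzky-Golay smoothing whose window length switches between three
#' regimes: a long window (cutoff about `cutoffs[1]` Hz) on low-power
#' isoelectric segments, a medium window (about `cutoffs[2]` Hz) on
#' high-power P/T waves, and a short window (cutoff above `cutoffs[3]` Hz)
#' inside QRS complexes so R amplitudes are preserved. QRS regions are found
#' with a coarse slope-envelope threshold.
#'
#' @param x Numeric signal in mV (baseline-corrected).
#' @param fs Sampling rate in Hz.
#' @param cutoffs Approximate cutoffs (Hz) of the low / medium / high
#'   regimes.
#' @param order Polynomial order of the smoother.
#' @return Smoothed signal.
#' @export
adaptive_lowpass <- function(x, fs = 500, cutoffs = c(14, 25, 100), order = 3) {
  n <- length(x)
  if (!n || all(x == 0)) return(x)
  w_low <- .sg_window(fs, cutoffs[1], order)
  w_mid <- .sg_window(fs, cutoffs[2], order)
  # QRS regime: cutoffs[3] is a lower bound (the cutoff must stay *above*
  # it so R amplitudes survive); design the window 1.5x beyond the bound
  w_hi  <- .sg_window(fs, cutoffs[3] * 1.5, order)
  if (n <= w_low) return(x)

  pre <- as.numeric(signal::sgolayfilt(x, p = order, n = min(w_hi, 2L * (n %/% 2L) - 1L)))
  slope <- c(0, abs(diff(pre))) * fs                        # mV/s
  env <- .moving_max(slope, ms_to_samples(50, fs))
  qrs_mask <- env > pmax(8, 0.2 * max(env))                 # >= 8 mV/s slew
  qrs_mask <- .dilate(qrs_mask, ms_to_samples(60, fs))
  # high-power P/T regime: deviation from the local isoelectric line
  bl <- stats::runmed(pre, 1 + 2 * (ms_to_samples(250, fs) %/% 2))
  amp_mask <- .moving_max(abs(pre - bl), ms_to_samples(50, fs)) > 0.05 & !qrs_mask

  out <- as.numeric(signal::sgolayfilt(x, p = order, n = w_low))
  if (any(amp_mask)) {
    mid <- as.numeric(signal::sgolayfilt(x, p = order, n = w_mid))
    out[amp_mask] <- mid[amp_mask]
  }
  if (any(qrs_mask)) out[qrs_mask] <- pre[qrs_mask]
  out
}

.moving_max <- function(x, half_w) {
  n <- length(x)
  out <- x
  for (k in seq_len(half_w)) {
    out <- pmax(out, c(x[-seq_len(k)], rep(0, k)), c(rep(0, k), x[seq_len(n - k)]))
  }
  out
}

.dilate <- function(mask, half_w) {
  idx <- which(mask)
  if (!length(idx)) return(mask)
  hits <- unique(unlist(lapply(idx, function(i)
    max(1L, i - half_w):min(length(mask), i + half_w))))
  out <- logical(length(mask))
  out[hits] <- TRUE
  out
}

#' Full preprocessing chain for one lead
#'
#' @inheritParams remove_powerline
#' @param mains_freq Mains frequency in Hz.
#' @param highpass_cutoff Baseline high-pass half-power frequency in Hz.
#' @param sg_regime_cutoffs Savitzky-Golay regime cutoffs in Hz.
#' @return Filtered signal.
#' @export
preprocess_signal <- function(x, fs = 500, mains_freq = 50,
                              highpass_cutoff = 0.64,
                              sg_regime_cutoffs = c(14, 25, 100)) {
  x <- remove_powerline(x, fs, mains_freq)
  x <- remove_baseline(x, fs, highpass_cutoff)
  adaptive_lowpass(x, fs, sg_regime_cutoffs)
}

#' Preprocess every lead of a record
#'
#' @param record An `ecg_record`.
#' @param ... Passed to [preprocess_signal()].
#' @return The record with filtered signals.
#' @export
preprocess_record <- function(record, ...) {
  stopifnot(inherits(record, "ecg_record"))
  record$signals <- apply(record$signals, 2, preprocess_signal,
                          fs = record$fs, ...)
  record
}
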