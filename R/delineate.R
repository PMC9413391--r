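# Delineation of the three characteristic points per beat: the R-wave
# fiducial (QRS detection on a reference lead), the QRS onset (Q) found as
# the first low-slope isoelectric point within 120 ms before R, and the
# preceding P-/f-peak found as the largest qualifying high-slope deflection
# 40-300 ms before Q.

#' Detect R-wave fiducials via adaptive spatial-velocity thresholding
#'
#' The detection function is the spatial velocity - the absolute first
#' derivative summed over the supplied leads, smoothed over 30 ms. Peaks are
#' accepted against an amplitude threshold that adapts beat-to-beat (a
#' running blend of recent peak heights), with a 200 ms refractory period
#' and a threshold drop (search-back) once no beat has been seen for 1.5x
#' the running median RR interval. Accepted velocity peaks are snapped to
#' the largest absolute deflection of the first lead within +-60 ms.
#'
#' @param signals Numeric matrix (samples x leads) or vector, in mV.
#' @param fs Sampling rate in Hz.
#' @return Integer vector of strictly increasing R sample indices (1-based).
#' @export
detect_qrs <- function(signals, fs = 500) {
  if (is.vector(signals)) signals <- matrix(signals, ncol = 1)
  n <- nrow(signals)
  if (n < 2 * fs) stop("need at least 2 s of signal for QRS detection")

  vel <- rowSums(abs(apply(signals, 2, function(x) c(0, diff(x)))))
  w <- ms_to_samples(30, fs)
  vel <- as.numeric(stats::filter(vel, rep(1 / w, w), sides = 2))
  vel[is.na(vel)] <- 0
  if (max(vel) <= 0) return(integer(0))

  refr <- ms_to_samples(200, fs)
  # local maxima of the velocity envelope
  peaks <- which(diff(sign(diff(vel))) < 0) + 1L
  peaks <- peaks[vel[peaks] > 0.05 * max(vel)]
  if (!length(peaks)) return(integer(0))

  level <- max(vel[seq_len(min(n, 2L * fs))])
  accepted <- integer(0)
  rr_hist <- numeric(0)
  last <- -Inf
  for (p in peaks) {
    thr <- 0.4 * level
    rr_med <- if (length(rr_hist) >= 2) median(rr_hist) else fs
    if (p - last > 1.5 * rr_med) thr <- 0.2 * level  # search-back regime
    if (vel[p] < thr) next
    if (p - last < refr) {
      # within refractory: keep the taller of the two candidates
      if (length(accepted) && vel[p] > vel[accepted[length(accepted)]]) {
        accepted[length(accepted)] <- p
        last <- p
      }
      next
    }
    if (length(accepted)) rr_hist <- c(rr_hist, p - last)
    if (length(rr_hist) > 8) rr_hist <- rr_hist[-1]
    accepted <- c(accepted, p)
    last <- p
    level <- 0.7 * level + 0.3 * vel[p]
  }
  if (!length(accepted)) return(integer(0))

  # snap each velocity peak to the dominant deflection of the first lead
  snap_w <- ms_to_samples(60, fs)
  ref <- signals[, 1]
  r_idx <- vapply(accepted, function(p) {
    lo <- max(1L, p - snap_w); hi <- min(n, p + snap_w)
    win <- ref[lo:hi]
    lo + which.max(abs(win - median(win))) - 1L
  }, 0L)
  r_idx <- sort(unique(r_idx))
  r_idx[c(TRUE, diff(r_idx) >= refr)]
}

# Thresholded low-slope quantities for Q-onset detection, independent of the
# running threshold: for each candidate t the minimal threshold (in mV) at
# which all four conditions hold.
.q_threshold_needed <- function(x, t_vec, l10, l20) {
  vapply(t_vec, function(t) {
    d20 <- abs(x[t] - x[t - l20])
    d10 <- abs(x[t] - x[t - l10])
    d10b <- abs(x[t - l10] - x[t - l20])
    exc <- max(abs(x[t] - x[(t - l20):t]))
    max(d20, exc / 4, d10 / 3, d10b / 3)
  }, 0)
}

#' Detect the QRS onset before an R fiducial
#'
#' Scans backward from R over t in [R - 120 ms, R] for the first (latest)
#' sample where four simultaneous low-slope conditions hold within a 20 ms
#' window: |x_t - x_(t-20ms)| <= Thr_Q, the maximal excursion
#' |x_t - x_(t-k)| over k <= 20 ms is <= 4 Thr_Q, and the two 10 ms
#' half-lags are <= 3 Thr_Q. If no sample qualifies, Thr_Q is incremented
#' by 1 uV and the scan repeats; termination is guaranteed because the
#' conditions become satisfiable as Thr_Q grows.
#'
#' @param x Numeric signal in mV (one lead, filtered).
#' @param r R fiducial sample index (1-based).
#' @param fs Sampling rate in Hz.
#' @param thr_q Starting threshold in uV (default 20).
#' @return List with `q` (sample index) and `thr_q` (final threshold, uV),
#'   or `NULL` when `r` is too close to the record start (beat skipped).
#' @export
detect_q_onset <- function(x, r, fs = 500, thr_q = 20) {
  l10 <- ms_to_samples(10, fs)
  l20 <- ms_to_samples(20, fs)
  l120 <- ms_to_samples(120, fs)
  if (r - l120 - l20 < 1 || r > length(x)) {
    message("beat at sample ", r, " skipped: too close to record start")
    return(NULL)
  }
  t_vec <- seq(r, r - l120)  # backward scan, first hit wins
  needed_uv <- .q_threshold_needed(x, t_vec, l10, l20) * 1000
  thr <- thr_q
  repeat {
    hit <- which(needed_uv <= thr)
    if (length(hit)) return(list(q = t_vec[hit[1]], thr_q = thr))
    thr <- thr + 1
  }
}

#' Detect the P-/f-peak preceding a QRS onset
#'
#' Candidates t in [Q - 300 ms, Q - 40 ms] qualify when all four high-slope
#' deflection conditions hold within 80 ms: |x_t - x_(t-40ms)| > 4 Thr_P,
#' |x_t - x_(t+40ms)| > Thr_P, |x_t - x_(t-20ms)| > Thr_P and
#' |x_t - x_(t+20ms)| > Thr_P / 2, with Thr_P = 3 uV. When no candidate
#' qualifies no peak is reported (a valid outcome: fibrillatory baselines or
#' artefacts may hide the atrial wave). Among qualifying candidates the one
#' with the largest total 80 ms deflection
#' |x_t - x_(t-40ms)| + |x_t - x_(t+40ms)| is returned.
#'
#' @param x Numeric signal in mV (one lead, filtered).
#' @param q QRS-onset sample index (1-based).
#' @param fs Sampling rate in Hz.
#' @param thr_p Threshold in uV (default 3).
#' @return Sample index of the peak, or `NA_integer_` when none qualifies.
#' @export
detect_p_peak <- function(x, q, fs = 500, thr_p = 3) {
  l20 <- ms_to_samples(20, fs)
  l40 <- ms_to_samples(40, fs)
  lo <- max(q - ms_to_samples(300, fs), l40 + 1L)
  hi <- q - l40
  if (hi < lo || hi + l40 > length(x)) return(NA_integer_)
  t_vec <- lo:hi
  thr <- thr_p / 1000
  d40m <- abs(x[t_vec] - x[t_vec - l40])
  d40p <- abs(x[t_vec] - x[t_vec + l40])
  d20m <- abs(x[t_vec] - x[t_vec - l20])
  d20p <- abs(x[t_vec] - x[t_vec + l20])
  ok <- d40m > 4 * thr & d40p > thr & d20m > thr & d20p > thr / 2
  if (!any(ok)) return(NA_integer_)
  cand <- t_vec[ok]
  cand[which.max((d40m + d40p)[ok])]
}

#' Delineate a full record
#'
#' R fiducials are detected once on the reference lead (lead I when present,
#' else the first lead); Q onsets and P-/f-peaks are then re-delineated per
#' lead on that lead's signal, because the PQ features are lead-specific.
#'
#' @param record An `ecg_record`.
#' @param leads Leads to delineate (default: all in the record).
#' @param preprocess Apply [preprocess_record()] first (default `TRUE`).
#' @return Object of class `fiducials`: list with `r_idx` (reference R
#'   fiducials), `table` (data.frame: lead, beat, r_idx, q_idx, p_idx with
#'   `NA` for missing peaks), `fs`, and `record_id`.
#' @export
delineate_record <- function(record, leads = colnames(record$signals),
                             preprocess = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  if (preprocess) record <- preprocess_record(record)
  fs <- record$fs
  ref_lead <- if ("I" %in% colnames(record$signals)) "I" else colnames(record$signals)[1]
  r_idx <- detect_qrs(record$signals[, ref_lead, drop = FALSE], fs)

  rows <- list()
  for (L in leads) {
    x <- record$signals[, L]
    for (b in seq_along(r_idx)) {
      qres <- detect_q_onset(x, r_idx[b], fs)
      if (is.null(qres)) next
      p <- detect_p_peak(x, qres$q, fs)
      rows[[length(rows) + 1L]] <- data.frame(
        lead = L, beat = b, r_idx = r_idx[b], q_idx = qres$q,
        p_idx = p, stringsAsFactors = FALSE)
    }
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(lead = character(), beat = integer(), r_idx = integer(),
               q_idx = integer(), p_idx = integer())
  structure(list(r_idx = r_idx, table = table, fs = fs,
                 record_id = record$record_id),
            class = "fiducials")
}

#' @export
print.fiducials <- function(x, ...) {
  cat("Fiducials for record", x$record_id, "\n")
  cat(sprintf("  %d beats, %d leads, fs = %g Hz\n", length(x$r_idx),
              length(unique(x$table$lead)), x$fs))
  cat(sprintf("  P-/f-peak detected in %.1f%% of beat-lead pairs\n",
              100 * mean(!is.na(x$table$p_idx))))
  invisible(x)
}
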