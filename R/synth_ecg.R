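# Synthetic 12-lead ECG generation with exact ground-truth fiducials.
#
# Sinus beats are built from Gaussian P/Q/S/T components and a sharp Gaussian
# R-wave; AF records drop the P-wave entirely and superimpose a continuous
# low-amplitude 4-9 Hz fibrillatory oscillation, with faster and far more
# irregular RR intervals. Chest-lead morphology reuses the limb-lead template
# with amplitude scaling; realistic precordial progression is not attempted.

# Per-lead amplitude scale of the QRS/T template and P-wave polarity,
# following the classic sinus P pattern: positive in I, II, aVF (and most
# chest leads), negative in aVR, small/variable in aVL and V1.
.lead_r_scale <- c(I = 0.9, II = 1.1, III = 0.6, aVR = -0.9, aVL = 0.5,
                   aVF = 1.0, V1 = 0.7, V2 = 1.4, V3 = 1.5, V4 = 1.3,
                   V5 = 1.1, V6 = 0.9)
.lead_p_polarity <- c(I = 1, II = 1, III = 0.6, aVR = -1, aVL = -0.4,
                      aVF = 1, V1 = 0.5, V2 = 0.8, V3 = 0.8, V4 = 0.8,
                      V5 = 0.8, V6 = 0.8)

# The ventricular deflection of the template is the R-wave Gaussian (sigma
# 9 ms): the waveform leaves the isoelectric line ~3 sigma before the apex,
# which defines the analytic ground-truth QRS onset.
.QRS_ONSET_MS <- 27

#' Configuration for one synthetic ECG record
#'
#' @param rhythm `"SINUS"` or `"AF"`.
#' @param hr_mean Mean heart rate in bpm. Default 70 for sinus, 100 for AF
#'   (AF presents a faster ventricular response).
#' @param rr_cv Coefficient of variation of the RR intervals. Default 0.03
#'   for sinus (low variability), 0.25 for AF.
#' @param p_amp P-wave apex amplitude in mV before per-lead polarity scaling;
#'   forced to 0 for AF (absent P-waves).
#' @param pq_interval_ms Interval from P apex to QRS onset in ms (sinus only).
#' @param f_wave List with `freq` (two component frequencies in Hz, drawn
#'   uniformly from 4-9 Hz when `NULL`) and `amp` (total amplitude in mV);
#'   amplitude forced to 0 for sinus.
#' @param noise List with `baseline` (slow-drift amplitude, mV), `mains`
#'   (power-line amplitude, mV) and `emg` (white-noise RMS, mV).
#' @param duration_s Record length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed making the record bit-reproducible.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(rhythm = c("SINUS", "AF"),
                         hr_mean = NULL, rr_cv = NULL,
                         p_amp = 0.15, pq_interval_ms = 160,
                         f_wave = list(freq = NULL, amp = 0.06),
                         noise = list(baseline = 0.02, mains = 0.01, emg = 0.004),
                         duration_s = 20, fs = 500, seed = 1L) {
  rhythm <- match.arg(rhythm)
  if (is.null(hr_mean)) hr_mean <- if (rhythm == "AF") 100 else 70
  if (is.null(rr_cv)) rr_cv <- if (rhythm == "AF") 0.25 else 0.03
  if (rhythm == "AF") p_amp <- 0 else f_wave$amp <- 0
  cfg <- list(rhythm = rhythm, hr_mean = hr_mean, rr_cv = rr_cv,
              p_amp = p_amp, pq_interval_ms = pq_interval_ms,
              f_wave = f_wave, noise = noise,
              duration_s = duration_s, fs = fs, seed = as.integer(seed))
  if (cfg$rr_cv < 0) stop("rr_cv must be >= 0")
  if (cfg$rhythm == "SINUS" && cfg$f_wave$amp != 0)
    stop("SINUS records must have zero f-wave amplitude")
  if (cfg$rhythm == "AF" && cfg$p_amp != 0)
    stop("AF records must have zero P amplitude")
  class(cfg) <- "synth_config"
  cfg
}

# Add a Gaussian component (centre in samples, sigma in ms) to a signal.
.add_gauss <- function(x, center, sigma_ms, amp, fs) {
  sigma <- sigma_ms * fs / 1000
  lo <- max(1L, as.integer(floor(center - 5 * sigma)))
  hi <- min(length(x), as.integer(ceiling(center + 5 * sigma)))
  if (lo > hi) return(x)
  idx <- lo:hi
  x[idx] <- x[idx] + amp * exp(-((idx - center)^2) / (2 * sigma^2))
  x
}

#' Generate one synthetic 12-lead ECG record with ground truth
#'
#' @param config A [synth_config()] object.
#' @param record_id,patient_id Identifiers stored in the record.
#' @return List with `record` (an `ecg_record`: `signals` matrix of mV with
#'   one column per lead, `fs`, `codes`, ids) and `truth` (per-beat R apex,
#'   QRS-onset and P-apex sample indices, 1-based; `p_idx` is `NA` for AF)
#'   plus the class label.
#' @export
generate_record <- function(config, record_id = "S0001", patient_id = record_id) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  fs <- config$fs
  n <- as.integer(round(config$duration_s * fs))
  leads <- ecg_leads()

  # RR train: log-normal with the requested mean and CV, truncated >= 250 ms
  rr_mean <- 60000 / config$hr_mean
  draw_rr <- function(k) {
    if (config$rr_cv < 1e-8) return(rep(rr_mean, k))
    sdlog <- sqrt(log(1 + config$rr_cv^2))
    meanlog <- log(rr_mean) - sdlog^2 / 2
    rr <- rlnorm(k, meanlog, sdlog)
    while (any(rr < 250)) rr[rr < 250] <- rlnorm(sum(rr < 250), meanlog, sdlog)
    rr
  }
  margin <- ms_to_samples(600, fs)
  r_ms <- 600
  r_centers <- numeric(0)
  repeat {
    r_idx <- ms_to_samples(r_ms, fs)
    if (r_idx > n - margin) break
    r_centers <- c(r_centers, r_idx)
    r_ms <- r_ms + draw_rr(1)
  }
  r_centers <- as.integer(r_centers)
  q_on <- r_centers - ms_to_samples(.QRS_ONSET_MS, fs)
  p_apex <- if (config$rhythm == "SINUS")
    q_on - ms_to_samples(config$pq_interval_ms, fs) else rep(NA_integer_, length(r_centers))

  # f-wave component frequencies/phases shared across leads
  f_freq <- config$f_wave$freq
  if (is.null(f_freq)) f_freq <- runif(2, 4, 9)
  f_phase <- runif(2, 0, 2 * pi)
  tt <- (seq_len(n) - 1) / fs

  signals <- matrix(0, nrow = n, ncol = length(leads),
                    dimnames = list(NULL, leads))
  for (L in leads) {
    s <- .lead_r_scale[[L]]
    x <- numeric(n)
    for (b in seq_along(r_centers)) {
      r <- r_centers[b]
      # QRS: sharp R upstroke from the isoelectric line, S dip, broad T-wave
      x <- .add_gauss(x, r, 9, 1.00 * s, fs)
      x <- .add_gauss(x, r + ms_to_samples(30, fs), 8, -0.25 * s, fs)
      x <- .add_gauss(x, r + ms_to_samples(250, fs), 55, 0.22 * s, fs)
      if (config$rhythm == "SINUS")
        x <- .add_gauss(x, p_apex[b], 22, config$p_amp * .lead_p_polarity[[L]], fs)
    }
    if (config$rhythm == "AF" && config$f_wave$amp > 0) {
      lead_scale <- runif(1, 0.8, 1.2)
      x <- x + lead_scale * config$f_wave$amp *
        (0.6 * sin(2 * pi * f_freq[1] * tt + f_phase[1]) +
         0.4 * sin(2 * pi * f_freq[2] * tt + f_phase[2]))
    }
    if (config$noise$baseline > 0)
      x <- x + config$noise$baseline * sin(2 * pi * runif(1, 0.15, 0.35) * tt +
                                           runif(1, 0, 2 * pi))
    if (config$noise$mains > 0)
      x <- x + config$noise$mains * sin(2 * pi * 50 * tt + runif(1, 0, 2 * pi))
    if (config$noise$emg > 0)
      x <- x + rnorm(n, sd = config$noise$emg)
    signals[, L] <- x
  }

  label <- if (config$rhythm == "AF") "AF" else "NON_AF"
  codes <- if (label == "AF") "164889003" else "426783006"
  record <- new_ecg_record(record_id = record_id, patient_id = patient_id,
                           signals = signals, fs = fs, codes = codes)
  truth <- list(r_idx = r_centers, q_idx = q_on, p_idx = p_apex, label = label)
  list(record = record, truth = truth, config = config)
}

#' Generate a labelled synthetic dataset
#'
#' Per-record rhythm parameters are drawn from realistic ranges: sinus
#' records with 55-85 bpm, RR CV 0.01-0.06 and 0.10-0.20 mV P-waves with a
#' stable 140-180 ms PQ interval; AF records with 90-140 bpm, RR CV
#' 0.15-0.35 and 0.02-0.10 mV f-waves.
#'
#' @param n_records Number of records.
#' @param af_fraction Fraction of AF records in (0, 1).
#' @param seed Integer seed.
#' @param duration_s Record length in seconds (default 20).
#' @param out_dir Optional directory: when given, WFDB record pairs and a
#'   `manifest.csv` are written there.
#' @return List with `records` (list of [generate_record()] results) and
#'   `manifest` (data.frame: record_id, patient_id, label).
#' @export
generate_dataset <- function(n_records, af_fraction = 0.08, seed = 1L,
                             duration_s = 20, out_dir = NULL) {
  stopifnot(af_fraction > 0, af_fraction < 1, n_records >= 1)
  set.seed(seed)
  n_af <- as.integer(round(n_records * af_fraction))
  is_af <- rep(FALSE, n_records)
  is_af[sample.int(n_records, n_af)] <- TRUE
  rec_seeds <- sample.int(.Machine$integer.max - 1L, n_records)

  records <- vector("list", n_records)
  for (i in seq_len(n_records)) {
    set.seed(rec_seeds[i])
    cfg <- if (is_af[i]) {
      synth_config("AF", hr_mean = runif(1, 90, 140), rr_cv = runif(1, 0.15, 0.35),
                   f_wave = list(freq = NULL, amp = runif(1, 0.02, 0.10)),
                   duration_s = duration_s, seed = rec_seeds[i])
    } else {
      synth_config("SINUS", hr_mean = runif(1, 55, 85), rr_cv = runif(1, 0.01, 0.06),
                   p_amp = runif(1, 0.10, 0.20),
                   pq_interval_ms = runif(1, 140, 180),
                   duration_s = duration_s, seed = rec_seeds[i])
    }
    rid <- sprintf("S%04d", i)
    records[[i]] <- generate_record(cfg, record_id = rid,
                                    patient_id = sprintf("P%04d", i))
  }
  manifest <- data.frame(
    record_id = vapply(records, function(r) r$record$record_id, ""),
    patient_id = vapply(records, function(r) r$record$patient_id, ""),
    label = ifelse(is_af, "AF", "NON_AF"),
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (r in records) write_wfdb(r$record, out_dir)
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(records = records, manifest = manifest)
}
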