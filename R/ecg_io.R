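# Dataset ingestion: diagnosis-code mapping, resampling, directory scans and
# patient-wise stratified partitioning.

.AF_CODES <- c("164889003", "164890007")                 # AFIB, AFL
.EXCLUDE_CODES <- c("365413008", "251146004", "10370003") # poor R progression,
                                                          # low QRS voltage, pacing

#' Map SNOMED-CT diagnosis codes to the AF / non-AF / excluded class
#'
#' A record with no codes, or carrying any exclusion code (poor R-wave
#' progression, low QRS voltages, pacing rhythm), is `EXCLUDED`; exclusion
#' takes precedence over AF membership. Otherwise the presence of the AFIB
#' or AFL code makes it `AF`, and anything else `NON_AF`.
#'
#' @param codes Character vector (possibly empty) of SNOMED-CT code strings.
#' @return One of `"AF"`, `"NON_AF"`, `"EXCLUDED"`.
#' @export
map_codes_to_class <- function(codes) {
  codes <- as.character(codes)
  if (length(codes) == 0 || any(codes %in% .EXCLUDE_CODES)) return("EXCLUDED")
  if (any(codes %in% .AF_CODES)) return("AF")
  "NON_AF"
}

#' Resample a record to a target sampling rate
#'
#' Polyphase FIR resampling (via [signal::resample()]), which preserves wave
#' morphology better than linear interpolation for slope-based delineation.
#'
#' @param record An `ecg_record`.
#' @param target_fs Target rate in Hz (default 500).
#' @return The resampled `ecg_record`.
#' @export
resample_record <- function(record, target_fs = 500) {
  stopifnot(inherits(record, "ecg_record"), target_fs > 0)
  if (nrow(record$signals) == 0) stop("cannot resample an empty signal")
  if (record$fs == target_fs) return(record)
  frac <- .rat_approx(target_fs / record$fs)
  out <- apply(record$signals, 2, function(x) signal::resample(x, frac[1], frac[2]))
  record$signals <- out
  record$fs <- target_fs
  record$duration_s <- nrow(out) / target_fs
  record
}

# small continued-fraction rational approximation p/q of a positive ratio
.rat_approx <- function(r, max_den = 1000) {
  best <- c(1L, 1L); best_err <- Inf
  for (q in 1:max_den) {
    p <- round(r * q)
    if (p < 1) next
    err <- abs(r - p / q)
    if (err < best_err - 1e-15) { best <- c(as.integer(p), as.integer(q)); best_err <- err }
    if (best_err < 1e-12) break
  }
  best
}

#' Scan a directory of WFDB records into a labelled manifest
#'
#' @param data_dir Directory containing `.hea`/`.dat` pairs.
#' @param target_fs Records are resampled to this rate.
#' @return List with `records` (named list of `ecg_record`s, excluded and
#'   rejected records dropped) and `manifest` (record_id, patient_id, label
#'   for every readable record, including EXCLUDED ones).
#' @export
read_dataset <- function(data_dir, target_fs = 500) {
  heas <- sort(list.files(data_dir, pattern = "\\.hea$", full.names = TRUE))
  if (!length(heas)) stop("no WFDB headers found in ", data_dir)
  records <- list(); rows <- list()
  for (h in heas) {
    rec <- read_wfdb(h)
    if (is.null(rec)) next
    label <- map_codes_to_class(rec$codes)
    rows[[length(rows) + 1L]] <- data.frame(
      record_id = rec$record_id, patient_id = rec$patient_id,
      label = label, stringsAsFactors = FALSE)
    if (label != "EXCLUDED") {
      rec <- resample_record(rec, target_fs)
      records[[rec$record_id]] <- rec
    }
  }
  list(records = records, manifest = do.call(rbind, rows))
}

#' Patient-wise stratified train/validation/test partition
#'
#' Patients (not records) are allocated so that no patient appears in more
#' than one subset; allocation is stratified by the patient's majority class
#' label so the AF prevalence of every subset tracks the overall prevalence.
#'
#' @param manifest Data frame with columns record_id, patient_id, label
#'   (labels must be `"AF"` / `"NON_AF"`; excluded records must be dropped
#'   beforehand).
#' @param fractions Length-3 numeric summing to 1 (train, validation, test).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return The manifest with an added `subset` column
#'   (`"train"`/`"validation"`/`"test"`).
#' @export
partition_dataset <- function(manifest, fractions = c(0.7, 0.2, 0.1), seed = 1L) {
  stopifnot(all(c("record_id", "patient_id", "label") %in% names(manifest)))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (!all(manifest$label %in% c("AF", "NON_AF")))
    stop("manifest must contain only AF/NON_AF records")

  # majority label per patient (ties -> AF, the rarer class)
  pat <- split(manifest$label, manifest$patient_id)
  pat_label <- vapply(pat, function(l) {
    if (sum(l == "AF") * 2 >= length(l)) "AF" else "NON_AF"
  }, "")
  pat_n <- vapply(pat, length, 0L)

  set.seed(seed)
  assign_subset <- setNames(rep(NA_character_, length(pat)), names(pat))
  for (cls in c("AF", "NON_AF")) {
    ids <- names(pat_label)[pat_label == cls]
    if (!length(ids)) next
    ids <- sample(ids)
    n_rec <- cumsum(pat_n[ids])
    total <- n_rec[length(n_rec)]
    # cut points at 70% / 90% of this class's records, patient-block granular
    cut1 <- findInterval(fractions[1] * total, n_rec) + 1L
    cut2 <- findInterval((fractions[1] + fractions[2]) * total, n_rec) + 1L
    cut2 <- max(cut2, cut1 + 1L)
    subset <- rep("test", length(ids))
    subset[seq_len(min(cut1 - 1L, length(ids)))] <- "train"
    if (cut1 <= length(ids))
      subset[cut1:min(cut2 - 1L, length(ids))] <- "validation"
    assign_subset[ids] <- subset
  }
  manifest$subset <- assign_subset[manifest$patient_id]
  manifest
}
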