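# Minimal WFDB support: format-16 signal files (.dat, interleaved 16-bit
# little-endian integers) with a plain-text .hea header carrying CinC-style
# "Dx:" comment lines. This is enough to round-trip the package's own
# synthetic records and to parse CinC-2021 style headers.

#' Construct an ECG record container
#'
#' @param record_id,patient_id Identifiers.
#' @param signals Numeric matrix (samples x leads) in mV with lead names as
#'   column names, ordered canonically.
#' @param fs Sampling rate in Hz.
#' @param codes Character vector of SNOMED-CT diagnosis codes.
#' @param validate_duration Reject records shorter than 5 s or longer than
#'   144 s (the supported record-length range) when `TRUE`.
#' @return An object of class `ecg_record`.
#' @export
new_ecg_record <- function(record_id, signals, fs, codes = character(),
                           patient_id = record_id, validate_duration = TRUE) {
  stopifnot(is.matrix(signals), is.numeric(signals), fs > 0)
  if (is.null(colnames(signals))) stop("signals must carry lead names")
  duration_s <- nrow(signals) / fs
  if (validate_duration && (duration_s < 5 || duration_s > 144)) {
    warning("record ", record_id, " rejected: duration ", round(duration_s, 2),
            " s outside the supported 5-144 s range")
    return(NULL)
  }
  structure(list(record_id = record_id, patient_id = patient_id,
                 signals = signals, fs = fs, duration_s = duration_s,
                 codes = unique(as.character(codes))),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat("ECG record", x$record_id, "(patient", paste0(x$patient_id, ")"), "\n")
  cat(sprintf("  %d leads x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$signals), nrow(x$signals), x$fs, x$duration_s))
  cat("  leads:", paste(colnames(x$signals), collapse = ", "), "\n")
  cat("  Dx:", if (length(x$codes)) paste(x$codes, collapse = ",") else "(none)", "\n")
  invisible(x)
}

#' Write a record as a WFDB format-16 pair
#'
#' Amplitudes are stored as 16-bit integers at 1000 ADC units/mV.
#'
#' @param record An `ecg_record`.
#' @param dir Output directory.
#' @return Invisibly, the header path.
#' @export
write_wfdb <- function(record, dir) {
  stopifnot(inherits(record, "ecg_record"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gain <- 1000
  n <- nrow(record$signals)
  leads <- colnames(record$signals)
  dat_name <- paste0(record$record_id, ".dat")
  ints <- round(record$signals * gain)
  ints[ints > 32767] <- 32767; ints[ints < -32768] <- -32768
  # interleave samples: s1_lead1 s1_lead2 ... s2_lead1 ...
  con <- file(file.path(dir, dat_name), "wb")
  writeBin(as.integer(t(ints)), con, size = 2, endian = "little")
  close(con)
  hea <- c(
    sprintf("%s %d %g %d", record$record_id, length(leads), record$fs, n),
    sprintf("%s 16 %d/mV 16 0 %d 0 0 %s", dat_name, gain,
            as.integer(ints[1, ]), leads),
    sprintf("# Pid: %s", record$patient_id),
    sprintf("# Dx: %s", paste(record$codes, collapse = ","))
  )
  path <- file.path(dir, paste0(record$record_id, ".hea"))
  writeLines(hea, path)
  invisible(path)
}

#' Read a WFDB format-16 record pair
#'
#' Parses the header's first line (record name, lead count, sampling rate,
#' sample count), the per-signal lines (gain and lead name), and comment
#' lines. A `Dx:` comment supplies comma-separated SNOMED-CT codes (the
#' CinC-2021 convention); a `Pid:` comment supplies the patient id (falling
#' back to the record name); other comment lines are ignored.
#'
#' @param path Path to the `.hea` file (or the record stem).
#' @param validate_duration See [new_ecg_record()].
#' @return An `ecg_record`, or `NULL` if the duration check rejects it.
#' @export
read_wfdb <- function(path, validate_duration = TRUE) {
  if (!grepl("\\.hea$", path)) path <- paste0(path, ".hea")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  record_id <- top[1]
  n_sig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  sig_lines <- lines[2:(1 + n_sig)]
  comments <- grep("^\\s*#", lines, value = TRUE)

  parse_sig <- function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    gain <- suppressWarnings(as.numeric(sub("^([0-9.eE+-]+).*", "\\1", f[3])))
    if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default gain
    list(file = f[1], fmt = f[2], gain = gain, lead = f[length(f)])
  }
  sigs <- lapply(sig_lines, parse_sig)
  fmts <- unique(vapply(sigs, `[[`, "", "fmt"))
  if (!all(fmts %in% "16"))
    stop("unsupported WFDB signal format(s): ", paste(fmts, collapse = ", "),
         " (only format 16 is supported)")
  dat_files <- unique(vapply(sigs, `[[`, "", "file"))
  if (length(dat_files) != 1)
    stop("multi-file WFDB records are not supported")

  con <- file(file.path(dirname(path), dat_files), "rb")
  raw_ints <- readBin(con, "integer", n = n * n_sig, size = 2,
                      signed = TRUE, endian = "little")
  close(con)
  mat <- matrix(raw_ints, ncol = n_sig, byrow = TRUE)
  gains <- vapply(sigs, `[[`, 0, "gain")
  signals <- sweep(mat, 2, gains, "/")
  colnames(signals) <- vapply(sigs, `[[`, "", "lead")

  grab <- function(key) {
    m <- grep(paste0("^\\s*#\\s*", key, ":"), comments, value = TRUE)
    if (!length(m)) return(character())
    trimws(sub(paste0("^\\s*#\\s*", key, ":\\s*"), "", m[1]))
  }
  dx <- grab("Dx")
  codes <- if (length(dx) && nzchar(dx)) trimws(strsplit(dx, ",")[[1]]) else character()
  pid <- grab("Pid")
  if (!length(pid) || !nzchar(pid)) pid <- record_id

  new_ecg_record(record_id = record_id, patient_id = pid, signals = signals,
                 fs = fs, codes = codes, validate_duration = validate_duration)
}
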