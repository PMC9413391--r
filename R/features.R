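# The six AV-synchronization statistics: global RR-interval mean/std plus
# per-lead PQ-interval and PQ-amplitude mean/std, assembled into 6/26/50
# dimensional feature vectors for single / six-lead / twelve-lead input.

#' RR-interval statistics
#'
#' Mean and sample standard deviation (n-1 denominator) of the distances
#' between consecutive R fiducials, in ms. These are global features: the R
#' train comes from the reference lead.
#'
#' @param r_idx Integer vector of R fiducial sample indices.
#' @param fs Sampling rate in Hz.
#' @return Named numeric: `RRi_mean`, `RRi_std` (ms).
#' @export
compute_rr_features <- function(r_idx, fs = 500) {
  if (length(r_idx) < 3)
    stop("record rejected: fewer than 3 R fiducials (", length(r_idx), ")")
  rr <- diff(r_idx) / fs * 1000
  c(RRi_mean = mean(rr), RRi_std = sd(rr))
}

#' Per-lead PQ-interval and PQ-amplitude statistics
#'
#' For each beat with a detected P-/f-peak, the PQ interval is the time from
#' the peak to the subsequent QRS onset (ms) and the PQ amplitude is the
#' signed amplitude difference between the peak and the QRS onset (mV).
#' Beats without a detected peak are excluded from the statistics. A lead
#' with no detected peaks at all returns `NA` for all four statistics (to be
#' imputed downstream); a lead with a single detected peak reports std = 0.
#'
#' @param q_idx,p_idx Integer vectors of per-beat QRS-onset and peak indices
#'   (`p_idx` may contain `NA`).
#' @param x The lead's signal in mV (the one delineation ran on).
#' @param fs Sampling rate in Hz.
#' @return Named numeric: `PQi_mean`, `PQi_std` (ms), `PQa_mean`, `PQa_std`
#'   (mV).
#' @export
compute_pq_features <- function(q_idx, p_idx, x, fs = 500) {
  keep <- !is.na(p_idx)
  out <- c(PQi_mean = NA_real_, PQi_std = NA_real_,
           PQa_mean = NA_real_, PQa_std = NA_real_)
  if (!any(keep)) return(out)
  q <- q_idx[keep]; p <- p_idx[keep]
  pqi <- (q - p) / fs * 1000
  pqa <- x[p] - x[q]
  out["PQi_mean"] <- mean(pqi)
  out["PQa_mean"] <- mean(pqa)
  if (length(pqi) >= 2) {
    out["PQi_std"] <- sd(pqi)
    out["PQa_std"] <- sd(pqa)
  } else {
    message("single PQ measurement on this lead; std set to 0")
    out["PQi_std"] <- 0
    out["PQa_std"] <- 0
  }
  out
}

#' Feature names of a lead set, in canonical order
#'
#' Ordering: `RRi_mean`, `RRi_std`, then for each lead of the set in
#' canonical order the block `PQi_mean`, `PQi_std`, `PQa_mean`, `PQa_std`.
#'
#' @inheritParams lead_set_leads
#' @return Character vector of length 2 + 4 x n_leads.
#' @export
feature_names <- function(lead_set = "twelve") {
  leads <- lead_set_leads(lead_set)
  c("RRi_mean", "RRi_std",
    as.vector(t(outer(leads, c("PQi_mean", "PQi_std", "PQa_mean", "PQa_std"),
                      function(l, f) paste(f, l, sep = "_")))))
}

#' Assemble a lead-set feature vector
#'
#' @param rr Named numeric from [compute_rr_features()].
#' @param pq_by_lead Named list: per lead, the output of
#'   [compute_pq_features()].
#' @inheritParams lead_set_leads
#' @return Named numeric of dimension 2 + 4 x n_leads (6 / 26 / 50).
#' @export
assemble_feature_vector <- function(rr, pq_by_lead, lead_set = "twelve") {
  leads <- lead_set_leads(lead_set)
  missing <- setdiff(leads, names(pq_by_lead))
  if (length(missing))
    stop("missing required lead(s): ", paste(missing, collapse = ", "))
  v <- c(rr[c("RRi_mean", "RRi_std")],
         unlist(lapply(leads, function(L)
           pq_by_lead[[L]][c("PQi_mean", "PQi_std", "PQa_mean", "PQa_std")])))
  names(v) <- feature_names(lead_set)
  stopifnot(length(v) == 2 + 4 * length(leads))
  v
}

#' Extract the feature vector of one record
#'
#' Runs (optionally) the preprocessing chain and delineation, then computes
#' the RR and per-lead PQ statistics.
#'
#' @param record An `ecg_record`.
#' @inheritParams lead_set_leads
#' @param fiducials Optional precomputed [delineate_record()] result.
#' @param preprocess Passed to [delineate_record()].
#' @return Named numeric feature vector (may contain `NA` for leads with no
#'   detected atrial peaks).
#' @export
extract_features <- function(record, lead_set = "twelve", fiducials = NULL,
                             preprocess = TRUE) {
  leads <- lead_set_leads(lead_set)
  filtered <- if (preprocess) preprocess_record(record) else record
  if (is.null(fiducials))
    fiducials <- delineate_record(filtered, leads = leads, preprocess = FALSE)
  rr <- compute_rr_features(fiducials$r_idx, fiducials$fs)
  pq <- lapply(leads, function(L) {
    tab <- fiducials$table[fiducials$table$lead == L, ]
    compute_pq_features(tab$q_idx, tab$p_idx, filtered$signals[, L], fiducials$fs)
  })
  names(pq) <- leads
  assemble_feature_vector(rr, pq, lead_set)
}

#' Extract a feature matrix for a list of records
#'
#' Records with fewer than three detectable R fiducials are rejected (with a
#' message) and listed in `rejected`.
#'
#' @param records List of `ecg_record`s (as from [generate_dataset()]'s
#'   `records` element, either the raw records or the wrapped list).
#' @inheritParams lead_set_leads
#' @return List with `features` (data.frame, rows named by record id) and
#'   `rejected` (character vector of record ids).
#' @export
extract_features_dataset <- function(records, lead_set = "twelve") {
  rows <- list(); rejected <- character()
  for (item in records) {
    rec <- if (inherits(item, "ecg_record")) item else item$record
    fv <- tryCatch(extract_features(rec, lead_set = lead_set),
                   error = function(e) {
                     message("record ", rec$record_id, " rejected: ",
                             conditionMessage(e))
                     NULL
                   })
    if (is.null(fv)) rejected <- c(rejected, rec$record_id)
    else rows[[rec$record_id]] <- fv
  }
  features <- as.data.frame(do.call(rbind, rows))
  list(features = features, rejected = rejected)
}
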