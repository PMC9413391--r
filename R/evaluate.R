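# Confusion-matrix metrics and operating-point selection at maximal
# validation balanced accuracy.

#' Confusion counts for AF/non-AF predictions
#'
#' @param pred,truth Character vectors of `"AF"` / `"NON_AF"`.
#' @return Named list with `tp`, `fn`, `tn`, `fp` (AF is the positive
#'   class).
#' @export
confusion_counts <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  list(tp = sum(pred == "AF" & truth == "AF"),
       fn = sum(pred == "NON_AF" & truth == "AF"),
       tn = sum(pred == "NON_AF" & truth == "NON_AF"),
       fp = sum(pred == "AF" & truth == "NON_AF"))
}

#' Benchmark metrics from confusion counts
#'
#' Se = 100 TP/(TP+FN), Sp = 100 TN/(TN+FP), BAC = (Se+Sp)/2 (percent) and
#' F1 = 2TP/(2TP+FN+FP) (unitless).
#'
#' @param counts List with `tp`, `fn`, `tn`, `fp`, or the `tp` count when
#'   the four counts are given separately.
#' @param fn,tn,fp Remaining counts when given separately.
#' @return List with `se`, `sp`, `bac` (percent) and `f1`.
#' @export
compute_metrics <- function(counts, fn = NULL, tn = NULL, fp = NULL) {
  if (is.list(counts)) {
    tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  } else tp <- counts
  if (tp + fn == 0) stop("no AF cases: sensitivity undefined")
  if (tn + fp == 0) stop("no non-AF cases: specificity undefined")
  se <- 100 * tp / (tp + fn)
  sp <- 100 * tn / (tn + fp)
  list(se = se, sp = sp, bac = (se + sp) / 2, f1 = 2 * tp / (2 * tp + fn + fp))
}

#' Select the probability threshold maximizing balanced accuracy
#'
#' Candidate thresholds are the midpoints between consecutive sorted
#' distinct probabilities plus 0 and 1; a record is called AF when its
#' probability exceeds the threshold. Among thresholds achieving the
#' maximal BAC the smallest is returned (maximizing sensitivity among the
#' BAC-optimal operating points).
#'
#' @param probs Predicted AF probabilities on the validation set.
#' @param labels Binary labels (1 = AF) or `"AF"`/`"NON_AF"`.
#' @return The selected threshold in `[0, 1]`.
#' @export
select_threshold <- function(probs, labels) {
  y <- .encode_labels(labels)
  if (length(unique(y)) < 2) stop("both classes required to select a threshold")
  u <- sort(unique(probs))
  cand <- unique(c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1))
  bac <- vapply(cand, function(thr) {
    pred <- probs > thr
    se <- sum(pred & y == 1) / sum(y == 1)
    sp <- sum(!pred & y == 0) / sum(y == 0)
    (se + sp) / 2
  }, 0)
  cand[which(bac == max(bac))[1]]  # candidates ascend, so first = smallest
}

#' Evaluate a trained model on a test set
#'
#' Thresholded predictions at the model's stored operating point, with
#' aggregated and (optionally) per-stratum confusion counts and metrics.
#'
#' @param model An `af_densenet` fit carrying `p_thr`.
#' @param x Test features.
#' @param labels Test labels.
#' @param strata Optional factor of source-dataset strata per record.
#' @return Data frame with columns stratum, tp, fn, tn, fp, se, sp, bac, f1
#'   (the `"Total"` row aggregates everything).
#' @export
evaluate_model <- function(model, x, labels, strata = NULL) {
  pred <- predict(model, x, type = "class")
  truth <- ifelse(.encode_labels(labels) == 1, "AF", "NON_AF")
  one <- function(sel, name) {
    cm <- confusion_counts(pred[sel], truth[sel])
    m <- compute_metrics(cm)
    data.frame(stratum = name, tp = cm$tp, fn = cm$fn, tn = cm$tn, fp = cm$fp,
               se = m$se, sp = m$sp, bac = m$bac, f1 = m$f1,
               stringsAsFactors = FALSE)
  }
  out <- list()
  if (!is.null(strata)) {
    for (s in unique(as.character(strata)))
      out[[s]] <- tryCatch(one(strata == s, s), error = function(e) NULL)
  }
  out$Total <- one(rep(TRUE, length(pred)), "Total")
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}
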