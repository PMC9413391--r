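# Shapley-value feature attribution for the dense classifier: exact subset
# enumeration for small feature maps, permutation sampling for the 26/50
# dimensional lead-set models, and the global mean-|SHAP| / percent-of-max
# report.

#' Coalition value function (marginal expectation over a background)
#'
#' Features inside the coalition `S` are fixed at the explained record's
#' values; features outside `S` take each background row's values in turn;
#' the value is the mean model output over the background rows.
#'
#' @param model An `af_densenet` fit.
#' @param x Named numeric feature vector of the record being explained.
#' @param S Integer or character indices of the coalition (may be empty).
#' @param background Feature matrix (rows = background records).
#' @return Scalar expected model output.
#' @export
value_function <- function(model, x, S, background) {
  background <- .prepare_x(background, model$feature_names,
                           model$imputation_means)
  if (nrow(background) == 0) stop("background must be non-empty")
  x <- .prepare_x(matrix(x, nrow = 1, dimnames = list(NULL, names(x))),
                  model$feature_names, model$imputation_means)
  if (is.character(S)) S <- match(S, model$feature_names)
  mat <- background
  if (length(S)) mat[, S] <- matrix(x[1, S], nrow(mat), length(S), byrow = TRUE)
  mean(.forward(model$params, mat, training = FALSE)$p)
}

#' Exact Shapley values by subset enumeration
#'
#' The Shapley attribution of feature i is the average marginal contribution
#' of i over all coalitions S not containing i, weighted by
#' `|S|! (M - |S| - 1)! / M!`. Exact enumeration over the 2^M coalitions is
#' supported up to M = 15 features; larger feature maps must use
#' [shapley_sampled()]. Efficiency (attributions sum to f(x) minus the base
#' value), symmetry and dummy axioms hold by construction.
#'
#' @inheritParams value_function
#' @return Named numeric of per-feature SHAP values (probability units) with
#'   attribute `base_value`.
#' @export
shapley_exact <- function(model, x, background) {
  M <- length(model$feature_names)
  if (M > 15)
    stop("exact enumeration supports at most 15 features; use shapley_sampled()")
  background <- .prepare_x(background, model$feature_names,
                           model$imputation_means)
  xm <- .prepare_x(matrix(x, nrow = 1, dimnames = list(NULL, names(x))),
                   model$feature_names, model$imputation_means)
  nbg <- nrow(background)

  # value of every coalition, coded as a bitmask
  n_masks <- bitwShiftL(1L, M)
  vals <- numeric(n_masks)
  for (mask in 0:(n_masks - 1L)) {
    S <- which(bitwAnd(mask, bitwShiftL(1L, 0:(M - 1L))) != 0L)
    mat <- background
    if (length(S)) mat[, S] <- matrix(xm[1, S], nbg, length(S), byrow = TRUE)
    vals[mask + 1L] <- mean(.forward(model$params, mat, training = FALSE)$p)
  }

  wts <- vapply(0:(M - 1L), function(s)
    exp(lfactorial(s) + lfactorial(M - s - 1L) - lfactorial(M)), 0)
  shap <- numeric(M)
  for (i in seq_len(M)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (mask in 0:(n_masks - 1L)) {
      if (bitwAnd(mask, bit) != 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, 0:(M - 1L))) != 0L)
      shap[i] <- shap[i] + wts[s + 1L] * (vals[mask + bit + 1L] - vals[mask + 1L])
    }
  }
  names(shap) <- model$feature_names
  attr(shap, "base_value") <- vals[1L]
  shap
}

#' Sampled Shapley values by permutation walks
#'
#' Unbiased permutation-sampling estimator: for each sampled feature
#' ordering, features are switched from background to the record's values
#' one at a time and the successive value differences are credited to the
#' switched feature. Because each permutation's contributions telescope,
#' the estimates sum exactly to f(x) minus the base value.
#'
#' @inheritParams value_function
#' @param n_permutations Number of sampled orderings (at least 100).
#' @param seed Integer seed; estimates are deterministic given the seed.
#' @return Named numeric of SHAP estimates with attributes `base_value` and
#'   `se` (per-feature Monte-Carlo standard errors).
#' @export
shapley_sampled <- function(model, x, background, n_permutations = 2000,
                            seed = 1L) {
  if (n_permutations < 100) stop("use at least 100 permutations")
  background <- .prepare_x(background, model$feature_names,
                           model$imputation_means)
  xm <- .prepare_x(matrix(x, nrow = 1, dimnames = list(NULL, names(x))),
                   model$feature_names, model$imputation_means)
  M <- length(model$feature_names)
  nbg <- nrow(background)
  set.seed(seed)

  base_value <- mean(.forward(model$params, background, training = FALSE)$p)
  contrib <- matrix(0, n_permutations, M)
  for (k in seq_len(n_permutations)) {
    ord <- sample.int(M)
    # block j = background with the first j features (in this order) fixed
    big <- background[rep(seq_len(nbg), M), , drop = FALSE]
    mat <- background
    for (j in seq_len(M)) {
      mat[, ord[j]] <- xm[1, ord[j]]
      big[((j - 1L) * nbg + 1L):(j * nbg), ] <- mat
    }
    p <- .forward(model$params, big, training = FALSE)$p
    vals <- colMeans(matrix(p, nrow = nbg))
    contrib[k, ord] <- diff(c(base_value, vals))
  }
  shap <- colMeans(contrib)
  names(shap) <- model$feature_names
  attr(shap, "base_value") <- base_value
  attr(shap, "se") <- apply(contrib, 2, sd) / sqrt(n_permutations)
  shap
}

#' Global SHAP importance over a dataset
#'
#' The global importance of a feature is the mean of its absolute SHAP
#' values over the records; percent-of-max scales each importance relative
#' to the largest one (rounded to integer percent for reporting).
#'
#' @param shap_matrix Numeric matrix of per-record SHAP values (rows =
#'   records, columns = features).
#' @return List with `global` (named numeric) and `percent_of_max` (named
#'   integer percents; the top feature is 100).
#' @export
shap_global <- function(shap_matrix) {
  shap_matrix <- as.matrix(shap_matrix)
  if (!nrow(shap_matrix)) stop("need at least one record")
  g <- colMeans(abs(shap_matrix))
  list(global = g, percent_of_max = round(100 * g / max(g)))
}

#' Ranked feature-importance report
#'
#' Flags features whose global importance exceeds a fraction of the maximal
#' importance (default 25%), and aggregates the PQ features per lead and per
#' feature family (mean and min-max across the group). RR features are
#' global (not lead-specific) and are excluded from the per-lead summary.
#'
#' @param global Named numeric of global importances (from [shap_global()]).
#' @param threshold_fraction Fraction of the maximum used as the cut
#'   (default 0.25).
#' @return List with `ranked` (data.frame: feature, global, percent_of_max,
#'   flagged), `threshold`, `by_lead` and `by_family` summaries.
#' @export
rank_report <- function(global, threshold_fraction = 0.25) {
  thr <- threshold_fraction * max(global)
  pom <- round(100 * global / max(global))
  ranked <- data.frame(feature = names(global), global = as.numeric(global),
                       percent_of_max = as.integer(pom),
                       flagged = as.numeric(global) >= thr,
                       stringsAsFactors = FALSE)
  ranked <- ranked[order(-ranked$global), ]
  rownames(ranked) <- NULL

  is_pq <- grepl("^PQ", names(global))
  fam <- sub("^(PQ[ia]_(mean|std))_.*$", "\\1", names(global)[is_pq])
  lead <- sub("^PQ[ia]_(mean|std)_", "", names(global)[is_pq])
  agg <- function(key) {
    vals <- split(as.numeric(global)[is_pq], key)
    data.frame(group = names(vals),
               mean = vapply(vals, mean, 0),
               min = vapply(vals, min, 0),
               max = vapply(vals, max, 0),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  by_lead <- agg(lead); by_family <- agg(fam)
  by_lead <- by_lead[order(-by_lead$mean), ]
  by_family <- by_family[order(-by_family$mean), ]
  list(ranked = ranked, threshold = thr,
       by_lead = by_lead, by_family = by_family)
}

#' Explain a model over a dataset
#'
#' Computes per-record SHAP values (exact when the feature map has at most
#' 15 features, sampled otherwise), the global mean-|SHAP| importance and
#' the ranked report.
#'
#' @param model An `af_densenet` fit.
#' @param x Feature matrix of the records to explain.
#' @param background Background feature matrix (e.g. 100 seeded training
#'   records).
#' @param n_permutations Permutations for the sampled estimator.
#' @param seed Integer seed.
#' @return List of class `shap_report`: `shap` (records x features),
#'   `base_value`, `global`, `percent_of_max`, `report`.
#' @export
explain_model <- function(model, x, background, n_permutations = 2000,
                          seed = 1L) {
  X <- .prepare_x(x, model$feature_names, model$imputation_means)
  M <- length(model$feature_names)
  shap <- matrix(0, nrow(X), M, dimnames = list(rownames(X), model$feature_names))
  base_value <- NA_real_
  for (r in seq_len(nrow(X))) {
    s <- if (M <= 15) shapley_exact(model, X[r, ], background)
         else shapley_sampled(model, X[r, ], background,
                              n_permutations = n_permutations,
                              seed = (seed + r) %% .Machine$integer.max)
    shap[r, ] <- s
    base_value <- attr(s, "base_value")
  }
  g <- shap_global(shap)
  structure(list(shap = shap, base_value = base_value, global = g$global,
                 percent_of_max = g$percent_of_max,
                 report = rank_report(g$global)),
            class = "shap_report")
}

#' @export
print.shap_report <- function(x, ...) {
  cat("SHAP feature-importance report (", nrow(x$shap), " records)\n", sep = "")
  cat(sprintf("  base value: %.4f\n", x$base_value))
  top <- head(x$report$ranked, 10)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-16s %.5f (%d%%)%s\n", top$feature[i], top$global[i],
                top$percent_of_max[i], if (top$flagged[i]) " *" else ""))
  invisible(x)
}
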