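# Shrinking dense neural network classifier: batch-normalized input, one to
# three non-increasing ReLU hidden layers with dropout, a single sigmoid
# output, trained by Adam on class-weighted binary cross-entropy with early
# stopping on the validation loss.

#' Enumerate all feasible shrinking architectures
#'
#' All non-increasing sequences of 1-3 hidden-layer widths drawn from
#' `width_options` (a later layer may never be wider than its predecessor).
#' The count is the multiset formula sum over depth k of C(m + k - 1, k) for
#' m options: 19 for 3 options, 55 for 5, 83 for 6.
#'
#' @param width_options Strictly increasing positive integers.
#' @return List of integer vectors in a deterministic order (by depth, then
#'   lexicographically).
#' @export
enumerate_architectures <- function(width_options) {
  if (!length(width_options)) stop("width_options must be non-empty")
  w <- as.integer(width_options)
  if (any(w <= 0) || is.unsorted(w, strictly = TRUE))
    stop("width_options must be strictly increasing positive integers")
  out <- list()
  for (k in 1:3) {
    grid <- do.call(expand.grid, rep(list(w), k))
    keep <- apply(grid, 1, function(r) all(diff(r) <= 0))
    rows <- grid[keep, , drop = FALSE]
    rows <- rows[do.call(order, as.list(rows)), , drop = FALSE]
    out <- c(out, lapply(seq_len(nrow(rows)), function(i) as.integer(rows[i, ])))
  }
  out
}

#' Class weights from AF prevalence
#'
#' Weights are the reciprocal of the class prevalence, normalized to sum to
#' one: with 8% AF the weights are (w_AF, w_nonAF) = (0.92, 0.08), so the
#' minority class carries the larger penalty.
#'
#' @param prevalence_af Fraction of AF samples in (0, 1).
#' @return Named numeric `c(AF = ..., NON_AF = ...)` summing to 1.
#' @export
class_weights_from_prevalence <- function(prevalence_af) {
  stopifnot(prevalence_af > 0, prevalence_af < 1)
  c(AF = 1 - prevalence_af, NON_AF = prevalence_af)
}

#' Class-weighted binary cross-entropy
#'
#' `Loss = -(1/N) sum_n [ d_n w_AF log p_n + (1 - d_n) w_nonAF log(1 - p_n) ]`
#' where `d_n` indicates AF membership. Probabilities are clipped to
#' `[eps, 1 - eps]` before taking logarithms.
#'
#' @param probs Predicted AF probabilities.
#' @param labels Binary labels (1 = AF).
#' @param class_weights Named numeric `c(AF=, NON_AF=)` summing to 1.
#' @param eps Clipping bound (default 1e-7).
#' @return Nonnegative scalar loss.
#' @export
weighted_bce_loss <- function(probs, labels,
                              class_weights = c(AF = 0.92, NON_AF = 0.08),
                              eps = 1e-7) {
  if (length(probs) != length(labels)) stop("probs and labels length mismatch")
  p <- pmin(pmax(probs, eps), 1 - eps)
  y <- as.numeric(labels)
  -mean(y * class_weights[["AF"]] * log(p) +
        (1 - y) * class_weights[["NON_AF"]] * log(1 - p))
}

# ---- internal network plumbing ---------------------------------------------

.encode_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("AF", "NON_AF"))
    if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
    return(as.numeric(y == "AF"))
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
  y
}

.init_params <- function(input_dim, widths, seed, init_bound = 0.05) {
  set.seed(seed)
  dims <- c(input_dim, widths, 1L)
  layers <- lapply(seq_len(length(dims) - 1L), function(i) {
    list(W = matrix(runif(dims[i + 1] * dims[i], -init_bound, init_bound),
                    nrow = dims[i + 1]),
         b = rep(0, dims[i + 1]))
  })
  list(bn = list(gamma = rep(1, input_dim), beta = rep(0, input_dim),
                 run_mean = rep(0, input_dim), run_var = rep(1, input_dim)),
       layers = layers)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# forward pass; training mode uses batch statistics + dropout masks
.forward <- function(params, X, training = FALSE, dropout = 0, bn_eps = 1e-3) {
  cache <- list()
  if (training) {
    mu <- colMeans(X)
    v <- colMeans(sweep(X, 2, mu)^2)
  } else {
    mu <- params$bn$run_mean
    v <- params$bn$run_var
  }
  xhat <- sweep(sweep(X, 2, mu), 2, sqrt(v + bn_eps), "/")
  h <- sweep(sweep(xhat, 2, params$bn$gamma, "*"), 2, params$bn$beta, "+")
  cache$xhat <- xhat; cache$mu <- mu; cache$v <- v
  cache$h <- list(h)
  cache$mask <- list()
  nl <- length(params$layers)
  for (i in seq_len(nl - 1L)) {
    a <- h %*% t(params$layers[[i]]$W)
    a <- sweep(a, 2, params$layers[[i]]$b, "+")
    h <- pmax(a, 0)
    if (training && dropout > 0) {
      mask <- matrix(rbinom(length(h), 1, 1 - dropout), nrow = nrow(h)) / (1 - dropout)
      h <- h * mask
      cache$mask[[i]] <- mask
    }
    cache$h[[i + 1L]] <- h
  }
  z <- as.numeric(h %*% t(params$layers[[nl]]$W) + params$layers[[nl]]$b)
  cache$z <- z
  cache$p <- .sigmoid(z)
  cache
}

.backward <- function(params, X, cache, y, sample_w, dropout) {
  nl <- length(params$layers)
  N <- nrow(X)
  grads <- list(layers = vector("list", nl))
  dz <- matrix(sample_w * (cache$p - y) / N, ncol = 1)     # N x 1
  dh <- dz %*% params$layers[[nl]]$W                        # N x width
  grads$layers[[nl]] <- list(W = t(dz) %*% cache$h[[nl]], b = sum(dz))
  for (i in rev(seq_len(nl - 1L))) {
    h_out <- cache$h[[i + 1L]]
    da <- dh
    if (dropout > 0 && length(cache$mask) >= i && !is.null(cache$mask[[i]]))
      da <- da * cache$mask[[i]]
    da <- da * (h_out > 0)
    grads$layers[[i]] <- list(W = t(da) %*% cache$h[[i]], b = colSums(da))
    dh <- da %*% params$layers[[i]]$W
  }
  grads$bn <- list(gamma = colSums(dh * cache$xhat), beta = colSums(dh))
  grads
}

# flatten/unflatten parameters for a generic Adam update
.adam_step <- function(state, params, grads, lr, beta1, beta2, eps = 1e-8) {
  upd <- function(name, theta, g) {
    if (is.null(state$m[[name]])) {
      state$m[[name]] <<- theta * 0
      state$v[[name]] <<- theta * 0
    }
    state$m[[name]] <<- beta1 * state$m[[name]] + (1 - beta1) * g
    state$v[[name]] <<- beta2 * state$v[[name]] + (1 - beta2) * g^2
    mhat <- state$m[[name]] / (1 - beta1^state$t)
    vhat <- state$v[[name]] / (1 - beta2^state$t)
    theta - lr * mhat / (sqrt(vhat) + eps)
  }
  state$t <- state$t + 1L
  params$bn$gamma <- upd("bn.g", params$bn$gamma, grads$bn$gamma)
  params$bn$beta <- upd("bn.b", params$bn$beta, grads$bn$beta)
  for (i in seq_along(params$layers)) {
    params$layers[[i]]$W <- upd(paste0("W", i), params$layers[[i]]$W,
                                grads$layers[[i]]$W)
    params$layers[[i]]$b <- upd(paste0("b", i), params$layers[[i]]$b,
                                grads$layers[[i]]$b)
  }
  list(state = state, params = params)
}

.prepare_x <- function(x, feature_names = NULL, imputation_means = NULL) {
  X <- as.matrix(x)
  storage.mode(X) <- "double"
  if (!is.null(feature_names)) {
    if (!all(feature_names %in% colnames(X)))
      stop("newdata lacks required feature columns")
    X <- X[, feature_names, drop = FALSE]
  }
  if (!is.null(imputation_means)) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- imputation_means[j]
    }
  } else if (anyNA(X)) stop("NA features and no imputation means available")
  X
}

# ---- fitting ----------------------------------------------------------------

#' Fit a shrinking dense neural network AF classifier
#'
#' Topology: input batch normalization, 1-3 non-increasing dense ReLU hidden
#' layers with dropout, one sigmoid output giving P(record is AF). Training
#' minimizes class-weighted binary cross-entropy with the Adam optimizer and
#' keeps the parameters at the epoch of minimal validation loss; training
#' stops after `max_epochs` or once the validation loss has not improved for
#' more than `patience` epochs. Missing features (leads with no detected
#' atrial peaks) are imputed with the training-set per-feature mean, which is
#' stored in the model. After training, the output probability threshold is
#' set at the validation ROC operating point of maximal balanced accuracy.
#'
#' @param x Numeric matrix or data.frame of features (rows = records), or a
#'   formula.
#' @param y Labels: `"AF"`/`"NON_AF"`, factor, or 0/1 (1 = AF).
#' @param hidden Integer vector of 1-3 non-increasing hidden-layer widths.
#' @param x_val,y_val Validation set; when omitted, a stratified 80/20 split
#'   of the training data is used.
#' @param lr,beta1,beta2 Adam learning rate and moment decay rates.
#' @param max_epochs Maximum training epochs (default 400).
#' @param patience Early-stopping patience in epochs (default 10; training
#'   halts on the 11th non-improving epoch).
#' @param dropout Dropout rate after each hidden layer (default 0.3).
#' @param class_weights Named `c(AF=, NON_AF=)` summing to 1; when `NULL`,
#'   derived from the training prevalence via
#'   [class_weights_from_prevalence()].
#' @param batch_size Mini-batch size (default 32, keeping enough gradient
#'   steps per epoch for early stopping to be meaningful at small n; any
#'   value up to the training-set size is accepted).
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @param data,... Formula-method data and shared arguments.
#' @return Object of class `af_densenet`.
#' @export
af_densenet <- function(x, ...) UseMethod("af_densenet")

#' @rdname af_densenet
#' @export
af_densenet.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  feats <- mf[, -1, drop = FALSE]
  fit <- af_densenet.default(feats, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname af_densenet
#' @export
af_densenet.default <- function(x, y, hidden = c(16, 8),
                                x_val = NULL, y_val = NULL,
                                lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                                max_epochs = 400, patience = 10,
                                dropout = 0.3, class_weights = NULL,
                                batch_size = 32, seed = 1L, ...) {
  hidden <- as.integer(hidden)
  if (length(hidden) < 1 || length(hidden) > 3 || any(hidden <= 0))
    stop("hidden must hold 1-3 positive widths")
  if (any(diff(hidden) > 0))
    stop("architecture must shrink: a layer cannot be wider than its predecessor")

  X <- .prepare_x(x)
  feature_names <- colnames(X)
  y <- .encode_labels(y)
  if (length(unique(y)) < 2) stop("training set must contain both classes")

  imputation_means <- vapply(seq_len(ncol(X)), function(j)
    mean(X[, j], na.rm = TRUE), 0)
  names(imputation_means) <- feature_names
  X <- .prepare_x(X, feature_names, imputation_means)

  if (is.null(x_val)) {
    set.seed(seed)
    idx_af <- which(y == 1); idx_non <- which(y == 0)
    val_idx <- c(sample(idx_af, max(1L, round(0.2 * length(idx_af)))),
                 sample(idx_non, max(1L, round(0.2 * length(idx_non)))))
    Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx]
    X <- X[-val_idx, , drop = FALSE]; y <- y[-val_idx]
  } else {
    Xv <- .prepare_x(x_val, feature_names, imputation_means)
    yv <- .encode_labels(y_val)
  }
  if (is.null(class_weights))
    class_weights <- class_weights_from_prevalence(mean(y))
  stopifnot(abs(sum(class_weights) - 1) < 1e-8)

  params <- .init_params(ncol(X), hidden, seed)
  adam <- list(m = list(), v = list(), t = 0L)
  set.seed(seed + 1L)
  n <- nrow(X)
  bs <- min(batch_size, n)
  momentum <- 0.99
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist_train <- hist_val <- numeric(0)
  bad_epochs <- 0L

  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    ep_loss <- 0
    for (s in starts) {
      bidx <- ord[s:min(s + bs - 1L, n)]
      Xb <- X[bidx, , drop = FALSE]; yb <- y[bidx]
      cache <- .forward(params, Xb, training = TRUE, dropout = dropout)
      params$bn$run_mean <- momentum * params$bn$run_mean + (1 - momentum) * cache$mu
      params$bn$run_var <- momentum * params$bn$run_var + (1 - momentum) * cache$v
      sw <- ifelse(yb == 1, class_weights[["AF"]], class_weights[["NON_AF"]])
      grads <- .backward(params, Xb, cache, yb, sw, dropout)
      step <- .adam_step(adam, params, grads, lr, beta1, beta2)
      adam <- step$state; params <- step$params
      ep_loss <- ep_loss + weighted_bce_loss(cache$p, yb, class_weights) * length(bidx)
    }
    hist_train[epoch] <- ep_loss / n
    val_p <- .forward(params, Xv, training = FALSE)$p
    hist_val[epoch] <- weighted_bce_loss(val_p, yv, class_weights)
    if (hist_val[epoch] < best$loss - 1e-9) {
      best <- list(loss = hist_val[epoch], params = params, epoch = epoch)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs > patience) break
    }
  }

  params <- best$params
  val_p <- .forward(params, Xv, training = FALSE)$p
  p_thr <- select_threshold(val_p, yv)
  fitted_p <- .forward(params, X, training = FALSE)$p

  structure(list(
    architecture = hidden, params = params,
    feature_names = feature_names, imputation_means = imputation_means,
    p_thr = p_thr, class_weights = class_weights,
    history = data.frame(epoch = seq_along(hist_train),
                         train_loss = hist_train, val_loss = hist_val),
    best_epoch = best$epoch, best_val_loss = best$loss,
    epochs_run = length(hist_train),
    seed = seed, dropout = dropout, lr = lr,
    fitted = fitted_p, y = y,
    val_probs = val_p, val_y = yv,
    call = match.call()
  ), class = "af_densenet")
}

#' Predict AF probabilities or classes
#'
#' Deterministic inference: dropout is inactive and batch normalization uses
#' the running statistics accumulated during training. `NA` features are
#' imputed with the stored training means.
#'
#' @param object An `af_densenet` fit.
#' @param newdata Feature matrix or data.frame with the model's columns.
#' @param type `"prob"` for P(AF) or `"class"` for thresholded labels.
#' @param ... Unused.
#' @return Numeric probabilities, or a character vector of `"AF"`/`"NON_AF"`.
#' @export
predict.af_densenet <- function(object, newdata,
                                type = c("prob", "class"), ...) {
  type <- match.arg(type)
  X <- .prepare_x(newdata, object$feature_names, object$imputation_means)
  p <- .forward(object$params, X, training = FALSE)$p
  if (type == "prob") return(p)
  ifelse(p > object$p_thr, "AF", "NON_AF")
}

#' @export
print.af_densenet <- function(x, ...) {
  cat("Dense AF/non-AF classifier\n")
  cat(sprintf("  architecture: [%s], input dim %d (%d parameters)\n",
              paste(x$architecture, collapse = ","),
              length(x$feature_names), .n_params(x)))
  cat(sprintf("  best validation loss %.5f at epoch %d/%d\n",
              x$best_val_loss, x$best_epoch, x$epochs_run))
  cat(sprintf("  probability threshold P_thr = %.4f (max validation BAC)\n",
              x$p_thr))
  invisible(x)
}

.n_params <- function(x) {
  2L * length(x$feature_names) +
    sum(vapply(x$params$layers, function(l) length(l$W) + length(l$b), 0))
}

#' @export
summary.af_densenet <- function(object, ...) {
  cm <- confusion_counts(ifelse(object$val_probs > object$p_thr, "AF", "NON_AF"),
                         ifelse(object$val_y == 1, "AF", "NON_AF"))
  out <- list(fit = object, val_metrics = compute_metrics(cm), val_counts = cm)
  class(out) <- "summary.af_densenet"
  out
}

#' @export
print.summary.af_densenet <- function(x, ...) {
  print(x$fit)
  m <- x$val_metrics
  cat(sprintf("  validation: Se %.1f%%, Sp %.1f%%, BAC %.1f%%, F1 %.3f\n",
              m$se, m$sp, m$bac, m$f1))
  cat(sprintf("  class weights: AF %.3f / non-AF %.3f\n",
              x$fit$class_weights[["AF"]], x$fit$class_weights[["NON_AF"]]))
  invisible(x)
}

#' @export
coef.af_densenet <- function(object, ...) {
  c(list(bn_gamma = object$params$bn$gamma, bn_beta = object$params$bn$beta),
    setNames(lapply(object$params$layers, `[[`, "W"),
             paste0("W", seq_along(object$params$layers))),
    setNames(lapply(object$params$layers, `[[`, "b"),
             paste0("b", seq_along(object$params$layers))))
}

#' @export
residuals.af_densenet <- function(object, ...) object$y - object$fitted

#' Plot training history
#'
#' Training and validation loss per epoch, with the checkpointed epoch
#' marked.
#'
#' @param x An `af_densenet` fit.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.af_densenet <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "weighted BCE loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"),
                   col = c("grey40", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Grid search over shrinking architectures
#'
#' Trains `runs` models per architecture with distinct seeds, records the
#' validation balanced accuracy at each model's selected threshold, and
#' returns the ranking (descending BAC; ties broken by fewer parameters)
#' together with the best model.
#'
#' @param x,y Training features and labels.
#' @param x_val,y_val Validation features and labels.
#' @param architectures List of width vectors, e.g. from
#'   [enumerate_architectures()].
#' @param runs Independent training runs per architecture (default 5).
#' @param seed Base seed; run seeds are derived deterministically.
#' @param ... Passed to [af_densenet()].
#' @return List with `results` (data.frame: architecture, run, seed,
#'   val_bac, n_params), `ranking` (aggregated, ordered), and `best` (the
#'   top model).
#' @export
grid_search <- function(x, y, x_val, y_val, architectures,
                        runs = 5, seed = 1L, ...) {
  rows <- list(); best <- NULL; best_key <- c(-Inf, Inf)
  for (ai in seq_along(architectures)) {
    arch <- architectures[[ai]]
    for (r in seq_len(runs)) {
      run_seed <- (seed + 7919L * ai + r) %% .Machine$integer.max
      fit <- af_densenet(x, y, hidden = arch, x_val = x_val, y_val = y_val,
                         seed = run_seed, ...)
      cm <- confusion_counts(
        ifelse(fit$val_probs > fit$p_thr, "AF", "NON_AF"),
        ifelse(fit$val_y == 1, "AF", "NON_AF"))
      bac <- compute_metrics(cm)$bac
      np <- .n_params(fit)
      rows[[length(rows) + 1L]] <- data.frame(
        architecture = paste0("[", paste(arch, collapse = ","), "]"),
        run = r, seed = run_seed, val_bac = bac, n_params = np,
        stringsAsFactors = FALSE)
      if (bac > best_key[1] || (bac == best_key[1] && np < best_key[2])) {
        best <- fit; best_key <- c(bac, np)
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- stats::aggregate(val_bac ~ architecture + n_params, results, mean)
  ranking <- agg[order(-agg$val_bac, agg$n_params), ]
  rownames(ranking) <- NULL
  list(results = results, ranking = ranking, best = best)
}

#' Save / load a trained model archive
#'
#' The archive holds the architecture, all learned parameters (batch-norm
#' and layer weights), the feature ordering, imputation means and the
#' selected probability threshold, serialized as JSON.
#'
#' @param model An `af_densenet` fit.
#' @param path File path.
#' @return `save_model` returns the path invisibly; `load_model` the
#'   restored `af_densenet`.
#' @export
save_model <- function(model, path) {
  payload <- list(
    architecture = model$architecture,
    bn = model$params$bn,
    layers = model$params$layers,
    feature_names = model$feature_names,
    imputation_means = as.list(model$imputation_means),
    p_thr = model$p_thr,
    class_weights = as.list(model$class_weights),
    seed = model$seed, best_epoch = model$best_epoch,
    best_val_loss = model$best_val_loss
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- lapply(seq_along(p$layers$W), function(i) {
    W <- p$layers$W[[i]]
    if (is.null(dim(W))) W <- matrix(W, nrow = 1)
    list(W = W, b = as.numeric(p$layers$b[[i]]))
  })
  # jsonlite may simplify the layer list differently depending on shapes
  if (is.null(p$layers$W)) {
    layers <- lapply(p$layers, function(l) {
      W <- l$W
      if (is.null(dim(W))) W <- matrix(unlist(W), nrow = length(l$b),
                                       byrow = TRUE)
      list(W = W, b = as.numeric(l$b))
    })
  }
  structure(list(
    architecture = as.integer(p$architecture),
    params = list(bn = lapply(p$bn, as.numeric), layers = layers),
    feature_names = p$feature_names,
    imputation_means = unlist(p$imputation_means),
    p_thr = p$p_thr,
    class_weights = unlist(p$class_weights),
    seed = p$seed, best_epoch = p$best_epoch, best_val_loss = p$best_val_loss,
    history = NULL, fitted = NULL, y = NULL,
    val_probs = NULL, val_y = NULL
  ), class = "af_densenet")
}
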