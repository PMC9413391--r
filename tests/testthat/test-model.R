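test_that("architecture enumeration matches the multiset closed form", {
  archs3 <- enumerate_architectures(c(4, 8, 16))
  expect_length(archs3, 19)
  depth <- vapply(archs3, length, 0L)
  expect_equal(as.vector(table(depth)), c(3, 6, 10))
  expect_length(enumerate_architectures(c(4, 8, 16, 32, 64)), 55)
  expect_length(enumerate_architectures(c(4, 8, 16, 32, 64, 128)), 83)

  expect_equal(enumerate_architectures(4), list(4L, c(4L, 4L), c(4L, 4L, 4L)))

  # closed-form oracle on arbitrary option counts
  for (m in 1:6) {
    opts <- sort(sample(1:200, m))
    expected <- sum(vapply(1:3, function(k) choose(m + k - 1, k), 0))
    archs <- enumerate_architectures(opts)
    expect_length(archs, expected)
    expect_true(all(vapply(archs, function(a) all(diff(a) <= 0), TRUE)))
    expect_equal(length(unique(vapply(archs, paste, "", collapse = ","))),
                 length(archs))
  }
  expect_error(enumerate_architectures(integer()), "non-empty")
  expect_error(enumerate_architectures(c(8, 4)), "strictly increasing")
})

test_that("class weights are the normalized reciprocal of prevalence", {
  expect_equal(class_weights_from_prevalence(0.08),
               c(AF = 0.92, NON_AF = 0.08))
  w <- class_weights_from_prevalence(0.3)
  expect_equal(sum(w), 1)
  expect_gt(w[["AF"]], w[["NON_AF"]])
})

test_that("weighted binary cross-entropy matches hand evaluation", {
  expect_lt(weighted_bce_loss(c(1, 0, 1), c(1, 0, 1)), 1e-6)
  # single AF sample at p = 0.5 with w_AF = 0.92
  expect_equal(weighted_bce_loss(0.5, 1, c(AF = 0.92, NON_AF = 0.08)),
               0.92 * log(2))
  # equal weights halve the unweighted cross-entropy
  set.seed(1)
  p <- runif(50); y <- rbinom(50, 1, 0.5)
  plain <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(weighted_bce_loss(p, y, c(AF = 0.5, NON_AF = 0.5)), 0.5 * plain)
  expect_error(weighted_bce_loss(c(0.5, 0.5), 1), "mismatch")
})

test_that("network construction obeys topology and determinism contracts", {
  sf <- separable_features(n = 50)
  expect_error(af_densenet(sf$x, sf$y, hidden = c(8, 16)), "shrink")
  expect_error(af_densenet(sf$x, rep("AF", 100), hidden = 4),
               "both classes")

  f1 <- af_densenet(sf$x, sf$y, hidden = c(8, 4), max_epochs = 3, seed = 9)
  f2 <- af_densenet(sf$x, sf$y, hidden = c(8, 4), max_epochs = 3, seed = 9)
  expect_identical(f1$params, f2$params)

  dims <- vapply(f1$params$layers, function(l) nrow(l$W), 0L)
  expect_equal(dims, c(8L, 4L, 1L))
  p <- predict(f1, sf$x)
  expect_true(all(p > 0 & p < 1))
  expect_identical(p, predict(f1, sf$x))
})

test_that("training separates two Gaussians and respects early stopping", {
  sf <- separable_features(n = 1000, gap = 4, seed = 42)
  fit <- af_densenet(sf$x, sf$y, hidden = c(8, 4), seed = 2)
  expect_lte(fit$epochs_run, 400)
  cm <- confusion_counts(
    ifelse(fit$val_probs > fit$p_thr, "AF", "NON_AF"),
    ifelse(fit$val_y == 1, "AF", "NON_AF"))
  expect_gte(compute_metrics(cm)$bac, 99)
  # early stopping engaged before the epoch cap on this easy problem
  expect_lt(fit$epochs_run, 400)
  expect_lte(fit$epochs_run - fit$best_epoch, 11)

  # cross-check: an independent single-hidden-layer classifier agrees that
  # the features are separable
  skip_if_not_installed("nnet")
  idx <- sample(length(sf$y))
  nn <- nnet::nnet(sf$x[idx, ], as.numeric(sf$y[idx] == "AF"), size = 4,
                   trace = FALSE, maxit = 200)
  acc <- mean((predict(nn, sf$x) > 0.5) == (sf$y == "AF"))
  expect_gte(acc, 0.99)
})

test_that("probability output is a monotone sigmoid of the pre-activation", {
  lm3 <- linear_model(c(0.7, 0, 0))
  xs <- cbind(f1 = seq(-2, 2, length.out = 9), f2 = 0, f3 = 0)
  p <- predict(lm3, xs)
  expect_true(all(diff(p) > 0))
  expect_equal(predict(lm3, cbind(f1 = 0, f2 = 0, f3 = 0)), 0.5)
})

test_that("AF-structured synthetic features are classified near-perfectly", {
  # surrogate for the rhythm signal: AF has short irregular RR and noisy PQ
  set.seed(10)
  n_af <- 150; n_non <- 850
  mk <- function(n, rr_m, rr_s, pqi_s, pqa_m) {
    cbind(RRi_mean = rnorm(n, rr_m, 60), RRi_std = rnorm(n, rr_s, 15),
          PQi_std_II = pmax(rnorm(n, pqi_s, 10), 0),
          PQa_mean_II = rnorm(n, pqa_m, 0.03))
  }
  x <- rbind(mk(n_af, 620, 160, 80, 0.01), mk(n_non, 870, 25, 6, 0.12))
  y <- rep(c("AF", "NON_AF"), c(n_af, n_non))
  fit <- af_densenet(x, y, hidden = c(16, 8), seed = 3)
  cm <- confusion_counts(
    ifelse(fit$val_probs > fit$p_thr, "AF", "NON_AF"),
    ifelse(fit$val_y == 1, "AF", "NON_AF"))
  expect_gte(compute_metrics(cm)$bac, 95)
})

test_that("grid search trains runs-per-architecture models and ranks them", {
  sf <- separable_features(n = 120, gap = 3, seed = 6)
  tr <- c(1:90, 121:210); va <- c(91:120, 211:240)  # stratified split
  archs <- enumerate_architectures(4)
  gs <- grid_search(sf$x[tr, ], sf$y[tr], sf$x[va, ],
                    sf$y[va], archs, runs = 2, seed = 1,
                    max_epochs = 60)
  expect_equal(nrow(gs$results), length(archs) * 2)
  expect_s3_class(gs$best, "af_densenet")
  expect_false(is.unsorted(rev(gs$ranking$val_bac)))
  # ties broken by fewer parameters
  top <- gs$ranking[gs$ranking$val_bac == max(gs$ranking$val_bac), ]
  expect_equal(top$n_params, sort(top$n_params))
})

test_that("model archives round-trip through JSON", {
  sf <- separable_features(n = 100, gap = 3)
  fit <- af_densenet(sf$x, sf$y, hidden = c(8, 4), max_epochs = 50, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit, path)
  back <- load_model(path)
  expect_equal(back$p_thr, fit$p_thr)
  expect_equal(back$feature_names, fit$feature_names)
  expect_equal(predict(back, sf$x), predict(fit, sf$x), tolerance = 1e-10)
})
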