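test_that("coalition value function obeys its boundary contracts", {
  tm <- toy_model(M = 4)
  bg <- random_background(4, n = 15)
  x <- setNames(rnorm(4), paste0("f", 1:4))

  full <- value_function(tm, x, 1:4, bg)
  expect_equal(full, as.numeric(predict(tm, matrix(x, nrow = 1,
                                dimnames = list(NULL, names(x))))))
  base <- value_function(tm, x, integer(), bg)
  expect_equal(base, mean(predict(tm, bg)))

  one_bg <- bg[1, , drop = FALSE]
  v <- value_function(tm, x, c("f1", "f3"), one_bg)
  sub <- one_bg; sub[, c(1, 3)] <- x[c(1, 3)]
  expect_equal(v, as.numeric(predict(tm, sub)))
  expect_error(value_function(tm, x, 1, bg[0, , drop = FALSE]), "non-empty")
})

test_that("exact Shapley values satisfy efficiency, dummy and symmetry", {
  w <- c(0.8, 0, -0.5, 0.8)
  lm4 <- linear_model(w)
  set.seed(2)
  bg <- random_background(4, n = 25)
  bg[, 4] <- bg[, 1]                     # symmetric pair f1/f4
  x <- c(f1 = 1.3, f2 = -0.7, f3 = 0.4, f4 = 1.3)

  s <- shapley_exact(lm4, x, bg)
  expect_equal(sum(s), value_function(lm4, x, 1:4, bg) -
                 attr(s, "base_value"), tolerance = 1e-10)
  expect_equal(s[["f2"]], 0)             # dummy feature: zero weight
  expect_equal(s[["f1"]], s[["f4"]], tolerance = 1e-10)
})

test_that("exact Shapley matches the linear closed form", {
  w <- c(0.002, -0.0015, 0.001)          # small weights: sigmoid ~ linear
  lm3 <- linear_model(w)
  bg <- random_background(3, n = 30, seed = 9)
  x <- c(f1 = 0.9, f2 = -1.1, f3 = 0.5)
  s <- shapley_exact(lm3, x, bg)
  closed <- w / 4 * (x - colMeans(bg))   # d sigmoid / dz at 0 is 1/4
  expect_equal(as.numeric(s), as.numeric(closed), tolerance = 1e-4)
})

test_that("exact Shapley equals the all-permutations average (3 features)", {
  tm <- toy_model(M = 3, seed = 13)
  bg <- random_background(3, n = 10, seed = 3)
  x <- setNames(c(0.6, -0.4, 1.1), paste0("f", 1:3))

  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  contrib <- matrix(0, length(perms), 3)
  for (k in seq_along(perms)) {
    S <- integer()
    v_prev <- value_function(tm, x, S, bg)
    for (i in perms[[k]]) {
      S <- c(S, i)
      v <- value_function(tm, x, S, bg)
      contrib[k, i] <- v - v_prev
      v_prev <- v
    }
  }
  oracle <- colMeans(contrib)
  s <- shapley_exact(tm, x, bg)
  expect_equal(as.numeric(s), oracle, tolerance = 1e-10)
  expect_error(shapley_exact(toy_model(M = 16), x, bg), "at most 15")
})

test_that("sampled Shapley is seeded, efficient and close to exact", {
  tm <- toy_model(M = 10, hidden = c(6, 3), seed = 17, scale = 25)
  bg <- random_background(10, n = 20, seed = 21)
  set.seed(30)
  x <- setNames(rnorm(10), paste0("f", 1:10))

  s_exact <- shapley_exact(tm, x, bg)
  s1 <- shapley_sampled(tm, x, bg, n_permutations = 2000, seed = 5)
  s2 <- shapley_sampled(tm, x, bg, n_permutations = 2000, seed = 5)
  expect_identical(as.numeric(s1), as.numeric(s2))
  expect_lt(max(abs(s1 - s_exact)), 0.01)

  fx <- value_function(tm, x, 1:10, bg)
  expect_equal(sum(s1), fx - attr(s1, "base_value"), tolerance = 1e-10)
  expect_error(shapley_sampled(tm, x, bg, n_permutations = 10), "at least 100")
})

test_that("sampling error shrinks as permutations grow", {
  tm <- toy_model(M = 8, hidden = 4, seed = 23, scale = 25)
  bg <- random_background(8, n = 15, seed = 2)
  x <- setNames(rep(0.8, 8), paste0("f", 1:8))
  s_exact <- shapley_exact(tm, x, bg)
  err <- vapply(c(200, 3200), function(np) {
    max(abs(shapley_sampled(tm, x, bg, n_permutations = np, seed = 11) -
              s_exact))
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("global importance and percent-of-max reproduce printed ratios", {
  shap <- rbind(c(A = 0.0196, B = -0.0164, C = 0.0120),
                c(A = -0.0196, B = 0.0164, C = -0.0120))
  g <- shap_global(shap)
  expect_equal(g$global, c(A = 0.0196, B = 0.0164, C = 0.0120))
  expect_equal(g$percent_of_max[["A"]], 100)
  expect_equal(g$percent_of_max[["B"]], 84)
  expect_equal(g$percent_of_max[["C"]], 61)

  expect_equal(shap_global(matrix(0.3, 2, 1))$percent_of_max[[1]], 100)
  # invariant to record ordering
  expect_equal(shap_global(shap[2:1, ]), g)
})

test_that("ranking report thresholds and aggregates feature families", {
  g <- c(RRi_mean = 0.0196, RRi_std = 0.0164,
         PQa_mean_aVR = 0.0120, PQi_std_V2 = 0.0108,
         PQi_mean_aVL = 0.00989, PQa_std_V1 = 0.00556,
         PQi_mean_I = 0.0050, PQa_mean_I = 0.0099,
         PQi_std_I = 0.004, PQa_std_I = 0.0030)
  rep_ <- rank_report(g, threshold_fraction = 0.25)
  expect_equal(rep_$threshold, 0.0049)
  expect_true(rep_$ranked$flagged[rep_$ranked$feature == "PQi_mean_I"])
  expect_false(rep_$ranked$flagged[rep_$ranked$feature == "PQi_std_I"])
  # RR features are global: absent from the per-lead summary
  expect_false(any(grepl("RRi", rep_$by_lead$group)))
  expect_true(all(c("aVR", "V2", "I") %in% rep_$by_lead$group))
  fam_means <- tapply(g[grep("^PQ", names(g))],
                      sub("^(PQ[ia]_(mean|std))_.*$", "\\1",
                          grep("^PQ", names(g), value = TRUE)), mean)
  expect_equal(rep_$by_family$group,
               names(sort(fam_means, decreasing = TRUE)))
  lead_I <- rep_$by_lead[rep_$by_lead$group == "I", ]
  expect_equal(lead_I$mean, mean(c(0.0050, 0.0099, 0.004, 0.0030)))

  all_eq <- rank_report(setNames(rep(0.01, 4),
                                 c("RRi_mean", "RRi_std",
                                   "PQi_mean_I", "PQa_std_I")))
  expect_true(all(all_eq$ranked$flagged))
})
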