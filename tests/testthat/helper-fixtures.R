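# Shared fixtures, memoized per test session: synthetic records are cheap
# but not free, and several files probe the same waveforms.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env)) assign(key, force(expr), .fixture_env)
  get(key, .fixture_env)
}

sinus_record <- function(seed = 1, duration_s = 10, ...) {
  memo(paste0("sinus", seed, "_", duration_s),
       generate_record(synth_config("SINUS", seed = seed,
                                    duration_s = duration_s, ...)))
}

af_record <- function(seed = 2, duration_s = 30) {
  memo(paste0("af", seed, "_", duration_s),
       generate_record(synth_config("AF", rr_cv = 0.25, seed = seed,
                                    duration_s = duration_s)))
}

# well-separated two-Gaussian features for classifier tests
separable_features <- function(n = 1000, d = 5, gap = 2, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * d, 0), ncol = d),
             matrix(rnorm(n * d, gap), ncol = d))
  colnames(x) <- paste0("f", seq_len(d))
  list(x = x, y = rep(c("NON_AF", "AF"), each = n))
}

# hand-built network computing exactly sigmoid(w . x): one hidden neuron
# held in its linear (active) ReLU region
linear_model <- function(weights, bias_shift = 10) {
  M <- length(weights)
  nm <- paste0("f", seq_len(M))
  params <- list(
    bn = list(gamma = rep(1, M), beta = rep(0, M),
              run_mean = rep(0, M), run_var = rep(1 - 1e-3, M)),
    layers = list(list(W = matrix(weights, nrow = 1), b = bias_shift),
                  list(W = matrix(1, 1, 1), b = -bias_shift))
  )
  structure(list(architecture = 1L, params = params, feature_names = nm,
                 imputation_means = setNames(rep(0, M), nm), p_thr = 0.5,
                 class_weights = c(AF = 0.5, NON_AF = 0.5)),
            class = "af_densenet")
}

# small random (untrained) network with non-trivial curvature
toy_model <- function(M = 3, hidden = c(4, 2), seed = 7, scale = 20) {
  nm <- paste0("f", seq_len(M))
  params <- afsync:::.init_params(M, as.integer(hidden), seed)
  params$layers <- lapply(params$layers, function(l) {
    l$W <- l$W * scale; l$b <- l$b + 0.1; l
  })
  structure(list(architecture = as.integer(hidden), params = params,
                 feature_names = nm,
                 imputation_means = setNames(rep(0, M), nm), p_thr = 0.5,
                 class_weights = c(AF = 0.5, NON_AF = 0.5)),
            class = "af_densenet")
}

random_background <- function(M, n = 20, seed = 5) {
  set.seed(seed)
  m <- matrix(rnorm(n * M), ncol = M)
  colnames(m) <- paste0("f", seq_len(M))
  m
}
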