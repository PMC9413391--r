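test_that("diagnosis-code mapping is total and exclusion dominates AF", {
  expect_equal(map_codes_to_class(c("164889003")), "AF")
  expect_equal(map_codes_to_class(c("164890007", "426783006")), "AF")
  expect_equal(map_codes_to_class(c("426783006")), "NON_AF")
  expect_equal(map_codes_to_class(character()), "EXCLUDED")
  # pacing rhythm excludes even in the presence of an AFL code
  expect_equal(map_codes_to_class(c("164890007", "10370003")), "EXCLUDED")
  expect_equal(map_codes_to_class(c("365413008")), "EXCLUDED")
  expect_equal(map_codes_to_class(c("251146004", "164889003")), "EXCLUDED")
})

test_that("resampling preserves morphology, duration and handles identity", {
  fs0 <- 250
  t <- (0:(10 * fs0 - 1)) / fs0
  sig <- matrix(sin(2 * pi * 5 * t), ncol = 1, dimnames = list(NULL, "I"))
  rec <- new_ecg_record("r1", sig, fs0)

  up <- resample_record(rec, 500)
  expect_equal(up$fs, 500)
  expect_equal(abs(up$duration_s - rec$duration_s) <= 1 / 250, TRUE)
  t2 <- (seq_len(nrow(up$signals)) - 1) / 500
  mid <- 200:(nrow(up$signals) - 200)  # away from filter edge effects
  expect_lt(max(abs(up$signals[mid, 1] - sin(2 * pi * 5 * t2[mid]))), 0.01)

  same <- resample_record(rec, 250)
  expect_identical(same$signals, rec$signals)

  rec1k <- new_ecg_record("r2", matrix(rnorm(10000), ncol = 1,
                                       dimnames = list(NULL, "I")), 1000)
  down <- resample_record(rec1k, 500)
  expect_equal(nrow(down$signals), 5000)

  empty <- new_ecg_record("r3", matrix(numeric(), ncol = 1, nrow = 0,
                                       dimnames = list(NULL, "I")), 500,
                          validate_duration = FALSE)
  expect_error(resample_record(empty, 500), "empty")
})

test_that("records outside the 5-144 s duration range are rejected at load", {
  short_sig <- matrix(0, nrow = 4 * 500, ncol = 1, dimnames = list(NULL, "I"))
  expect_warning(r <- new_ecg_record("tooshort", short_sig, 500), "rejected")
  expect_null(r)
})

test_that("WFDB round-trip preserves signals, codes and patient id", {
  g <- sinus_record(seed = 21)
  d <- withr::local_tempdir()
  write_wfdb(g$record, d)
  back <- read_wfdb(file.path(d, paste0(g$record$record_id, ".hea")))
  expect_equal(colnames(back$signals), colnames(g$record$signals))
  expect_equal(back$fs, g$record$fs)
  expect_equal(back$codes, g$record$codes)
  expect_equal(back$patient_id, g$record$patient_id)
  # 16-bit storage at 1000 units/mV: half-LSB quantization
  expect_lt(max(abs(back$signals - g$record$signals)), 5e-4 + 1e-9)
})

test_that("CinC-style headers with unknown comment lines parse", {
  d <- withr::local_tempdir()
  n <- 2500
  writeBin(as.integer(rep(0, n)), con <- file(file.path(d, "A1.dat"), "wb"),
           size = 2, endian = "little"); close(con)
  writeLines(c("A1 1 500 2500",
               "A1.dat 16 1000/mV 16 0 0 0 0 II",
               "# Age: 64", "# Sex: Female", "# Dx: 164889003,59118001"),
             file.path(d, "A1.hea"))
  rec <- read_wfdb(file.path(d, "A1.hea"))
  expect_equal(rec$codes, c("164889003", "59118001"))
  expect_equal(map_codes_to_class(rec$codes), "AF")
  expect_equal(rec$patient_id, "A1")
})

make_manifest <- function(n, af_frac, seed, records_per_patient = 1) {
  set.seed(seed)
  n_pat <- n %/% records_per_patient
  pid <- rep(sprintf("P%04d", seq_len(n_pat)), each = records_per_patient)[1:n]
  lab <- rep("NON_AF", n)
  af_pat <- sample(unique(pid), round(af_frac * n_pat))
  lab[pid %in% af_pat] <- "AF"
  data.frame(record_id = sprintf("R%04d", 1:n), patient_id = pid,
             label = lab, stringsAsFactors = FALSE)
}

test_that("partition is patient-wise, stratified and deterministic", {
  man <- make_manifest(1000, 0.08, seed = 3)
  sp <- partition_dataset(man, seed = 7)
  sizes <- table(sp$subset)[c("train", "validation", "test")]
  expect_true(all(abs(sizes - c(700, 200, 100)) <= 5))

  prev <- mean(man$label == "AF")
  for (s in c("train", "validation", "test")) {
    p <- mean(sp$label[sp$subset == s] == "AF")
    expect_lt(abs(p - prev), 0.02)
  }
  # no patient straddles subsets, and all records are covered
  straddle <- tapply(sp$subset, sp$patient_id, function(x) length(unique(x)))
  expect_true(all(straddle == 1))
  expect_false(anyNA(sp$subset))

  again <- partition_dataset(man, seed = 7)
  expect_identical(sp, again)
  other <- partition_dataset(man, seed = 8)
  expect_false(identical(sp$subset, other$subset))
  expect_true(all(abs(table(other$subset)[names(sizes)] - sizes) <= 10))
})

test_that("multi-record patients stay together and bad fractions error", {
  man <- make_manifest(500, 0.1, seed = 4, records_per_patient = 5)
  sp <- partition_dataset(man, seed = 1)
  one_pat <- sp[sp$patient_id == sp$patient_id[1], ]
  expect_equal(length(unique(one_pat$subset)), 1)
  expect_equal(nrow(one_pat), 5)

  expect_error(partition_dataset(man, fractions = c(0.7, 0.2, 0.2)), "sum to 1")
  man$label[1] <- "EXCLUDED"
  expect_error(partition_dataset(man), "AF/NON_AF")
})

test_that("directory scan labels, excludes and resamples records", {
  d <- withr::local_tempdir()
  g <- sinus_record(seed = 22)
  write_wfdb(g$record, d)
  excl <- g$record; excl$record_id <- "EX01"; excl$codes <- "10370003"
  write_wfdb(excl, d)
  ds <- read_dataset(d)
  expect_equal(sort(ds$manifest$record_id), sort(c(g$record$record_id, "EX01")))
  expect_equal(ds$manifest$label[ds$manifest$record_id == "EX01"], "EXCLUDED")
  expect_false("EX01" %in% names(ds$records))
  expect_equal(ds$records[[g$record$record_id]]$fs, 500)
})
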