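test_that("csv and rds round-trips are value-exact; wfdb is exact to quantization", {
  rec <- tiny_records()[[1]]
  tmp <- withr::local_tempdir()

  csv <- file.path(tmp, "r.csv")
  write_ecg(rec, csv, "csv")
  back <- read_ecg(csv)
  expect_identical(back$signal, rec$signal)
  expect_identical(back$sampling_rate, rec$sampling_rate)
  expect_identical(back$record_id, rec$record_id)
  # header carries the canonical lead order
  expect_identical(strsplit(readLines(csv, n = 2)[2], ",")[[1]][-1], ECG_LEADS)

  rds <- file.path(tmp, "r.rds")
  write_ecg(rec, rds, "rds")
  expect_identical(read_ecg(rds)$signal, rec$signal)

  hea <- file.path(tmp, "r.hea")
  write_ecg(rec, hea, "wfdb", gain = 1000)
  wb <- read_ecg(hea)
  expect_lte(max(abs(wb$signal - rec$signal)), 0.5 / 1000)
  expect_equal(wb$sampling_rate, rec$sampling_rate)
})

test_that("readers reorder non-canonical lead order and name missing leads", {
  rec <- tiny_records()[[1]]
  tmp <- withr::local_tempdir()
  csv <- file.path(tmp, "r.csv")
  write_ecg(rec, csv, "csv")

  # permute the lead columns of the written file: content must be preserved
  lines <- readLines(csv)
  perm <- c(1, 3, 2, 4:13)  # swap I and II columns (time_s first)
  reorder_line <- function(l) paste(strsplit(l, ",")[[1]][perm], collapse = ",")
  writeLines(c(lines[1], vapply(lines[-1], reorder_line, "")),
             file.path(tmp, "perm.csv"))
  back <- read_ecg(file.path(tmp, "perm.csv"))
  expect_identical(back$signal, rec$signal)

  # drop lead V6 -> error naming it
  keep <- strsplit(lines[2], ",")[[1]] != "V6"
  drop_line <- function(l) paste(strsplit(l, ",")[[1]][keep], collapse = ",")
  writeLines(c(lines[1], vapply(lines[-1], drop_line, "")),
             file.path(tmp, "short.csv"))
  expect_error(read_ecg(file.path(tmp, "short.csv")), "V6")
})

test_that("resampling honors the round(duration x rate) contract", {
  p <- morphology_params()
  r500 <- simulate_record(p, fs = 500, duration_s = 10, seed = 4)
  expect_identical(ncol(resample_record(r500, 250)$signal), 2500L)
  r4s <- simulate_record(p, fs = 500, duration_s = 4, seed = 4)
  expect_identical(ncol(resample_record(r4s, 250)$signal), 1000L)
  expect_error(resample_record(r500, -1), "positive")
  # idempotent length
  once <- resample_record(r500, 250)
  expect_identical(ncol(resample_record(once, 250)$signal), ncol(once$signal))
})

test_that("downsampling preserves an in-band spectral peak (FFT oracle)", {
  fs <- 500; n <- fs * 10
  t <- (seq_len(n) - 1) / fs
  sig <- rbind(sin(2 * pi * 5 * t))[rep(1, 12), ]
  rec <- ecg_record("sine", sig, fs)
  out <- resample_record(rec, 250)
  x <- out$signal[1, ]
  spec <- Mod(stats::fft(x))[2:(length(x) %/% 2)]
  f <- (2:(length(x) %/% 2) - 1) * 250 / length(x)
  expect_lt(abs(f[which.max(spec)] - 5), 250 / length(x) + 1e-9)
})

test_that("lead consistency check accepts generated records and flags violations", {
  rec <- tiny_records()[[2]]
  chk <- lead_consistency_check(rec, tolerance = 0)
  expect_true(chk$consistent)
  expect_identical(max(chk$deviations), 0)

  bad <- rec
  bad$signal["III", ] <- 0
  res <- lead_consistency_check(bad, 1e-6)
  expect_false(res$consistent)
  expect_gt(res$deviations["III"], 1e-6)

  # independent white-noise leads essentially never satisfy Einthoven
  set.seed(99)
  fails <- vapply(1:100, function(i) {
    r <- ecg_record(sprintf("n%d", i), matrix(stats::rnorm(12 * 250), 12), 250)
    !lead_consistency_check(r, 1e-3)$consistent
  }, TRUE)
  expect_true(all(fails))
})

test_that("quality screen flags flat leads, gaps and clipping deterministically", {
  rec <- tiny_records()[[3]]
  expect_true(quality_screen(rec)$passed)

  flat <- rec
  flat$signal[4, ] <- 0
  qs <- quality_screen(flat)
  expect_false(qs$passed)
  expect_identical(qs$flags$flat_lead, 4L)

  gap <- rec$signal
  gap[2, 100:110] <- NA
  qs2 <- quality_screen(rec, signal = gap)
  expect_false(qs2$passed)
  expect_identical(qs2$flags$missing_samples, 2L)

  clip <- rec
  clip$signal[1, 50:80] <- 5
  qs3 <- quality_screen(clip)
  expect_true(1L %in% qs3$flags$clipping)

  # purity: identical input -> identical report
  expect_identical(quality_screen(clip), quality_screen(clip))
})

test_that("cohort directories round-trip with the documented metadata columns", {
  tmp <- withr::local_tempdir()
  coh <- mini_cohort()
  write_cohort(coh, tmp, "csv")
  meta <- utils::read.csv(file.path(tmp, "metadata.csv"))
  expect_identical(names(meta), c("record_id", "label", "lvef_percent", "age",
                                  "sex", "htn", "dm", "cad", "ckd"))
  back <- read_cohort(tmp)
  expect_identical(names(back$records), coh$metadata$record_id)
  expect_identical(back$records[[1]]$signal, coh$records[[1]]$signal)
})
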