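NOISE_TYPES <- c("power_line", "emg", "baseline_wander", "baseline_shift",
                 "partial_white", "time_mask")

#' Specify one of the six artificial ECG noise types
#'
#' Amplitudes are absolute (mV), fixed at specification time, so that the
#' same spec applied to two different records injects exactly the same
#' artifact (additive types' residuals are input-independent). Use
#' [default_noise_specs()] to derive amplitudes from a reference signal RMS.
#'
#' \describe{
#'   \item{power_line}{fixed-frequency sinusoid (50/60 Hz), random phase per
#'     lead; `amplitude` = peak mV.}
#'   \item{emg}{band-limited (20--120 Hz, capped at 0.48 fs) white noise;
#'     `amplitude` = RMS mV.}
#'   \item{baseline_wander}{three low-frequency sinusoids drawn from
#'     `wander_band`; `amplitude` = total peak mV.}
#'   \item{baseline_shift}{piecewise-constant offsets, 1--3 switch points at
#'     random times, steps of +/- `amplitude` mV.}
#'   \item{partial_white}{white noise (`amplitude` = RMS mV) inside randomly
#'     placed segments covering `segment_fraction` of samples per lead.}
#'   \item{time_mask}{zeroes randomly placed segments covering exactly
#'     `round(segment_fraction * N)` samples per lead; the only
#'     non-additive type.}
#' }
#'
#' @param noise_type one of the six types.
#' @param amplitude mV (meaning per type, above); >= 0. `NULL` uses the
#'   type's default at reference RMS 0.25 mV.
#' @param frequency_hz power-line frequency (50 or 60).
#' @param wander_band low-frequency band in Hz for baseline wander.
#' @param segment_fraction fraction of samples in \[0, 1\] for the segmented
#'   types.
#' @param seed integer seed; with the record it fully determines the output.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(noise_type, amplitude = NULL, frequency_hz = 60,
                       wander_band = c(0.05, 0.5), segment_fraction = NULL,
                       seed = 1L) {
  assert_that(noise_type %in% NOISE_TYPES, "noise_type '%s' not one of: %s",
              noise_type, paste(NOISE_TYPES, collapse = ", "))
  ref <- 0.25  # default reference RMS in mV
  amplitude <- amplitude %||% switch(noise_type,
    power_line = 0.25 * ref, emg = 0.5 * ref, baseline_wander = 0.5,
    baseline_shift = 0.5, partial_white = 1.0 * ref, time_mask = 0)
  segment_fraction <- segment_fraction %||%
    switch(noise_type, partial_white = 0.2, time_mask = 0.1, 0)
  assert_that(amplitude >= 0, "amplitude must be >= 0")
  assert_that(segment_fraction >= 0 && segment_fraction <= 1,
              "segment_fraction must lie in [0, 1]")
  structure(list(noise_type = noise_type, amplitude = amplitude,
                 frequency_hz = frequency_hz, wander_band = wander_band,
                 segment_fraction = segment_fraction, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Default specs for the six noise types
#'
#' Amplitude defaults follow the ambulatory-artifact literature scale:
#' power line 60 Hz at 0.25 x RMS, EMG at 0.5 x RMS, baseline wander 0.5 mV,
#' baseline shift steps of 0.5 mV, partial white noise at 1.0 x RMS over 20%
#' of samples, time mask over 10% of samples. The RMS reference is the
#' median per-record signal RMS of `records` (or 0.25 mV if none given),
#' converted to absolute mV here so every spec is input-independent.
#'
#' @param records optional list of [ecg_record()] to set the RMS reference.
#' @param seed base seed; each type gets a derived seed.
#' @return named list of six [noise_spec()].
#' @export
default_noise_specs <- function(records = NULL, seed = 1L) {
  ref <- if (is.null(records)) 0.25 else
    stats::median(vapply(records, function(r) rms(r$signal), 1))
  specs <- list(
    power_line = noise_spec("power_line", 0.25 * ref, frequency_hz = 60,
                            seed = derive_seed(seed, 1)),
    emg = noise_spec("emg", 0.5 * ref, seed = derive_seed(seed, 2)),
    baseline_wander = noise_spec("baseline_wander", 0.5,
                                 seed = derive_seed(seed, 3)),
    baseline_shift = noise_spec("baseline_shift", 0.5,
                                seed = derive_seed(seed, 4)),
    partial_white = noise_spec("partial_white", 1.0 * ref,
                               segment_fraction = 0.2,
                               seed = derive_seed(seed, 5)),
    time_mask = noise_spec("time_mask", segment_fraction = 0.1,
                           seed = derive_seed(seed, 6)))
  specs
}

# Randomly place 2 non-overlapping segments totalling `total` samples.
place_segments <- function(n, total) {
  if (total <= 0) return(integer(0))
  l1 <- total %/% 2L; l2 <- total - l1
  half <- n %/% 2L
  s1 <- if (l1 > 0) sample.int(max(1L, half - l1 + 1L), 1L) else NA
  s2 <- half + sample.int(max(1L, n - half - l2 + 1L), 1L)
  c(if (l1 > 0) seq(s1, length.out = l1), seq(s2, length.out = l2))
}

#' Apply a noise specification to a record
#'
#' Deterministic given `(record, spec)`; amplitude 0 returns the input
#' unchanged (for all types). Shape, sampling rate and lead order are never
#' altered. Noise is applied to all 12 leads with independent per-lead
#' phases/segments and a common amplitude.
#'
#' @param record an [ecg_record()].
#' @param spec a [noise_spec()].
#' @return noised [ecg_record()].
#' @export
apply_noise <- function(record, spec) {
  assert_that(inherits(spec, "noise_spec"), "spec must come from noise_spec()")
  fs <- record$sampling_rate
  n <- ncol(record$signal)
  if (spec$noise_type == "power_line" && spec$frequency_hz >= fs / 2)
    stopf("power-line frequency %g Hz is at/above Nyquist (fs = %g Hz)",
          spec$frequency_hz, fs)
  if (spec$amplitude == 0 && spec$noise_type != "time_mask") return(record)
  if (spec$noise_type == "time_mask" && spec$segment_fraction == 0) return(record)
  t <- (seq_len(n) - 1) / fs
  s <- record$signal
  with_seed(spec$seed, {
    for (i in 1:12) {
      s[i, ] <- s[i, ] + switch(spec$noise_type,
        power_line = spec$amplitude *
          sin(2 * pi * spec$frequency_hz * t + stats::runif(1, 0, 2 * pi)),
        emg = {
          band <- c(20, min(120, 0.48 * fs))
          x <- stats::rnorm(n)
          f <- seq(0, fs, length.out = n + 1L)[1:n]
          fsym <- pmin(f, fs - f)
          keep <- fsym >= band[1] & fsym <= band[2]
          xf <- stats::fft(x)
          xf[!keep] <- 0
          y <- Re(stats::fft(xf, inverse = TRUE)) / n
          spec$amplitude * y / rms(y)
        },
        baseline_wander = {
          w <- numeric(n)
          for (j in 1:3)
            w <- w + sin(2 * pi * stats::runif(1, spec$wander_band[1],
                                               spec$wander_band[2]) * t +
                           stats::runif(1, 0, 2 * pi))
          spec$amplitude * w / max(abs(w))
        },
        baseline_shift = {
          k <- sample(1:3, 1L)
          pts <- sort(sample.int(n - 1L, k))
          lev <- cumsum(sample(c(-1, 1), k, replace = TRUE)) * spec$amplitude
          off <- numeric(n)
          for (j in seq_len(k)) off[(pts[j] + 1L):n] <- lev[j]
          off
        },
        partial_white = {
          segs <- place_segments(n, round(spec$segment_fraction * n))
          z <- numeric(n)
          z[segs] <- stats::rnorm(length(segs), sd = spec$amplitude)
          z
        },
        time_mask = {
          segs <- place_segments(n, round(spec$segment_fraction * n))
          z <- numeric(n)
          z[segs] <- -s[i, segs]  # zero out in place (non-additive)
          z
        })
    }
  })
  out <- ecg_record(record$record_id, s, fs)
  attr(out, "noise_spec") <- spec
  out
}

#' Noise robustness suite
#'
#' Evaluates the model on the clean records once, then on one noised copy of
#' the cohort per spec, producing a clean baseline row plus one row per
#' noise type with AUROC/AUPRC/Se/Sp/PPV/NPV (with CIs) and deltas versus
#' clean. Zero-amplitude specs reproduce the clean row bitwise.
#'
#' @param records list of [ecg_record()].
#' @param labels two-class labels aligned with `records`.
#' @param model model for [predict_scores()].
#' @param specs named list of [noise_spec()] (default [default_noise_specs()]
#'   referenced to these records).
#' @param threshold operating threshold.
#' @return data.frame: first row `clean`, then one row per spec, with
#'   `delta_auroc`, `delta_sensitivity`, `delta_specificity` columns.
#' @export
noise_robustness_suite <- function(records, labels, model,
                                   specs = default_noise_specs(records),
                                   threshold = model$config$threshold) {
  assert_that(length(specs) > 0, "empty noise spec list")
  assert_that(length(records) > 0, "empty record set")
  y <- as01(labels)
  eval_rows <- function(recs, name) {
    sc <- predict_scores(model, recs, threshold)$score
    cbind(data.frame(condition = name), metrics_row(sc, y, threshold))
  }
  rows <- list(eval_rows(records, "clean"))
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    if (sp$amplitude == 0 &&
        !(sp$noise_type == "time_mask" && sp$segment_fraction > 0)) {
      r <- rows[[1]]; r$condition <- nm       # identity spec: share clean row
      rows[[nm]] <- r
    } else {
      rows[[nm]] <- eval_rows(lapply(records, apply_noise, spec = sp), nm)
    }
  }
  out <- do.call(rbind, rows)
  out$delta_auroc <- out$auroc - out$auroc[1]
  out$delta_sensitivity <- out$sensitivity - out$sensitivity[1]
  out$delta_specificity <- out$specificity - out$specificity[1]
  rownames(out) <- NULL
  out
}
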