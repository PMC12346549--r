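#' Canonical 12-lead names, in the fixed package-wide order
#'
#' Limb leads I, II, III, augmented leads aVR, aVL, aVF, then precordials
#' V1--V6. Every `ecg_record` stores its signal rows in this order; readers
#' reorder on ingest so downstream modules can never see a permuted lead set
#' silently -- the very failure mode the lead-reversal module simulates.
#' @export
ECG_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))

#' Construct a 12-lead ECG record
#'
#' The canonical in-memory ECG container: a 12 x N voltage matrix in mV with
#' a sampling rate and the fixed lead order [ECG_LEADS].
#'
#' @param record_id character scalar identifier.
#' @param signal numeric matrix, 12 rows (leads, canonical order), N columns
#'   (samples), units mV. All values must be finite.
#' @param sampling_rate sampling frequency in Hz (positive).
#' @param lead_names lead names for the rows of `signal`; if they are a
#'   permutation of [ECG_LEADS] the rows are reordered to canonical order.
#' @return an object of class `ecg_record` with fields `record_id`, `signal`,
#'   `sampling_rate`, `lead_names`, `duration_s`.
#' @export
ecg_record <- function(record_id, signal, sampling_rate, lead_names = ECG_LEADS) {
  assert_that(is.character(record_id) && length(record_id) == 1L,
              "record_id must be a single string")
  signal <- as.matrix(signal)
  assert_that(nrow(signal) == 12L,
              "signal must have exactly 12 rows (got %d)", nrow(signal))
  assert_that(all(is.finite(signal)), "signal contains non-finite values")
  assert_that(is.numeric(sampling_rate) && length(sampling_rate) == 1L &&
              sampling_rate > 0, "sampling_rate must be a positive scalar")
  assert_that(length(lead_names) == 12L, "lead_names must have length 12")
  missing <- setdiff(ECG_LEADS, lead_names)
  if (length(missing))
    stopf("missing leads: %s", paste(missing, collapse = ", "))
  if (!identical(as.character(lead_names), ECG_LEADS))
    signal <- signal[match(ECG_LEADS, lead_names), , drop = FALSE]
  rownames(signal) <- ECG_LEADS
  structure(
    list(record_id = record_id,
         signal = signal,
         sampling_rate = as.numeric(sampling_rate),
         lead_names = ECG_LEADS,
         duration_s = ncol(signal) / as.numeric(sampling_rate)),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s> 12 x %d @ %g Hz (%.3g s), range [%.3g, %.3g] mV\n",
              x$record_id, ncol(x$signal), x$sampling_rate, x$duration_s,
              min(x$signal), max(x$signal)))
  invisible(x)
}

is_ecg_record <- function(x) inherits(x, "ecg_record")

#' Check the derived-lead identities of a 12-lead record
#'
#' When the limb leads derive from three electrode potentials the identities
#' III = II - I, aVR = -(I+II)/2, aVL = I - II/2 and aVF = II - I/2 hold
#' exactly (Einthoven's law and the augmented-lead definitions). Records from
#' [simulate_record()] satisfy them with deviation 0; digitized or corrupted
#' data may not.
#'
#' @param record an [ecg_record()].
#' @param tolerance maximum allowed absolute deviation in mV (default 1e-6).
#' @return list with `consistent` (logical) and `deviations`, the named
#'   per-identity maximum absolute deviation in mV.
#' @export
lead_consistency_check <- function(record, tolerance = 1e-6) {
  s <- record$signal
  dev <- c(III = max(abs(s["III", ] - (s["II", ] - s["I", ]))),
           aVR = max(abs(s["aVR", ] + (s["I", ] + s["II", ]) / 2)),
           aVL = max(abs(s["aVL", ] - (s["I", ] - s["II", ] / 2))),
           aVF = max(abs(s["aVF", ] - (s["II", ] - s["I", ] / 2))))
  list(consistent = all(dev <= tolerance), deviations = dev)
}

#' Quality-screening configuration
#'
#' Defaults: a lead is flat if its standard deviation falls below 0.01 mV;
#' clipping is flagged for runs of 10 or more consecutive samples pinned at
#' the lead's extreme value beyond `clip_limit_mv`; any non-finite sample
#' fails; samples beyond `range_mv` are out of range.
#' @param flat_sd_mv,clip_run,clip_limit_mv,range_mv thresholds (see above).
#' @return a named list of thresholds.
#' @export
quality_config <- function(flat_sd_mv = 0.01, clip_run = 10L,
                           clip_limit_mv = 2, range_mv = 10) {
  list(flat_sd_mv = flat_sd_mv, clip_run = as.integer(clip_run),
       clip_limit_mv = clip_limit_mv, range_mv = range_mv)
}

#' Screen an ECG record for common quality defects
#'
#' Deterministic rule-based screen: flat leads, non-finite samples, rail
#' clipping and out-of-range voltages. The report passes iff no flag fires.
#'
#' @param record an [ecg_record()] (non-finite samples are tolerated here and
#'   reported, unlike the constructor -- pass a raw signal via `signal=`).
#' @param config thresholds from [quality_config()].
#' @param signal optional raw 12 x N matrix to screen instead of
#'   `record$signal` (allows screening data that cannot construct a record).
#' @return list with `record_id`, `passed`, and `flags`, a named list of
#'   integer lead indices per defect type.
#' @export
quality_screen <- function(record, config = quality_config(), signal = NULL) {
  s <- signal %||% record$signal
  flags <- list(flat_lead = integer(0), missing_samples = integer(0),
                clipping = integer(0), out_of_range = integer(0))
  for (i in seq_len(nrow(s))) {
    x <- s[i, ]
    if (any(!is.finite(x))) {
      flags$missing_samples <- c(flags$missing_samples, i)
      x <- x[is.finite(x)]
      if (!length(x)) next
    }
    if (stats::sd(x) < config$flat_sd_mv)
      flags$flat_lead <- c(flags$flat_lead, i)
    if (any(abs(x) > config$range_mv))
      flags$out_of_range <- c(flags$out_of_range, i)
    rail <- max(abs(x))
    if (rail >= config$clip_limit_mv) {
      at_rail <- abs(x) >= rail - 1e-12
      r <- rle(at_rail)
      if (any(r$lengths[r$values] >= config$clip_run))
        flags$clipping <- c(flags$clipping, i)
    }
  }
  flags <- flags[vapply(flags, length, 1L) > 0L]
  list(record_id = if (is.null(record)) NA_character_ else record$record_id,
       passed = length(flags) == 0L, flags = flags)
}

# Windowed-sinc FIR low-pass kernel (Hamming window), cutoff in cycles/sample.
sinc_lowpass_kernel <- function(cutoff_norm, taps = 63L) {
  m <- seq(-(taps %/% 2), taps %/% 2)
  h <- 2 * cutoff_norm * sinc(2 * cutoff_norm * m)
  w <- 0.54 + 0.46 * cos(pi * m / (taps %/% 2))
  h <- h * w
  h / sum(h)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Zero-phase FIR filtering with edge replication padding.
fir_filter <- function(x, kernel) {
  m <- length(kernel) %/% 2
  xp <- c(rep(x[1], m), x, rep(x[length(x)], m))
  y <- stats::filter(xp, kernel, method = "convolution", sides = 2)
  as.numeric(y)[(m + 1):(m + length(x))]
}

#' Resample a record to a new sampling rate
#'
#' Downsampling applies a windowed-sinc anti-aliasing low-pass with cutoff at
#' 0.9 x the target Nyquist frequency before interpolation; upsampling
#' interpolates directly (and emits a message, since it adds no information).
#' The output has `round(duration_s * target_rate)` samples per lead, so a
#' 10 s record at 500 Hz resampled to 250 Hz becomes 12 x 2500.
#'
#' @param record an [ecg_record()].
#' @param target_rate target sampling rate in Hz (> 0).
#' @return resampled [ecg_record()] of identical duration.
#' @export
resample_record <- function(record, target_rate) {
  assert_that(is.numeric(target_rate) && length(target_rate) == 1L &&
              target_rate > 0, "target_rate must be a positive scalar")
  fs <- record$sampling_rate
  if (target_rate == fs) return(record)
  if (target_rate > fs)
    message(sprintf("upsampling %g -> %g Hz: interpolation only", fs, target_rate))
  n_in <- ncol(record$signal)
  n_out <- round(record$duration_s * target_rate)
  t_in <- (seq_len(n_in) - 1) / fs
  t_out <- (seq_len(n_out) - 1) / target_rate
  s <- record$signal
  if (target_rate < fs) {
    kern <- sinc_lowpass_kernel(0.9 * (target_rate / 2) / fs)
    s <- t(apply(s, 1L, fir_filter, kernel = kern))
  }
  out <- t(apply(s, 1L, function(x)
    stats::approx(t_in, x, xout = pmin(t_out, t_in[n_in]), rule = 2)$y))
  ecg_record(record$record_id, out, target_rate)
}
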