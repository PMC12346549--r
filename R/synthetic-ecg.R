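#' Morphology parameters for the synthetic beat generator
#'
#' Parameters of one subject's beat morphology. The generator synthesizes a
#' 3-D cardiac dipole as a sum of Gaussian bumps (P, Q, R, S, T, plus
#' optional notch and late anterior deflections), projects it onto nine
#' electrode lead-field vectors (RA, LA, LL, V1--V6) and forms the 12 leads
#' from potential differences, so Einthoven and augmented-lead identities
#' hold exactly by construction.
#'
#' @param heart_rate beats per minute, in \[20, 250\].
#' @param rhythm_irregularity coefficient of variation of RR intervals,
#'   \[0, 1\]. Sinus rhythm ~0.02--0.06; atrial fibrillation > 0.2.
#' @param qrs_width_ms nominal QRS duration in ms, \[60, 220\]; normal ~90,
#'   bundle branch block >= 120.
#' @param qrs_amplitude_scale unitless scale of the QRS dipole (> 0).
#' @param t_polarity +1 (concordant T) or -1 (T inversion).
#' @param q_wave_depth_scale unitless scale of the Q-wave bump (> 0);
#'   values > 2 produce pathological Q waves.
#' @param frontal_axis_deg frontal-plane QRS axis in degrees (0 = leftward,
#'   90 = inferior); normal -30..+90, left axis deviation < -30, right > +90.
#' @param qt_scale unitless scale of the QT interval (> 0); > 1.2 models
#'   prolonged QT.
#' @param noise_floor_mv standard deviation of white electrode noise in mV
#'   (added at the electrode-potential level, preserving lead identities).
#' @param p_amplitude unitless P-wave scale; 0 suppresses the P wave (AF).
#' @param qrs_notch unitless amplitude of a mid-QRS notch bump (LBBB-like).
#' @param anterior_late unitless amplitude of a late anteriorly-directed QRS
#'   deflection, dominant in V1 (RBBB-like rSR').
#' @return a validated `morphology_params` list.
#' @export
morphology_params <- function(heart_rate = 70, rhythm_irregularity = 0.03,
                              qrs_width_ms = 90, qrs_amplitude_scale = 1,
                              t_polarity = 1, q_wave_depth_scale = 1,
                              frontal_axis_deg = 45, qt_scale = 1,
                              noise_floor_mv = 0.01, p_amplitude = 1,
                              qrs_notch = 0, anterior_late = 0) {
  p <- list(heart_rate = heart_rate, rhythm_irregularity = rhythm_irregularity,
            qrs_width_ms = qrs_width_ms,
            qrs_amplitude_scale = qrs_amplitude_scale,
            t_polarity = t_polarity, q_wave_depth_scale = q_wave_depth_scale,
            frontal_axis_deg = frontal_axis_deg, qt_scale = qt_scale,
            noise_floor_mv = noise_floor_mv, p_amplitude = p_amplitude,
            qrs_notch = qrs_notch, anterior_late = anterior_late)
  assert_that(heart_rate >= 20 && heart_rate <= 250,
              "heart_rate %g outside [20, 250]", heart_rate)
  assert_that(qrs_width_ms >= 60 && qrs_width_ms <= 220,
              "qrs_width_ms %g outside [60, 220]", qrs_width_ms)
  assert_that(rhythm_irregularity >= 0 && rhythm_irregularity <= 1,
              "rhythm_irregularity %g outside [0, 1]", rhythm_irregularity)
  assert_that(qrs_amplitude_scale > 0 && q_wave_depth_scale > 0 && qt_scale > 0,
              "scale parameters must be > 0")
  assert_that(t_polarity %in% c(-1, 1), "t_polarity must be +1 or -1")
  assert_that(noise_floor_mv >= 0, "noise_floor_mv must be >= 0")
  structure(p, class = "morphology_params")
}

# Electrode lead-field vectors (rows: RA, LA, LL, V1..V6) in a body frame
# with x toward the left arm, y inferior, z anterior. Limb vectors form an
# equilateral (Einthoven) triangle so lead I points at 0 deg and aVF at
# 90 deg on the hexaxial reference; chest vectors carry independent x/z
# mixes so the Wilson-terminal pathway is exercised by lead reversals.
lead_field_matrix <- function() {
  rbind(RA = c(-0.5, -0.28867513459481287, 0),
        LA = c( 0.5, -0.28867513459481287, 0),
        LL = c( 0.0,  0.57735026918962573, 0),
        V1 = c(-0.30, 0.00, 0.70),
        V2 = c(-0.10, 0.05, 0.90),
        V3 = c( 0.10, 0.10, 0.80),
        V4 = c( 0.30, 0.15, 0.60),
        V5 = c( 0.50, 0.20, 0.40),
        V6 = c( 0.70, 0.20, 0.20))
}

# Gaussian-bump description of one beat's dipole trajectory. Times in s
# relative to the R peak; each bump has a 3-D direction.
beat_bumps <- function(p) {
  w <- p$qrs_width_ms / 1000
  ax <- p$frontal_axis_deg * pi / 180
  u_qrs <- c(cos(ax), sin(ax), 0.25)        # QRS axis, slightly anterior
  u_t <- c(cos(ax), sin(ax), 0.10)          # T concordant with QRS by default
  u_p <- c(cos(60 * pi / 180), sin(60 * pi / 180), 0.05)
  amp <- 1.2 * p$qrs_amplitude_scale
  bumps <- list(
    list(center = -0.17, sd = 0.025, amp = 0.12 * p$p_amplitude, dir = u_p),
    list(center = -0.30 * w, sd = 0.10 * w,
         amp = -0.20 * amp * p$q_wave_depth_scale, dir = u_qrs),
    list(center = 0, sd = 0.18 * w, amp = amp, dir = u_qrs),
    list(center = 0.30 * w, sd = 0.10 * w, amp = -0.25 * amp, dir = u_qrs),
    list(center = 0.32 * p$qt_scale, sd = 0.055 * p$qt_scale,
         amp = 0.35 * p$t_polarity, dir = u_t))
  if (p$qrs_notch > 0)
    bumps <- c(bumps, list(list(center = 0.18 * w, sd = 0.07 * w,
                                amp = p$qrs_notch * amp, dir = u_qrs)))
  if (p$anterior_late > 0)
    bumps <- c(bumps, list(list(center = 0.35 * w, sd = 0.10 * w,
                                amp = p$anterior_late * amp, dir = c(-0.2, -0.1, 1))))
  bumps
}

# Dipole trajectory d(t) (3 x N) for beats at `beat_times` seconds.
dipole_series <- function(p, t, beat_times) {
  d <- matrix(0, 3L, length(t))
  bumps <- beat_bumps(p)
  for (bt in beat_times)
    for (b in bumps) {
      g <- b$amp * exp(-((t - bt - b$center)^2) / (2 * b$sd^2))
      d <- d + outer(b$dir, g)
    }
  d
}

potentials_to_leads <- function(phi_limb, chest) {
  ra <- phi_limb[1, ]; la <- phi_limb[2, ]; ll <- phi_limb[3, ]
  I <- la - ra; II <- ll - ra
  # derived leads computed from I and II with the same arithmetic as
  # lead_consistency_check, so the identities hold bitwise (deviation 0)
  rbind(I = I, II = II, III = II - I,
        aVR = -(I + II) / 2, aVL = I - II / 2, aVF = II - I / 2, chest)
}

#' Simulate one physically consistent 12-lead ECG record
#'
#' Synthesizes limb and chest electrode potentials from a beat-template
#' dipole projection and forms the 12 leads from potential differences.
#' Electrode noise is injected at the potential level, so
#' [lead_consistency_check()] passes with deviation 0 whatever the noise
#' floor. Identical `(params, seed)` give bitwise-identical records.
#'
#' @param params a [morphology_params()].
#' @param fs sampling rate in Hz.
#' @param duration_s record duration in seconds.
#' @param seed integer seed.
#' @param record_id identifier (default derived from the seed).
#' @return an [ecg_record()] with attributes `beat_times_s` (ground-truth R
#'   peak times) and `params`.
#' @export
simulate_record <- function(params, fs = 250, duration_s = 10, seed = 1,
                            record_id = sprintf("sim%06d", seed)) {
  assert_that(inherits(params, "morphology_params"),
              "params must come from morphology_params()")
  with_seed(seed, {
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    mean_rr <- 60 / params$heart_rate
    n_beats <- ceiling(duration_s / mean_rr) + 3L
    rr <- mean_rr * pmax(0.35, 1 + params$rhythm_irregularity * stats::rnorm(n_beats))
    beat_times <- cumsum(c(stats::runif(1, 0.1, 0.1 + mean_rr), rr[-1]))
    beat_times <- beat_times[beat_times < duration_s + 0.4]
    d <- dipole_series(params, t, beat_times)
    lf <- lead_field_matrix()
    phi <- lf %*% d                                   # 9 x N raw potentials
    if (params$noise_floor_mv > 0)
      phi <- phi + matrix(stats::rnorm(length(phi), sd = params$noise_floor_mv),
                          nrow(phi))
    wct <- colMeans(phi[1:3, , drop = FALSE])         # Wilson central terminal
    phi_limb <- sweep(phi[1:3, , drop = FALSE], 2L, wct)
    chest <- sweep(phi[4:9, , drop = FALSE], 2L, wct)
    rec <- ecg_record(record_id, potentials_to_leads(phi_limb, chest), fs)
    attr(rec, "beat_times_s") <- beat_times[beat_times >= 0 & beat_times < duration_s]
    attr(rec, "params") <- params
    rec
  })
}

#' Measure QRS width of a morphology's noiseless beat template
#'
#' Threshold-crossing width: duration over which the QRS-complex dipole
#' magnitude exceeds 10% of its peak, measured on a finely sampled noiseless
#' single beat (T and P bumps excluded). Used as the independent width
#' oracle for generator tests.
#'
#' @param params a [morphology_params()].
#' @param fs_fine template sampling rate in Hz.
#' @return width in ms.
#' @export
measure_template_qrs_width <- function(params, fs_fine = 2000) {
  w <- params$qrs_width_ms / 1000
  t <- seq(-w, w, by = 1 / fs_fine)
  bumps <- beat_bumps(params)
  qrs <- bumps[vapply(bumps, function(b) abs(b$center) <= 0.5 * w, TRUE)]
  d <- matrix(0, 3L, length(t))
  for (b in qrs) d <- d + outer(b$dir, b$amp * exp(-(t - b$center)^2 / (2 * b$sd^2)))
  mag <- sqrt(colSums(d^2))
  above <- which(mag > 0.1 * max(mag))
  (t[max(above)] - t[min(above)]) * 1000
}

#' Detect R peaks and summarize the RR series of a record
#'
#' Simple amplitude-threshold detector on lead II: local maxima of |II|
#' above half the lead maximum, separated by at least 250 ms.
#'
#' @param record an [ecg_record()].
#' @param lead lead to use (default `"II"`).
#' @return list with `peaks_s`, `rr_s` and `rr_cv` (coefficient of variation).
#' @export
detect_r_peaks <- function(record, lead = "II") {
  x <- abs(record$signal[lead, ])
  fs <- record$sampling_rate
  thr <- 0.5 * max(x)
  min_gap <- round(0.25 * fs)
  cand <- which(x >= thr)
  peaks <- integer(0)
  while (length(cand)) {
    seg <- cand[cand <= cand[1] + min_gap]
    peaks <- c(peaks, seg[which.max(x[seg])])
    cand <- cand[cand > peaks[length(peaks)] + min_gap]
  }
  rr <- diff(peaks) / fs
  list(peaks_s = (peaks - 1) / fs, rr_s = rr,
       rr_cv = if (length(rr) > 1) stats::sd(rr) / mean(rr) else NA_real_)
}

#' Net QRS area of a lead (axis oracle)
#'
#' Integrates each lead over +/- 0.6 QRS widths around the ground-truth beat
#' times, giving the net (signed) QRS area used to verify axis placement.
#'
#' @param record a record from [simulate_record()] (needs its attributes).
#' @param lead lead name.
#' @return net area in mV.s summed across beats.
#' @export
net_qrs_area <- function(record, lead) {
  bt <- attr(record, "beat_times_s")
  p <- attr(record, "params")
  assert_that(!is.null(bt) && !is.null(p),
              "record lacks generator attributes (not from simulate_record)")
  fs <- record$sampling_rate
  half <- 0.6 * p$qrs_width_ms / 1000
  x <- record$signal[lead, ]
  t <- (seq_along(x) - 1) / fs
  keep <- Reduce(`|`, lapply(bt, function(b) abs(t - b) <= half))
  sum(x[keep]) / fs
}

# -- class-conditional morphology distributions -------------------------------

rnorm_clip <- function(n, mu, sd, lo, hi) pmin(hi, pmax(lo, stats::rnorm(n, mu, sd)))

#' Default class-conditional morphology configurations
#'
#' The stated world of the default synthetic cohort. The LVSD-like class has
#' wider QRS, lower QRS amplitude, deeper Q waves, more frequent T-wave
#' inversion, a leftward-shifted axis and a more irregular rhythm; the
#' non-LVSD class is neutral. Each entry is `c(mean, sd, lo, hi)` for
#' clipped-normal draws, `c(lo, hi)` for uniform draws, or a probability.
#'
#' @return named list with `LVSD` and `non-LVSD` sampling configurations.
#' @export
default_class_configs <- function() {
  list(
    "LVSD" = list(qrs_width_ms = c(135, 15, 106, 180),
                  qrs_amplitude = c(0.80, 0.10, 0.50, 1.05),
                  t_inversion_prob = 0.60,
                  irregularity = c(0.05, 0.30),
                  axis = c(-10, 25, -80, 100),
                  q_depth = c(1.6, 0.4, 0.8, 3.0),
                  qt = c(1.12, 0.06, 0.9, 1.4),
                  heart_rate = c(80, 14, 45, 130)),
    "non-LVSD" = list(qrs_width_ms = c(90, 8, 70, 110),
                      qrs_amplitude = c(1.05, 0.08, 0.80, 1.30),
                      t_inversion_prob = 0.05,
                      irregularity = c(0.01, 0.06),
                      axis = c(45, 15, -25, 85),
                      q_depth = c(1.0, 0.15, 0.6, 1.5),
                      qt = c(1.0, 0.05, 0.85, 1.2),
                      heart_rate = c(72, 11, 45, 110)))
}

#' Class configurations differing in a single trait
#'
#' Both classes use the neutral (non-LVSD) distributions except for the named
#' trait, which takes its LVSD-class distribution in the positive class.
#' Used for causal TCAV experiments where the surrogate's positive class is
#' defined by exactly one morphology trait.
#'
#' @param trait one of `"qrs_width_ms"`, `"qrs_amplitude"`,
#'   `"t_inversion_prob"`, `"irregularity"`, `"axis"`, `"q_depth"`, `"qt"`.
#' @return class-config list as in [default_class_configs()].
#' @export
single_trait_class_configs <- function(trait = "qrs_width_ms") {
  cfg <- default_class_configs()
  assert_that(trait %in% names(cfg$`LVSD`), "unknown trait '%s'", trait)
  pos <- cfg$`non-LVSD`
  pos[[trait]] <- cfg$`LVSD`[[trait]]
  list("LVSD" = pos, "non-LVSD" = cfg$`non-LVSD`)
}

sample_morphology <- function(cfg, noise_floor_mv = 0.01) {
  u <- function(v) stats::runif(1, v[1], v[2])
  cn <- function(v) rnorm_clip(1, v[1], v[2], v[3], v[4])
  morphology_params(
    heart_rate = cn(cfg$heart_rate),
    rhythm_irregularity = u(cfg$irregularity),
    qrs_width_ms = cn(cfg$qrs_width_ms),
    qrs_amplitude_scale = cn(cfg$qrs_amplitude),
    t_polarity = if (stats::runif(1) < cfg$t_inversion_prob) -1 else 1,
    q_wave_depth_scale = cn(cfg$q_depth),
    frontal_axis_deg = cn(cfg$axis),
    qt_scale = cn(cfg$qt),
    noise_floor_mv = noise_floor_mv)
}

sample_metadata <- function(record_id, label) {
  if (label == "LVSD") {
    lvef <- stats::runif(1, 15, 40)
    age <- rnorm_clip(1, 67.5, 13.6, 25, 95)
    probs <- c(male = 0.684, htn = 0.49, dm = 0.49, cad = 0.367, ckd = 0.143)
  } else {
    repeat { lvef <- stats::rnorm(1, 64, 7); if (lvef > 40 && lvef < 85) break }
    age <- rnorm_clip(1, 59.6, 14.7, 20, 95)
    probs <- c(male = 0.485, htn = 0.412, dm = 0.16, cad = 0.117, ckd = 0.029)
  }
  flags <- stats::runif(5) < probs
  data.frame(record_id = record_id, label = label, lvef_percent = lvef,
             age = age, sex = ifelse(flags[1], "M", "F"),
             htn = flags[2], dm = flags[3], cad = flags[4], ckd = flags[5],
             stringsAsFactors = FALSE)
}

#' Simulate a labeled two-class ECG cohort
#'
#' Generates `n_pos` LVSD-like and `n_neg` non-LVSD records with morphology
#' drawn from class-conditional distributions and per-record metadata
#' (LVEF, age, sex, comorbidity flags). The label is `"LVSD"` iff the
#' simulated LVEF is <= 40. Fully determined by `(arguments, seed)`.
#'
#' @param n_pos,n_neg class counts (> 0).
#' @param class_configs from [default_class_configs()] (the default) or
#'   [single_trait_class_configs()].
#' @param fs,duration_s sampling rate (Hz) and duration (s) per record.
#' @param seed integer seed.
#' @param id_prefix record id prefix.
#' @return list with `records` (named list of [ecg_record()]) and `metadata`
#'   (data.frame, joinable on `record_id`, plus a `qrs_width_ms` ground-truth
#'   column and the per-record `seed`).
#' @export
simulate_cohort <- function(n_pos, n_neg, class_configs = default_class_configs(),
                            fs = 250, duration_s = 10, seed = 1,
                            id_prefix = "rec") {
  assert_that(n_pos > 0 && n_neg > 0, "class counts must be > 0")
  labels <- c(rep("LVSD", n_pos), rep("non-LVSD", n_neg))
  n <- length(labels)
  records <- vector("list", n)
  meta <- vector("list", n)
  seeds <- with_seed(seed, sample.int(2^30, n))
  for (i in seq_len(n)) {
    rid <- sprintf("%s%05d", id_prefix, i)
    params <- with_seed(seeds[i], sample_morphology(class_configs[[labels[i]]]))
    records[[i]] <- simulate_record(params, fs, duration_s,
                                    seed = seeds[i] + 1L, record_id = rid)
    meta[[i]] <- with_seed(seeds[i] + 2L, sample_metadata(rid, labels[i]))
    meta[[i]]$qrs_width_ms <- params$qrs_width_ms
    meta[[i]]$seed <- seeds[i]
  }
  names(records) <- vapply(records, `[[`, "", "record_id")
  list(records = records, metadata = do.call(rbind, meta))
}

#' The nine ECG concepts
#'
#' Concept names accepted by [make_concept_dataset()]: atrial fibrillation /
#' flutter, left and right bundle branch block, left and right axis
#' deviation, prolonged QT, nonspecific conduction disorder, abnormal Q wave
#' and abnormal T wave.
#' @export
ECG_CONCEPTS <- c("AF", "LBBB", "RBBB", "LAD", "RAD", "prolonged_qt",
                  "conduction_disorder", "abnormal_q_wave", "abnormal_t_wave")

concept_overrides <- function(concept_name) {
  switch(concept_name,
    AF = list(irregularity = c(0.25, 0.45), p_amplitude = 0,
              heart_rate = c(95, 15, 60, 150)),
    LBBB = list(qrs_width_ms = c(145, 10, 122, 175), qrs_notch = 0.5),
    RBBB = list(qrs_width_ms = c(140, 10, 120, 170), anterior_late = 0.8),
    LAD = list(axis = c(-55, 8, -75, -38)),
    RAD = list(axis = c(120, 12, 95, 155)),
    prolonged_qt = list(qt = c(1.35, 0.05, 1.25, 1.5)),
    conduction_disorder = list(qrs_width_ms = c(140, 12, 121, 175)),
    abnormal_q_wave = list(q_depth = c(3.0, 0.4, 2.4, 4.0)),
    abnormal_t_wave = list(t_inversion_prob = 1),
    stopf("unknown concept '%s'; valid concepts: %s", concept_name,
          paste(ECG_CONCEPTS, collapse = ", ")))
}

sample_concept_morphology <- function(concept_name) {
  cfg <- default_class_configs()$`non-LVSD`
  ov <- concept_overrides(concept_name)
  simple <- intersect(names(ov), names(cfg))
  cfg[simple] <- ov[simple]
  p <- sample_morphology(cfg)
  for (f in setdiff(names(ov), names(cfg))) p[[f]] <- ov[[f]]
  # re-validate after direct field overrides
  do.call(morphology_params, unclass(p))
}

#' Generate a concept dataset (positives with the trait, neutral negatives)
#'
#' Positives exhibit the concept's defining trait by construction: LBBB and
#' nonspecific conduction disorder have QRS width >= 120 ms (LBBB with a
#' notched mid-QRS bump, RBBB with a V1-dominant late anterior deflection);
#' AF has high RR irregularity and no P wave; LAD/RAD place the frontal axis
#' beyond -30 / +90 degrees; prolonged QT scales the QT interval >= 1.25;
#' abnormal Q / T deform the corresponding template bumps. Negatives are
#' drawn from the neutral (non-LVSD) morphology distribution.
#'
#' @param concept_name one of [ECG_CONCEPTS].
#' @param n_pos,n_neg set sizes (> 0).
#' @param fs,duration_s record geometry.
#' @param seed integer seed.
#' @return list of class `concept_dataset` with `concept_name`, `positives`
#'   and `random_negatives` (lists of [ecg_record()]).
#' @export
make_concept_dataset <- function(concept_name, n_pos = 30, n_neg = 30,
                                 fs = 250, duration_s = 10, seed = 1) {
  concept_overrides(concept_name)  # validates the name
  assert_that(n_pos > 0 && n_neg > 0, "set sizes must be > 0")
  seeds <- with_seed(seed, sample.int(2^30, n_pos + n_neg))
  pos <- lapply(seq_len(n_pos), function(i) {
    p <- with_seed(seeds[i], sample_concept_morphology(concept_name))
    simulate_record(p, fs, duration_s, seed = seeds[i] + 1L,
                    record_id = sprintf("%s_pos%04d_s%d", concept_name, i, seed))
  })
  neg <- lapply(seq_len(n_neg), function(i) {
    j <- n_pos + i
    p <- with_seed(seeds[j], sample_morphology(default_class_configs()$`non-LVSD`))
    simulate_record(p, fs, duration_s, seed = seeds[j] + 1L,
                    record_id = sprintf("%s_neg%04d_s%d", concept_name, i, seed))
  })
  structure(list(concept_name = concept_name, positives = pos,
                 random_negatives = neg), class = "concept_dataset")
}

#' Generate a pool of neutral-morphology records
#'
#' Random pools for TCAV: records drawn from the neutral (non-LVSD)
#' distribution, used as concept-free negatives and for null calibration.
#'
#' @param n pool size.
#' @param fs,duration_s record geometry.
#' @param seed integer seed.
#' @return list of [ecg_record()].
#' @export
make_random_pool <- function(n = 30, fs = 250, duration_s = 10, seed = 1) {
  seeds <- with_seed(seed, sample.int(2^30, n))
  lapply(seq_len(n), function(i) {
    p <- with_seed(seeds[i], sample_morphology(default_class_configs()$`non-LVSD`))
    simulate_record(p, fs, duration_s, seed = seeds[i] + 1L,
                    record_id = sprintf("pool%04d_s%d", i, seed))
  })
}
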