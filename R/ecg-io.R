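#' Read a 12-lead ECG record from disk
#'
#' Supported formats:
#' \describe{
#'   \item{csv}{One metadata comment line `# record_id=<id> fs=<Hz>`, a
#'     header row `time_s,I,II,...,V6`, one row per sample, voltages in mV.
#'     Round-trips written by [write_ecg()] are value-exact.}
#'   \item{wfdb}{A minimal WFDB subset: `.hea` header plus format-16 `.dat`
#'     (16-bit little-endian, interleaved), gain and baseline honored, units
#'     converted to mV. Exact to ADC quantization (1/gain mV).}
#'   \item{rds}{Array container: an RDS file holding `signal` (12 x N, mV),
#'     `fs`, `lead_names`, `record_id`. Value-exact.}
#' }
#' Leads in non-canonical source order are reordered to [ECG_LEADS]; a file
#' that does not declare all 12 leads raises an error naming the absent ones.
#'
#' @param path file path (for WFDB, the `.hea` path or the record stem).
#' @param format one of `"csv"`, `"wfdb"`, `"rds"`; guessed from the
#'   extension when missing.
#' @return an [ecg_record()].
#' @export
read_ecg <- function(path, format = c("auto", "csv", "wfdb", "rds")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", rds = "rds", hea = "wfdb", dat = "wfdb",
                     stopf("cannot guess format from extension '%s'", ext))
  }
  switch(format,
         csv = read_ecg_csv(path),
         wfdb = read_ecg_wfdb(path),
         rds = read_ecg_rds(path))
}

#' Write a 12-lead ECG record to disk
#'
#' See [read_ecg()] for the format descriptions. CSV and RDS round-trip
#' bitwise on voltage values; WFDB quantizes to the ADC step (1/gain mV).
#' The canonical lead order is always written in the header.
#'
#' @param record an [ecg_record()].
#' @param path output path (for WFDB the `.hea` path; the `.dat` is written
#'   alongside).
#' @param format one of `"csv"`, `"wfdb"`, `"rds"`.
#' @param gain WFDB ADC gain in units/mV (default 1000).
#' @return the path, invisibly.
#' @export
write_ecg <- function(record, path, format = c("csv", "wfdb", "rds"),
                      gain = 1000) {
  format <- match.arg(format)
  assert_that(is_ecg_record(record), "record must be an ecg_record")
  switch(format,
         csv = write_ecg_csv(record, path),
         wfdb = write_ecg_wfdb(record, path, gain),
         rds = saveRDS(list(signal = record$signal, fs = record$sampling_rate,
                            lead_names = record$lead_names,
                            record_id = record$record_id), path))
  invisible(path)
}

# -- CSV dialect --------------------------------------------------------------

write_ecg_csv <- function(record, path) {
  n <- ncol(record$signal)
  t_s <- (seq_len(n) - 1) / record$sampling_rate
  body <- matrix(sprintf("%.17g", rbind(t_s, record$signal)), nrow = 13L)
  lines <- c(sprintf("# record_id=%s fs=%.17g", record$record_id,
                     record$sampling_rate),
             paste(c("time_s", ECG_LEADS), collapse = ","),
             apply(body, 2L, paste, collapse = ","))
  writeLines(lines, path)
}

read_ecg_csv <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- regmatches(first, regexec("# record_id=(\\S+) fs=(\\S+)", first))[[1]]
  assert_that(length(meta) == 3L, "CSV missing '# record_id=... fs=...' line")
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  have <- setdiff(names(df), "time_s")
  missing <- setdiff(ECG_LEADS, have)
  if (length(missing))
    stopf("CSV is missing leads: %s", paste(missing, collapse = ", "))
  sig <- t(as.matrix(df[, ECG_LEADS]))
  ecg_record(meta[2], sig, as.numeric(meta[3]))
}

# -- minimal WFDB subset (format 16) ------------------------------------------

write_ecg_wfdb <- function(record, path, gain = 1000) {
  stem <- sub("\\.hea$", "", path)
  name <- basename(stem)
  n <- ncol(record$signal)
  adc <- round(record$signal * gain)
  assert_that(all(abs(adc) <= 32767),
              "signal exceeds int16 range at gain %g", gain)
  hdr <- c(sprintf("%s 12 %.17g %d", name, record$sampling_rate, n),
           sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
                   name, gain, as.integer(adc[, 1]), ECG_LEADS))
  writeLines(hdr, paste0(stem, ".hea"))
  con <- file(paste0(stem, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.integer(adc), con, size = 2L, endian = "little")
}

read_ecg_wfdb <- function(path) {
  stem <- sub("\\.(hea|dat)$", "", path)
  hdr <- readLines(paste0(stem, ".hea"))
  hdr <- hdr[!grepl("^#", hdr)]
  top <- strsplit(trimws(hdr[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3]); n <- as.integer(top[4])
  assert_that(!is.na(nsig) && !is.na(fs) && !is.na(n),
              "unparseable WFDB header line: %s", hdr[1])
  specs <- lapply(hdr[1 + seq_len(nsig)], function(l) strsplit(trimws(l), "\\s+")[[1]])
  fmt <- vapply(specs, `[`, "", 2L)
  assert_that(all(fmt == "16"), "only WFDB format 16 is supported (got %s)",
              paste(unique(fmt), collapse = ","))
  gainspec <- vapply(specs, `[`, "", 3L)
  m <- regmatches(gainspec, regexec("^([0-9.eE+-]+)(\\(([0-9-]+)\\))?(/(.*))?$", gainspec))
  gain <- vapply(m, function(g) as.numeric(g[2]), 1)
  baseline <- vapply(m, function(g) ifelse(g[4] == "", 0, as.numeric(g[4])), 1)
  units <- vapply(m, function(g) ifelse(g[6] == "", "mV", g[6]), "")
  assert_that(all(units %in% c("mV", "mv")),
              "unknown WFDB units '%s' (only mV supported)",
              paste(setdiff(units, c("mV", "mv")), collapse = ","))
  gain[is.na(gain) | gain == 0] <- 200  # WFDB default gain
  leads <- vapply(specs, function(s) s[length(s)], "")
  missing <- setdiff(ECG_LEADS, leads)
  if (length(missing))
    stopf("WFDB record is missing leads: %s", paste(missing, collapse = ", "))
  con <- file(paste0(stem, ".dat"), "rb")
  on.exit(close(con))
  raw <- readBin(con, integer(), n = nsig * n, size = 2L, signed = TRUE,
                 endian = "little")
  adc <- matrix(raw, nrow = nsig)  # sample-major interleave
  sig <- (adc - baseline) / gain
  ecg_record(basename(stem), sig, fs, lead_names = leads)
}

read_ecg_rds <- function(path) {
  x <- readRDS(path)
  missing <- setdiff(ECG_LEADS, x$lead_names)
  if (length(missing))
    stopf("container is missing leads: %s", paste(missing, collapse = ", "))
  ecg_record(x$record_id, x$signal, x$fs, lead_names = x$lead_names)
}

#' Write a cohort to a directory
#'
#' One signal file per record plus `metadata.csv` with columns exactly
#' `record_id, label, lvef_percent, age, sex, htn, dm, cad, ckd`.
#'
#' @param cohort list with `records` (list of [ecg_record()]) and `metadata`
#'   (data.frame), as returned by [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param format per-record signal format, `"csv"`, `"wfdb"` or `"rds"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "wfdb", "rds")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- c(csv = ".csv", wfdb = ".hea", rds = ".rds")[format]
  for (r in cohort$records)
    write_ecg(r, file.path(dir, paste0(r$record_id, ext)), format)
  cols <- c("record_id", "label", "lvef_percent", "age", "sex",
            "htn", "dm", "cad", "ckd")
  utils::write.csv(cohort$metadata[, cols], file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir cohort directory.
#' @return list with `records` and `metadata`.
#' @export
read_cohort <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "metadata.csv"))
  files <- list.files(dir, pattern = "\\.(csv|hea|rds)$", full.names = TRUE)
  files <- files[basename(files) != "metadata.csv"]
  recs <- lapply(files, read_ecg)
  names(recs) <- vapply(recs, `[[`, "", "record_id")
  list(records = recs[meta$record_id], metadata = meta)
}
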