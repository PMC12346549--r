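#' Reconstruct electrode potentials from a consistent 12-lead record
#'
#' Inverts the standard lead definitions under the Wilson-central-terminal
#' zero convention: phi_RA = -(I+II)/3, phi_LA = (2I-II)/3,
#' phi_LL = (2II-I)/3 (so phi_RA + phi_LA + phi_LL = 0 at every sample), with
#' the right leg equipotential to the left leg (phi_RL = phi_LL) and chest
#' electrode potentials equal to the stored precordial leads. Re-deriving the
#' 12 leads from these potentials reproduces the input to < 1e-9 mV.
#'
#' @param record an [ecg_record()] passing [lead_consistency_check()].
#' @param tolerance consistency tolerance passed to the check.
#' @return list with `phi` (3 x N matrix, rows RA/LA/LL; RL = LL) and
#'   `chest` (6 x N matrix, rows V1--V6).
#' @export
reconstruct_potentials <- function(record, tolerance = 1e-6) {
  chk <- lead_consistency_check(record, tolerance)
  if (!chk$consistent)
    stopf(paste("record %s fails the derived-lead identities (max deviation",
                "%.3g mV); run lead_consistency_check() and repair the record",
                "before reconstructing potentials"),
          record$record_id, max(chk$deviations))
  s <- record$signal
  phi <- rbind(RA = -(s["I", ] + s["II", ]) / 3,
               LA = (2 * s["I", ] - s["II", ]) / 3,
               LL = (2 * s["II", ] - s["I", ]) / 3)
  list(phi = phi, chest = s[paste0("V", 1:6), , drop = FALSE])
}

# Coefficients of each limb site's potential on the (I, II) channel basis,
# under the WCT-zero convention and phi_RL = phi_LL.
SITE_COEF <- rbind(RA = c(-1, -1) / 3,
                   LA = c(2, -1) / 3,
                   LL = c(-1, 2) / 3,
                   RL = c(-1, 2) / 3)

CABLES <- c("RA", "LA", "LL", "RL")

all_limb_permutations <- function() {
  idx <- expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4)
  idx <- idx[apply(idx, 1L, function(r) length(unique(r)) == 4L), ]
  lapply(seq_len(nrow(idx)), function(i) {
    m <- CABLES[unlist(idx[i, ])]
    names(m) <- CABLES
    m
  })
}

# 8x8 transformation matrix of a cable->site mapping on the channel basis
# (I, II, V1..V6): limb rows from site-potential differences, precordial rows
# shifted by the recomputed Wilson terminal of the active cables.
reversal_matrix <- function(mapping) {
  p <- SITE_COEF[mapping[c("RA", "LA", "LL")], , drop = FALSE]  # 3 x 2
  pRA <- p[1, ]; pLA <- p[2, ]; pLL <- p[3, ]
  wct <- (pRA + pLA + pLL) / 3
  T <- matrix(0, 8L, 8L,
              dimnames = list(c("I", "II", paste0("V", 1:6)),
                              c("I", "II", paste0("V", 1:6))))
  T["I", 1:2] <- pLA - pRA
  T["II", 1:2] <- pLL - pRA
  for (i in 1:6) {
    T[paste0("V", i), 1:2] <- -wct
    T[paste0("V", i), paste0("V", i)] <- 1
  }
  T
}

perm_desc <- function(mapping) {
  if (all(mapping == CABLES)) return("nonreversal")
  # cycle decomposition of the cable -> site map
  seen <- character(0); parts <- character(0)
  for (c0 in CABLES) {
    if (c0 %in% seen || mapping[c0] == c0) next
    cyc <- c0; nxt <- mapping[c0]
    while (nxt != c0) { cyc <- c(cyc, nxt); nxt <- mapping[nxt] }
    seen <- c(seen, cyc)
    parts <- c(parts, if (length(cyc) == 2L)
      paste(cyc, collapse = "<->") else paste(c(cyc, cyc[1]), collapse = "->"))
  }
  paste(parts, collapse = " ")
}

#' Enumerate the 12 unique limb lead-reversal morphology classes
#'
#' All 24 bijections of the four limb cables onto the four limb sites are
#' expanded into linear transformations on the channel basis (I, II, V1--V6)
#' under the equipotential-legs model, then deduplicated. Exactly 12 distinct
#' transformations remain; the class containing the identity comprises
#' precisely the nonreversal and the LL/RL swap (the legs are electrically
#' indistinguishable). Class 1 is always the identity class; the remaining
#' classes are ordered by their canonical member's description.
#'
#' @param tol coefficient tolerance for matrix deduplication (the entries are
#'   exact thirds; the tolerance only guards floating point).
#' @return list of class `reversal_classes`; each element has `class_id`,
#'   `canonical_name` (both members' cycle descriptions), `members` (list of
#'   cable->site mappings), `matrix` (8 x 8), `invertible` and
#'   `precordials_unchanged`.
#' @export
enumerate_reversal_classes <- function(tol = 1e-9) {
  perms <- all_limb_permutations()
  mats <- lapply(perms, reversal_matrix)
  keys <- vapply(mats, function(m) paste(sprintf("%.9f", m), collapse = ","), "")
  groups <- split(seq_along(perms), keys)
  classes <- lapply(groups, function(ix) {
    m <- mats[[ix[1]]]
    descs <- sort(vapply(perms[ix], perm_desc, ""))
    list(canonical_name = paste(descs, collapse = " | "),
         members = perms[ix],
         matrix = m,
         invertible = qr(m)$rank == 8L,
         precordials_unchanged = max(abs(m[3:8, , drop = FALSE] -
           diag(8)[3:8, , drop = FALSE])) <= tol)
  })
  is_id <- vapply(classes, function(cl)
    max(abs(cl$matrix - diag(8))) <= tol, TRUE)
  ord <- c(which(is_id), setdiff(order(vapply(classes, `[[`, "", "canonical_name")),
                                 which(is_id)))
  classes <- classes[ord]
  for (i in seq_along(classes)) classes[[i]]$class_id <- i
  structure(classes, class = "reversal_classes")
}

#' @export
print.reversal_classes <- function(x, ...) {
  cat(sprintf("%d lead-reversal morphology classes (from %d cable permutations)\n",
              length(x), sum(vapply(x, function(c) length(c$members), 1L))))
  for (cl in x)
    cat(sprintf("  %2d: %-55s V-leads %s\n", cl$class_id, cl$canonical_name,
                if (cl$precordials_unchanged) "unchanged" else "changed"))
  invisible(x)
}

normalize_permutation <- function(perm) {
  if (is.list(perm) && !is.null(perm$members)) perm <- perm$members[[1]]
  assert_that(is.character(perm) && length(perm) == 4L &&
              setequal(names(perm), CABLES) && setequal(perm, CABLES),
              "perm must be a named bijection of cables {RA, LA, LL, RL} onto sites")
  perm[CABLES]
}

#' Apply a limb-cable placement permutation to a record
#'
#' Reconstructs electrode potentials, reads each cable from its permuted
#' site (legs equipotential), and regenerates all 12 leads, including the
#' precordials referenced to the recomputed Wilson terminal of the active
#' cables. The output is again physically consistent. Chest electrodes are
#' never permuted; limb reversals only.
#'
#' @param record a consistent [ecg_record()].
#' @param perm a named cable->site mapping (names and values in
#'   `c("RA","LA","LL","RL")`), or a class entry from
#'   [enumerate_reversal_classes()] (its first member is applied).
#' @return transformed [ecg_record()].
#' @export
apply_reversal <- function(record, perm) {
  perm <- normalize_permutation(perm)
  pot <- reconstruct_potentials(record)
  site <- rbind(pot$phi, RL = pot$phi["LL", ])
  p <- site[perm[c("RA", "LA", "LL")], , drop = FALSE]
  wct <- colMeans(p)
  limb <- sweep(p, 2L, wct)
  rownames(limb) <- c("RA", "LA", "LL")
  chest <- sweep(pot$chest, 2L, wct)
  ecg_record(record$record_id, potentials_to_leads(limb, chest),
             record$sampling_rate)
}

#' Lead-reversal robustness suite
#'
#' Evaluates the model on every one of the 12 reversal morphology classes:
#' each class's canonical transform is applied to every record, scores are
#' recomputed, and a metrics row (AUROC with CI, AUPRC, sensitivity,
#' specificity with CIs) is produced. The nonreversal row is computed from
#' the untransformed records, so it equals the clean evaluation bitwise; a
#' `delta_auroc` column reports degradation relative to it.
#'
#' @param records list of consistent [ecg_record()].
#' @param labels two-class labels aligned with `records`.
#' @param model surrogate (or compatible) model for [predict_scores()].
#' @param threshold operating threshold.
#' @param classes optionally a precomputed [enumerate_reversal_classes()].
#' @return data.frame with one row per class: `class_id`, `canonical_name`,
#'   `n`, AUROC/AUPRC/Se/Sp columns and `delta_auroc`.
#' @export
reversal_robustness_suite <- function(records, labels, model,
                                      threshold = model$config$threshold,
                                      classes = enumerate_reversal_classes()) {
  assert_that(length(records) > 0, "empty record set")
  y <- as01(labels)
  rows <- lapply(classes, function(cl) {
    recs <- if (cl$class_id == 1L) records
            else lapply(records, apply_reversal, perm = cl$members[[1]])
    sc <- predict_scores(model, recs, threshold)$score
    cbind(data.frame(class_id = cl$class_id, canonical_name = cl$canonical_name),
          metrics_row(sc, y, threshold))
  })
  out <- do.call(rbind, rows)
  out$delta_auroc <- out$auroc - out$auroc[out$class_id == 1L]
  rownames(out) <- NULL
  out
}
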