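as01 <- function(labels) {
  if (is.character(labels) || is.factor(labels))
    return(as.integer(as.character(labels) %in% c("1", "LVSD", "high", "TRUE", "pos")))
  as.integer(labels != 0)
}

check_two_class <- function(y) {
  assert_that(length(unique(y)) == 2L,
              "both classes must be present (got a single class)")
}

#' Area under the ROC curve (pairwise-probability definition)
#'
#' Rank-based AUROC; ties between a positive and a negative count 1/2. For a
#' binarized 0/1 predictor this equals `(sensitivity + specificity) / 2`.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels two-class labels (1/0, `"LVSD"`/`"non-LVSD"`, logical...).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- as01(labels)
  check_two_class(y)
  r <- rank(scores)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance of the AUROC via placement values.
delong_var <- function(scores, labels) {
  y <- as01(labels)
  sp <- scores[y == 1L]; sn <- scores[y == 0L]
  m <- length(sp); n <- length(sn)
  psi <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  stats::var(v10) / m + stats::var(v01) / n
}

#' AUROC with a 95% confidence interval
#'
#' @param scores,labels as in [auroc()].
#' @param method `"delong"` (default; asymptotic normal CI from the DeLong
#'   variance of placement values) or `"bootstrap"` (stratified percentile
#'   bootstrap, seeded).
#' @param seed bootstrap seed (required for `method = "bootstrap"`).
#' @param conf confidence level.
#' @param n_boot bootstrap replicates.
#' @return list with `value`, `ci95 = c(lo, hi)` (clipped to \[0, 1\]) and
#'   `method`.
#' @export
auroc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                     seed = 1L, conf = 0.95, n_boot = 2000L) {
  method <- match.arg(method)
  y <- as01(labels)
  check_two_class(y)
  a <- auroc(scores, y)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (method == "delong") {
    se <- sqrt(delong_var(scores, y))
    ci <- c(a - z * se, a + z * se)
  } else {
    ip <- which(y == 1L); in0 <- which(y == 0L)
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      ii <- c(sample(ip, replace = TRUE), sample(in0, replace = TRUE))
      auroc(scores[ii], y[ii])
    }, 1))
    ci <- unname(stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  list(value = a, ci95 = pmin(1, pmax(0, ci)), method = method)
}

#' Area under the precision--recall curve (step interpolation)
#'
#' Average precision: the sum over descending score thresholds of
#' `(recall increment) x precision`, the step-function PR area.
#'
#' @param scores,labels as in [auroc()].
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  y <- as01(labels)
  check_two_class(y)
  thr <- sort(unique(scores), decreasing = TRUE)
  m <- sum(y == 1L)
  area <- 0; prev_recall <- 0
  for (t in thr) {
    called <- scores >= t
    tp <- sum(y[called] == 1L)
    prec <- tp / sum(called)
    rec <- tp / m
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}

#' Wilson score interval for a binomial proportion
#' @param x successes, @param n trials, @param conf confidence level.
#' @return `c(lo, hi)`, or `c(NA, NA)` when `n == 0`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, mid - half), min(1, mid + half))
}

#' Operating-point metrics at a score threshold
#'
#' A positive call is `score >= threshold` (boundary inclusive). Sensitivity,
#' specificity, PPV and NPV each carry a Wilson 95% CI; PPV/NPV with an empty
#' denominator are reported as `NA` ("absent"), never fabricated.
#'
#' @param scores,labels as in [auroc()].
#' @param threshold score cutoff.
#' @param conf confidence level for the Wilson intervals.
#' @return list with `counts` (tp, fp, tn, fn), `sensitivity`, `specificity`,
#'   `ppv`, `npv` (each a list with `value`, `ci95`), `threshold`.
#' @export
operating_point_metrics <- function(scores, labels, threshold, conf = 0.95) {
  y <- as01(labels)
  pos_call <- scores >= threshold
  tp <- sum(pos_call & y == 1L); fp <- sum(pos_call & y == 0L)
  fn <- sum(!pos_call & y == 1L); tn <- sum(!pos_call & y == 0L)
  rate <- function(x, n) list(value = if (n > 0) x / n else NA_real_,
                              ci95 = wilson_ci(x, n, conf))
  list(counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
       sensitivity = rate(tp, tp + fn), specificity = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn),
       threshold = threshold)
}

#' Reconstruct confusion counts from printed sensitivity/specificity
#'
#' Given group sizes and printed Se/Sp, reconstructs integer confusion counts
#' by nearest rounding of the expected counts, then re-derives PPV, NPV, the
#' binary AUROC `(Se + Sp)/2` and the number of positive calls. With
#' n_pos = 98, n_neg = 583, Se = 0.898, Sp = 0.940 this yields tp = 88,
#' fn = 10, tn = 548, fp = 35, PPV = 88/123, NPV = 548/558 and 123 positive
#' calls.
#'
#' @param n_pos,n_neg class sizes.
#' @param sensitivity,specificity printed rates.
#' @return list with `counts`, `ppv`, `npv`, `auroc_binary`,
#'   `n_positive_calls`.
#' @export
confusion_from_rates <- function(n_pos, n_neg, sensitivity, specificity) {
  tp <- round(sensitivity * n_pos); fn <- n_pos - tp
  tn <- round(specificity * n_neg); fp <- n_neg - tn
  list(counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
       ppv = tp / (tp + fp), npv = tn / (tn + fn),
       auroc_binary = (tp / n_pos + tn / n_neg) / 2,
       n_positive_calls = tp + fp)
}

#' Largest threshold achieving a target sensitivity
#'
#' Returns the largest score threshold whose sensitivity on the given data is
#' at least `target` (positive call at `score >= threshold`).
#'
#' @param scores,labels as in [auroc()].
#' @param target target sensitivity in (0, 1].
#' @return the threshold (one of the positive scores).
#' @export
threshold_for_sensitivity <- function(scores, labels, target = 0.90) {
  assert_that(target > 0 && target <= 1, "target must lie in (0, 1]")
  y <- as01(labels)
  pos <- sort(scores[y == 1L], decreasing = TRUE)
  assert_that(length(pos) > 0, "no positive examples")
  pos[ceiling(target * length(pos))]
}

#' Pearson correlation with a two-sided p-value
#'
#' Closed-form product-moment correlation; p from the exact t reference
#' distribution with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, length >= 3, nonzero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  assert_that(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  assert_that(n >= 3, "need at least 3 observations")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "zero variance in x or y")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Full diagnostic metrics report
#'
#' Table-style report: continuous-score AUROC, binarized-predictor AUROC
#' (which equals (Se+Sp)/2), AUPRC, and the operating-point metrics with
#' Wilson CIs; optionally the Pearson correlation of score with a continuous
#' reference (e.g. LVEF).
#'
#' @param scores,labels as in [auroc()].
#' @param threshold operating threshold.
#' @param reference optional continuous reference values for correlation.
#' @param ci_method AUROC CI method, see [auroc_ci()].
#' @param seed bootstrap seed.
#' @return list of class `ecg_metrics_report`.
#' @export
metrics_report <- function(scores, labels, threshold, reference = NULL,
                           ci_method = "delong", seed = 1L) {
  y <- as01(labels)
  op <- operating_point_metrics(scores, y, threshold)
  out <- list(n_pos = sum(y == 1L), n_neg = sum(y == 0L),
              auroc_continuous = auroc_ci(scores, y, ci_method, seed = seed),
              auroc_binary = auroc_ci(as.numeric(scores >= threshold), y,
                                      ci_method, seed = seed),
              auprc = auprc(scores, y),
              op = op, threshold = threshold)
  if (!is.null(reference))
    out$pearson <- pearson_r(scores, reference)
  structure(out, class = "ecg_metrics_report")
}

#' @export
print.ecg_metrics_report <- function(x, ...) {
  cat(sprintf("ecg metrics report: %d pos / %d neg, threshold %g\n",
              x$n_pos, x$n_neg, x$threshold))
  cat(sprintf("  AUROC %.3f (%.3f-%.3f) continuous; %.3f binary; AUPRC %.3f\n",
              x$auroc_continuous$value, x$auroc_continuous$ci95[1],
              x$auroc_continuous$ci95[2], x$auroc_binary$value, x$auprc))
  cat(sprintf("  Se %.3f Sp %.3f PPV %.3f NPV %.3f\n",
              x$op$sensitivity$value, x$op$specificity$value,
              x$op$ppv$value, x$op$npv$value))
  invisible(x)
}

metrics_row <- function(scores, y, threshold, ci_method = "delong", seed = 1L) {
  a <- auroc_ci(scores, y, ci_method, seed = seed)
  op <- operating_point_metrics(scores, y, threshold)
  data.frame(n = length(y), auroc = a$value, auroc_lo = a$ci95[1],
             auroc_hi = a$ci95[2], auprc = auprc(scores, y),
             sensitivity = op$sensitivity$value,
             se_lo = op$sensitivity$ci95[1], se_hi = op$sensitivity$ci95[2],
             specificity = op$specificity$value,
             sp_lo = op$specificity$ci95[1], sp_hi = op$specificity$ci95[2],
             ppv = op$ppv$value, npv = op$npv$value)
}

#' Diagnostic performance by subgroup
#'
#' One metrics row per group. Groups in which only one class is present are
#' flagged in the `note` column (AUROC left `NA`), never silently dropped.
#'
#' @param scores,labels as in [auroc()].
#' @param grouping factor/character vector aligned with `scores`.
#' @param threshold operating threshold.
#' @return data.frame, one row per group.
#' @export
subgroup_performance <- function(scores, labels, grouping, threshold = 9.7) {
  assert_that(length(grouping) == length(scores) && length(grouping) > 0,
              "grouping must align with scores and be non-empty")
  y <- as01(labels)
  rows <- lapply(split(seq_along(y), grouping), function(ix) {
    if (length(unique(y[ix])) < 2L) {
      cbind(data.frame(n = length(ix), auroc = NA_real_, auroc_lo = NA_real_,
                       auroc_hi = NA_real_, auprc = NA_real_,
                       sensitivity = NA_real_, se_lo = NA_real_,
                       se_hi = NA_real_, specificity = NA_real_,
                       sp_lo = NA_real_, sp_hi = NA_real_, ppv = NA_real_,
                       npv = NA_real_),
            note = "single-class group")
    } else cbind(metrics_row(scores[ix], y[ix], threshold), note = "")
  })
  out <- do.call(rbind, rows)
  cbind(group = names(rows), out, row.names = NULL)
}
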