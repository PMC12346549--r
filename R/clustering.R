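standardize_features <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  center <- center %||% colMeans(x)
  scale <- scale %||% apply(x, 2L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  out <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

# Seeded greedy spreading (k-means++-style) initialization.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- d2 / sum(d2)
    if (!all(is.finite(p)) || sum(d2) == 0) p <- rep(1 / n, n)
    i <- sample.int(n, 1L, prob = p)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

kmeans_best <- function(x, k, seed, restarts = 10L, extra_init = NULL) {
  best <- NULL
  with_seed(seed, {
    inits <- lapply(seq_len(restarts), function(r) kmeanspp_init(x, k))
    if (!is.null(extra_init)) inits <- c(inits, list(extra_init))
    for (init in inits) {
      init <- init[!duplicated(round(init, 12)), , drop = FALSE]
      if (nrow(init) < k) next
      fit <- suppressWarnings(stats::kmeans(x, centers = init,
                                            iter.max = 100L,
                                            algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  assert_that(!is.null(best), "k-means failed for k = %d (degenerate data?)", k)
  best
}

#' Hidden features of positively predicted records
#'
#' Scores all records, keeps those called positive (`score >= threshold`),
#' and extracts their pooled activations at the given feature block -- the
#' feature matrix on which phenotype clustering operates.
#'
#' @param model trained surrogate.
#' @param records list of [ecg_record()].
#' @param threshold operating threshold.
#' @param block_index feature block (typically the top-ranked TCAV block).
#' @return list with `features` (matrix, rownames = kept record ids),
#'   `record_ids`, `scores` (kept records' scores).
#' @export
select_positive_features <- function(model, records,
                                     threshold = model$config$threshold,
                                     block_index = 1L) {
  pred <- predict_scores(model, records, threshold)
  keep <- pred$score >= threshold
  if (!any(keep))
    stopf("no record scored >= %g; review the threshold before clustering",
          threshold)
  kept <- records[keep]
  list(features = extract_activations(model, kept, block_index),
       record_ids = pred$record_id[keep], scores = pred$score[keep])
}

#' Select the cluster count by the elbow rule
#'
#' Fits seeded K-means for each k in `k_range`, records the within-cluster
#' sum of squares (inertia) curve, and returns the knee: the k with maximum
#' perpendicular distance to the chord joining the first and last curve
#' points, computed on the unit-square-normalized log-inertia curve anchored
#' at k = 1 (total sum of squares) so the smallest candidate stays
#' selectable. Each k's fit reuses
#' the previous k's centroids (plus the farthest point) as one candidate
#' initialization, which guarantees a non-increasing curve.
#'
#' @param features feature matrix (rows = records).
#' @param k_range candidate counts, within \[2, n-1\].
#' @param seed integer seed.
#' @param standardize standardize columns first (default TRUE).
#' @return list with `k` and `inertia_curve` (data.frame k, inertia).
#' @export
select_cluster_count <- function(features, k_range = 2:8, seed = 1L,
                                 standardize = TRUE) {
  x <- as.matrix(features)
  assert_that(min(k_range) >= 2L && max(k_range) <= nrow(x) - 1L,
              "k_range must lie within [2, n-1]")
  if (standardize) x <- standardize_features(x)
  assert_that(max(apply(x, 2L, stats::sd)) > 1e-12,
              "degenerate features: all rows identical")
  k_range <- sort(k_range)
  inertia <- numeric(length(k_range))
  prev_centers <- NULL
  for (i in seq_along(k_range)) {
    extra <- NULL
    if (!is.null(prev_centers)) {
      d2 <- apply(x, 1L, function(r)
        min(rowSums(sweep(prev_centers, 2L, r)^2)))
      extra <- rbind(prev_centers, x[which.max(d2), ])
    }
    fit <- kmeans_best(x, k_range[i], derive_seed(seed, k_range[i]),
                       extra_init = extra)
    inertia[i] <- fit$tot.withinss
    prev_centers <- fit$centers
  }
  # anchor the chord at k = 1 (total sum of squares) so the smallest k in
  # k_range remains selectable, and take the knee on the log-inertia curve:
  # resolving a true cluster drops the inertia by a multiplicative factor,
  # which the log scale turns into comparable-sized steps
  ks <- c(1L, k_range)
  inert <- log(pmax(c(sum(sweep(x, 2L, colMeans(x))^2), inertia), 1e-12))
  u <- (ks - ks[1]) / max(1, diff(range(ks)))
  v <- (inert - inert[length(inert)]) /
    max(1e-12, inert[1] - inert[length(inert)])
  # perpendicular distance from (u, v) to the chord from (0, 1) to (1, 0)
  dist <- abs(u + v - 1) / sqrt(2)
  dist[1] <- -Inf  # k = 1 is the anchor, never the answer
  list(k = ks[which.max(dist)],
       inertia_curve = data.frame(k = k_range, inertia = inertia))
}

#' Fit the phenotype K-means model
#'
#' Seeded greedy-spreading initialization with 10 restarts, best inertia
#' kept; features are standardized per dimension (the scaling is stored so
#' the model can be applied to a second dataset).
#'
#' @param features feature matrix.
#' @param k number of clusters (>= 2, <= n).
#' @param seed integer seed.
#' @param standardize standardize columns first.
#' @return list with `model` (class `ecg_cluster_model`: k, centroids,
#'   center/scale, seed, inertia) and `assignments` (integer vector named by
#'   rownames).
#' @export
fit_phenotype_clusters <- function(features, k, seed = 1L, standardize = TRUE) {
  x <- as.matrix(features)
  assert_that(k >= 2L, "k must be >= 2")
  assert_that(k <= nrow(x), "k = %d exceeds n = %d", k, nrow(x))
  xs <- if (standardize) standardize_features(x) else x
  fit <- kmeans_best(xs, k, derive_seed(seed, 77L))
  model <- structure(list(k = k, centroids = fit$centers,
                          center = attr(xs, "center"),
                          scale = attr(xs, "scale"),
                          seed = as.integer(seed),
                          inertia = fit$tot.withinss),
                     class = "ecg_cluster_model")
  asg <- fit$cluster
  names(asg) <- rownames(x)
  list(model = model, assignments = asg)
}

#' Assign new records' features to fitted phenotype clusters
#' @param model an `ecg_cluster_model` from [fit_phenotype_clusters()].
#' @param features feature matrix (same activation space).
#' @return integer cluster assignments (nearest centroid).
#' @export
assign_clusters <- function(model, features) {
  x <- as.matrix(features)
  if (!is.null(model$center))
    x <- standardize_features(x, model$center, model$scale)
  d <- sapply(seq_len(model$k), function(j)
    rowSums(sweep(x, 2L, model$centroids[j, ])^2))
  asg <- max.col(-as.matrix(d), ties.method = "first")
  names(asg) <- rownames(x)
  asg
}

#' Two-dimensional t-SNE embedding
#'
#' Exact (O(n^2)) t-distributed stochastic neighbor embedding with
#' perplexity-calibrated Gaussian affinities, early exaggeration, momentum
#' gradient descent and deterministic PCA-based initialization plus seeded
#' jitter. Intended for the few hundred positively predicted records of an
#' audit, not for large datasets.
#'
#' @param features feature matrix (rows = records).
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity; requires `n > 3 * perplexity`.
#' @param n_iter gradient iterations.
#' @return n x 2 coordinate matrix (rownames preserved).
#' @export
embed_2d <- function(features, seed = 1L, perplexity = 10, n_iter = 500L) {
  x <- standardize_features(as.matrix(features))
  n <- nrow(x)
  assert_that(n > 3 * perplexity,
              "too few points (n = %d) for perplexity %g (need n > 3*perplexity)",
              n, perplexity)
  d2 <- as.matrix(stats::dist(x))^2
  # per-point precision calibrated to the target perplexity by bisection
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      p <- exp(-di * beta)
      sump <- sum(p)
      if (sump == 0) { beta <- beta / 2; next }
      H <- log(sump) + beta * sum(di * p) / sump
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  pc <- stats::prcomp(x, rank. = 2L)$x
  Y <- pc / stats::sd(pc[, 1]) * 1e-2 +
    with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n))
  G <- matrix(0, n, 2L)
  gain <- matrix(1, n, 2L)
  for (iter in seq_len(n_iter)) {
    ex <- if (iter <= 100L) 12 else 1
    mom <- if (iter <= 250L) 0.5 else 0.8
    yd2 <- as.matrix(stats::dist(Y))^2
    Q <- 1 / (1 + yd2); diag(Q) <- 0
    Qn <- pmax(Q / sum(Q), 1e-12)
    W <- (ex * P - Qn) * Q
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gain <- ifelse(sign(grad) != sign(G), gain + 0.2, gain * 0.8)
    gain[gain < 0.01] <- 0.01
    G <- mom * G - 200 * gain * grad
    Y <- Y + G
    Y <- sweep(Y, 2L, colMeans(Y))
  }
  rownames(Y) <- rownames(x)
  colnames(Y) <- c("tsne1", "tsne2")
  Y
}

#' Profile phenotype clusters against metadata
#'
#' Per-cluster summary: size, true-positive rate (fraction of truly LVSD
#' records among these positively predicted ones), mean score, mean LVEF,
#' and means/proportions of the remaining numeric and logical metadata
#' fields. Cluster sizes sum to the number of clustered records.
#'
#' @param assignments named integer vector (names = record ids).
#' @param metadata data.frame with `record_id`, `label`, `lvef_percent`, ...
#' @param scores named numeric vector or data.frame (`record_id`, `score`).
#' @return data.frame, one row per cluster plus summary columns.
#' @export
profile_clusters <- function(assignments, metadata, scores) {
  ids <- names(assignments)
  assert_that(!is.null(ids) && all(ids %in% metadata$record_id),
              "assignment ids missing from metadata")
  if (is.data.frame(scores)) {
    s <- scores$score; names(s) <- scores$record_id; scores <- s
  }
  assert_that(all(ids %in% names(scores)), "assignment ids missing from scores")
  md <- metadata[match(ids, metadata$record_id), ]
  rows <- lapply(sort(unique(assignments)), function(cl) {
    ix <- assignments == cl
    base <- data.frame(cluster = cl, n = sum(ix),
                       true_positive_rate = mean(md$label[ix] == "LVSD"),
                       mean_score = mean(scores[ids[ix]]),
                       mean_lvef = mean(md$lvef_percent[ix]))
    extra <- md[ix, setdiff(names(md), c("record_id", "label", "lvef_percent",
                                         "seed")), drop = FALSE]
    for (nm in names(extra)) {
      v <- extra[[nm]]
      if (is.logical(v)) base[[paste0("prop_", nm)]] <- mean(v)
      else if (is.numeric(v)) base[[paste0("mean_", nm)]] <- mean(v)
      else if (nm == "sex") base[["prop_male"]] <- mean(v == "M")
    }
    base
  })
  out <- do.call(rbind, rows)
  stopifnot(sum(out$n) == length(assignments))
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between cluster assignments and (e.g.) planted
#' archetype labels; 1 = identical partitions, ~0 = chance.
#'
#' @param a,b two partitions of the same items.
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  assert_that(length(a) == length(b), "partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
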