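# Ridge-regularized logistic regression by IRLS; returns the weight vector
# (no intercept penalty). Small, deterministic, and robust to separable data
# thanks to the ridge term.
ridge_logistic <- function(X, y, lambda = 1e-2, max_iter = 50L) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  w <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X1 %*% w)
    mu <- stats::plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-6)
    H <- crossprod(X1 * wt, X1) + pen
    g <- crossprod(X1, y - mu) - pen %*% w
    step <- solve(H, g)
    w <- w + as.numeric(step)
    if (max(abs(step)) < 1e-8) break
  }
  w
}

#' Train a concept activation vector (CAV)
#'
#' Fits a ridge-regularized linear logistic separator between concept
#' activations and random activations in one block's pooled activation
#' space; the CAV is the unit-normalized normal vector oriented toward the
#' concept class. Held-out accuracy on a seeded split is reported so
#' uninformative concepts are visible (accuracy ~ 0.5).
#'
#' @param concept_acts matrix of concept activations (rows = examples).
#' @param random_acts matrix of random/negative activations, same number of
#'   columns.
#' @param seed seed for the held-out split.
#' @param lambda ridge penalty.
#' @param holdout held-out fraction.
#' @param concept_name,block_index optional annotations.
#' @return object of class `ecg_cav`: `direction` (unit vector),
#'   `accuracy`, `concept_name`, `block_index`, `run_seed`.
#' @export
train_cav <- function(concept_acts, random_acts, seed = 1L, lambda = 1e-2,
                      holdout = 0.25, concept_name = NA_character_,
                      block_index = NA_integer_) {
  concept_acts <- as.matrix(concept_acts)
  random_acts <- as.matrix(random_acts)
  assert_that(ncol(concept_acts) == ncol(random_acts),
              "dimension mismatch: concept %d vs random %d columns",
              ncol(concept_acts), ncol(random_acts))
  assert_that(nrow(concept_acts) >= 2L && nrow(random_acts) >= 2L,
              "need at least 2 examples per class")
  X <- rbind(concept_acts, random_acts)
  y <- c(rep(1L, nrow(concept_acts)), rep(0L, nrow(random_acts)))
  n <- length(y)
  te <- with_seed(seed, sort(unlist(lapply(split(seq_len(n), y), function(ix)
    sample(ix, max(1L, floor(holdout * length(ix))))))))
  tr <- setdiff(seq_len(n), te)
  w <- ridge_logistic(X[tr, , drop = FALSE], y[tr], lambda)
  dir <- w[-1]
  nd <- sqrt(sum(dir^2))
  assert_that(nd > 0, "degenerate separator (zero normal vector)")
  acc <- mean((as.numeric(cbind(1, X[te, , drop = FALSE]) %*% w) > 0) == (y[te] == 1L))
  structure(list(direction = dir / nd, accuracy = acc,
                 concept_name = concept_name, block_index = block_index,
                 run_seed = as.integer(seed)),
            class = "ecg_cav")
}

#' TCAV score: fraction of class examples moved toward the concept
#'
#' The conceptual sensitivity score: the fraction of class examples whose
#' positive-class logit has a strictly positive directional derivative along
#' the CAV direction, the derivative taken in the block's pooled activation
#' space. Negating the direction maps a score s to 1 - s (up to examples
#' with an exactly zero derivative, which do not occur in float practice).
#'
#' @param model surrogate model (ignored when `gradients` is supplied).
#' @param class_examples list of [ecg_record()] of the predicted class.
#' @param cav an [train_cav()] object (its `block_index` must be set) or a
#'   bare unit vector together with `block_index`.
#' @param block_index feature block; defaults to `cav$block_index`.
#' @param gradients optional precomputed [pooled_logit_gradients()] matrix
#'   (rows = examples) to avoid recomputing backprops across runs.
#' @return score in \[0, 1\].
#' @export
tcav_score <- function(model = NULL, class_examples = NULL, cav,
                       block_index = NULL, gradients = NULL) {
  dir <- if (inherits(cav, "ecg_cav")) cav$direction else as.numeric(cav)
  if (is.null(gradients)) {
    assert_that(!is.null(class_examples) && length(class_examples) > 0,
                "empty class example set")
    block_index <- block_index %||%
      (if (inherits(cav, "ecg_cav")) cav$block_index else NULL)
    assert_that(!is.null(block_index) && !is.na(block_index),
                "block_index is required")
    gradients <- pooled_logit_gradients(model, class_examples, block_index)
  }
  assert_that(nrow(gradients) > 0, "empty class example set")
  assert_that(ncol(gradients) == length(dir),
              "CAV dimension %d does not match gradient dimension %d",
              length(dir), ncol(gradients))
  mean(as.numeric(gradients %*% dir) > 0)
}

safe_welch_p <- function(a, b) {
  if (stats::sd(a) < 1e-12 && stats::sd(b) < 1e-12)
    return(if (abs(mean(a) - mean(b)) < 1e-12) 1 else 0)
  tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
}

#' TCAV score with repeated-run confidence interval and significance
#'
#' One CAV is trained per run against a different random pool; the TCAV
#' score is the mean of the per-run scores, the 95% CI the empirical
#' 2.5/97.5 percentiles across runs, and the p-value a Welch two-sample
#' two-sided test of the per-run concept scores against matched
#' random-vs-random scores (pool i vs pool i+1), the TCAV null.
#'
#' @param model trained surrogate.
#' @param concept_ds a [make_concept_dataset()] (positives are the concept
#'   set; its `random_negatives` are ignored here in favor of the pools).
#' @param random_pools list of at least `n_runs + 1` record pools (e.g. from
#'   [make_random_pool()]); activations may be passed directly as matrices.
#' @param class_examples records of the predicted class at which the
#'   directional derivatives are evaluated.
#' @param block_index feature block, 1--4.
#' @param n_runs number of repeated runs (>= 2).
#' @param seed base seed.
#' @param gradients optional precomputed [pooled_logit_gradients()] matrix
#'   for `class_examples` at `block_index` (avoids recomputation when many
#'   concepts share one block).
#' @return object of class `ecg_tcav_result`: `concept_name`, `block_index`,
#'   `score`, `ci95`, `p_value`, `n_runs`, `run_scores`, `null_scores`,
#'   `mean_cav_accuracy`.
#' @export
tcav_significance <- function(model, concept_ds, random_pools, class_examples,
                              block_index, n_runs = 30L, seed = 1L,
                              gradients = NULL) {
  assert_that(n_runs >= 2L, "n_runs must be >= 2")
  assert_that(length(random_pools) >= n_runs + 1L,
              "need at least n_runs + 1 = %d random pools, got %d",
              n_runs + 1L, length(random_pools))
  as_acts <- function(x) if (is.matrix(x)) x else
    extract_activations(model, x, block_index)
  concept_acts <- as_acts(concept_ds$positives)
  pool_acts <- lapply(random_pools, as_acts)
  grads <- gradients %||% pooled_logit_gradients(model, class_examples, block_index)
  run_scores <- numeric(n_runs)
  null_scores <- numeric(n_runs)
  accs <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    s_r <- derive_seed(seed, r)
    cav <- train_cav(concept_acts, pool_acts[[r]], seed = s_r,
                     concept_name = concept_ds$concept_name,
                     block_index = block_index)
    run_scores[r] <- tcav_score(cav = cav, gradients = grads)
    accs[r] <- cav$accuracy
    null_cav <- train_cav(pool_acts[[r]], pool_acts[[r + 1L]], seed = s_r + 1L,
                          concept_name = "random", block_index = block_index)
    null_scores[r] <- tcav_score(cav = null_cav, gradients = grads)
  }
  ci <- unname(stats::quantile(run_scores, c(0.025, 0.975), type = 7))
  structure(list(concept_name = concept_ds$concept_name,
                 block_index = block_index,
                 score = mean(run_scores), ci95 = ci,
                 p_value = safe_welch_p(run_scores, null_scores),
                 n_runs = n_runs, run_scores = run_scores,
                 null_scores = null_scores,
                 mean_cav_accuracy = mean(accs)),
            class = "ecg_tcav_result")
}

#' @export
print.ecg_tcav_result <- function(x, ...) {
  cat(sprintf("TCAV %s @ block %d: %.3f (95%% CI %.3f-%.3f), p = %.3g, %d runs\n",
              x$concept_name, x$block_index, x$score, x$ci95[1], x$ci95[2],
              x$p_value, x$n_runs))
  invisible(x)
}

#' Rank feature blocks by mean TCAV score
#'
#' Expects the complete concepts x blocks grid of [tcav_significance()]
#' results; returns the block with the highest concept-averaged score (ties
#' broken toward the lower block index, logged) together with the grid.
#'
#' @param results list of `ecg_tcav_result` covering every (concept, block)
#'   cell exactly once.
#' @param blocks blocks expected in the grid.
#' @return list with `block_index`, `block_means` and `grid` (data.frame:
#'   concept, block, score, ci_lo, ci_hi, p_value, n_runs).
#' @export
rank_blocks <- function(results, blocks = 1:4) {
  grid <- do.call(rbind, lapply(results, function(r)
    data.frame(concept = r$concept_name, block = r$block_index,
               score = r$score, ci_lo = r$ci95[1], ci_hi = r$ci95[2],
               p_value = r$p_value, n_runs = r$n_runs)))
  concepts <- unique(grid$concept)
  want <- expand.grid(concept = concepts, block = blocks)
  have <- paste(grid$concept, grid$block)
  missing <- setdiff(paste(want$concept, want$block), have)
  assert_that(length(missing) == 0L, "incomplete TCAV grid; missing cells: %s",
              paste(missing, collapse = "; "))
  assert_that(!any(duplicated(have)), "duplicate TCAV grid cells")
  block_means <- vapply(blocks, function(b) mean(grid$score[grid$block == b]), 1)
  names(block_means) <- blocks
  best <- blocks[which.max(block_means)]  # which.max takes the first maximum
  if (sum(block_means == max(block_means)) > 1L)
    message(sprintf("block tie at mean score %.3f; choosing block %d",
                    max(block_means), best))
  list(block_index = best, block_means = block_means,
       grid = grid[order(grid$concept, grid$block), ])
}
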