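test_that("CAVs recover a known separating axis", {
  set.seed(14)
  d <- 8
  concept <- cbind(rnorm(60, mean = 4), matrix(rnorm(60 * (d - 1)), 60))
  random <- cbind(rnorm(60, mean = -4), matrix(rnorm(60 * (d - 1)), 60))
  cav <- train_cav(concept, random, seed = 2)
  expect_equal(sqrt(sum(cav$direction^2)), 1, tolerance = 1e-12)
  expect_gt(abs(cav$direction[1]), 0.99)       # |cosine| with e1
  expect_gt(cav$direction[1], 0)               # oriented toward the concept
  expect_gt(cav$accuracy, 0.95)
})

test_that("an uninformative concept yields chance-level held-out accuracy", {
  set.seed(15)
  a <- matrix(rnorm(200 * 6), 200)
  b <- matrix(rnorm(200 * 6), 200)
  cav <- train_cav(a, b, seed = 3)
  # held-out n = 100; binomial 95% band around 0.5 is ~ +/- 0.10
  expect_gt(cav$accuracy, 0.35)
  expect_lt(cav$accuracy, 0.65)
})

test_that("CAV preconditions are enforced", {
  a <- matrix(rnorm(10), 5)
  expect_error(train_cav(a, matrix(rnorm(9), 3)), "mismatch")
  expect_error(train_cav(a[1, , drop = FALSE], a), "2 examples")
})

test_that("a toy linear logit gives score 1 along its weights and 0 against", {
  # gradients of a linear head are the weight vector at every example
  w <- c(2, -1, 0.5)
  grads <- matrix(w, nrow = 20, ncol = 3, byrow = TRUE)
  expect_identical(tcav_score(cav = w / sqrt(sum(w^2)), gradients = grads), 1)
  expect_identical(tcav_score(cav = -w / sqrt(sum(w^2)), gradients = grads), 0)
})

test_that("direction negation maps scores to their complement exactly", {
  set.seed(16)
  grads <- matrix(rnorm(50 * 6), 50)
  for (i in 1:20) {
    v <- rnorm(6); v <- v / sqrt(sum(v^2))
    expect_identical(tcav_score(cav = v, gradients = grads) +
                       tcav_score(cav = -v, gradients = grads), 1)
  }
})

test_that("random directions on model gradients average to the 0.5 null", {
  m <- tiny_model()
  grads <- ecgaudit:::pooled_logit_gradients_all(m, tiny_records(n = 20,
                                                                seed = 810))[[2]]
  set.seed(17)
  draws <- replicate(500, {
    v <- rnorm(ncol(grads))
    tcav_score(cav = v / sqrt(sum(v^2)), gradients = grads)
  })
  expect_lt(abs(mean(draws) - 0.5), 0.05)
})

test_that("significance machinery is calibrated under the null", {
  # concept drawn from the same distribution as the random pools: the Welch
  # p-value should rarely clear 0.05
  set.seed(18)
  grads <- matrix(rnorm(40 * 6), 40)
  hits <- vapply(1:20, function(rep) {
    pools <- lapply(1:9, function(i) matrix(rnorm(25 * 6), 25))
    ds <- list(concept_name = "null", positives = matrix(rnorm(25 * 6), 25))
    res <- tcav_significance(NULL, ds, pools, NULL, block_index = 1L,
                             n_runs = 8L, seed = 100 + rep, gradients = grads)
    res$p_value < 0.05
  }, TRUE)
  expect_lte(sum(hits), 4L)
})

test_that("tcav results respect their invariants and preconditions", {
  set.seed(19)
  grads <- matrix(rnorm(30 * 5), 30)
  pools <- lapply(1:6, function(i) matrix(rnorm(20 * 5), 20))
  ds <- list(concept_name = "c", positives = matrix(rnorm(20 * 5) + 1, 20))
  res <- tcav_significance(NULL, ds, pools, NULL, 1L, n_runs = 5L, seed = 4,
                           gradients = grads)
  expect_true(res$ci95[1] <= res$score && res$score <= res$ci95[2])
  expect_true(res$ci95[1] >= 0 && res$ci95[2] <= 1)
  expect_identical(res$n_runs, 5L)
  expect_error(
    tcav_significance(NULL, ds, pools, NULL, 1L, n_runs = 10L, seed = 4,
                      gradients = grads),
    "random pools")
  expect_error(
    tcav_significance(NULL, ds, pools, NULL, 1L, n_runs = 1L, seed = 4,
                      gradients = grads),
    "n_runs")
})

test_that("rank_blocks picks the dominant block, breaks ties low, checks the grid", {
  mk <- function(cn, b, s) structure(
    list(concept_name = cn, block_index = b, score = s, ci95 = c(s, s),
         p_value = 0.01, n_runs = 5L), class = "ecg_tcav_result")
  res <- list()
  for (cn in c("a", "b")) for (b in 1:4)
    res[[paste(cn, b)]] <- mk(cn, b, if (b == 1) 0.9 else 0.4)
  expect_identical(rank_blocks(res)$block_index, 1L)

  res_tie <- list()
  for (cn in c("a", "b")) for (b in 1:4)
    res_tie[[paste(cn, b)]] <- mk(cn, b, if (b %in% c(2, 3)) 0.8 else 0.3)
  expect_message(out <- rank_blocks(res_tie), "tie")
  expect_identical(out$block_index, 2L)

  expect_error(rank_blocks(res[-1]), "missing cells")
})
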