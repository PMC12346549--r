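test_that("build is deterministic and the input contract is enforced", {
  m1 <- build_surrogate(tiny_config())
  m2 <- build_surrogate(tiny_config())
  rec <- tiny_records()[[1]]
  expect_identical(predict_scores(m1, rec)$score, predict_scores(m2, rec)$score)

  bad11 <- rec$signal[1:11, ]
  expect_error(ecgaudit:::surrogate_forward(m1, bad11), "12")
  bad_len <- rec$signal[, 1:400]
  expect_error(ecgaudit:::surrogate_forward(m1, bad_len), "resample")
  # sampling-rate mismatch points the caller to resample_record
  wrong_fs <- simulate_record(morphology_params(), fs = 100, duration_s = 5,
                              seed = 2)
  expect_error(predict_scores(m1, wrong_fs), "resample_record")
})

test_that("scores live in [0, 100] and the 9.7 boundary is inclusive", {
  m <- tiny_model()
  pred <- predict_scores(m, tiny_records())
  expect_true(all(pred$score >= 0 & pred$score <= 100))
  expect_identical(pred$record_id, vapply(tiny_records(), `[[`, "", "record_id"))

  expect_identical(classify_risk(9.7), "high")
  expect_identical(classify_risk(9.69), "low")
  expect_identical(classify_risk(0), "low")
  expect_identical(classify_risk(100), "high")
  expect_error(classify_risk(101), "\\[0, 100\\]")
  expect_identical(pred$risk_class, ifelse(pred$score >= 9.7, "high", "low"))
})

test_that("pooled activations have block dimension and see amplitude", {
  m <- tiny_model()
  recs <- tiny_records()[1:3]
  for (b in 1:4) {
    acts <- extract_activations(m, recs, b)
    expect_identical(dim(acts), c(3L, tiny_config()$channels[b]))
    expect_true(all(is.finite(acts)))
  }
  expect_error(extract_activations(m, recs, 5), "1, 2, 3, 4")

  # identical records -> identical vectors
  twice <- extract_activations(m, list(recs[[1]], recs[[1]]), 2)
  expect_identical(twice[1, ], twice[2, ])

  # doubling voltages must change the activations (no silent normalization)
  doubled <- recs[[1]]
  doubled$signal <- 2 * doubled$signal
  pair <- extract_activations(m, list(recs[[1]], doubled), 2)
  expect_gt(max(abs(pair[1, ] - pair[2, ])), 1e-6)
})

test_that("analytic gradients match finite differences", {
  m <- build_surrogate(surrogate_config(channels = c(3L, 4L, 5L, 6L),
                                        input_samples = 200L, seed = 13))
  set.seed(8)
  X <- matrix(rnorm(12 * 200), 12)
  fwd <- ecgaudit:::surrogate_forward(m, X, keep_cache = TRUE)
  g <- ecgaudit:::surrogate_backward(m, fwd, dlogit = 1)
  fp <- ecgaudit:::flatten_params(m$weights)
  gp <- ecgaudit:::flatten_params(g)
  eps <- 1e-5
  for (key in c("stem.W1", "b2.u1.c1.W3", "b3.u2.c2.b", "b4.u1.pr.W1", "head.W")) {
    upd <- lapply(fp, function(p) p * 0)
    upd[[key]][1] <- eps
    up <- m; up$weights <- ecgaudit:::apply_flat_update(m$weights, upd)
    upd[[key]][1] <- -eps
    dn <- m; dn$weights <- ecgaudit:::apply_flat_update(m$weights, upd)
    num <- (ecgaudit:::surrogate_forward(up, X)$logit -
              ecgaudit:::surrogate_forward(dn, X)$logit) / (2 * eps)
    expect_equal(gp[[key]][1], num, tolerance = 1e-5)
  }
})

test_that("pooled logit gradients equal the uniform-shift directional derivative", {
  m <- tiny_model()
  X <- tiny_records()[[4]]$signal
  b <- 2L
  g <- pooled_logit_gradients(m, list(tiny_records()[[4]]), b)[1, ]

  # finite difference: shift block-b output by eps on one channel, rerun the
  # tail of the network by hand
  run_tail <- function(shift_ch, eps) {
    w <- m$weights
    s1 <- ecgaudit:::relu(ecgaudit:::conv_fwd(X, w$stem, 2L))
    h <- ecgaudit:::maxpool_fwd(s1, m$config$stem_pool)$Y
    for (bb in 1:4) {
      for (u in w$blocks[[bb]]) h <- ecgaudit:::res_fwd(h, u)$out
      if (bb == b) h[shift_ch, ] <- h[shift_ch, ] + eps
    }
    pooled <- rowMeans(ecgaudit:::relu(h))
    as.numeric(w$head$W %*% pooled + w$head$b)
  }
  # small step keeps the finite difference on one side of the downstream
  # rectifier kinks
  for (ch in c(1L, 3L)) {
    num <- (run_tail(ch, 1e-6) - run_tail(ch, -1e-6)) / 2e-6
    expect_equal(g[ch], num, tolerance = 1e-3)
  }
})

test_that("training contracts: single class, zero LR, determinism", {
  coh <- mini_cohort()
  single <- list(records = coh$records[coh$metadata$label == "LVSD"],
                 metadata = coh$metadata[coh$metadata$label == "LVSD", ])
  expect_error(train_surrogate(tiny_model(), single, train_config(epochs = 1)),
               "single class")

  # one batch per epoch so the epoch loss is order-invariant
  fit0 <- train_surrogate(tiny_model(), coh,
                          train_config(epochs = 2, lr = 0, batch_size = 32,
                                       seed = 3))
  expect_lt(diff(range(fit0$history$loss)), 1e-9)

  f1 <- train_surrogate(tiny_model(), coh, train_config(epochs = 1, seed = 3))
  f2 <- train_surrogate(tiny_model(), coh, train_config(epochs = 1, seed = 3))
  expect_identical(f1$val_scores, f2$val_scores)
  expect_identical(f1$history, f2$history)
})

test_that("checkpoints round-trip through save/load", {
  tmp <- withr::local_tempfile(fileext = ".rds")
  m <- tiny_model()
  save_surrogate(m, tmp)
  back <- load_surrogate(tmp)
  rec <- tiny_records()[[1]]
  expect_identical(predict_scores(back, rec)$score, predict_scores(m, rec)$score)
})
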