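test_that("AUROC equals the pairwise-probability definition", {
  expect_identical(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_identical(auroc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  # seeded property check against the exhaustive oracle, including ties
  set.seed(21)
  for (i in 1:50) {
    n <- sample(4:60, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    expect_equal(auroc(s, y), auroc_bruteforce(s, y), tolerance = 1e-12)
  }
})

test_that("binary AUROC equals (Se + Sp)/2 to 1e-12", {
  set.seed(22)
  for (i in 1:25) {
    n <- sample(10:80, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.3))
    calls <- rbinom(n, 1, 0.5)
    se <- sum(calls & y) / sum(y)
    sp <- sum(!calls & !y) / sum(1 - y)
    expect_equal(auroc(calls, y), (se + sp) / 2, tolerance = 1e-12)
  }
})

test_that("AUROC confidence intervals behave", {
  set.seed(23)
  s <- c(rnorm(40, 1), rnorm(60))
  y <- rep(c(1, 0), c(40, 60))
  d <- auroc_ci(s, y, "delong")
  expect_true(d$ci95[1] <= d$value && d$value <= d$ci95[2])
  expect_true(d$ci95[1] >= 0 && d$ci95[2] <= 1)
  b1 <- auroc_ci(s, y, "bootstrap", seed = 5, n_boot = 200)
  b2 <- auroc_ci(s, y, "bootstrap", seed = 5, n_boot = 200)
  expect_identical(b1$ci95, b2$ci95)
  expect_lt(abs(b1$ci95[1] - d$ci95[1]), 0.1)
  expect_error(auroc_ci(s, rep(1, 100)), "single class")
})

test_that("AUPRC: exact small cases and the rank-walk oracle", {
  expect_identical(auprc(c(5, 4, 3), c(1, 1, 0)), 1)
  # step area: precision 1 at recall 1/2, precision 2/3 at recall 1
  # => 1 * 1/2 + 2/3 * 1/2 = 5/6 (confirmed by the rank-walk oracle below)
  expect_equal(auprc(c(0.9, 0.8, 0.7), c(1, 0, 1)), 5 / 6, tolerance = 1e-12)
  set.seed(24)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.4))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(auprc(s, y), auprc_rankwalk(s, y), tolerance = 1e-12)
  }
  # random scores: AUPRC ~ prevalence
  set.seed(25)
  y <- rbinom(10000, 1, 0.15)
  s <- runif(10000)
  expect_lt(abs(auprc(s, y) - 0.15), 0.03)
})

test_that("operating-point metrics and Wilson intervals", {
  set.seed(26)
  s <- c(rnorm(30, 2), rnorm(70))
  y <- rep(c(1, 0), c(30, 70))
  op <- operating_point_metrics(s, y, threshold = 1)
  with(op$counts, {
    expect_identical(tp + fn, 30L)
    expect_identical(tn + fp, 70L)
  })
  # Wilson CI against the prop.test oracle (no continuity correction)
  pt <- stats::prop.test(op$counts$tp, op$counts$tp + op$counts$fn,
                         correct = FALSE)
  expect_equal(unname(op$sensitivity$ci95), as.numeric(pt$conf.int),
               tolerance = 1e-10)

  lo <- operating_point_metrics(s, y, threshold = min(s) - 1)
  expect_identical(lo$sensitivity$value, 1)
  expect_identical(lo$specificity$value, 0)
  hi <- operating_point_metrics(s, y, threshold = max(s) + 1)
  expect_identical(hi$sensitivity$value, 0)
  expect_identical(hi$specificity$value, 1)
  expect_true(is.na(hi$ppv$value))  # zero positive calls: flagged absent

  # PPV satisfies the Bayes identity with prevalence
  p <- 0.3
  se <- op$sensitivity$value; sp <- op$specificity$value
  expect_equal(op$ppv$value, se * p / (se * p + (1 - sp) * (1 - p)),
               tolerance = 1e-12)
})

test_that("fixed-sensitivity thresholding picks the largest feasible cutoff", {
  s <- seq(10, 100, by = 10)
  y <- rep(1, 10)
  neg <- data.frame(s = c(1, 2, 3), y = 0)
  scores <- c(s, neg$s); labels <- c(y, neg$y)
  expect_identical(threshold_for_sensitivity(scores, labels, 0.9), 20)
  expect_identical(threshold_for_sensitivity(scores, labels, 1), 10)
  expect_identical(threshold_for_sensitivity(rep(7, 5), rep(1, 5), 0.5), 7)
  expect_error(threshold_for_sensitivity(scores, labels, 1.2), "\\(0, 1\\]")
  # the returned threshold actually achieves the target
  thr <- threshold_for_sensitivity(scores, labels, 0.9)
  expect_gte(mean(s >= thr), 0.9)
})

test_that("Pearson correlation matches the closed form and cor.test", {
  expect_identical(pearson_r(1:10, -(1:10))$r, -1)
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  y <- c(0.5, 2.9, 1.4, 4.0, 4.2)
  ours <- pearson_r(x, y)
  ref <- stats::cor.test(x, y)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  set.seed(27)
  expect_lt(abs(pearson_r(rnorm(10000), rnorm(10000))$r), 0.03)
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
  expect_error(pearson_r(1:2, 2:1), "3 observations")
})

test_that("subgroup tables cover every group and flag single-class ones", {
  set.seed(28)
  n <- 200L
  y <- rbinom(n, 1, 0.3)
  s <- y * 2 + rnorm(n)
  g <- sample(c("F", "M"), n, replace = TRUE)  # performance-neutral covariate
  tab <- subgroup_performance(s, y, g, threshold = 1)
  expect_identical(nrow(tab), 2L)
  expect_identical(sum(tab$n), n)
  # neutral split: the two groups' 95% CIs overlap
  expect_true(tab$auroc_lo[1] <= tab$auroc_hi[2] &&
                tab$auroc_lo[2] <= tab$auroc_hi[1])

  one <- subgroup_performance(s, y, rep("all", n), threshold = 1)
  expect_equal(one$auroc, auroc(s, y), tolerance = 1e-12)

  g2 <- ifelse(y == 1, "onlypos", g)
  tab2 <- subgroup_performance(s, y, g2, threshold = 1)
  expect_true("single-class group" %in% tab2$note)
  expect_error(subgroup_performance(s, y, character(0)), "align")
})

test_that("metrics reports assemble all pieces coherently", {
  set.seed(29)
  y <- rep(c(1, 0), c(40, 160))
  s <- y * 30 + abs(rnorm(200, 5, 4))
  lvef <- 60 - 0.5 * s + rnorm(200, 0, 4)
  rep <- metrics_report(s, y, threshold = 20, reference = lvef)
  expect_equal(rep$auroc_binary$value,
               (rep$op$sensitivity$value + rep$op$specificity$value) / 2,
               tolerance = 1e-12)
  expect_lt(rep$pearson$r, 0)
  expect_output(print(rep), "AUROC")
})
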