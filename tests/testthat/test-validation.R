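ols_refit <- function(descriptors) {
  function(d) fit_mlr(d, descriptors = descriptors)
}

test_that("fit metrics follow their definitions", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  perfect <- fit_metrics(y, y, p = 1)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$r2_adj, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$s, 0)

  withr::with_seed(31, {
    yy <- rnorm(10)
    yh <- yy + rnorm(10, 0, 0.5)
  })
  m <- fit_metrics(yy, yh, p = 1)
  r2 <- cor(yy, yh)^2
  expect_equal(m$r2_adj, 1 - (1 - r2) * 9 / 8, tolerance = 1e-12)
  expect_lte(m$r2_adj, m$r2)
  e <- yy - yh
  expect_equal(m$rmse, sqrt(mean(e^2)))
  expect_equal(m$s, sqrt(sum(e^2) / 8))
  expect_error(fit_metrics(rep(1, 10), yh, p = 1), "zero variance")
})

test_that("Q2_LOO equals the brute-force refit loop and the PRESS shortcut", {
  withr::with_seed(32, {
    d <- tibble::tibble(x1 = rnorm(30), x2 = rnorm(30))
    d$log_kca <- 1 + 2 * d$x1 - d$x2 + rnorm(30, 0, 0.5)
  })
  refit <- ols_refit(c("x1", "x2"))
  q_impl <- q2_loo(d, refit = refit)
  q_oracle <- oracle_q2_loo(d, "log_kca", refit)
  expect_equal(q_impl, q_oracle, tolerance = 1e-12)
  q_press <- q2_loo(d, refit = refit, method = "press")
  expect_equal(q_impl, q_press, tolerance = 1e-10)
})

test_that("Q2_LOO is 1 in the noiseless linear limit and penalizes the mean-only model", {
  withr::with_seed(33, {
    d <- tibble::tibble(x1 = rnorm(20), x2 = rnorm(20))
    d$log_kca <- 3 - d$x1 + 0.5 * d$x2
  })
  expect_equal(q2_loo(d, refit = ols_refit(c("x1", "x2"))), 1,
               tolerance = 1e-10)

  # mean-only learner (zero slope): LOO prediction is the left-out mean;
  # Q2 is always negative
  mean_refit <- function(dd) linear_model(c(x1 = 0), mean(dd$log_kca))
  q_mean <- q2_loo(d, refit = mean_refit)
  expect_equal(q_mean, oracle_q2_loo(d, "log_kca", mean_refit),
               tolerance = 1e-12)
  expect_lt(q_mean, 0)
})

test_that("bootstrap Q2 is seeded, near 1 without noise, and tracks the signal share", {
  withr::with_seed(34, {
    d0 <- tibble::tibble(x1 = rnorm(30), x2 = rnorm(30))
    d0$log_kca <- 2 * d0$x1 + d0$x2
  })
  refit <- ols_refit(c("x1", "x2"))
  q0 <- q2_boot(d0, refit = refit, iterations = 100, seed = 5)
  expect_gt(q0, 1 - 1e-8)
  expect_identical(q0, q2_boot(d0, refit = refit, iterations = 100, seed = 5))

  # noisy case: Q2 approaches Var(signal)/(Var(signal) + sigma^2)
  withr::with_seed(35, {
    n <- 200
    d <- tibble::tibble(x1 = rnorm(n))
    signal <- 2 * d$x1                      # Var(signal) = 4
    d$log_kca <- signal + rnorm(n, 0, 1)    # sigma^2 = 1 -> ratio 0.8
  })
  q <- q2_boot(d, refit = ols_refit("x1"), iterations = 200, seed = 9)
  expect_equal(q, 0.8, tolerance = 0.08)
  # a different seed resamples differently but stays in the same band
  q_alt <- q2_boot(d, refit = ols_refit("x1"), iterations = 200, seed = 10)
  expect_false(identical(q, q_alt))
  expect_equal(q_alt, 0.8, tolerance = 0.08)
  expect_error(q2_boot(d, refit = ols_refit("x1"), iterations = 0), ">= 1")
})

test_that("external metrics match hand arithmetic on a printed fixture", {
  y <- c(1.0, 2.0, 3.0, 4.0, 5.0, 6.0)
  yh <- c(1.2, 1.8, 3.3, 3.9, 5.4, 5.8)
  m <- external_metrics(y, yh, ybar_train = 3.2, p = 2)
  my <- mean(y); mp <- mean(yh)
  vy <- mean((y - my)^2); vp <- mean((yh - mp)^2)
  cv <- mean((y - my) * (yh - mp))
  expect_equal(m$ccc, 2 * cv / (vy + vp + (my - mp)^2), tolerance = 1e-12)
  expect_equal(m$q2_ext, 1 - sum((y - yh)^2) / sum((y - 3.2)^2),
               tolerance = 1e-12)
  expect_equal(m$r2_ext, cor(y, yh)^2, tolerance = 1e-12)
  expect_equal(m$s_ext, sqrt(sum((y - yh)^2) / 3), tolerance = 1e-12)
})

test_that("CCC penalizes location shift that Pearson correlation ignores", {
  y <- c(2, 4, 5, 7, 9, 11)
  base <- external_metrics(y, y, ybar_train = mean(y))
  expect_equal(base$ccc, 1)
  expect_equal(base$q2_ext, 1)
  shifted1 <- external_metrics(y, y + 1, ybar_train = mean(y))
  shifted2 <- external_metrics(y, y + 3, ybar_train = mean(y))
  expect_equal(shifted1$r2_ext, 1)
  expect_lt(shifted1$ccc, 1)
  expect_lt(shifted2$ccc, shifted1$ccc)
  # identical shifts of both arguments leave CCC unchanged
  m1 <- external_metrics(y, y + 1, ybar_train = mean(y))
  m2 <- external_metrics(y + 5, y + 6, ybar_train = mean(y) + 5)
  expect_equal(m1$ccc, m2$ccc, tolerance = 1e-12)
  # bounds and dominance by |r|
  withr::with_seed(36, {
    a <- rnorm(50); b <- rnorm(50)
  })
  mm <- external_metrics(a, b, ybar_train = 0)
  expect_true(abs(mm$ccc) <= 1)
  expect_lte(abs(mm$ccc), abs(cor(a, b)) + 1e-12)
})

test_that("Q2_ext variants differ as documented", {
  y <- c(1, 3, 5, 7)
  yh <- c(1.5, 2.5, 5.5, 6.5)
  f1 <- external_metrics(y, yh, ybar_train = 10)$q2_ext
  f2 <- external_metrics(y, yh, ybar_train = 10, variant = "F2")$q2_ext
  expect_equal(f2, 1 - sum((y - yh)^2) / sum((y - mean(y))^2))
  expect_gt(f1, f2)  # far-off training mean inflates the F1 denominator
  f3 <- external_metrics(y, yh, ybar_train = 10, variant = "F3",
                         y_train = c(0, 2, 4, 6, 8))$q2_ext
  expect_true(is.finite(f3))
  expect_error(external_metrics(y, yh, ybar_train = 10, variant = "F3"),
               "y_train")
})

test_that("threshold verdicts reproduce the reference battery's pass table", {
  # the eight reported models' validation statistics, typed as a fixture
  tab2 <- tibble::tribble(
    ~model,   ~r2_adj, ~q2_loo, ~q2_boot, ~r2_ext, ~q2_ext, ~ccc,
    "MLR-1",  0.873,   0.869,   0.872,    0.839,   0.835,   0.914,
    "MLP-1",  0.850,   0.678,   0.676,    0.790,   0.784,   0.889,
    "KNN-1",  0.920,   0.742,   0.778,    0.859,   0.855,   0.925,
    "GBDT-1", 0.995,   0.936,   0.964,    0.911,   0.902,   0.952,
    "MLR-2",  0.891,   0.874,   0.886,    0.833,   0.807,   0.902,
    "MLP-2",  0.921,   0.798,   0.809,    0.887,   0.884,   0.940,
    "KNN-2",  0.919,   0.661,   0.802,    0.821,   0.815,   0.891,
    "GBDT-2", 0.925,   0.756,   0.864,    0.837,   0.811,   0.891
  )
  verdicts <- check_thresholds(tab2)
  expect_true(all(verdicts$pass[!is.na(verdicts$pass)]))
  expect_equal(sum(!is.na(verdicts$pass)), 8 * 6)

  # a failing metric is caught
  bad <- check_thresholds(tibble::tibble(r2_adj = 0.65, q2_loo = 0.7,
                                         q2_boot = 0.7, r2_ext = 0.8,
                                         q2_ext = 0.7, ccc = 0.8))
  expect_equal(sum(!bad$pass, na.rm = TRUE), 2)  # r2_adj and ccc fail
})

test_that("residual CDFs count fractions and end at 1", {
  pr <- tibble::tibble(
    model = rep(c("a", "b"), each = 4),
    y = rep(c(0, 0, 0, 0), 2),
    y_hat = c(0, 0, 0, 0, 2, 0.5, -0.5, -2)
  )
  rc <- residual_cdf(pr)
  expect_equal(rc$fraction_within_1$fraction[rc$fraction_within_1$model == "a"], 1)
  expect_equal(rc$fraction_within_1$fraction[rc$fraction_within_1$model == "b"], 0.5)
  for (m in c("a", "b")) {
    cdf <- rc$cdf$cdf[rc$cdf$model == m]
    expect_true(all(diff(cdf) >= 0))
    expect_equal(cdf[length(cdf)], 1)
  }
})
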