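# A small full-rank synthetic descriptor table used throughout.
synthetic_X <- function(n = 100, seed = 1) {
  withr::with_seed(seed, tibble::tibble(
    VE1_L = rnorm(n, 1.9, 0.4),
    SpPos_A = rnorm(n, 8, 1.5),
    `SpMax2_Bh(v)` = rnorm(n, 1.2, 0.3),
    `H_Dz(p)` = rnorm(n, 80, 20),
    LLS_01 = round(6 * runif(n)) / 6,
    LLS_02 = round(8 * runif(n)) / 8
  ))
}

test_that("the prefilter drops missing, constant, near-constant and redundant columns", {
  withr::with_seed(2, {
    n <- 200
    a <- rnorm(n)
    X <- tibble::tibble(
      log_kca = a + rnorm(n, 0, 0.3),
      a = a,
      b = a + rnorm(n, 0, 0.05),            # |r| with a > 0.9
      c = rnorm(n),                          # independent
      const = 1,
      nearly = c(rep(0, 195), rnorm(5)),     # modal value in 97.5% of rows
      holey = replace(rnorm(n), 3, NA)
    )
  })
  out <- prefilter_descriptors(X)
  expect_setequal(setdiff(names(out), "log_kca"), c("a", "c"))
  dropped <- attr(out, "dropped")
  expect_setequal(dropped$column, c("const", "nearly", "holey", "b"))
  expect_match(dropped$reason[dropped$column == "b"], "r")

  # two identical columns: exactly one survives
  Y <- tibble::tibble(log_kca = rnorm(50), u = rnorm(50))
  Y$v <- Y$u
  out2 <- prefilter_descriptors(Y)
  expect_equal(sum(c("u", "v") %in% names(out2)), 1)

  expect_error(prefilter_descriptors(
    tibble::tibble(log_kca = rnorm(10), k = 1)
  ), "every descriptor")
})

test_that("VIF matches the closed form and flags exact collinearity", {
  withr::with_seed(3, {
    n <- 2000
    z <- rnorm(n)
    x1 <- z
    x2 <- 0.8 * z + sqrt(1 - 0.64) * rnorm(n)
  })
  # two standardized columns with correlation r: VIF = 1/(1 - r^2)
  v <- vif(tibble::tibble(x1 = x1, x2 = x2))
  r2 <- cor(x1, x2)^2
  expect_equal(v$vif, rep(1 / (1 - r2), 2), tolerance = 1e-10)
  expect_equal(v$vif[1], 1 / (1 - 0.64), tolerance = 0.15)

  ortho <- vif(tibble::tibble(a = rep(c(1, -1), 10), b = rep(c(1, 1, -1, -1), 5)))
  expect_equal(ortho$vif, c(1, 1), tolerance = 1e-12)

  dup <- tibble::tibble(a = rnorm(20))
  dup$b <- dup$a
  expect_equal(vif(dup)$vif, c(Inf, Inf))
})

test_that("OLS recovers the reference coefficient sets from noiseless data", {
  X <- synthetic_X()
  for (preset_name in c("replicate", "averaged")) {
    preset <- mlr_preset(preset_name)
    X$log_kca <- predict(preset, X)
    fit <- fit_mlr(X, descriptors = preset$descriptors)
    expect_equal(fit$coefficients, preset$coefficients, tolerance = 1e-8)
    expect_equal(fit$intercept, preset$intercept, tolerance = 1e-8)
  }
})

test_that("OLS agrees with the normal-equation solve and is orthogonal to X", {
  X <- synthetic_X(60, seed = 4)
  withr::with_seed(5, X$log_kca <- 2 + rnorm(60))
  desc <- setdiff(names(X), "log_kca")
  fit <- fit_mlr(X, descriptors = desc)
  M <- cbind(1, as.matrix(X[desc]))
  beta <- solve(crossprod(M), crossprod(M, X$log_kca))
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(drop(beta)), tolerance = 1e-8)
  expect_lt(max(abs(crossprod(M, fit$residuals))), 1e-8)
})

test_that("rank deficiency errors and names a dependent column", {
  X <- tibble::tibble(a = rnorm(30), log_kca = rnorm(30))
  X$b <- 2 * X$a
  expect_error(fit_mlr(X, descriptors = c("a", "b")), "b")
})

test_that("preset predictions are affine with the printed intercepts at zero", {
  zero <- tibble::tibble(VE1_L = 0, SpPos_A = 0, `SpMax2_Bh(v)` = 0,
                         `H_Dz(p)` = 0, LLS_01 = 0, LLS_02 = 0)
  expect_equal(predict(mlr_preset("replicate"), zero), -13.433)
  expect_equal(predict(mlr_preset("averaged"), zero), -15.724)

  m <- mlr_preset("averaged")
  x1 <- synthetic_X(5, seed = 8)
  x2 <- synthetic_X(5, seed = 9)
  xsum <- x1
  for (d in m$descriptors) xsum[[d]] <- x1[[d]] + x2[[d]]
  expect_equal(predict(m, xsum) - predict(m, x2),
               predict(m, x1) - predict(m, zero),
               tolerance = 1e-12)
})

test_that("prediction refuses descriptor-name mismatches", {
  m <- mlr_preset("averaged")
  expect_error(predict(m, tibble::tibble(SpPos_A = 1)), "LLS_02")
})

test_that("stepwise selection recovers true descriptors under high SNR", {
  hits <- 0
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- 120
      X <- as.data.frame(matrix(rnorm(n * 10), n, 10))
      names(X) <- paste0("d", 1:10)
      X$log_kca <- 3 * X$d2 - 2 * X$d7 + rnorm(n, 0, 0.3)
    })
    fit <- stepwise_mlr(X)
    if (all(c("d2", "d7") %in% fit$descriptors)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("stepwise honors max_p and the VIF gate", {
  withr::with_seed(10, {
    n <- 150
    X <- as.data.frame(matrix(rnorm(n * 8), n, 8))
    names(X) <- paste0("d", 1:8)
    X$log_kca <- rowSums(X[paste0("d", 1:6)]) + rnorm(n, 0, 0.2)
  })
  fit <- stepwise_mlr(X, max_p = 4)
  expect_lte(length(fit$descriptors), 4)

  # a candidate nearly collinear with an included one is skipped
  withr::with_seed(11, {
    Z <- tibble::tibble(a = rnorm(100), c = rnorm(100))
    Z$b <- Z$a + rnorm(100, 0, 0.01)              # VIF with a far above 10
    Z$log_kca <- 2 * Z$a + 1.9 * Z$b + Z$c + rnorm(100, 0, 0.1)
  })
  fit2 <- stepwise_mlr(Z, vif_max = 10)
  expect_false(all(c("a", "b") %in% fit2$descriptors))
  v <- vif(Z[fit2$descriptors])
  expect_true(all(v$vif < 10))

  expect_error(
    stepwise_mlr(tibble::tibble(x = rnorm(50), log_kca = rnorm(50)),
                 p_enter = 1e-12),
    "entry threshold"
  )
})

test_that("tidy and glance expose the fit in broom style", {
  X <- synthetic_X(50, seed = 13)
  X$log_kca <- predict(mlr_preset("averaged"), X) + rnorm(50, 0, 0.5)
  fit <- fit_mlr(X, descriptors = mlr_preset("averaged")$descriptors)
  td <- tidy(fit)
  expect_setequal(names(td),
                  c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_equal(nrow(td), 5)
  gl <- glance(fit)
  expect_true(all(c("r2", "r2_adj", "rmse", "mae", "s") %in% names(gl)))
  expect_gt(gl$r2_adj, 0.9)
})
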