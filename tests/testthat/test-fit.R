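test_that("adjusted R2 follows the closed form", {
  set.seed(1)
  # R2 = 0.5, n = 100, p = 1 -> 1 - 0.5 * 99 / 98
  y <- rnorm(100)
  # build yhat with exact squared correlation 0.5 via orthogonalization
  e <- residuals(lm(rnorm(100) ~ y))
  yc <- y - mean(y)
  yhat <- yc / sqrt(sum(yc^2)) + e / sqrt(sum(e^2))
  expect_equal(cor(y, yhat)^2, 0.5, tolerance = 1e-10)
  expect_equal(adjusted_r2(y, yhat, p = 1), 1 - 0.5 * 99 / 98, tolerance = 1e-10)
  expect_equal(adjusted_r2(y, y), 1)
  # constant prediction counts as zero R2 (negative after adjustment)
  expect_equal(adjusted_r2(y, rep(2, 100), p = 1), 1 - 99 / 98)
  # unbiased near zero under the null
  set.seed(2)
  m <- replicate(2000, adjusted_r2(rnorm(50), rnorm(50), p = 1))
  expect_lt(abs(mean(m)), 0.01)
})

test_that("the Gaussian LRT is calibrated and respects nesting", {
  y <- rnorm(80)
  expect_equal(lrt_significance(y, rep(1, 80))$p, 1)
  # nested-model oracle: adding the residual signal can only lower the p-value
  set.seed(3)
  x1 <- rnorm(200); x2 <- rnorm(200)
  yy <- x1 + x2 + rnorm(200)
  p1 <- lrt_significance(yy, x1)$p
  p2 <- lrt_significance(yy, cbind(x1, x2))$p
  expect_lte(p2, p1)
  # null calibration at 1e4 replicates (vectorized over correlation form)
  set.seed(4)
  n <- 500
  r <- replicate(10000, cor(rnorm(n), rnorm(n)))
  pvals <- pchisq(-n * log(1 - r^2), df = 1, lower.tail = FALSE)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("fit_component recovers strong signals and nothing from permuted data", {
  set.seed(5)
  n <- 120; M <- 30
  G <- matrix(rbinom(n * M, 2, 0.3), n, M,
              dimnames = list(paste0("i", 1:n), paste0("s", 1:M)))
  y <- as.numeric(scale(G[, 1]))
  f <- fit_component(y, G, seed = 11)
  expect_gt(f$cv_r2, 0.9)
  expect_lt(f$lrt_p, 1e-10)
  expect_identical(f$weights, fit_component(y, G, seed = 11)$weights)
  expect_equal(predict(f, G), drop(f$intercept + G %*% f$weights))
  # honest CV: permuting y destroys apparent predictability
  r2s <- sapply(1:5, function(k) {
    fit_component(sample(y), G, seed = k)$cv_r2
  })
  expect_lt(mean(r2s), 0.1)
  expect_error(fit_component(y[1:10], G[1:10, ]), "at least 20")
})

test_that("nested cross-validation mode produces honest predictions too", {
  set.seed(6)
  n <- 80; M <- 15
  G <- matrix(rbinom(n * M, 2, 0.4), n, M,
              dimnames = list(NULL, paste0("s", 1:M)))
  y <- G[, 2] * 0.8 + rnorm(n, sd = 0.5)
  f <- fit_component(y, G, cv = "nested", nfolds = 5, seed = 3)
  expect_length(f$preval, n)
  expect_true(all(is.finite(f$preval)))
  expect_gt(f$cv_r2, 0.15)
})

test_that("an unpenalized elastic-net refit matches OLS on well-posed data", {
  set.seed(7)
  n <- 300; M <- 8
  G <- matrix(rnorm(n * M), n, M, dimnames = list(NULL, paste0("s", 1:M)))
  y <- G %*% runif(M, -1, 1) + rnorm(n)
  co <- content:::enet_refit(G, y, lambda = 0)
  ols <- coef(lm(y ~ G))
  expect_lt(max(abs(co - ols)), 1e-6)
})

test_that("full-model recombination rescales and re-signs components", {
  set.seed(8)
  n <- 100
  sh <- rnorm(n); sp <- rnorm(n)
  # expression equal to the shared prediction: weights (1, 0), perfect fit
  f1 <- fit_full(sh, sh, sp)
  expect_equal(f1$w_shared, 1, tolerance = 1e-10)
  expect_equal(f1$w_specific, 0, tolerance = 1e-10)
  expect_equal(f1$cv_r2, 1, tolerance = 1e-10)
  # specific prediction with flipped sign is re-aligned by the regression
  y <- sh - sp
  f2 <- fit_full(y, sh, sp)
  expect_equal(f2$w_specific, -1, tolerance = 1e-10)
  expect_lt(f2$lrt_p, 1e-12)
  # constant predictor degrades gracefully to a one-predictor model
  f3 <- fit_full(y, rep(1, n), sp)
  expect_true(f3$degenerate)
  expect_equal(f3$w_shared, 0)
  # pure-noise predictors: adjusted R2 near zero on average
  m <- replicate(300, {
    fit_full(rnorm(50), rnorm(50), rnorm(50))$cv_adj_r2
  })
  expect_lt(mean(m), 0.02)
  # combined weights are the stated linear combination
  w1 <- setNames(runif(5), paste0("s", 1:5))
  w2 <- setNames(runif(5), paste0("s", 1:5))
  fake_sh <- list(weights = w1); fake_sp <- list(weights = w2)
  expect_equal(combine_weights(f2, fake_sh, fake_sp), f2$w_shared * w1 + f2$w_specific * w2)
})

test_that("model selection prefers the best cross-validated score with principled ties", {
  s <- data.frame(gene = "g1",
                  context = c("all", "c1", "c1", "c2", "c2"),
                  model = c("shared", "specific", "full", "specific", "full"),
                  n = 50, cv_r2 = 0,
                  cv_adj_r2 = c(0.2, 0.5, 0.4, 0.3, 0.3),
                  lrt_p = 0.5)
  fake <- structure(list(method = "content", summary = s), class = "content_models")
  best <- select_best_model(fake)
  expect_equal(best$model[best$context == "c1"], "specific")
  # tie between specific and full resolved toward the simpler model
  expect_equal(best$model[best$context == "c2"], "specific")
})
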