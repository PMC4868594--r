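test_that("scoring matches hand arithmetic", {
  obs <- c(0, 1, 2)
  pred <- c(0, 1, 3)
  s <- score(obs, pred)
  expect_equal(unname(s["RMSE"]), sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(unname(s["R2"]), 0.5, tolerance = 1e-12)
  # explicit reference mean (external/CV convention)
  s2 <- score(c(0, 2), c(1, 1), reference_mean = 0)
  expect_equal(unname(s2["R2"]), 0.5)
  expect_equal(unname(score(c(0, 2), c(0, 2), reference_mean = 1)["R2"]), 1)
})

test_that("default grids follow the documented shapes", {
  g <- default_grid("random_forest", p = 234, n = 176)
  expect_identical(g$mtry, sort(unique(c(15L, 78L, 156L))))
  g <- default_grid("pls", p = 3, n = 100)
  expect_identical(g$ncomp, 1:3)
  g <- default_grid("pls", p = 500, n = 8)
  expect_identical(max(g$ncomp), 6L)         # capped at n - 2
  expect_identical(nrow(default_grid("ridge", p = 10, n = 50)), 6L)
  expect_identical(nrow(default_grid("svm_rbf", p = 10, n = 50)), 9L)
})

test_that("standardization uses training statistics and tolerates constants", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  std <- pcmfit:::std_fit(X)
  Xs <- pcmfit:::std_apply(X, std)
  expect_equal(colMeans(Xs), c(a = 0, b = 0))
  expect_equal(sd(Xs[, "a"]), 1)
  expect_true(all(is.finite(Xs)))             # sd 0 column passes through
})

test_that("closed-form shrinkage solves the penalized normal equations", {
  set.seed(8)
  X <- matrix(rnorm(200), 40, 5)
  Xs <- scale(X)
  y <- rnorm(40)
  yc <- y - mean(y)
  lambda <- 2.5
  sv <- pcmfit:::.ridge_svd(Xs, yc)
  beta <- pcmfit:::.ridge_coef(sv, yc, lambda)
  direct <- solve(crossprod(Xs) + lambda * diag(5), crossprod(Xs, yc))
  expect_equal(as.numeric(beta), as.numeric(direct), tolerance = 1e-10)
})

test_that("bayesian_linear recovers an exact linear relation", {
  set.seed(21)
  X <- matrix(rnorm(300), 60, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- 2 + X %*% c(1, -0.5, 0.25, 0, 0.75)
  f <- tune_and_fit(X, as.numeric(y), family = "bayesian_linear", seed = 1)
  expect_gt(f$metrics[["R2_Tr"]], 0.999)
  expect_gt(f$metrics[["Q2_CV"]], 0.99)
  expect_lt(f$metrics[["RMSE_Tr"]], 0.05)
})

test_that("tuning reports the winner's out-of-fold metrics and refits", {
  set.seed(4)
  X <- matrix(rnorm(400), 80, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- as.numeric(X %*% c(2, -1, 0, 0, 1) + rnorm(80, sd = 0.3))
  f <- tune_and_fit(X, y, family = "ridge", seed = 1)
  expect_s3_class(f, "pcm_fit_result")
  expect_named(f$metrics, c("R2_Tr", "Q2_CV", "RMSE_Tr", "RMSE_CV"))
  expect_true(f$best_params$lambda %in% default_grid("ridge", 5, 80)$lambda)
  expect_gt(f$metrics[["Q2_CV"]], 0.8)
  # refit on all training rows: fitted values have full length
  expect_length(f$fitted, 80)
})

test_that("fits are deterministic under a fixed seed", {
  set.seed(5)
  X <- matrix(rnorm(600), 60, 10, dimnames = list(NULL, paste0("x", 1:10)))
  y <- as.numeric(X %*% rep(c(1, 0), 5) + rnorm(60, sd = 0.2))
  f1 <- tune_and_fit(X, y, family = "random_forest", seed = 7)
  f2 <- tune_and_fit(X, y, family = "random_forest", seed = 7)
  expect_identical(f1$fitted, f2$fitted)
  expect_identical(f1$best_params, f2$best_params)
})

test_that("prediction refuses design matrices with mismatched columns", {
  set.seed(6)
  X <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- rnorm(20)
  f <- tune_and_fit(X, y, family = "ridge", seed = 1)
  Xbad <- X[, c(2, 1, 3, 4, 5)]
  expect_error(pcmfit:::predict_engine(f$engine, Xbad), "same names")
  Xren <- X; colnames(Xren)[1] <- "zz"
  expect_error(pcmfit:::predict_engine(f$engine, Xren), "same names")
})

test_that("the forest engine agrees with an independent implementation", {
  set.seed(30)
  X <- matrix(rnorm(600), 60, 10, dimnames = list(NULL, paste0("x", 1:10)))
  y <- as.numeric(X %*% c(3, -2, rep(0, 8)) + rnorm(60, sd = 0.2))
  f <- pcmfit:::fit_engine("random_forest", X, y,
                           params = list(mtry = 3), seed = 1)
  p1 <- pcmfit:::predict_engine(f, X)
  rf <- randomForest::randomForest(X, y, ntree = 500, mtry = 3)
  p2 <- as.numeric(predict(rf, X))
  expect_gt(cor(p1, y), 0.95)
  expect_gt(cor(p2, y), 0.95)
  expect_gt(cor(p1, p2), 0.95)
  # impurity importance ranks the true drivers first in both
  imp <- sort(pcmfit:::engine_importance(f), decreasing = TRUE)
  expect_setequal(names(imp)[1:2], c("x1", "x2"))
})

test_that("importance is defined for the forest family only", {
  set.seed(9)
  X <- matrix(rnorm(100), 20, 5, dimnames = list(NULL, paste0("x", 1:5)))
  f <- tune_and_fit(X, rnorm(20), family = "ridge", seed = 1)
  expect_error(pcmfit:::engine_importance(f$engine), "random")
})
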