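test_that("the fitted object carries partition, metrics and methods", {
  fit <- shared_fit()
  expect_s3_class(fit, "pcm")
  expect_identical(length(fit$partition$internal), 176L)
  expect_identical(length(fit$partition$external), 44L)
  expect_named(fit$metrics, c("R2_Tr", "Q2_CV", "RMSE_Tr", "RMSE_CV",
                              "Q2_Ext", "RMSE_Ext"))
  expect_output(print(fit), "Proteochemometric model 3")
  expect_output(summary(fit), "reliability gap")
  expect_output(summary(fit), "top impurity importances")

  f <- fitted(fit)
  r <- residuals(fit)
  expect_length(f, 220)
  expect_equal(r, fit$activities$pic50 - f)
  imp <- importance(fit)
  expect_identical(names(imp), colnames(fit$design))

  pdf(NULL)
  expect_invisible(plot(fit))
  dev.off()
})

test_that("predictions on the training pairs reproduce the design encoding", {
  fit <- shared_fit()
  all_pred <- predict(fit)
  expect_length(all_pred, 220)
  pairs <- fit$activities[5:9, c("compound_id", "variant_id")]
  p <- predict(fit, pairs = pairs)
  expect_equal(p, all_pred[5:9], tolerance = 1e-10)
  expect_error(predict(fit, pairs = data.frame(compound_id = "999",
                                               variant_id = "WT")),
               "unknown compound")
  expect_length(predict(fit, pairs = fit$activities[0, ]), 0)
})

test_that("new compounds and variants can be encoded for prediction", {
  fit <- shared_fit()
  newc <- data.frame(id = "new1", smiles = "OCc1ccc(Cl)cc1")
  newv <- shared_sim()$variants[2, ]
  newv$variant_id <- "NEWV"
  p <- predict(fit,
               pairs = data.frame(compound_id = "new1", variant_id = "NEWV"),
               compounds = newc, variants = newv)
  expect_length(p, 1)
  expect_true(is.finite(p))
})

test_that("linear-family coefficients are returned on the raw scale", {
  sim <- shared_sim()
  fit <- pcm(sim$activities, sim$compounds, sim$variants, model = 6,
             learner = "ridge", seed = 1)
  b <- coef(fit)
  expect_identical(names(b)[1], "(Intercept)")
  expect_length(b, ncol(fit$design) + 1)
  # coefficients reproduce the engine's predictions
  manual <- b[1] + as.numeric(fit$design %*% b[-1])
  expect_equal(unname(manual), unname(predict(fit)), tolerance = 1e-6)
  expect_error(coef(shared_fit()), "ridge and bayesian_linear")
})

test_that("split='none' trains on everything and skips external metrics", {
  sim <- shared_sim()
  fit <- pcm(sim$activities, sim$compounds, sim$variants, model = 2,
             learner = "bayesian_linear", split = "none", seed = 1)
  expect_length(fit$partition$external, 0)
  expect_false("Q2_Ext" %in% names(fit$metrics))
})

test_that("cross-validation schemes pool Q2 over all records", {
  sim <- shared_sim()
  fit <- pcm(sim$activities, sim$compounds, sim$variants, model = 7,
             learner = "ridge", seed = 1)
  for (scheme in c("cv10", "loco", "lopo")) {
    cv <- pcm_crossvalidate(fit, scheme = scheme, seed = 2)
    expect_identical(cv$scheme, scheme)
    expect_length(cv$predictions, 220)
    expect_true(all(is.finite(cv$predictions)))
    expect_lt(cv$Q2, 1)
  }
  lopo <- pcm_crossvalidate(fit, scheme = "lopo")
  expect_identical(nrow(lopo$per_fold), 22L)
  expect_identical(sort(lopo$per_fold$group), sort(unique(sim$activities$variant_id)))
})

test_that("repeated partitions aggregate and collect importances", {
  rp <- pcm_repeat(shared_fit(), repeats = 3, base_seed = 900, tune = FALSE)
  expect_s3_class(rp, "pcm_repeat")
  expect_identical(nrow(rp$aggregate$per_run), 3L)
  expect_true(all(c("Q2_Ext", "RMSE_Ext") %in% names(rp$aggregate$mean)))
  expect_identical(dim(rp$importance), c(3L, ncol(shared_fit()$design)))
  expect_true(all(is.finite(rp$importance)))
})

test_that("identical records in the descriptor space abort the split", {
  sim <- shared_sim()
  dup_compounds <- sim$compounds
  # three distinct structures across ten ids: 66 distinct descriptor rows,
  # fewer than the 176 clusters the 80% split requires
  dup_compounds$smiles[4:10] <- dup_compounds$smiles[1]
  expect_error(
    suppressWarnings(pcm(sim$activities, dup_compounds, sim$variants,
                         model = 3, learner = "bayesian_linear", seed = 1)),
    "distinct descriptor rows")
})
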