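# Learner engines: random forest, PLS, ridge, RBF support-vector and
# Bayesian linear regression, with grid tuning by 10-fold cross-validation
# over the training set (caret-style: the winning grid point's CV metrics
# are the reported CV performance, and the final model is refit on all
# training rows).

LEARNERS <- c("random_forest", "pls", "ridge", "svm_rbf", "bayesian_linear")

#' Default hyperparameter grid for a learner family
#'
#' Grids are ordered from simpler to more complex so that ties in
#' cross-validated RMSE resolve to the simpler model: fewer candidate
#' features per split (random forest), fewer latent variables (PLS), more
#' shrinkage (ridge and Bayesian linear), smaller cost (SVM).
#'
#' @param family One of `"random_forest"`, `"pls"`, `"ridge"`, `"svm_rbf"`,
#'   `"bayesian_linear"`.
#' @param p,n Number of predictors and training rows.
#' @return A `data.frame`, one row per grid point.
#' @export
default_grid <- function(family = LEARNERS, p, n) {
  family <- match.arg(family)
  switch(family,
    random_forest = data.frame(
      mtry = sort(unique(pmax(1L, as.integer(c(floor(sqrt(p)), floor(p / 3),
                                               floor(2 * p / 3))))))),
    pls = data.frame(ncomp = seq_len(max(1L, min(8L, p, n - 2L)))),
    ridge = data.frame(lambda = 10^seq(2, -3, by = -1)),
    svm_rbf = expand.grid(cost = c(1, 10, 100), gamma = c(0.5, 1, 2) / max(1, p)),
    bayesian_linear = data.frame(prior_scale = 10^seq(-1.5, 1.5, by = 0.5)))
}

# Column standardization by training statistics (zero-sd columns pass
# through unscaled so constant features cannot produce NaNs).
std_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  list(center = ctr, scale = scl)
}
std_apply <- function(X, std) sweep(sweep(X, 2, std$center), 2, std$scale, "/")

# mixOmics requires unique rownames on its data matrix.
.with_rownames <- function(X) {
  rownames(X) <- as.character(seq_len(nrow(X)))
  X
}

# Closed-form ridge / Gaussian-prior posterior mean on standardized X.
.ridge_svd <- function(Xs, yc) svd(Xs)
.ridge_coef <- function(sv, yc, lambda) {
  d <- sv$d
  sv$v %*% ((d / (d^2 + lambda)) * crossprod(sv$u, yc))
}

# Fit one engine at fixed hyperparameters.
fit_engine <- function(family, X, y, params, seed = 1L) {
  X <- as.matrix(X)
  fit <- switch(family,
    random_forest = {
      ranger::ranger(
        x = X, y = y, num.trees = 500L, mtry = min(params$mtry, ncol(X)),
        importance = "impurity", seed = seed, num.threads = 1L)
    },
    pls = {
      std <- std_fit(X)
      m <- mixOmics::pls(.with_rownames(std_apply(X, std)), y,
                         ncomp = params$ncomp, mode = "regression",
                         scale = FALSE)
      list(model = m, std = std, ncomp = params$ncomp)
    },
    ridge = {
      std <- std_fit(X)
      m <- glmnet::glmnet(std_apply(X, std), y, alpha = 0, standardize = FALSE,
                          lambda = sort(unique(c(params$lambda, 10^seq(-3, 2))),
                                        decreasing = TRUE))
      list(model = m, std = std, lambda = params$lambda)
    },
    svm_rbf = {
      std <- std_fit(X)
      m <- e1071::svm(std_apply(X, std), y, type = "eps-regression",
                      kernel = "radial", gamma = params$gamma,
                      cost = params$cost, epsilon = 0.1, scale = FALSE)
      list(model = m, std = std)
    },
    bayesian_linear = {
      std <- std_fit(X)
      Xs <- std_apply(X, std)
      yc <- y - mean(y)
      sv <- .ridge_svd(Xs, yc)
      beta <- .ridge_coef(sv, yc, 1 / params$prior_scale^2)
      list(beta = drop(beta), intercept = mean(y), std = std)
    },
    stop("unknown learner family: ", family))
  structure(list(family = family, params = params, fit = fit,
                 colnames = colnames(X), seed = seed),
            class = "pcm_engine")
}

# Predict from a fitted engine; column set and order must match exactly.
predict_engine <- function(object, X) {
  X <- as.matrix(X)
  if (nrow(X) == 0) return(numeric(0))
  if (!identical(colnames(X), object$colnames)) {
    stop("prediction columns do not match the fitted design ",
         "(same names in the same order are required)")
  }
  f <- object$fit
  switch(object$family,
    random_forest = predict(f, data = X, num.threads = 1L)$predictions,
    pls = {
      p <- predict(f$model, .with_rownames(std_apply(X, f$std)))
      drop(p$predict[, 1, f$ncomp])
    },
    ridge = drop(predict(f$model, std_apply(X, f$std), s = f$lambda, exact = FALSE)),
    svm_rbf = as.numeric(predict(f$model, std_apply(X, f$std))),
    bayesian_linear = drop(std_apply(X, f$std) %*% f$beta + f$intercept))
}

#' Regression scoring: R-squared / Q-squared and RMSE
#'
#' `RMSE = sqrt(mean((y - yhat)^2))` and
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - ref)^2)`.  For training-set
#' scoring the reference is the evaluated set's own mean; for CV or external
#' scoring pass the training-set mean so the statistic measures improvement
#' over the null model fitted on the training data (the Q-squared
#' convention).
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @param reference_mean Baseline mean; defaults to `mean(observed)`.
#' @return Named numeric vector `c(R2 = ..., RMSE = ...)`.
#' @export
score <- function(observed, predicted, reference_mean = mean(observed)) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 2) stop("need at least 2 observations")
  press <- sum((observed - predicted)^2)
  tss <- sum((observed - reference_mean)^2)
  c(R2 = 1 - press / tss, RMSE = sqrt(mean((observed - predicted)^2)))
}

# Cross-validated out-of-fold predictions for every grid point.
# Returns a matrix n x nrow(grid).
cv_grid_predictions <- function(family, X, y, grid, fold_ids, seed) {
  n <- length(y)
  nfold <- max(fold_ids)
  pred <- matrix(NA_real_, n, nrow(grid))
  for (k in seq_len(nfold)) {
    test <- which(fold_ids == k)
    train <- which(fold_ids != k)
    Xtr <- X[train, , drop = FALSE]; ytr <- y[train]
    Xte <- X[test, , drop = FALSE]
    if (family == "pls") {
      std <- std_fit(Xtr)
      m <- mixOmics::pls(.with_rownames(std_apply(Xtr, std)), ytr,
                         ncomp = max(grid$ncomp), mode = "regression",
                         scale = FALSE)
      p <- predict(m, .with_rownames(std_apply(Xte, std)))$predict
      for (g in seq_len(nrow(grid))) pred[test, g] <- p[, 1, grid$ncomp[g]]
    } else if (family == "ridge") {
      std <- std_fit(Xtr)
      m <- glmnet::glmnet(std_apply(Xtr, std), ytr, alpha = 0,
                          standardize = FALSE,
                          lambda = sort(unique(c(grid$lambda, 10^seq(-3, 2))),
                                        decreasing = TRUE))
      p <- predict(m, std_apply(Xte, std), s = grid$lambda)
      pred[test, ] <- as.matrix(p)
    } else if (family == "bayesian_linear") {
      std <- std_fit(Xtr)
      Xs <- std_apply(Xtr, std)
      yc <- ytr - mean(ytr)
      sv <- .ridge_svd(Xs, yc)
      Xts <- std_apply(Xte, std)
      for (g in seq_len(nrow(grid))) {
        beta <- .ridge_coef(sv, yc, 1 / grid$prior_scale[g]^2)
        pred[test, g] <- drop(Xts %*% beta) + mean(ytr)
      }
    } else {
      for (g in seq_len(nrow(grid))) {
        m <- fit_engine(family, Xtr, ytr, grid[g, , drop = FALSE],
                        seed = seed + 101L * k + g)
        pred[test, g] <- predict_engine(m, Xte)
      }
    }
  }
  pred
}

#' Tune and fit one learner on a training design
#'
#' Grid search by `folds`-fold cross-validation over the training rows: the
#' grid point with the lowest cross-validated RMSE wins (ties go to the
#' earlier, simpler grid point), its out-of-fold metrics are reported as the
#' CV performance, and the final model is refit on all training rows at the
#' winning point.
#'
#' @param design Numeric matrix (training rows x descriptors).
#' @param targets Numeric response (pIC50), one value per row.
#' @param family Learner family (see [default_grid()]).
#' @param grid Hyperparameter grid; defaults to [default_grid()].
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   learner.
#' @return An object of class `"pcm_fit_result"`: the fitted engine, the
#'   winning parameters, out-of-fold CV predictions and metrics
#'   (`R2_Tr`, `Q2_CV`, `RMSE_Tr`, `RMSE_CV`).
#' @export
tune_and_fit <- function(design, targets, family = LEARNERS, grid = NULL,
                         folds = 10L, seed = 1L) {
  family <- match.arg(family)
  design <- as.matrix(design)
  n <- nrow(design)
  if (n != length(targets)) stop("design rows and targets differ in length")
  if (n < folds) stop("fewer training rows (", n, ") than folds (", folds, ")")
  if (var(targets) == 0) stop("degenerate target: zero variance")
  if (is.null(grid)) grid <- default_grid(family, p = ncol(design), n = n)
  if (nrow(grid) == 0) stop("empty tuning grid")

  fold_ids <- cv_folds(n, folds = folds, seed = seed)$fold_ids
  pred <- cv_grid_predictions(family, design, targets, grid, fold_ids, seed)
  cv_rmse <- sqrt(colMeans((pred - targets)^2))
  best <- which(cv_rmse <= min(cv_rmse) + 1e-12)[1]

  final <- fit_engine(family, design, targets, grid[best, , drop = FALSE],
                      seed = seed)
  fitted_vals <- predict_engine(final, design)
  tr <- score(targets, fitted_vals)
  cv <- score(targets, pred[, best], reference_mean = mean(targets))

  structure(list(
    family = family,
    grid = grid,
    best_params = grid[best, , drop = FALSE],
    engine = final,
    fitted = fitted_vals,
    cv_predictions = pred[, best],
    cv_rmse_grid = cv_rmse,
    metrics = c(R2_Tr = unname(tr["R2"]), Q2_CV = unname(cv["R2"]),
                RMSE_Tr = unname(tr["RMSE"]), RMSE_CV = unname(cv["RMSE"])),
    y_train_mean = mean(targets),
    seed = seed), class = "pcm_fit_result")
}

#' @export
print.pcm_fit_result <- function(x, ...) {
  cat("Tuned ", x$family, " fit (seed ", x$seed, ")\n", sep = "")
  cat("  best parameters:",
      paste(names(x$best_params), unlist(x$best_params), sep = " = ",
            collapse = ", "), "\n")
  m <- x$metrics
  cat(sprintf("  R2_Tr = %.3f, Q2_CV = %.3f, RMSE_Tr = %.3f, RMSE_CV = %.3f\n",
              m["R2_Tr"], m["Q2_CV"], m["RMSE_Tr"], m["RMSE_CV"]))
  invisible(x)
}

# Impurity importance of a fitted random-forest engine (total decrease in
# node variance attributable to each descriptor -- the regression analogue
# of mean-decrease-Gini).
engine_importance <- function(object) {
  if (object$family != "random_forest") {
    stop("impurity importance is defined for the random_forest family only")
  }
  ranger::importance(object$fit)
}
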