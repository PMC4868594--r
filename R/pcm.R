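# The pcm() front end: one call from raw tables to a tuned, externally
# validated proteochemometric model, returned as a classed object with the
# usual modelling methods.

#' Fit a proteochemometric model
#'
#' Encodes compounds (substructure-fingerprint counts) and protein variants
#' (position-specific z-scales), filters each block by near-zero variance
#' and pairwise correlation, builds cross-terms, assembles the design for
#' one of the 13 canonical block combinations, splits the records into an
#' internal and external set by K-means in the joint C + P descriptor
#' space, tunes the chosen learner by 10-fold cross-validation on the
#' internal set, and scores the refit model externally.
#'
#' @param activities Activity table: `compound_id`, `variant_id`, `pic50`
#'   (see [activity_table()]); need not be a complete grid.
#' @param compounds Compound table: `id`, `smiles`(, `name`).
#' @param variants Variant table: `variant_id` plus one `p<position>`
#'   residue column per varied position.
#' @param model Block combination id, 1..13 (see [model_blocks()]).
#' @param learner Learner family (see [default_grid()]).
#' @param dictionary SMARTS dictionary (default: package dictionary).
#' @param zscales z-scale table (default: package table).
#' @param positions Varied positions (default: the 13 aromatase positions).
#' @param split `"kmeans"` for the 80/20 calibration split, `"none"` to
#'   train on all records (no external metrics).
#' @param fraction Internal-set fraction for the split (default 0.8).
#' @param folds Tuning/CV folds (default 10).
#' @param grid Hyperparameter grid; default [default_grid()].
#' @param cor_cutoff Pairwise-correlation cutoff (default 0.7).
#' @param freq_cut Near-zero-variance frequency-ratio cutoff (default 95/5).
#' @param seed Integer seed controlling the split, fold assignment and any
#'   stochastic learner.
#' @return An object of class `"pcm"`; see [predict.pcm()],
#'   [summary.pcm()], [importance()], [pcm_crossvalidate()],
#'   [pcm_yscramble()], [pcm_repeat()].
#' @examples
#' \donttest{
#' sim <- simulate_pcm_data(seed = 1)
#' fit <- pcm(sim$activities, sim$compounds, sim$variants,
#'            model = 3, learner = "random_forest", seed = 1)
#' summary(fit)
#' }
#' @export
pcm <- function(activities, compounds, variants, model = 3L,
                learner = LEARNERS,
                dictionary = default_smarts_dictionary(),
                zscales = default_zscale_table(),
                positions = aromatase_positions(),
                split = c("kmeans", "none"), fraction = 0.8,
                folds = 10L, grid = NULL,
                cor_cutoff = 0.7, freq_cut = 95 / 5, seed = 1L) {
  learner <- match.arg(learner)
  split <- match.arg(split)
  cl <- match.call()

  bb <- build_blocks(activities, compounds, variants,
                     dictionary = dictionary, zscales = zscales,
                     positions = positions, cor_cutoff = cor_cutoff,
                     freq_cut = freq_cut)
  design <- assemble_design(model, bb$blocks)
  y <- bb$activities$pic50
  split_space <- cbind(as.matrix(bb$blocks$C), as.matrix(bb$blocks$P))

  if (split == "kmeans") {
    part <- kmeans_split(split_space, fraction = fraction, seed = seed)
  } else {
    part <- structure(list(internal = seq_along(y), external = integer(0),
                           seed = seed, retries = 0L),
                      class = "pcm_partition")
  }

  fit <- tune_and_fit(design[part$internal, , drop = FALSE], y[part$internal],
                      family = learner, grid = grid, folds = folds, seed = seed)

  metrics <- fit$metrics
  ext_pred <- NULL
  if (length(part$external)) {
    ext_pred <- predict_engine(fit$engine, design[part$external, , drop = FALSE])
    ext <- score(y[part$external], ext_pred, reference_mean = fit$y_train_mean)
    metrics <- c(metrics, Q2_Ext = unname(ext["R2"]), RMSE_Ext = unname(ext["RMSE"]))
  }

  structure(list(
    call = cl,
    model_id = as.integer(model),
    learner = learner,
    blocks_used = model_blocks(model),
    activities = bb$activities,
    design = design,
    split_space = split_space,
    kept = list(C = colnames(bb$blocks$C), P = colnames(bb$blocks$P)),
    blocks = bb$blocks,
    curation = bb$curation,
    filter = bb$filter,
    partition = part,
    fit = fit,
    metrics = metrics,
    external_predictions = ext_pred,
    config = list(dictionary = dictionary, zscales = zscales,
                  positions = positions, cor_cutoff = cor_cutoff,
                  freq_cut = freq_cut, fraction = fraction, folds = folds,
                  grid = fit$grid, seed = seed)),
    class = "pcm")
}

#' @export
print.pcm <- function(x, ...) {
  cat("Proteochemometric model ", x$model_id, " [",
      paste(x$blocks_used, collapse = " + "), "], learner: ", x$learner,
      "\n", sep = "")
  cat("  ", nrow(x$activities), " records (",
      length(unique(x$activities$compound_id)), " compounds x ",
      length(unique(x$activities$variant_id)), " variants), ",
      ncol(x$design), " descriptors after filtering\n", sep = "")
  cat("  internal/external: ", length(x$partition$internal), "/",
      length(x$partition$external), " (seed ", x$config$seed, ")\n", sep = "")
  m <- x$metrics
  line <- paste(sprintf("%s = %.3f", names(m), m), collapse = ", ")
  cat("  ", line, "\n", sep = "")
  invisible(x)
}

#' Summarize a proteochemometric model
#'
#' @param object A `"pcm"` fit.
#' @param top_k Number of top important descriptors to display (random
#'   forest only).
#' @param ... Unused.
#' @return `object`, invisibly; prints metrics, the reliability gap and,
#'   for random-forest fits, the leading impurity importances.
#' @export
summary.pcm <- function(object, top_k = 10L, ...) {
  print(object)
  cat("  tuned: ", paste(names(object$fit$best_params),
                         unlist(object$fit$best_params),
                         sep = " = ", collapse = ", "), "\n", sep = "")
  q2 <- if ("Q2_Ext" %in% names(object$metrics))
    object$metrics[["Q2_Ext"]] else object$metrics[["Q2_CV"]]
  rel <- reliability_check(object$metrics[["R2_Tr"]], q2)
  cat(sprintf("  reliability gap R2 - Q2 = %.3f (%s)\n", rel$gap,
              if (rel$pass) "pass" else "check for overfitting"))
  if (object$learner == "random_forest") {
    imp <- sort(engine_importance(object$fit$engine), decreasing = TRUE)
    k <- min(top_k, length(imp))
    cat("  top impurity importances:\n")
    for (i in seq_len(k)) {
      cat(sprintf("    %-28s %.3f\n", names(imp)[i], imp[i]))
    }
  }
  invisible(object)
}

#' Predict pIC50 for compound-variant pairs
#'
#' Without new data, returns predictions for every record the model was
#' built on.  With new data, the pairs are encoded with the stored
#' dictionary, z-scale table and filtered descriptor set, the cross-terms
#' rebuilt, and the design assembled with exactly the fitted columns; a
#' column mismatch is an error, never a silent reordering.
#'
#' @param object A `"pcm"` fit.
#' @param pairs `data.frame` with `compound_id`, `variant_id` for the pairs
#'   to predict.
#' @param compounds,variants Tables defining any ids in `pairs` that the
#'   training tables did not contain (defaults: the training entities).
#' @param ... Unused.
#' @return Numeric vector of predicted pIC50, one per pair.
#' @export
predict.pcm <- function(object, pairs = NULL, compounds = NULL,
                        variants = NULL, ...) {
  if (is.null(pairs)) {
    return(predict_engine(object$fit$engine, object$design))
  }
  stopifnot(is.data.frame(pairs),
            all(c("compound_id", "variant_id") %in% names(pairs)))
  if (nrow(pairs) == 0) return(numeric(0))
  design <- .encode_pairs(object, pairs, compounds, variants)
  predict_engine(object$fit$engine, design)
}

.encode_pairs <- function(object, pairs, compounds = NULL, variants = NULL) {
  cfg <- object$config
  if (is.null(compounds)) {
    # training-compound descriptors reconstructed from the stored C block
    ids <- unique(object$activities$compound_id)
    first <- match(ids, object$activities$compound_id)
    counts <- as.matrix(object$blocks$C)[first, , drop = FALSE]
    rownames(counts) <- ids
  } else {
    cur <- curate_compounds(compounds)
    if (nrow(cur$rejected)) {
      stop("compound(s) rejected during curation: ",
           paste(cur$rejected$id, collapse = ", "))
    }
    counts <- fingerprint_counts(cur$kept, cfg$dictionary)
  }
  if (is.null(variants)) {
    ids <- unique(object$activities$variant_id)
    first <- match(ids, object$activities$variant_id)
    zmat <- as.matrix(object$blocks$P)[first, , drop = FALSE]
    rownames(zmat) <- ids
  } else {
    zmat <- zscale_encode(variant_table(variants, cfg$positions),
                          cfg$zscales, cfg$positions)
  }
  missC <- setdiff(object$kept$C, colnames(counts))
  if (length(missC)) stop("encoded compounds lack fitted descriptor(s): ",
                          paste(head(missC, 3), collapse = ", "))
  unknownC <- setdiff(pairs$compound_id, rownames(counts))
  if (length(unknownC)) stop("unknown compound id(s): ",
                             paste(unique(unknownC), collapse = ", "))
  unknownP <- setdiff(pairs$variant_id, rownames(zmat))
  if (length(unknownP)) stop("unknown variant id(s): ",
                             paste(unique(unknownP), collapse = ", "))
  C <- descriptor_block(counts[pairs$compound_id, object$kept$C, drop = FALSE],
                        kind = "C")
  P <- descriptor_block(zmat[pairs$variant_id, object$kept$P, drop = FALSE],
                        kind = "P")
  blocks <- list(C = C, P = P)
  need <- object$blocks_used
  if ("CxP" %in% need) blocks$CxP <- cross_block(C, P)
  if ("CxC" %in% need) blocks$CxC <- self_cross_block(C)
  if ("PxP" %in% need) blocks$PxP <- self_cross_block(P)
  assemble_design(object$model_id, blocks)
}

#' @export
fitted.pcm <- function(object, ...) {
  out <- rep(NA_real_, nrow(object$activities))
  out[object$partition$internal] <- object$fit$fitted
  if (length(object$partition$external)) {
    out[object$partition$external] <- object$external_predictions
  }
  out
}

#' @export
residuals.pcm <- function(object, ...) {
  object$activities$pic50 - fitted(object)
}

#' Observed-versus-predicted plot
#'
#' @param x A `"pcm"` fit.
#' @param ... Passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.pcm <- function(x, ...) {
  obs <- x$activities$pic50
  pred <- fitted(x)
  set_col <- rep("steelblue", length(obs))
  set_col[x$partition$external] <- "firebrick"
  plot(obs, pred, col = set_col, pch = 19,
       xlab = "experimental pIC50", ylab = "predicted pIC50",
       main = sprintf("model %d (%s)", x$model_id, x$learner), ...)
  abline(0, 1, lty = 2, col = "grey40")
  legend("topleft", legend = c("internal", "external"), pch = 19,
         col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
coef.pcm <- function(object, ...) {
  f <- object$fit$engine
  switch(object$learner,
    ridge = {
      b <- as.matrix(coef(f$fit$model, s = f$fit$lambda))
      # undo the internal standardization so coefficients are on raw scale
      beta <- b[-1, 1] / f$fit$std$scale
      c(`(Intercept)` = b[1, 1] - sum(beta * f$fit$std$center), beta)
    },
    bayesian_linear = {
      beta <- f$fit$beta / f$fit$std$scale
      names(beta) <- f$colnames
      c(`(Intercept)` = f$fit$intercept - sum(beta * f$fit$std$center), beta)
    },
    stop("coefficients are defined for the ridge and bayesian_linear ",
         "families only"))
}

#' Impurity importance of a fitted model
#'
#' @param object A fitted model object.
#' @param ... Method-specific arguments.
#' @return Named numeric vector of importances.
#' @export
importance <- function(object, ...) UseMethod("importance")

#' @rdname importance
#' @export
importance.pcm <- function(object, ...) {
  engine_importance(object$fit$engine)
}

#' Grouped and random cross-validation of a fitted model
#'
#' Re-evaluates the model's configuration under random 10-fold,
#' leave-one-compound-out or leave-one-protein-out resampling over all
#' records.  Each fold's model is fit on the remaining records at the
#' tuned hyperparameters (set `retune = TRUE` to redo the grid search inside
#' every fold).
#'
#' @param object A `"pcm"` fit.
#' @param scheme `"cv10"`, `"loco"` or `"lopo"`.
#' @param folds Folds for `"cv10"` (default 10).
#' @param retune Redo hyperparameter tuning inside each fold (default
#'   `FALSE`: reuse the tuned parameters).
#' @param seed Integer seed (fold assignment for `"cv10"`).
#' @return List with `scheme`, pooled `Q2` and `RMSE` (reference mean =
#'   full-data mean), `per_fold` metrics and the out-of-fold `predictions`.
#' @export
pcm_crossvalidate <- function(object, scheme = c("cv10", "loco", "lopo"),
                              folds = 10L, retune = FALSE, seed = 1L) {
  scheme <- match.arg(scheme)
  y <- object$activities$pic50
  n <- length(y)
  fl <- switch(scheme,
    cv10 = cv_folds(n, folds = folds, seed = seed),
    loco = loco_folds(object$activities),
    lopo = lopo_folds(object$activities))
  pred <- rep(NA_real_, n)
  per_fold <- list()
  for (k in seq_along(fl$folds)) {
    test <- fl$folds[[k]]
    train <- setdiff(seq_len(n), test)
    Xtr <- object$design[train, , drop = FALSE]
    Xte <- object$design[test, , drop = FALSE]
    if (retune) {
      f <- tune_and_fit(Xtr, y[train], family = object$learner,
                        grid = object$config$grid, folds = min(folds, length(train)),
                        seed = seed + k)
      eng <- f$engine
    } else {
      eng <- fit_engine(object$learner, Xtr, y[train],
                        object$fit$best_params, seed = seed + k)
    }
    pred[test] <- predict_engine(eng, Xte)
    sc <- if (length(test) >= 2)
      score(y[test], pred[test], reference_mean = mean(y[train]))
    else c(R2 = NA_real_, RMSE = abs(y[test] - pred[test]))
    per_fold[[k]] <- data.frame(fold = k,
                                group = if (!is.null(fl$groups)) fl$groups[k] else NA,
                                n = length(test), Q2 = sc["R2"], RMSE = sc["RMSE"],
                                row.names = NULL)
  }
  pooled <- score(y, pred, reference_mean = mean(y))
  list(scheme = scheme,
       Q2 = unname(pooled["R2"]), RMSE = unname(pooled["RMSE"]),
       per_fold = do.call(rbind, per_fold),
       predictions = pred)
}

#' Y-scrambling test of a fitted model
#'
#' Permutes the internal-set response `rounds` times and reruns the
#' training protocol (same partition and CV folds) on each scrambled copy,
#' so real and scrambled performance are compared like for like.  By
#' default each round reuses the real fit's selected hyperparameters
#' (`retune = FALSE`): scrambling probes chance correlation at the chosen
#' model complexity; set `retune = TRUE` to redo the full grid search per
#' round.
#'
#' @param object A `"pcm"` fit (with a K-means partition).
#' @param rounds Number of permutations (default 50).
#' @param seed Integer seed for the permutations.
#' @param retune Rerun the hyperparameter grid per round (default `FALSE`).
#' @return List with `real` (named metrics of the unscrambled fit),
#'   `scrambled` (`data.frame` of per-round `R2_Tr`, `Q2_CV`, `RMSE_CV`)
#'   and the `separation` between real Q2_CV and the scrambled maximum.
#' @export
pcm_yscramble <- function(object, rounds = 50L, seed = 1L, retune = FALSE) {
  internal <- object$partition$internal
  X <- object$design[internal, , drop = FALSE]
  y <- object$activities$pic50[internal]
  grid <- if (retune) object$config$grid else
    as.data.frame(object$fit$best_params)
  perms <- y_scramble(y, rounds = rounds, seed = seed)
  rows <- lapply(seq_along(perms), function(i) {
    f <- tune_and_fit(X, perms[[i]], family = object$learner,
                      grid = grid, folds = object$config$folds,
                      seed = object$config$seed)
    data.frame(round = i, R2_Tr = f$metrics[["R2_Tr"]],
               Q2_CV = f$metrics[["Q2_CV"]], RMSE_CV = f$metrics[["RMSE_CV"]])
  })
  scr <- do.call(rbind, rows)
  list(real = object$fit$metrics,
       scrambled = scr,
       separation = object$fit$metrics[["Q2_CV"]] - max(scr$Q2_CV))
}

#' Repeated independent partitions of a fitted model's configuration
#'
#' Reruns split -> tune -> fit -> score over `repeats` independent K-means
#' partitions (seeds `base_seed + 1 ...`), aggregating every metric as mean
#' and standard deviation; for random-forest fits the per-partition
#' impurity importances are collected for [importance_aggregate()].
#'
#' @param object A `"pcm"` fit.
#' @param repeats Number of partitions (default 100).
#' @param base_seed Seed offset (default 0).
#' @param tune Tune the grid inside every partition (default `TRUE`; with
#'   `FALSE` the object's tuned parameters are reused and no CV metrics are
#'   produced — the fast path for importance batteries).
#' @return An object of class `"pcm_repeat"`: the [repeat_partitions()]
#'   aggregate plus, for random forests, an `importance` matrix
#'   (partitions x descriptors).
#' @export
pcm_repeat <- function(object, repeats = 100L, base_seed = 0L, tune = TRUE) {
  y <- object$activities$pic50
  design <- object$design
  space <- object$split_space
  imp <- if (object$learner == "random_forest")
    matrix(NA_real_, repeats, ncol(design), dimnames = list(NULL, colnames(design)))
  else NULL
  i_run <- 0L
  pipeline <- function(s) {
    part <- kmeans_split(space, fraction = object$config$fraction, seed = s)
    Xtr <- design[part$internal, , drop = FALSE]
    ytr <- y[part$internal]
    if (tune) {
      f <- tune_and_fit(Xtr, ytr, family = object$learner,
                        grid = object$config$grid,
                        folds = object$config$folds, seed = s)
      eng <- f$engine
      m <- f$metrics
    } else {
      eng <- fit_engine(object$learner, Xtr, ytr, object$fit$best_params,
                        seed = s)
      tr <- score(ytr, predict_engine(eng, Xtr))
      m <- c(R2_Tr = unname(tr["R2"]), RMSE_Tr = unname(tr["RMSE"]))
    }
    ext <- score(y[part$external],
                 predict_engine(eng, design[part$external, , drop = FALSE]),
                 reference_mean = mean(ytr))
    i_run <<- i_run + 1L
    if (!is.null(imp)) imp[i_run, ] <<- engine_importance(eng)
    c(m, Q2_Ext = unname(ext["R2"]), RMSE_Ext = unname(ext["RMSE"]))
  }
  agg <- repeat_partitions(pipeline, repeats = repeats, base_seed = base_seed)
  structure(list(aggregate = agg, importance = imp,
                 model_id = object$model_id, learner = object$learner,
                 repeats = repeats, base_seed = base_seed),
            class = "pcm_repeat")
}

#' @export
print.pcm_repeat <- function(x, ...) {
  cat("Repeated partitions of model ", x$model_id, " (", x$learner, "), ",
      x$repeats, " runs\n", sep = "")
  print(x$aggregate)
  invisible(x)
}
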