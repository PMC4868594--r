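# Exploration of the chemical and biological spaces: PCA on standardized
# descriptor blocks, Horn's parallel analysis for component retention, and
# aggregation of random-forest impurity importance over repeated partitions.

#' Principal component analysis of a descriptor block
#'
#' Centers and (by default) scales the block to unit variance, then
#' decomposes it by SVD.  Signs are fixed deterministically: within each
#' component, the largest-magnitude loading is made positive.
#'
#' @param block Numeric matrix or [descriptor_block()]; zero-variance
#'   columns must be removed first (see [near_zero_variance_filter()]).
#' @param center,scale. Standardization switches (defaults `TRUE`).
#' @return An object of class `"pcm_pca"`: list with `scores`
#'   (rows x components), `loadings` (descriptors x components),
#'   `explained_variance` (fraction per component, non-increasing) and
#'   `sdev`.
#' @export
pcm_pca <- function(block, center = TRUE, scale. = TRUE) {
  x <- as.matrix(block)
  if (nrow(x) < 2) stop("need at least 2 rows for PCA")
  sds <- apply(x, 2, sd)
  if (scale. && any(sds == 0)) {
    stop("zero-variance column(s): ",
         paste(head(colnames(x)[sds == 0], 3), collapse = ", "),
         "; remove them before PCA")
  }
  pc <- prcomp(x, center = center, scale. = scale.)
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2
  structure(list(scores = pc$x, loadings = pc$rotation,
                 explained_variance = ev / sum(ev), sdev = pc$sdev),
            class = "pcm_pca")
}

#' @export
print.pcm_pca <- function(x, ...) {
  k <- min(4L, length(x$explained_variance))
  cat("PCA:", nrow(x$scores), "rows,", nrow(x$loadings), "descriptors\n")
  cat("  explained variance (first", k, "PCs):",
      paste(sprintf("%.2f%%", 100 * x$explained_variance[seq_len(k)]),
            collapse = ", "), "\n")
  cat("  cumulative:",
      sprintf("%.2f%%", 100 * sum(x$explained_variance[seq_len(k)])), "\n")
  invisible(x)
}

#' Horn's parallel analysis
#'
#' Decides how many principal components to retain by comparing the
#' observed correlation-matrix eigenvalues with the distribution of
#' eigenvalues from `iterations` random standard-normal matrices of the
#' same shape.  Leading components are retained while the observed
#' eigenvalue exceeds the chosen null quantile; retention stops at the
#' first failure.
#'
#' @param block Numeric matrix (rows x descriptors); standardized
#'   internally.
#' @param iterations Number of null matrices (default 5000).
#' @param prob Null quantile an eigenvalue must beat (default 0.95).
#' @param seed Integer seed for the null simulation.
#' @return An object of class `"horns_pa"`: list with `retained` (component
#'   count), `eigenvalues`, `thresholds` and the call parameters.
#' @export
horns_parallel <- function(block, iterations = 5000L, prob = 0.95,
                           seed = 1L) {
  if (iterations < 1) stop("iterations must be >= 1")
  x <- as.matrix(block)
  n <- nrow(x); p <- ncol(x)
  if (n < 3 || p < 2) stop("need at least 3 rows and 2 columns")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) stop("zero-variance column(s); remove them first")
  obs <- eigen(cor(x), symmetric = TRUE, only.values = TRUE)$values
  set.seed(seed)
  null_eig <- matrix(NA_real_, iterations, p)
  for (i in seq_len(iterations)) {
    z <- matrix(rnorm(n * p), n, p)
    null_eig[i, ] <- eigen(cor(z), symmetric = TRUE, only.values = TRUE)$values
  }
  thr <- apply(null_eig, 2, quantile, probs = prob, names = FALSE)
  keep <- obs > thr
  retained <- if (!keep[1]) 0L else which.min(c(keep, FALSE)) - 1L
  structure(list(retained = as.integer(retained), eigenvalues = obs,
                 thresholds = thr, iterations = iterations,
                 prob = prob, seed = seed),
            class = "horns_pa")
}

#' @export
print.horns_pa <- function(x, ...) {
  cat("Horn's parallel analysis (", x$iterations, " iterations, ",
      100 * x$prob, "th percentile): retain ", x$retained,
      " component(s)\n", sep = "")
  k <- min(6L, length(x$eigenvalues))
  cat("  eigenvalues:", paste(sprintf("%.2f", x$eigenvalues[1:k]), collapse = ", "),
      "\n  thresholds: ", paste(sprintf("%.2f", x$thresholds[1:k]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Aggregate impurity importance over repeated partitions
#'
#' Averages the per-partition random-forest impurity importances (total
#' decrease in node variance per descriptor — the regression analogue of
#' mean-decrease-Gini) and ranks descriptors by the mean.
#'
#' @param importance A matrix (partitions x descriptors), e.g. the
#'   `importance` element of [pcm_repeat()], or a `"pcm_repeat"` object.
#' @param top_k Number of leading descriptors to return (default all).
#' @return A `data.frame` with `feature`, `mean_importance`,
#'   `sd_importance`, `rank`, sorted by decreasing mean.
#' @export
importance_aggregate <- function(importance, top_k = NULL) {
  if (inherits(importance, "pcm_repeat")) {
    if (is.null(importance$importance)) {
      stop("impurity importance is defined for the random_forest family only")
    }
    importance <- importance$importance
  }
  if (is.null(dim(importance))) stop("expected a partitions x descriptors matrix")
  mu <- colMeans(importance)
  sdev <- apply(importance, 2, sd)
  ord <- order(mu, decreasing = TRUE)
  out <- data.frame(feature = colnames(importance)[ord],
                    mean_importance = unname(mu[ord]),
                    sd_importance = unname(sdev[ord]),
                    rank = seq_along(ord),
                    stringsAsFactors = FALSE)
  if (!is.null(top_k)) out <- out[seq_len(min(top_k, nrow(out))), ]
  rownames(out) <- NULL
  out
}
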