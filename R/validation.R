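# Resampling machinery: K-means 80/20 partitioning, random and grouped
# cross-validation folds, Y-scrambling, repeated-partition aggregation and
# the R2 - Q2 reliability check.

#' K-means calibration split
#'
#' Partitions interaction records into an internal (training) and external
#' (test) set by clustering the records in descriptor space into
#' `round(fraction * n)` clusters and picking, from each cluster, the record
#' closest to its center (ties to the lowest row index).  The selected
#' records form the internal set; the remainder is external.  This spreads
#' the training set over the occupied descriptor space instead of sampling
#' it at random.
#'
#' @param design Numeric matrix of descriptors (rows = records).  Columns
#'   are standardized internally before clustering so no descriptor
#'   dominates the Euclidean metric.
#' @param fraction Internal-set fraction (default 0.8); the internal size is
#'   `round(fraction * n)` (round half up).
#' @param seed Integer seed.
#' @return An object of class `"pcm_partition"`: list with
#'   `internal` / `external` integer row indices, `seed` and `retries`.
#' @export
kmeans_split <- function(design, fraction = 0.8, seed = 1L) {
  X <- as.matrix(design)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 records to split")
  k <- floor(fraction * n + 0.5)
  if (k >= n) stop("internal-set size k = ", k, " must be < n = ", n)
  if (k < 1) stop("fraction too small: empty internal set")
  n_distinct <- nrow(unique(X))
  if (n_distinct < k) {
    stop("only ", n_distinct, " distinct descriptor rows for k = ", k,
         " clusters; identical records cannot be split by K-means")
  }
  sds <- apply(X, 2, sd)
  Xs <- sweep(sweep(X, 2, colMeans(X)), 2, ifelse(sds == 0, 1, sds), "/")
  retries <- 0L
  km <- NULL
  for (attempt in 0:9) {
    set.seed(seed + 1000L * attempt)
    km <- tryCatch(suppressWarnings(
      kmeans(Xs, centers = k, iter.max = 50L, nstart = 1L)),
      error = function(e) NULL)
    if (!is.null(km) && all(km$size > 0)) break
    retries <- retries + 1L
    km <- NULL
  }
  if (is.null(km)) stop("K-means failed to produce ", k, " non-empty clusters")
  internal <- integer(k)
  for (cl in seq_len(k)) {
    members <- which(km$cluster == cl)
    d2 <- rowSums((Xs[members, , drop = FALSE] -
                   matrix(km$centers[cl, ], length(members), ncol(Xs),
                          byrow = TRUE))^2)
    internal[cl] <- members[which.min(d2)]  # which.min takes the first = lowest index
  }
  internal <- sort(internal)
  structure(list(internal = internal,
                 external = setdiff(seq_len(n), internal),
                 seed = seed, retries = retries),
            class = "pcm_partition")
}

#' @export
print.pcm_partition <- function(x, ...) {
  cat("K-means partition: ", length(x$internal), " internal / ",
      length(x$external), " external records (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Random cross-validation folds
#'
#' @param n Number of records.
#' @param folds Number of folds (default 10); fold sizes differ by at most
#'   one record.
#' @param seed Integer seed; the same seed reproduces the same folds.
#' @return List with `fold_ids` (integer vector, one fold id per record),
#'   `folds` (list of test-index sets) and `grouping = "random"`.
#' @export
cv_folds <- function(n, folds = 10L, seed = 1L) {
  if (folds < 2) stop("folds must be >= 2")
  if (n < folds) stop("n (", n, ") must be >= folds (", folds, ")")
  set.seed(seed)
  ids <- sample(rep(seq_len(folds), length.out = n))
  list(fold_ids = ids,
       folds = split(seq_len(n), ids),
       grouping = "random")
}

#' Leave-one-compound-out / leave-one-protein-out folds
#'
#' One fold per compound (LOCO) or per variant (LOPO): all records of that
#' group form the test set, so the model is always asked to extrapolate to
#' an entirely unseen compound or protein.
#'
#' @param activities Activity table (see [activity_table()]).
#' @return List with `fold_ids`, `folds`, `groups` (the left-out id per
#'   fold) and `grouping` (`"by_compound"` or `"by_variant"`).
#' @export
loco_folds <- function(activities) {
  .group_folds(activities$compound_id, "by_compound")
}

#' @rdname loco_folds
#' @export
lopo_folds <- function(activities) {
  .group_folds(activities$variant_id, "by_variant")
}

.group_folds <- function(group, grouping) {
  levels <- unique(group)
  if (length(levels) < 2) stop("need at least 2 groups for grouped folds")
  ids <- match(group, levels)
  list(fold_ids = ids,
       folds = split(seq_along(group), ids),
       groups = levels,
       grouping = grouping)
}

#' Y-scrambling permutations of the response
#'
#' Returns `rounds` independent uniform random permutations of the target
#' vector.  Refitting the modeling pipeline on scrambled responses and
#' comparing with the real fit exposes chance correlation: a sound model's
#' real performance must separate clearly from the scrambled distribution.
#'
#' @param targets Numeric response vector.
#' @param rounds Number of permutations (default 50).
#' @param seed Integer seed.
#' @return List of `rounds` permuted vectors.
#' @export
y_scramble <- function(targets, rounds = 50L, seed = 1L) {
  if (rounds < 1) stop("rounds must be >= 1")
  set.seed(seed)
  lapply(seq_len(rounds), function(i) targets[sample(length(targets))])
}

#' Repeat a seeded pipeline over independent partitions
#'
#' Runs `pipeline(seed)` for seeds `base_seed + 1 ... base_seed + repeats`
#' and aggregates every metric it returns as mean and standard deviation.
#' A single failing run aborts with the offending seed in the error.
#'
#' @param pipeline Function taking one integer seed and returning a named
#'   numeric vector of metrics (deterministic given the seed).
#' @param repeats Number of independent partitions (default 100).
#' @param base_seed Integer offset for the per-run seeds.
#' @return An object of class `"pcm_aggregate"`: list with `per_run`
#'   (matrix, one row per run), `mean`, `sd` and `repeats`.
#' @export
repeat_partitions <- function(pipeline, repeats = 100L, base_seed = 0L) {
  if (repeats < 1) stop("repeats must be >= 1")
  rows <- vector("list", repeats)
  for (i in seq_len(repeats)) {
    s <- base_seed + i
    rows[[i]] <- tryCatch(pipeline(s), error = function(e) {
      stop("pipeline failed at seed ", s, ": ", conditionMessage(e))
    })
  }
  per_run <- do.call(rbind, rows)
  structure(list(per_run = per_run,
                 mean = colMeans(per_run),
                 sd = apply(per_run, 2, sd),
                 repeats = repeats),
            class = "pcm_aggregate")
}

#' @export
print.pcm_aggregate <- function(x, digits = 3, ...) {
  cat("Aggregate over", x$repeats, "partitions (mean +/- sd):\n")
  for (m in names(x$mean)) {
    cat(sprintf("  %-10s %.*f +/- %.*f\n", m, digits, x$mean[m], digits, x$sd[m]))
  }
  invisible(x)
}

#' R-squared vs Q-squared reliability check
#'
#' A fitted model is considered reliable when its goodness of fit does not
#' exceed its predictive ability by more than `margin` (0.2-0.3 on the
#' R2/Q2 scale is the usual band); a larger gap flags overfitting or chance
#' correlation.
#'
#' @param R2 Goodness of fit (training).
#' @param Q2 Predictive ability (CV or external).
#' @param margin Maximum tolerated gap (default 0.3).
#' @return List with `gap = R2 - Q2` and logical `pass`.
#' @export
reliability_check <- function(R2, Q2, margin = 0.3) {
  if (!is.finite(R2) || !is.finite(Q2)) stop("R2 and Q2 must be finite")
  gap <- R2 - Q2
  # small tolerance so floating-point noise cannot flip a boundary verdict
  list(gap = gap, pass = gap <= margin + 1e-8)
}
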