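# Interaction-space construction: descriptor blocks, variance and
# correlation filters, compound-protein cross-terms, and the 13 canonical
# block-combination design matrices.

#' Construct a descriptor block
#'
#' A descriptor block is a numeric matrix over interaction records with a
#' block kind: `C` (compound), `P` (protein), `CxP` (compound-protein
#' cross-terms), `CxC` or `PxP` (within-block cross-terms).
#'
#' @param x Numeric matrix with unique column names.
#' @param kind One of `"C"`, `"P"`, `"CxP"`, `"CxC"`, `"PxP"`.
#' @return `x` with class `"descriptor_block"` and attribute `kind`.
#' @export
descriptor_block <- function(x, kind = c("C", "P", "CxP", "CxC", "PxP")) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)) && ncol(x) > 0) stop("descriptor block needs column names")
  if (anyDuplicated(colnames(x))) stop("duplicated descriptor names in block")
  structure(x, kind = kind, class = c("descriptor_block", class(x)))
}

#' @export
print.descriptor_block <- function(x, ...) {
  cat("Descriptor block [", attr(x, "kind"), "]: ", nrow(x), " records x ",
      ncol(x), " descriptors\n", sep = "")
  invisible(x)
}

block_kind <- function(x) attr(x, "kind") %||% "C"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rewrap a plain matrix as a block of the same kind as a template.
reblock <- function(x, template) descriptor_block(x, kind = block_kind(template))

#' Near-zero-variance filter
#'
#' Drops descriptors that carry (almost) no information: columns whose
#' variance is below `var_tol`, or whose ratio of the most common to the
#' second most common value exceeds `freq_cut` (the standard
#' frequency-ratio rule, default 95/5).  Column order is preserved.
#'
#' @param block A [descriptor_block()] or numeric matrix.
#' @param freq_cut Frequency-ratio cutoff (default `95/5 = 19`).
#' @param var_tol Variance tolerance (default `1e-8`).
#' @return The filtered block; removed names in attribute `"removed"`.
#' @export
near_zero_variance_filter <- function(block, freq_cut = 95 / 5, var_tol = 1e-8) {
  x <- unclass(block)
  if (is.null(dim(x)) || ncol(x) == 0 || nrow(x) == 0) stop("empty block")
  drop_col <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (var(v) < var_tol) return(TRUE)
    tab <- sort(table(v), decreasing = TRUE)
    if (length(tab) == 1L) return(TRUE)
    (tab[1] / tab[2]) > freq_cut
  }, logical(1))
  if (all(drop_col)) {
    stop("all ", ncol(x), " descriptors removed by the near-zero-variance ",
         "filter; inspect the input block")
  }
  out <- reblock(x[, !drop_col, drop = FALSE], block)
  attr(out, "removed") <- colnames(x)[drop_col]
  out
}

#' Pairwise-correlation filter
#'
#' Removes descriptors until no pair has absolute Pearson correlation above
#' `cutoff`.  Removal is deterministic: repeatedly take the most correlated
#' offending pair and drop the member with the larger mean absolute
#' correlation to all remaining descriptors; ties are broken by column
#' order (the earlier column is removed).
#'
#' @param block A [descriptor_block()] or numeric matrix with at least one
#'   column; all columns must have positive variance (run
#'   [near_zero_variance_filter()] first).
#' @param cutoff Absolute-correlation threshold (default 0.7).
#' @return The filtered block; removed names in attribute `"removed"`.
#' @export
correlation_filter <- function(block, cutoff = 0.7) {
  x <- unclass(block)
  if (is.null(dim(x)) || ncol(x) == 0) stop("empty block")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("zero-variance column(s) in block (",
         paste(head(colnames(x)[sds == 0], 3), collapse = ", "),
         "); run near_zero_variance_filter first")
  }
  if (ncol(x) == 1L) {
    out <- reblock(x, block); attr(out, "removed") <- character(0); return(out)
  }
  cm <- abs(cor(x))
  diag(cm) <- 0
  alive <- rep(TRUE, ncol(x))
  removed <- character(0)
  repeat {
    sub <- cm[alive, alive, drop = FALSE]
    if (max(sub) <= cutoff) break
    idx <- which(alive)
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- idx[worst[1]]; b <- idx[worst[2]]
    mean_a <- mean(cm[a, alive])
    mean_b <- mean(cm[b, alive])
    drop_j <- if (mean_a > mean_b) a else if (mean_b > mean_a) b else min(a, b)
    alive[drop_j] <- FALSE
    removed <- c(removed, colnames(x)[drop_j])
  }
  out <- reblock(x[, alive, drop = FALSE], block)
  attr(out, "removed") <- removed
  out
}

#' Compound-protein cross-terms (C x P block)
#'
#' One column per (compound descriptor, protein descriptor) pair, equal to
#' their rowwise product, named `<c_name>_<p_name>` (e.g.
#' `SubFPC184_p133z3`).  With `|C|` and `|P|` filtered descriptors the block
#' has `|C| * |P|` columns.
#'
#' @param C,P Row-aligned descriptor blocks over the same interaction
#'   records.
#' @return A [descriptor_block()] of kind `"CxP"`.
#' @export
cross_block <- function(C, P) {
  C <- as.matrix(C); P <- as.matrix(P)
  if (nrow(C) != nrow(P)) stop("C and P blocks are not row-aligned")
  nc <- ncol(C); np <- ncol(P)
  out <- matrix(NA_real_, nrow = nrow(C), ncol = nc * np)
  nm <- character(nc * np)
  k <- 0L
  for (i in seq_len(nc)) {
    for (j in seq_len(np)) {
      k <- k + 1L
      out[, k] <- C[, i] * P[, j]
      nm[k] <- paste0(colnames(C)[i], "_", colnames(P)[j])
    }
  }
  colnames(out) <- nm
  rownames(out) <- rownames(C)
  descriptor_block(out, kind = "CxP")
}

#' Within-block cross-terms (C x C or P x P)
#'
#' One column per unordered pair of distinct descriptors `(i < j)`, equal to
#' their rowwise product; squares are excluded, so a block of `N` columns
#' yields `N * (N - 1) / 2` cross-terms.
#'
#' @param block A descriptor block of kind `"C"` or `"P"`.
#' @return A [descriptor_block()] of kind `"CxC"` or `"PxP"`.
#' @export
self_cross_block <- function(block) {
  kind <- switch(block_kind(block), C = "CxC", P = "PxP",
                 stop("self cross-terms are defined for C or P blocks"))
  x <- as.matrix(block)
  n <- ncol(x)
  m <- n * (n - 1L) / 2L
  out <- matrix(NA_real_, nrow = nrow(x), ncol = m)
  nm <- character(m)
  k <- 0L
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        k <- k + 1L
        out[, k] <- x[, i] * x[, j]
        nm[k] <- paste0(colnames(x)[i], "_", colnames(x)[j])
      }
    }
  }
  colnames(out) <- nm
  rownames(out) <- rownames(x)
  descriptor_block(out, kind = kind)
}

#' The 13 canonical block combinations
#'
#' Model 1 uses the compound block alone; 2 the protein block; 3 the
#' compound-protein cross-terms; 4 and 5 the within-block C x C and P x P
#' cross-terms; 6-13 combine the main blocks with increasing numbers of
#' cross-term blocks.
#'
#' @param model_id Integer 1..13.
#' @return Character vector of block kinds.
#' @export
model_blocks <- function(model_id) {
  specs <- list(
    `1` = "C", `2` = "P", `3` = "CxP", `4` = "CxC", `5` = "PxP",
    `6` = c("C", "P"),
    `7` = c("C", "P", "CxP"),
    `8` = c("C", "P", "CxC"),
    `9` = c("C", "P", "PxP"),
    `10` = c("C", "P", "CxP", "CxC"),
    `11` = c("C", "P", "CxP", "PxP"),
    `12` = c("C", "P", "CxC", "PxP"),
    `13` = c("C", "P", "CxP", "CxC", "PxP"))
  if (length(model_id) != 1 || !model_id %in% 1:13) {
    stop("model_id must be 1..13")
  }
  specs[[as.character(model_id)]]
}

#' Assemble a design matrix for one block combination
#'
#' Concatenates the blocks required by `model_id` in the canonical order
#' C, P, CxP, CxC, PxP.
#'
#' @param model_id Integer 1..13 (see [model_blocks()]).
#' @param blocks Named list with (at least) the required blocks, names in
#'   `c("C", "P", "CxP", "CxC", "PxP")`, all row-aligned.
#' @return A numeric matrix with attribute `"blocks"` (the kinds used) and
#'   `"model_id"`.
#' @export
assemble_design <- function(model_id, blocks) {
  need <- model_blocks(model_id)
  missing <- setdiff(need, names(blocks))
  if (length(missing)) stop("missing block(s): ", paste(missing, collapse = ", "))
  order_kinds <- intersect(c("C", "P", "CxP", "CxC", "PxP"), need)
  n <- unique(vapply(blocks[order_kinds], nrow, integer(1)))
  if (length(n) != 1) stop("blocks are not row-aligned")
  out <- do.call(cbind, lapply(blocks[order_kinds], as.matrix))
  if (anyDuplicated(colnames(out))) stop("duplicated descriptor names across blocks")
  attr(out, "blocks") <- order_kinds
  attr(out, "model_id") <- as.integer(model_id)
  out
}

#' Build all descriptor blocks for an activity table
#'
#' The full interaction-space pipeline: fingerprint and z-scale encoding at
#' the compound/variant level, expansion to one row per interaction record,
#' near-zero-variance and pairwise-correlation filtering within the C and
#' the P block separately, then cross-term construction on the filtered
#' blocks.  Filtering precedes cross-terms so cross-term dimensions are
#' products of the filtered block sizes.
#'
#' @param activities Activity table (see [activity_table()]).
#' @param compounds Compound table; curated internally.
#' @param variants Variant table.
#' @param dictionary SMARTS dictionary.
#' @param zscales z-scale table.
#' @param positions Varied positions.
#' @param cor_cutoff Absolute-correlation cutoff (default 0.7).
#' @param freq_cut Near-zero-variance frequency-ratio cutoff (default 95/5).
#' @return A list with `blocks` (named list of the five descriptor blocks),
#'   `activities`, `curation` (rejection log), and `filter` (names removed
#'   from C and P).
#' @export
build_blocks <- function(activities, compounds, variants,
                         dictionary = default_smarts_dictionary(),
                         zscales = default_zscale_table(),
                         positions = aromatase_positions(),
                         cor_cutoff = 0.7, freq_cut = 95 / 5) {
  compounds <- compound_table(compounds)
  variants <- variant_table(variants, positions = positions)
  cur <- curate_compounds(compounds)
  activities <- activity_table(activities, compounds = cur$kept, variants = variants)

  counts <- fingerprint_counts(cur$kept, dictionary)
  zmat <- zscale_encode(variants, zscales, positions)

  C_raw <- compound_block(counts, activities$compound_id)
  P_raw <- protein_block(zmat, activities$variant_id)

  C_nzv <- near_zero_variance_filter(C_raw, freq_cut = freq_cut)
  P_nzv <- near_zero_variance_filter(P_raw, freq_cut = freq_cut)
  C_f <- correlation_filter(C_nzv, cutoff = cor_cutoff)
  P_f <- correlation_filter(P_nzv, cutoff = cor_cutoff)

  blocks <- list(
    C = C_f,
    P = P_f,
    CxP = cross_block(C_f, P_f),
    CxC = self_cross_block(C_f),
    PxP = self_cross_block(P_f))

  list(blocks = blocks, activities = activities, curation = cur$rejected,
       filter = list(
         C_removed = c(attr(C_nzv, "removed"), attr(C_f, "removed")),
         P_removed = c(attr(P_nzv, "removed"), attr(P_f, "removed"))))
}
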