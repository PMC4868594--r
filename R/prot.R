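# Position-specific z-scale encoding of protein variants (the P block).
# Each varied residue position contributes three descriptors: z1
# (hydrophobicity/hydrophilicity), z2 (side-chain bulk/steric volume),
# z3 (polarizability and charge).

#' Read a z-scale table
#'
#' Delimited text with header `aa,z1,z2,z3`, one row per canonical
#' amino-acid letter.  Alternative amino-acid property scales with the same
#' shape can be plugged in anywhere a z-scale table is accepted.
#'
#' @param path Path to the file.
#' @return A `data.frame` with rownames = amino-acid letters and columns
#'   `z1`, `z2`, `z3`.
#' @export
read_zscale_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("aa", "z1", "z2", "z3") %in% names(df))) {
    stop("z-scale table needs columns aa, z1, z2, z3")
  }
  df$aa <- toupper(trimws(df$aa))
  if (!setequal(df$aa, AA_LETTERS) || anyDuplicated(df$aa)) {
    stop("z-scale table must cover exactly the 20 canonical amino acids")
  }
  if (any(!is.finite(as.matrix(df[, c("z1", "z2", "z3")])))) {
    stop("z-scale values must be finite")
  }
  out <- df[, c("z1", "z2", "z3")]
  rownames(out) <- df$aa
  out[AA_LETTERS, ]
}

#' The package's default three-component z-scale table
#'
#' The classical principal-component-derived amino-acid property scale
#' (Hellberg, Sjoestroem, Skagerberg & Wold 1987, J. Med. Chem. 30:1126),
#' condensing 29 measured physicochemical properties of the 20 amino acids
#' into three components: hydrophobicity (z1), side-chain bulk (z2), and
#' polarizability/charge (z3).
#'
#' @return A z-scale table (see [read_zscale_table()]).
#' @export
default_zscale_table <- function() {
  if (is.null(.pcm_cache$zscales)) {
    path <- system.file("extdata", "zscales_3.csv", package = "pcmfit")
    .pcm_cache$zscales <- read_zscale_table(path)
  }
  .pcm_cache$zscales
}

#' Encode protein variants as position-specific z-scale descriptors
#'
#' For each varied position `p` and scale `j`, descriptor `p<p>z<j>` is the
#' z_j value of the residue the variant carries at `p` — a pure table
#' lookup, so two variants identical at all varied positions get identical
#' vectors, and a single-point variant differs from the reference only in
#' the three descriptors of the mutated position.
#'
#' @param variants Variant table (see [variant_table()]), or a single row.
#' @param zscales z-scale table; defaults to the package table.
#' @param positions Varied positions; defaults to the 13 aromatase positions.
#' @return Numeric matrix, one row per variant (rownames = variant ids),
#'   `3 * length(positions)` columns named `p<position>z<j>`, ordered by
#'   position then scale.
#' @export
zscale_encode <- function(variants, zscales = default_zscale_table(),
                          positions = aromatase_positions()) {
  variants <- variant_table(variants, positions = positions)
  pcols <- paste0("p", positions)
  out <- matrix(NA_real_, nrow = nrow(variants), ncol = 3L * length(positions),
                dimnames = list(variants$variant_id,
                                paste0(rep(pcols, each = 3), "z", 1:3)))
  for (i in seq_along(pcols)) {
    aa <- variants[[pcols[i]]]
    out[, (3 * i - 2):(3 * i)] <- as.matrix(zscales[aa, c("z1", "z2", "z3")])
  }
  out
}

#' Assemble the protein (P) descriptor block
#'
#' Expands variant-level z-scale vectors to one row per interaction record
#' and wraps them as a P-kind descriptor block.  Columns that are constant
#' across all variants (positions never mutated in the data) are reported
#' via the `"constant_columns"` attribute; they fall to the
#' near-zero-variance filter downstream.
#'
#' @param zmat Matrix from [zscale_encode()].
#' @param variant_ids Character vector, one variant id per interaction
#'   record.  When omitted, rows are the variants themselves, ordered by id.
#' @return A [descriptor_block()] of kind `"P"` with attribute
#'   `"constant_columns"`.
#' @export
protein_block <- function(zmat, variant_ids = NULL) {
  if (is.null(dim(zmat)) || nrow(zmat) == 0) stop("empty z-scale input")
  const <- colnames(zmat)[apply(zmat, 2, function(x) length(unique(x)) == 1L)]
  if (is.null(variant_ids)) {
    rows <- zmat[order(rownames(zmat)), , drop = FALSE]
  } else {
    unknown <- setdiff(variant_ids, rownames(zmat))
    if (length(unknown)) stop("no z-scale encoding for variant(s): ",
                              paste(unique(unknown), collapse = ", "))
    rows <- zmat[variant_ids, , drop = FALSE]
  }
  blk <- descriptor_block(rows, kind = "P")
  attr(blk, "constant_columns") <- const
  blk
}
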