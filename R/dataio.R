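# Data model and file IO: compound, variant and activity tables, and the
# IC50 -> pIC50 transform.  Everything downstream consumes the validated
# data.frames produced here.

#' Varied residue positions of the aromatase variant panel
#'
#' The 13 amino-acid positions at which the modeled aromatase (CYP19A1)
#' variants differ from one another, in 1-based protein-sequence numbering.
#' These cover the inhibitor binding site and residues near the active site.
#'
#' @return Integer vector of length 13.
#' @export
aromatase_positions <- function() {
  c(119L, 124L, 130L, 133L, 235L, 302L, 308L, 309L, 310L, 320L, 395L, 474L, 476L)
}

#' Wild-type residues at the varied aromatase positions
#'
#' @return Named character vector (names `"p119"` ... `"p476"`) of one-letter
#'   amino-acid codes for the reference (wild-type) enzyme.
#' @export
aromatase_wildtype <- function() {
  pos <- aromatase_positions()
  aa <- c("K", "C", "K", "I", "F", "E", "P", "D", "T", "F", "I", "I", "D")
  names(aa) <- paste0("p", pos)
  aa
}

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Convert IC50 to pIC50
#'
#' Applies the negative base-10 logarithm to molar IC50 values, the standard
#' transform that spreads potency data onto an additive scale suitable for
#' regression.
#'
#' @param ic50 Numeric vector of IC50 values in molar units (M). Must be
#'   strictly positive and finite.
#' @param units Input units, one of `"M"`, `"mM"`, `"uM"`, `"nM"`, `"pM"`.
#'   Values are converted to molar before the transform; the explicit units
#'   argument guards against the classic silent-unit pIC50 mistake.
#' @return Numeric vector of pIC50 values (dimensionless).
#' @examples
#' to_pic50(1e-9)          # 9
#' to_pic50(50, "nM")      # 7.3
#' @export
to_pic50 <- function(ic50, units = c("M", "mM", "uM", "nM", "pM")) {
  units <- match.arg(units)
  if (!is.numeric(ic50)) stop("'ic50' must be numeric")
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("IC50 values must be finite and > 0 (got ",
         paste(head(ic50[!is.finite(ic50) | ic50 <= 0], 3), collapse = ", "), ")")
  }
  factor <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)[[units]]
  -log10(ic50 * factor)
}

#' Read a compound table
#'
#' Accepts either a delimited text file with header columns `id`, `smiles`
#' (and optionally `name`), or a SMILES file (`.smi`, one `SMILES<ws>id`
#' record per line, `#` comments allowed).  Every SMILES must parse in the
#' chemistry layer and ids must be unique.
#'
#' @param path Path to the file.
#' @param validate_smiles Check each SMILES with the chemistry layer
#'   (default `TRUE`).
#' @return A `data.frame` with columns `id`, `smiles`, `name`, in file order.
#' @export
read_compounds <- function(path, validate_smiles = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.smi$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "[ \t]+")
    smiles <- vapply(parts, `[[`, "", 1L)
    id <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else NA_character_, "")
    name <- vapply(parts, function(p)
      if (length(p) >= 3) paste(p[-(1:2)], collapse = " ") else NA_character_, "")
    if (anyNA(id)) stop("SMILES file rows must carry an id in the title field")
    df <- data.frame(id = id, smiles = smiles, name = name,
                     stringsAsFactors = FALSE)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    names(df) <- tolower(names(df))
    if (!all(c("id", "smiles") %in% names(df))) {
      stop("compound file needs header columns 'id' and 'smiles'")
    }
    if (!"name" %in% names(df)) df$name <- NA_character_
    df <- df[, c("id", "smiles", "name")]
    df$id <- as.character(df$id)
  }
  compound_table(df, validate_smiles = validate_smiles)
}

#' Validate a compound table
#'
#' @param df `data.frame` with columns `id`, `smiles` and optionally `name`.
#' @param validate_smiles Check SMILES parseability (default `TRUE`).
#' @return The validated `data.frame` (columns `id`, `smiles`, `name`).
#' @export
compound_table <- function(df, validate_smiles = TRUE) {
  stopifnot(is.data.frame(df))
  if (!all(c("id", "smiles") %in% names(df))) {
    stop("compound table needs columns 'id' and 'smiles'")
  }
  if (!"name" %in% names(df)) df$name <- NA_character_
  df <- df[, c("id", "smiles", "name")]
  df$id <- as.character(df$id)
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stop("duplicated compound id(s): ", paste(unique(dup), collapse = ", "))
  if (validate_smiles) {
    ok <- smiles_parseable(df$smiles)
    if (!all(ok)) {
      bad <- which(!ok)[1]
      stop("unparseable SMILES at row ", bad, " (id ", df$id[bad], "): ", df$smiles[bad])
    }
  }
  rownames(df) <- NULL
  df
}

#' Read a variant table
#'
#' Delimited text with a header: `variant_id` followed by one column per
#' varied position (named `p<position>`, e.g. `p119`).  Residues must be
#' canonical one-letter amino-acid codes and the file must cover every
#' configured position.
#'
#' @param path Path to the CSV file.
#' @param positions Integer vector of varied positions; defaults to the 13
#'   aromatase positions.
#' @return A `data.frame` with column `variant_id` and one character column
#'   per position.
#' @export
read_variants <- function(path, positions = aromatase_positions()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  variant_table(df, positions = positions)
}

#' Validate a variant table
#'
#' @param df `data.frame` with `variant_id` plus `p<position>` columns.
#' @param positions Integer vector of required positions.
#' @return The validated `data.frame`, position columns ordered by position.
#' @export
variant_table <- function(df, positions = aromatase_positions()) {
  stopifnot(is.data.frame(df))
  if (!"variant_id" %in% names(df)) stop("variant table needs a 'variant_id' column")
  pcols <- paste0("p", positions)
  missing <- setdiff(pcols, names(df))
  if (length(missing)) stop("missing position column(s): ", paste(missing, collapse = ", "))
  df <- df[, c("variant_id", pcols)]
  df$variant_id <- as.character(df$variant_id)
  dup <- df$variant_id[duplicated(df$variant_id)]
  if (length(dup)) stop("duplicated variant id(s): ", paste(unique(dup), collapse = ", "))
  for (pc in pcols) {
    v <- toupper(trimws(as.character(df[[pc]])))
    bad <- !v %in% AA_LETTERS
    if (any(bad)) {
      stop("invalid amino-acid code '", v[which(bad)[1]], "' in column ", pc,
           " (variant ", df$variant_id[which(bad)[1]], ")")
    }
    df[[pc]] <- v
  }
  rownames(df) <- NULL
  df
}

#' Read an activity table
#'
#' Delimited text with header `compound_id`, `variant_id` and either a
#' `pic50` column or an `ic50` column plus a `units` column (`M`, `mM`, `uM`,
#' `nM`, `pM`), converted via [to_pic50()].  The table need not be a complete
#' compound x variant grid; downstream splitting operates on observed pairs.
#'
#' @param path Path to the CSV file.
#' @param compounds,variants Optional validated tables; when given, every
#'   referenced id must exist in them.
#' @return A `data.frame` with columns `compound_id`, `variant_id`, `pic50`.
#' @export
read_activities <- function(path, compounds = NULL, variants = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("compound_id", "variant_id") %in% names(df))) {
    stop("activity file needs columns 'compound_id' and 'variant_id'")
  }
  if (!"pic50" %in% names(df)) {
    if (!all(c("ic50", "units") %in% names(df))) {
      stop("activity file needs a 'pic50' column, or 'ic50' plus 'units'")
    }
    df$pic50 <- vapply(seq_len(nrow(df)), function(i)
      to_pic50(df$ic50[i], df$units[i]), numeric(1))
  }
  activity_table(df[, c("compound_id", "variant_id", "pic50")],
                 compounds = compounds, variants = variants)
}

#' Validate an activity table
#'
#' @param df `data.frame` with columns `compound_id`, `variant_id`, `pic50`.
#' @param compounds,variants Optional reference tables for id checking.
#' @return The validated `data.frame`.
#' @export
activity_table <- function(df, compounds = NULL, variants = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("compound_id", "variant_id", "pic50")
  if (!all(need %in% names(df))) {
    stop("activity table needs columns ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  df$compound_id <- as.character(df$compound_id)
  df$variant_id <- as.character(df$variant_id)
  df$pic50 <- as.numeric(df$pic50)
  if (any(!is.finite(df$pic50))) stop("pIC50 values must be finite")
  key <- paste(df$compound_id, df$variant_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicated (compound, variant) pair: (",
         df$compound_id[d], ", ", df$variant_id[d], ")")
  }
  if (!is.null(compounds)) {
    unknown <- setdiff(df$compound_id, compounds$id)
    if (length(unknown)) stop("unknown compound id(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(variants)) {
    unknown <- setdiff(df$variant_id, variants$variant_id)
    if (length(unknown)) stop("unknown variant id(s): ", paste(unknown, collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' Write a results table
#'
#' Serializes metric or importance tables as CSV or JSON; the matching
#' [read_results()] round-trips the file back to a `data.frame`.
#'
#' @param results A `data.frame`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(results))
  if (format == "csv") {
    write.csv(results, path, row.names = FALSE)
  } else {
    jsonlite::write_json(results, path, dataframe = "rows", digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a results table written by [write_results()]
#'
#' @param path Input path.
#' @param format `"csv"` or `"json"`.
#' @return A `data.frame`.
#' @export
read_results <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}
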