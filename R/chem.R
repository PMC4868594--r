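# Compound curation and substructure-fingerprint count descriptors.
# The chemistry engine is Open Babel, reached through ChemmineR/ChemmineOB;
# the SMARTS dictionary is a configuration input, never hard-coded in logic.

METAL_ELEMENTS <- c(
  "Li", "Be", "Na", "Mg", "Al", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Rb", "Sr", "Y", "Zr", "Nb", "Mo", "Tc", "Ru",
  "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Cs", "Ba", "La", "Hf", "Ta", "W", "Re",
  "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi")

# Element symbols appearing in one SMILES fragment (crude lexical scan:
# bracket atoms by symbol, plus the aromatic/organic subset outside brackets).
fragment_elements <- function(frag) {
  els <- character(0)
  brackets <- regmatches(frag, gregexpr("\\[[^]]*\\]", frag))[[1]]
  for (b in brackets) {
    sym <- regmatches(b, regexpr("[A-Z][a-z]?|as|se|[bcnops]", sub("^\\[[0-9]*", "[", b)))
    m <- regmatches(b, regexpr("(?<=\\[)[0-9]*([A-Z][a-z]?|as|se|[bcnops])", b, perl = TRUE))
    if (length(m)) els <- c(els, sub("^[0-9]*", "", m)) else if (length(sym)) els <- c(els, sym)
  }
  rest <- gsub("\\[[^]]*\\]", "", frag)
  plain <- regmatches(rest, gregexpr("Cl|Br|[BCNOPSFI]|[bcnops]", rest))[[1]]
  up <- ifelse(plain %in% c("b", "c", "n", "o", "p", "s"), toupper(plain), plain)
  c(els, up)
}

.ob_convert <- function(smiles, to = "CAN", op = NULL) {
  out <- tryCatch(
    if (is.null(op)) {
      ChemmineOB::convertFormat("SMI", to, paste0(smiles, "\n"))
    } else {
      ChemmineOB::convertFormat("SMI", to, paste0(smiles, "\n"),
                                options = data.frame(names = op, args = ""))
    },
    error = function(e) "")
  out <- strsplit(out, "[\t\n ]")[[1]]
  if (length(out) == 0) "" else out[[1]]
}

#' Canonicalize a SMILES string
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES (`""` where unparseable).
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, .ob_convert, "", USE.NAMES = FALSE)
}

# TRUE where the chemistry layer can parse the SMILES.
smiles_parseable <- function(smiles) {
  nzchar(canonical_smiles(smiles))
}

#' Curate compound structures
#'
#' Standard QSAR pre-processing: metal-containing structures are rejected
#' (descriptors are unreliable for organometallics), counter-ions are removed
#' by keeping the largest organic component of multi-component SMILES,
#' charges are neutralized where chemically valid, and the structure is
#' written as a canonical SMILES, which also fixes one deterministic tautomer
#' representation.  Rejections are logged, never raised.
#'
#' @param compounds A compound table (see [compound_table()]).
#' @return A list with elements `kept` (curated compound table, column
#'   `smiles` replaced by the curated canonical SMILES and `smiles_input`
#'   preserving the original) and `rejected` (`data.frame` of `id`, `reason`).
#' @examples
#' \donttest{
#' curate_compounds(data.frame(id = "1", smiles = "CC(=O)[O-].[Na+]"))
#' }
#' @export
curate_compounds <- function(compounds) {
  compounds <- compound_table(compounds, validate_smiles = FALSE)
  kept <- list()
  rejected <- list()
  for (i in seq_len(nrow(compounds))) {
    id <- compounds$id[i]
    smi <- compounds$smiles[i]
    if (!smiles_parseable(smi)) {
      rejected[[length(rejected) + 1L]] <- data.frame(id = id, reason = "unparseable")
      next
    }
    frags <- strsplit(smi, ".", fixed = TRUE)[[1]]
    organic <- vapply(frags, function(f) "C" %in% fragment_elements(f), logical(1))
    if (!any(organic)) {
      reason <- if (any(unlist(lapply(frags, fragment_elements)) %in% METAL_ELEMENTS))
        "metal" else "inorganic"
      rejected[[length(rejected) + 1L]] <- data.frame(id = id, reason = reason)
      next
    }
    sizes <- vapply(frags, function(f) length(fragment_elements(f)), integer(1))
    sizes[!organic] <- -1L
    main <- frags[[which.max(sizes)]]
    if (any(fragment_elements(main) %in% METAL_ELEMENTS)) {
      rejected[[length(rejected) + 1L]] <- data.frame(id = id, reason = "metal")
      next
    }
    cur <- .ob_convert(main, op = "neutralize")
    if (!nzchar(cur)) cur <- .ob_convert(main)
    if (!nzchar(cur)) {
      rejected[[length(rejected) + 1L]] <- data.frame(id = id, reason = "unparseable")
      next
    }
    row <- compounds[i, ]
    row$smiles_input <- row$smiles
    row$smiles <- cur
    kept[[length(kept) + 1L]] <- row
  }
  list(
    kept = if (length(kept)) do.call(rbind, kept) else
      cbind(compounds[0, ], smiles_input = character(0)),
    rejected = if (length(rejected)) do.call(rbind, rejected) else
      data.frame(id = character(0), reason = character(0))
  )
}

#' Read a SMARTS dictionary
#'
#' A dictionary is delimited text with header `id,smarts,label`; ids follow
#' the `SubFPC<k>` substructure-fingerprint-count naming and must be unique.
#' Every pattern is compiled against a probe molecule at load time so that
#' malformed SMARTS fail here, not during fingerprinting.
#'
#' @param path Path to the dictionary file.
#' @return A `data.frame` with columns `id`, `smarts`, `label`, ordered by
#'   the numeric part of `id`, with class `"smarts_dictionary"` prepended.
#' @export
read_smarts_dictionary <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "smarts", "label") %in% names(df))) {
    stop("SMARTS dictionary needs columns id, smarts, label")
  }
  if (anyDuplicated(df$id)) stop("duplicated descriptor ids in dictionary")
  k <- suppressWarnings(as.integer(sub("^SubFPC", "", df$id)))
  if (anyNA(k)) stop("descriptor ids must have the form 'SubFPC<k>'")
  df <- df[order(k), c("id", "smarts", "label")]
  probe <- .obmol_list("CC(=O)c1ccncc1O")
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch(
      {ChemmineOB::smartsSearch_OB(probe, df$smarts[i], uniqueMatches = TRUE); TRUE},
      error = function(e) FALSE)
    if (!ok) stop("SMARTS pattern for ", df$id[i], " does not compile: ", df$smarts[i])
  }
  rownames(df) <- NULL
  class(df) <- c("smarts_dictionary", class(df))
  df
}

#' The package's default substructure-fingerprint dictionary
#'
#' An authored SMARTS dictionary covering the functional-group,
#' heteroaromatic, charge and tautomerism fingerprint families relevant to
#' aromatase inhibitor chemistry.  Ids follow the published SubFPC
#' substructure-fingerprint-count numbering for the families it names
#' (e.g. SubFPC12 alcohol, SubFPC49 ketone, SubFPC184 heteroaromatic,
#' SubFPC299 salt); a full external dictionary can be substituted via
#' [read_smarts_dictionary()] — counts are defined by the dictionary in use.
#'
#' @return A `smarts_dictionary` (see [read_smarts_dictionary()]).
#' @export
default_smarts_dictionary <- function() {
  if (is.null(.pcm_cache$dictionary)) {
    path <- system.file("extdata", "subfpc_smarts.csv", package = "pcmfit")
    .pcm_cache$dictionary <- read_smarts_dictionary(path)
  }
  .pcm_cache$dictionary
}

.pcm_cache <- new.env(parent = emptyenv())

#' Substructure-fingerprint count vectors
#'
#' Counts, for each dictionary pattern, the number of distinct substructure
#' matches (unique atom-index sets) in each curated compound.  Deterministic
#' for a fixed dictionary; automorphic repeats of the same atom set are not
#' double-counted.
#'
#' @param compounds Curated compound table (the `kept` element of
#'   [curate_compounds()], or any table of parseable SMILES).
#' @param dictionary A `smarts_dictionary`; defaults to the package
#'   dictionary.
#' @return Integer matrix, one row per compound (rownames = compound ids),
#'   one column per descriptor (colnames = `SubFPC<k>` ids).
#' @export
fingerprint_counts <- function(compounds, dictionary = default_smarts_dictionary()) {
  compounds <- compound_table(compounds, validate_smiles = TRUE)
  if (nrow(compounds) == 0) stop("no compounds to fingerprint")
  mols <- .obmol_list(compounds$smiles)
  if (length(mols) != nrow(compounds)) {
    stop("chemistry layer parsed ", length(mols), " of ", nrow(compounds), " SMILES")
  }
  counts <- matrix(0L, nrow = nrow(compounds), ncol = nrow(dictionary),
                   dimnames = list(compounds$id, dictionary$id))
  for (j in seq_len(nrow(dictionary))) {
    hits <- ChemmineOB::smartsSearch_OB(mols, dictionary$smarts[j], uniqueMatches = TRUE)
    counts[, j] <- as.integer(hits)
  }
  counts
}

# Parse SMILES into a list of Open Babel molecule references.
.obmol_list <- function(smiles) {
  mols <- vector("list", 0L)
  ChemmineOB::forEachMol("SMILES", paste0(paste(smiles, collapse = "\n"), "\n"),
                         function(mol) mols[[length(mols) + 1L]] <<- mol)
  mols
}

#' Assemble the compound (C) descriptor block
#'
#' Expands compound-level fingerprint counts to one row per interaction
#' record and wraps them as a C-kind descriptor block.
#'
#' @param counts Fingerprint count matrix from [fingerprint_counts()].
#' @param compound_ids Character vector, one compound id per interaction
#'   record (row order of the activity table).  When omitted, rows are the
#'   compounds themselves, ordered by id.
#' @return A [descriptor_block()] of kind `"C"`.
#' @export
compound_block <- function(counts, compound_ids = NULL) {
  if (is.null(dim(counts)) || nrow(counts) == 0) stop("empty fingerprint input")
  if (is.null(compound_ids)) {
    ord <- order(rownames(counts))
    return(descriptor_block(counts[ord, , drop = FALSE], kind = "C"))
  }
  unknown <- setdiff(compound_ids, rownames(counts))
  if (length(unknown)) stop("no fingerprints for compound(s): ",
                            paste(unique(unknown), collapse = ", "))
  descriptor_block(counts[compound_ids, , drop = FALSE], kind = "C")
}
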