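# Seeded synthetic-data generator: compound, variant and activity fixtures
# with the statistical structure the PCM analysis assumes (sparse linear
# effects over compound, protein and compound x protein features plus
# Gaussian noise), so every pipeline stage is testable with known truth.

# Drug-like scaffolds with one substitution slot, spanning the fingerprint
# families the dictionary distinguishes (benzene, azines/azoles, ketones,
# saturated rings, a steroid-like core).
.scaffold_pool <- c(
  "c1ccc(%s)cc1",                      # benzene
  "c1cc(%s)ccn1",                      # pyridine
  "c1cc(%s)[nH]c1",                    # pyrrole
  "c1cc(%s)no1",                       # isoxazole
  "c1ccnc(%s)n1",                      # pyrimidine
  "c1cc(%s)sc1",                       # thiophene
  "O=C1CCC(%s)CC1",                    # cyclohexanone
  "C1CCC(%s)CC1",                      # cyclohexane
  "c1ccc2cc(%s)ccc2c1",                # naphthalene
  "c1ccc(-c2ccc(%s)cc2)cc1",           # biphenyl
  "CC12CCC3c4ccc(%s)cc4CCC3C1CCC2=O",  # estrone-like steroid core
  "O=C1C=CC2(C)C(CCC3C2CCC2(C)C3CCC2=O)C1%s")  # androstenedione-like core

# Decorations covering alcohols, ethers, nitriles, ketones, amines,
# halogens, azoles and charge-bearing groups.
.decoration_pool <- c(
  "O", "CO", "OC", "C#N", "C(C)=O", "N", "Cl", "C(C)O",
  "n1ccnc1", "Cn1cncn1", "CC(C)(C)O", "OCC(O)CO", "[N+](C)(C)C", "C(=O)O")

#' Generate synthetic inhibitor structures
#'
#' Draws compounds from a pool of drug-like scaffolds with randomized
#' decorations, guaranteeing variation across fingerprint families
#' (alcohols, heteroaromatics, nitriles, ketones).  All outputs are
#' parseable and pass curation unchanged, and the returned set is distinct
#' not only as structures but also in the filtered fingerprint space (after
#' the package's default near-zero-variance and correlation filters), so
#' every compound remains identifiable to downstream record-level analyses;
#' candidates that collapse onto an earlier compound there are redrawn.
#'
#' @param n_compounds Number of compounds (default 10).
#' @param seed Integer seed.
#' @return A compound table (`id`, `smiles`, `name`), ids `"1"..."n"`.
#' @export
generate_compounds <- function(n_compounds = 10L, seed = 1L) {
  if (n_compounds < 2) stop("n_compounds must be >= 2")
  set.seed(seed)
  combos <- expand.grid(s = seq_along(.scaffold_pool),
                        d = seq_along(.decoration_pool))
  combos <- combos[sample(nrow(combos)), ]
  smiles <- character(0)
  names_ <- character(0)
  i <- 0L
  draw_one <- function() {
    while (i < nrow(combos)) {
      i <<- i + 1L
      smi <- sprintf(.scaffold_pool[combos$s[i]], .decoration_pool[combos$d[i]])
      can <- canonical_smiles(smi)
      if (!nzchar(can) || can %in% smiles) next
      smiles <<- c(smiles, can)
      names_ <<- c(names_, sprintf("scaffold%d-dec%d", combos$s[i], combos$d[i]))
      return(invisible(TRUE))
    }
    stop("scaffold/decoration pool exhausted at ", length(smiles),
         " of ", n_compounds, " requested compounds")
  }
  while (length(smiles) < n_compounds) draw_one()
  # post-condition: compounds stay distinct after default descriptor filtering
  repeat {
    fps <- fingerprint_counts(
      data.frame(id = as.character(seq_along(smiles)), smiles = smiles,
                 stringsAsFactors = FALSE))
    filt <- tryCatch(
      correlation_filter(near_zero_variance_filter(fps)),
      error = function(e) fps)
    dup <- duplicated(as.data.frame(unclass(filt)))
    if (!any(dup)) break
    j <- which(dup)[1L]
    smiles <- smiles[-j]
    names_ <- names_[-j]
    draw_one()
  }
  compound_table(data.frame(id = as.character(seq_len(n_compounds)),
                            smiles = smiles, name = names_,
                            stringsAsFactors = FALSE))
}

#' Generate synthetic protein variants
#'
#' One wild-type plus single/double substitution mutants, structured the way
#' designed mutant panels are: substitutions concentrate on a subset of
#' "hotspot" positions, each mutated in several variants with distinct
#' replacement residues, while the remaining positions are each touched at
#' least once as the second substitution of a double mutant.  The hotspot
#' structure keeps every variant distinguishable even after downstream
#' near-zero-variance filtering (a position substituted in only one or two
#' variants carries almost no variance and is removed there); coverage of
#' all positions is still guaranteed.
#'
#' @param n_variants Number of variants (default 22).
#' @param positions Varied positions (default the 13 aromatase positions).
#' @param wildtype Named character vector of reference residues (names
#'   `p<position>`); default [aromatase_wildtype()].
#' @param seed Integer seed.
#' @return A variant table; the first row is the wild type (`"WT"`).
#' @export
generate_variants <- function(n_variants = 22L,
                              positions = aromatase_positions(),
                              wildtype = aromatase_wildtype(),
                              seed = 1L) {
  if (n_variants < 2) stop("n_variants must be >= 2")
  pcols <- paste0("p", positions)
  if (!all(pcols %in% names(wildtype))) stop("wildtype must cover all positions")
  n_mut <- n_variants - 1L
  if (n_mut < length(pcols)) {
    warning("n_variants - 1 < number of positions: not every position can be mutated")
  }
  set.seed(seed)
  # hotspots: enough that each collects >= 3 primary substitutions
  n_hot <- max(1L, min(length(pcols), n_mut %/% 3L))
  hot <- sample(pcols, n_hot)
  cold <- setdiff(pcols, hot)
  # distinct replacement letters per hotspot => variants never collide there
  letters_left <- lapply(stats::setNames(hot, hot),
                         function(p) sample(setdiff(AA_LETTERS, wildtype[[p]])))
  rows <- list(c(variant_id = "WT", wildtype[pcols]))
  for (i in seq_len(n_mut)) {
    res <- wildtype[pcols]
    p1 <- hot[(i - 1L) %% n_hot + 1L]
    res[p1] <- letters_left[[p1]][1L]
    letters_left[[p1]] <- letters_left[[p1]][-1L]
    p2 <- if (i <= length(cold)) cold[i]                 # coverage pass
          else if (runif(1) < 0.4) sample(setdiff(pcols, p1), 1L)
    if (!is.null(p2)) res[p2] <- sample(setdiff(AA_LETTERS, res[p2]), 1L)
    rows[[length(rows) + 1L]] <- c(variant_id = sprintf("V%02d", i), res)
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  variant_table(df, positions = positions)
}

#' Generate synthetic activities with known ground truth
#'
#' Builds the full compound x variant grid and generates
#' `pIC50 = b0 + sum(beta_C * C) + sum(beta_P * P) + sum(beta_CxP * CxP) + e`,
#' `e ~ Normal(0, noise_sd)`, where the features come from the package's own
#' encoders applied to the generated entities and effect features are drawn
#' from the descriptors that survive the near-zero-variance and correlation
#' filters — so recovery tests are exact in the noiseless limit and planted
#' features are guaranteed to exist in the assembled designs.
#'
#' Effect weights are fixed so that cross-term effects carry the largest
#' share of signal variance, compound main effects an intermediate share,
#' and protein main effects a small share; all effects are then scaled
#' jointly so the noiseless pIC50 grid has standard deviation `signal_sd`.
#' The default 1.2 reproduces the dynamic range typical of published
#' compound-panel pIC50 data, where cross-validated models reach Q2 near
#' 0.9 at RMSE near 0.4 (sd = RMSE / sqrt(1 - Q2) ~ 1.26); the resulting
#' noiseless grid spans well over 3 log-units.
#'
#' @param compounds,variants Generated (or user) tables.
#' @param noise_sd Gaussian noise standard deviation in pIC50 units
#'   (default 0.3).
#' @param n_effects Named integer vector: number of planted effects per
#'   block (default `c(C = 2, P = 2, CxP = 3)`).
#' @param effect_features Optional named list of character vectors (`C`,
#'   `P`, `CxP`) naming the effect descriptors explicitly; an absent or
#'   filtered-out name is an error listing it.
#' @param intercept Baseline pIC50 (default 6.5).
#' @param signal_sd Target standard deviation of the noiseless grid in
#'   pIC50 units (default 1.2).
#' @param dictionary,zscales,positions Encoders (package defaults).
#' @param seed Integer seed.
#' @return List with `activities` (activity table) and `truth` (class
#'   `"pcm_truth"`): coefficients per named feature, intercept,
#'   noiseless response `y_true`, `noise_sd`, `signal_sd`, realized
#'   `span`, `seed`.
#' @export
generate_activities <- function(compounds, variants, noise_sd = 0.3,
                                n_effects = c(C = 2L, P = 2L, CxP = 3L),
                                effect_features = NULL,
                                intercept = 6.5, signal_sd = 1.2,
                                dictionary = default_smarts_dictionary(),
                                zscales = default_zscale_table(),
                                positions = aromatase_positions(),
                                seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  grid <- expand.grid(compound_id = compounds$id,
                      variant_id = variants$variant_id,
                      stringsAsFactors = FALSE)
  skeleton <- data.frame(grid, pic50 = 0)
  bb <- build_blocks(skeleton, compounds, variants, dictionary = dictionary,
                     zscales = zscales, positions = positions)
  feats <- list(C = as.matrix(bb$blocks$C),
                P = as.matrix(bb$blocks$P),
                CxP = as.matrix(bb$blocks$CxP))

  set.seed(seed)
  chosen <- list()
  for (blk in c("C", "P", "CxP")) {
    avail <- colnames(feats[[blk]])[apply(feats[[blk]], 2, var) > 0]
    if (!is.null(effect_features[[blk]])) {
      missing <- setdiff(effect_features[[blk]], avail)
      if (length(missing)) {
        stop("requested effect feature(s) absent after filtering: ",
             paste(missing, collapse = ", "))
      }
      chosen[[blk]] <- effect_features[[blk]]
    } else {
      k <- min(n_effects[[blk]], length(avail))
      chosen[[blk]] <- sample(avail, k)
    }
  }
  if (sum(lengths(chosen)) == 0) stop("no nonzero effects: nothing to generate")

  # fixed relative weights per block (cross-terms dominate); random signs
  weight_pool <- list(C = c(0.8, 0.6, 0.5, 0.4),
                      P = c(0.45, 0.35, 0.3, 0.25),
                      CxP = c(1.0, 0.85, 0.7, 0.6, 0.5))
  y_raw <- rep(0, nrow(skeleton))
  beta <- numeric(0)
  for (blk in c("C", "P", "CxP")) {
    nm <- chosen[[blk]]
    if (!length(nm)) next
    w <- rep_len(weight_pool[[blk]], length(nm)) * sample(c(-1, 1), length(nm),
                                                          replace = TRUE)
    for (j in seq_along(nm)) {
      x <- feats[[blk]][, nm[j]]
      b <- w[j] / sd(x)           # weight on the standardized feature scale
      beta[nm[j]] <- b
      y_raw <- y_raw + b * x
    }
  }
  s <- signal_sd / sd(y_raw)
  beta <- beta * s
  y_true <- intercept + s * (y_raw - mean(y_raw))
  y <- y_true + rnorm(length(y_true), 0, noise_sd)

  activities <- activity_table(data.frame(grid, pic50 = y),
                               compounds = compounds, variants = variants)
  truth <- structure(list(beta = beta, intercept = intercept,
                          effect_features = chosen, y_true = y_true,
                          noise_sd = noise_sd, signal_sd = signal_sd,
                          span = diff(range(y_true)), seed = seed),
                     class = "pcm_truth")
  list(activities = activities, truth = truth)
}

#' Generate a complete synthetic PCM data set
#'
#' Convenience wrapper: [generate_compounds()], [generate_variants()] and
#' [generate_activities()] with one root seed.
#'
#' @param seed Root seed; sub-seeds are derived from it.
#' @param n_compounds,n_variants Panel sizes (defaults 10 and 22).
#' @param noise_sd Noise in pIC50 units (default 0.3).
#' @param ... Passed to [generate_activities()].
#' @return List with `compounds`, `variants`, `activities`, `truth`.
#' @export
simulate_pcm_data <- function(seed = 1L, n_compounds = 10L, n_variants = 22L,
                              noise_sd = 0.3, ...) {
  compounds <- generate_compounds(n_compounds, seed = seed * 3L + 1L)
  variants <- generate_variants(n_variants, seed = seed * 3L + 2L)
  act <- generate_activities(compounds, variants, noise_sd = noise_sd,
                             seed = seed * 3L + 3L, ...)
  list(compounds = compounds, variants = variants,
       activities = act$activities, truth = act$truth)
}

#' @export
print.pcm_truth <- function(x, ...) {
  cat("Synthetic ground truth (seed ", x$seed, "): ", length(x$beta),
      " nonzero effects, noise sd ", x$noise_sd, "\n", sep = "")
  for (blk in names(x$effect_features)) {
    cat("  ", blk, ": ", paste(x$effect_features[[blk]], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
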