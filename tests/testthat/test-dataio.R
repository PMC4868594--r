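test_that("to_pic50 converts IC50 to pIC50 with explicit units", {
  expect_equal(to_pic50(5e-6), 5.30103, tolerance = 1e-6)
  expect_equal(to_pic50(5, "uM"), 5.30103, tolerance = 1e-6)
  expect_equal(to_pic50(1, "uM"), 6)
  expect_equal(to_pic50(50, "nM"), 7.30103, tolerance = 1e-6)
  expect_equal(to_pic50(1e-9), 9)
  expect_equal(to_pic50(c(1, 10), "nM"), c(9, 8))
})

test_that("to_pic50 rejects non-positive, non-finite and non-numeric input", {
  expect_error(to_pic50(0), "finite and > 0")
  expect_error(to_pic50(-1e-6), "finite and > 0")
  expect_error(to_pic50(NA_real_), "finite and > 0")
  expect_error(to_pic50("5e-6"), "numeric")
  expect_error(to_pic50(1, "fM"))
})

test_that("positions and wild type describe the 13 varied residues", {
  pos <- aromatase_positions()
  wt <- aromatase_wildtype()
  expect_length(pos, 13)
  expect_identical(pos, sort(pos))
  expect_identical(names(wt), paste0("p", pos))
  expect_true(all(wt %in% c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")))
})

test_that("compound tables read from .smi and csv files", {
  smi <- system.file("extdata", "synthetic_inhibitors.smi", package = "pcmfit")
  cp <- read_compounds(smi)
  expect_identical(nrow(cp), 10L)
  expect_identical(names(cp), c("id", "smiles", "name"))
  expect_false(anyDuplicated(cp$id) > 0)

  csv <- tempfile(fileext = ".csv")
  write.csv(cp, csv, row.names = FALSE)
  cp2 <- read_compounds(csv)
  expect_identical(cp2$smiles, cp$smiles)

  expect_error(read_compounds(tempfile()), "not found")
})

test_that("compound table validation catches duplicates and bad SMILES", {
  expect_error(
    compound_table(data.frame(id = c("a", "a"), smiles = c("C", "CC"))),
    "duplicated compound id")
  expect_error(
    compound_table(data.frame(id = "a", smiles = "C1CC")),
    "unparseable SMILES")
  expect_error(compound_table(data.frame(id = "a")), "'id' and 'smiles'")
})

test_that("variant tables validate residues and required positions", {
  path <- system.file("extdata", "synthetic_variants.csv", package = "pcmfit")
  v <- read_variants(path)
  expect_identical(nrow(v), 22L)
  expect_identical(v$variant_id[1], "WT")
  expect_identical(names(v), c("variant_id", paste0("p", aromatase_positions())))

  bad <- v
  bad$p119[2] <- "Z"
  expect_error(variant_table(bad), "invalid amino-acid code 'Z'")
  expect_error(variant_table(v[, -2]), "missing position column")
  dup <- v
  dup$variant_id[2] <- "WT"
  expect_error(variant_table(dup), "duplicated variant id")
})

test_that("activity files accept pic50 directly or ic50 plus units", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(compound_id = c("1", "1"), variant_id = c("WT", "V01"),
                       ic50 = c(1, 50), units = c("uM", "nM")),
            f, row.names = FALSE)
  a <- read_activities(f)
  expect_equal(a$pic50, c(6, 7.30103), tolerance = 1e-6)

  write.csv(data.frame(compound_id = "1", variant_id = "WT", pic50 = 6.5),
            f, row.names = FALSE)
  expect_equal(read_activities(f)$pic50, 6.5)

  write.csv(data.frame(compound_id = "1", variant_id = "WT", ic50 = 1),
            f, row.names = FALSE)
  expect_error(read_activities(f), "'ic50' plus 'units'")
})

test_that("activity table validation catches duplicates and unknown ids", {
  a <- data.frame(compound_id = c("1", "1"), variant_id = c("WT", "WT"),
                  pic50 = c(6, 7))
  expect_error(activity_table(a), "duplicated \\(compound, variant\\) pair")
  a2 <- data.frame(compound_id = "9", variant_id = "WT", pic50 = 6)
  expect_error(
    activity_table(a2, compounds = data.frame(id = "1", smiles = "C")),
    "unknown compound id")
  a3 <- data.frame(compound_id = "1", variant_id = "VX", pic50 = NA)
  expect_error(activity_table(a3), "finite")
})

test_that("results tables round-trip through csv and json", {
  df <- data.frame(model = c(3L, 13L), Q2_Ext = c(0.91, 0.87))
  for (fmt in c("csv", "json")) {
    f <- tempfile()
    write_results(df, f, format = fmt)
    back <- read_results(f, format = fmt)
    expect_equal(back$model, df$model)
    expect_equal(back$Q2_Ext, df$Q2_Ext, tolerance = 1e-12)
  }
})
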