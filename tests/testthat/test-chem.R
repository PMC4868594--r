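test_that("canonical SMILES is deterministic and flags unparseable input", {
  can1 <- canonical_smiles(c("OCC", "c1ccccc1"))
  can2 <- canonical_smiles(c("CCO", "C1=CC=CC=C1"))
  expect_identical(can1, can2)
  expect_identical(canonical_smiles("C1CC"), "")
  expect_identical(canonical_smiles("C"), canonical_smiles("C"))
})

test_that("curation strips counter-ions, rejects metals, logs reasons", {
  res <- curate_compounds(data.frame(
    id = c("salt", "metal", "broken", "plain", "ironsalt"),
    smiles = c("CC(=O)[O-].[Na+]", "[Fe]", "C1CC", "CCO", "[Fe].c1ccccc1")))
  # the iron counter-ion is stripped, keeping the organic component
  expect_identical(sort(res$kept$id), c("ironsalt", "plain", "salt"))
  expect_identical(res$rejected$reason[res$rejected$id == "metal"], "metal")
  # counter-ion removed: curated SMILES contains no dot
  expect_false(any(grepl(".", res$kept$smiles, fixed = TRUE)))
  expect_identical(res$rejected$reason[res$rejected$id == "broken"],
                   "unparseable")
  # originals preserved alongside the curated structures
  expect_true("smiles_input" %in% names(res$kept))
})

test_that("curation rejects organometallics with reason 'metal'", {
  res <- curate_compounds(data.frame(id = "g", smiles = "CC[Zn]CC"))
  expect_identical(nrow(res$kept), 0L)
  expect_identical(res$rejected$reason, "metal")
})

test_that("the default dictionary loads, is ordered and fully compiles", {
  d <- default_smarts_dictionary()
  expect_s3_class(d, "smarts_dictionary")
  expect_identical(names(d), c("id", "smarts", "label"))
  expect_true(all(grepl("^SubFPC[0-9]+$", d$id)))
  k <- as.integer(sub("^SubFPC", "", d$id))
  expect_identical(k, sort(k))
  expect_gte(nrow(d), 40)
})

test_that("malformed dictionaries are rejected at load time", {
  f <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = "SubFPC1", smarts = "[CX4", label = "broken"),
            f, row.names = FALSE)
  expect_error(read_smarts_dictionary(f), "does not compile")
  write.csv(data.frame(id = c("SubFPC1", "SubFPC1"),
                       smarts = c("C", "N"), label = c("a", "b")),
            f, row.names = FALSE)
  expect_error(read_smarts_dictionary(f), "duplicated")
  write.csv(data.frame(id = "FP1", smarts = "C", label = "a"),
            f, row.names = FALSE)
  expect_error(read_smarts_dictionary(f), "SubFPC")
})

test_that("fingerprint counts match hand-counted oracles", {
  fc <- fingerprint_counts(data.frame(
    id = c("ethanol", "phenol", "butane"),
    smiles = c("CCO", "Oc1ccccc1", "CCCC")))
  expect_true(is.matrix(fc))
  expect_identical(rownames(fc), c("ethanol", "phenol", "butane"))
  expect_true(all(fc >= 0))
  # ethanol: one primary carbon bonded to carbon, one (primary) alcohol
  expect_identical(fc["ethanol", "SubFPC1"], 1L)
  expect_identical(fc["ethanol", "SubFPC12"], 1L)
  expect_identical(fc["ethanol", "SubFPC13"], 1L)
  expect_identical(fc["ethanol", "SubFPC15"], 0L)
  # butane: two terminal methyls, two methylenes, one rotatable bond
  expect_identical(fc["butane", "SubFPC1"], 2L)
  expect_identical(fc["butane", "SubFPC2"], 2L)
  # phenol: aromatic hydroxyl, not an aliphatic alcohol
  expect_identical(fc["phenol", "SubFPC42"], 1L)
  expect_identical(fc["phenol", "SubFPC12"], 0L)
})

test_that("fingerprinting handles single-atom molecules", {
  fc <- fingerprint_counts(data.frame(id = "methane", smiles = "C"))
  expect_identical(nrow(fc), 1L)
  expect_true(all(fc["methane", ] >= 0))
})

test_that("compound_block expands compound counts to record level", {
  fc <- fingerprint_counts(data.frame(id = c("a", "b"),
                                      smiles = c("CCO", "CCCC")))
  blk <- compound_block(fc, compound_ids = c("a", "a", "b"))
  expect_identical(nrow(blk), 3L)
  expect_identical(unname(blk[1, ]), unname(blk[2, ]))
  expect_error(compound_block(fc, compound_ids = "zzz"), "no fingerprints")
})
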