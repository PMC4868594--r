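test_that("near-zero-variance filter removes constant and lopsided columns", {
  n <- 22
  x <- cbind(const = rep(1, n),
             lopsided = c(rep(0, n - 1), 1),      # 21:1 > 19 -> removed
             balanced = rep(c(0, 1), n / 2),
             varied = seq_len(n))
  out <- near_zero_variance_filter(descriptor_block(x, "C"))
  expect_identical(colnames(out), c("balanced", "varied"))
  expect_identical(attr(out, "removed"), c("const", "lopsided"))
  # a 20:2 column survives the default 95/5 ratio
  x2 <- cbind(x, twohit = c(rep(0, n - 2), 1, 1))
  out2 <- near_zero_variance_filter(descriptor_block(x2, "C"))
  expect_true("twohit" %in% colnames(out2))
  expect_error(near_zero_variance_filter(matrix(1, 5, 2,
    dimnames = list(NULL, c("a", "b")))), "all 2 descriptors removed")
})

test_that("correlation filter removes the more redundant member first", {
  set.seed(3)
  a <- rnorm(60)
  b <- a + rnorm(60, sd = 0.05)       # |r(a,b)| ~ 1
  c <- rnorm(60)                      # independent
  x <- cbind(a = a, b = b, c = c)
  out <- correlation_filter(descriptor_block(x, "C"), cutoff = 0.7)
  # exactly one of the correlated pair is dropped; c survives
  expect_identical(ncol(out), 2L)
  expect_true("c" %in% colnames(out))
  expect_length(attr(out, "removed"), 1)
  # post-condition: no remaining pair exceeds the cutoff
  cm <- abs(cor(unclass(out))); diag(cm) <- 0
  expect_lt(max(cm), 0.7)
  # column order of survivors is preserved
  expect_identical(colnames(out), intersect(c("a", "b", "c"), colnames(out)))
})

test_that("correlation filter is deterministic and rejects zero variance", {
  x <- toy_matrix(40, 8, seed = 5)
  x[, 2] <- x[, 1] * 0.9 + 0.1 * x[, 8]
  r1 <- correlation_filter(descriptor_block(x, "P"))
  r2 <- correlation_filter(descriptor_block(x, "P"))
  expect_identical(colnames(r1), colnames(r2))
  x0 <- cbind(x, z = 0)
  expect_error(correlation_filter(descriptor_block(x0, "P")), "zero-variance")
})

test_that("compound-protein cross-terms are rowwise products with joined names", {
  C <- descriptor_block(cbind(SubFPC1 = c(1, 2, 0), SubFPC9 = c(0, 1, 3)), "C")
  P <- descriptor_block(cbind(p133z1 = c(0.5, -1, 2), p308z2 = c(1, 0, -2)), "P")
  x <- cross_block(C, P)
  expect_identical(colnames(x), c("SubFPC1_p133z1", "SubFPC1_p308z2",
                                  "SubFPC9_p133z1", "SubFPC9_p308z2"))
  expect_equal(unname(x[, "SubFPC1_p133z1"]), c(0.5, -2, 0))
  expect_equal(unname(x[, "SubFPC9_p308z2"]), c(0, 0, -6))
  expect_identical(attr(x, "kind"), "CxP")
  expect_error(cross_block(C, descriptor_block(cbind(p1z1 = 1:2), "P")),
               "row-aligned")
})

test_that("within-block cross-terms exclude squares and keep i < j order", {
  blk <- descriptor_block(cbind(a = c(1, 2), b = c(3, 4), c = c(5, 6)), "C")
  x <- self_cross_block(blk)
  expect_identical(colnames(x), c("a_b", "a_c", "b_c"))
  expect_equal(unname(x[, "a_b"]), c(3, 8))
  expect_identical(attr(x, "kind"), "CxC")
  expect_identical(attr(self_cross_block(descriptor_block(cbind(p = 1:2), "P")),
                        "kind"), "PxP")
  expect_error(self_cross_block(descriptor_block(cbind(q = 1:2), "CxP")),
               "C or P blocks")
})

test_that("the 13 model specifications map to their block combinations", {
  expect_identical(model_blocks(1), "C")
  expect_identical(model_blocks(2), "P")
  expect_identical(model_blocks(3), "CxP")
  expect_identical(model_blocks(4), "CxC")
  expect_identical(model_blocks(5), "PxP")
  expect_identical(model_blocks(6), c("C", "P"))
  expect_identical(model_blocks(7), c("C", "P", "CxP"))
  expect_identical(model_blocks(13), c("C", "P", "CxP", "CxC", "PxP"))
  expect_error(model_blocks(14), "model_id must be 1..13")
  expect_error(model_blocks(0), "model_id must be 1..13")
})

test_that("designs concatenate blocks in canonical order", {
  set.seed(11)
  C <- descriptor_block(matrix(rpois(12, 2), 4,
         dimnames = list(NULL, c("c1", "c2", "c3"))), "C")
  P <- descriptor_block(matrix(rnorm(8), 4,
         dimnames = list(NULL, c("p1", "p2"))), "P")
  blocks <- list(P = P, C = C, CxP = cross_block(C, P),
                 CxC = self_cross_block(C), PxP = self_cross_block(P))
  d13 <- assemble_design(13, blocks)
  expect_identical(ncol(d13), 3L + 2L + 6L + 3L + 1L)
  expect_identical(colnames(d13)[1:5], c("c1", "c2", "c3", "p1", "p2"))
  expect_identical(attr(d13, "blocks"), c("C", "P", "CxP", "CxC", "PxP"))
  expect_identical(attr(assemble_design(3, blocks), "model_id"), 3L)
  expect_error(assemble_design(7, blocks["C"]), "missing block")
})

test_that("build_blocks filters before building cross-terms", {
  sim <- shared_sim()
  bb <- build_blocks(sim$activities, sim$compounds, sim$variants)
  nC <- ncol(bb$blocks$C); nP <- ncol(bb$blocks$P)
  expect_identical(ncol(bb$blocks$CxP), nC * nP)
  expect_identical(ncol(bb$blocks$CxC), nC * (nC - 1L) %/% 2L)
  expect_identical(ncol(bb$blocks$PxP), nP * (nP - 1L) %/% 2L)
  # removed names never appear in any block
  expect_length(intersect(bb$filter$C_removed, colnames(bb$blocks$C)), 0)
  expect_length(intersect(bb$filter$P_removed, colnames(bb$blocks$P)), 0)
  # every block is row-aligned with the activity table
  for (b in bb$blocks) expect_identical(nrow(b), nrow(sim$activities))
})
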