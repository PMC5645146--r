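test_that("docks produces small verified hitting sets", {
  sp <- kmer_space(4)
  res <- docks(sp, 10)
  expect_s3_class(res, "uhs_result")
  expect_equal(res$size, 91L)
  expect_true(verify_uhs(res$set, 10, method = "walk")$is_uhs)
  expect_equal(res$params$ell, 6L)
  expect_true(all(mykkeltveit_set(sp)$codes %in% res$set$codes))
  expect_gte(res$size, res$lower_bound)
  # iteration log records the additional members in removal order
  expect_equal(sort(res$iterations$code),
               sort(res$set$codes[res$set$provenance == "additional"]))
  expect_true(all(as.numeric(res$iterations$score) > 0))
})

test_that("when the decycling set already hits all windows, no extras are added", {
  sp <- kmer_space(6)
  res <- docks(sp, 71)   # longest avoiding sequence is 70 bases
  expect_equal(res$size, 700L)
  expect_equal(nrow(res$iterations), 0L)
  res_any <- docks_any(sp, 71)
  expect_equal(res_any$size, 700L)
})

test_that("binary instances verify by literal enumeration", {
  sp <- kmer_space(3, "01")
  res <- docks(sp, 8)
  expect_true(oracle_hits_all(as.character(res$set), sp$chars, 8L))
  sp4 <- kmer_space(4, "01")
  res4 <- docks_any(sp4, 10)
  expect_true(oracle_hits_all(as.character(res4$set), sp4$chars, 10L))
  resx <- docks_any_x(sp, 8, X = 4L)
  expect_true(oracle_hits_all(as.character(resx$set), sp$chars, 8L))
})

test_that("the L-free removal order is independent of L", {
  sp <- kmer_space(5)
  r20 <- docks_any(sp, 20)
  r30 <- docks_any(sp, 30)
  n30 <- nrow(r30$iterations)
  expect_lte(n30, nrow(r20$iterations))
  # larger L stops earlier: its log is a prefix of the smaller-L log
  expect_identical(r30$iterations$code, r20$iterations$code[seq_len(n30)])
  expect_identical(r30$iterations$score, r20$iterations$score[seq_len(n30)])
})

test_that("batched removal with X = 1 is bit-for-bit the plain heuristic", {
  sp <- kmer_space(4)
  a <- docks_any(sp, 12)
  b <- docks_any_x(sp, 12, X = 1L)
  expect_identical(a$set$codes, b$set$codes)
  expect_identical(a$iterations, b$iterations)
  # larger batches still verify, and cannot be smaller than X = 1... they
  # are observed to be at least as large (recorded, not a theorem)
  c4 <- docks_any_x(sp, 12, X = 25L)
  expect_true(verify_uhs(c4$set, 12, method = "walk")$is_uhs)
  expect_gte(c4$size, a$size)
})

test_that("the pure greedy baseline breaks every cycle and verifies", {
  sp <- kmer_space(2, "01")
  res <- greedy_baseline(sp, 6)
  expect_true(oracle_hits_all(as.character(res$set), sp$chars, 6L))
  alive <- rep(TRUE, sp$n_kmers)
  alive[res$set$codes + 1L] <- FALSE
  expect_true(oracle_is_acyclic(sp$sigma, sp$k, alive))

  spd <- kmer_space(4)
  resd <- greedy_baseline(spd, 10)
  expect_true(verify_uhs(resd$set, 10, method = "walk")$is_uhs)
  expect_gte(resd$size, 89L)  # no smaller than any valid hitting set bound
})

test_that("set sizes shrink as L grows and runs are deterministic", {
  sp <- kmer_space(4)
  sizes <- vapply(c(10L, 14L, 20L), function(L) docks(sp, L)$size,
                  integer(1))
  expect_true(all(diff(sizes) <= 0))
  r1 <- docks(sp, 10)
  r2 <- docks(sp, 10)
  expect_identical(r1$set$codes, r2$set$codes)
  expect_identical(r1$iterations, r2$iterations)
  expect_error(docks(sp, 4), "L must")
  expect_error(docks(sp, 3), "L must")
})
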