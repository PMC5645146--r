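test_that("the two verification oracles agree and produce witnesses", {
  sp <- kmer_space(2)
  all_set <- kmer_set(0:15, sp)
  expect_true(verify_uhs(all_set, 5, method = "walk")$is_uhs)
  expect_true(verify_uhs(all_set, 5, method = "exhaustive")$is_uhs)

  empty <- kmer_set(integer(0), sp)
  for (m in c("walk", "exhaustive")) {
    v <- verify_uhs(empty, 4, method = m)
    expect_false(v$is_uhs)
    expect_equal(v$witness, "AAAA")   # smallest avoiding string
  }

  # agreement (including avoiding-string counts) on assorted sets
  set.seed(7)
  for (rep in 1:10) {
    spb <- kmer_space(sample(2:3, 1), "01")
    codes <- which(runif(spb$n_kmers) < 0.4) - 1L
    s <- kmer_set(codes, spb)
    L <- spb$k + sample(1:4, 1)
    vw <- verify_uhs(s, L, method = "walk")
    ve <- verify_uhs(s, L, method = "exhaustive")
    expect_equal(vw$is_uhs, ve$is_uhs)
    expect_equal(vw$n_avoiding, ve$n_avoiding)
    if (!vw$is_uhs) expect_equal(vw$witness, ve$witness)
  }
})

test_that("the decycling set hits exactly the sequences longer than L_max", {
  sp <- kmer_space(6)
  dec <- mykkeltveit_set(sp)
  v70 <- verify_uhs(dec, 70, method = "walk")
  expect_false(v70$is_uhs)
  expect_equal(nchar(v70$witness), 70L)
  expect_true(verify_uhs(dec, 71, method = "walk")$is_uhs)
})

test_that("every decycling member is essential for unbounded windows", {
  sp <- kmer_space(3)
  dec <- mykkeltveit_set(sp)
  for (drop in dec$codes[c(1L, 5L, 11L)]) {
    reduced <- kmer_set(setdiff(dec$codes, drop), sp)
    alive <- rep(TRUE, sp$n_kmers)
    alive[reduced$codes + 1L] <- FALSE
    expect_false(oracle_is_acyclic(sp$sigma, sp$k, alive))
  }
})

test_that("extension multiplies size by sigma^j and stays universal", {
  spb <- kmer_space(2, "01")
  u <- docks(spb, 6)
  ext <- extend_uhs(u$set, 2L)
  expect_equal(length(ext), length(u$set) * 4L)
  expect_equal(ext$space$k, 4L)
  expect_true(oracle_hits_all(as.character(ext), spb$chars, 8L))
  expect_error(extend_uhs(u$set, 0L), "positive")

  sp <- kmer_space(4)
  u91 <- docks(sp, 10)
  e1 <- extend_uhs(u91$set, 1L)
  expect_equal(length(e1), 91L * 4L)   # 364
  expect_true(verify_uhs(e1, 11, method = "walk")$is_uhs)
})

test_that("approximation factors are exact rationals", {
  sp <- kmer_space(4)
  dec <- mykkeltveit_set(sp)
  f <- approximation_factor(dec)
  expect_equal(as.numeric(f), 1)
  u <- docks(sp, 10)
  f91 <- approximation_factor(u)
  expect_equal(as.numeric(f91), 91 / 70)
  expect_equal(attr(f91, "numerator"), 13)
  expect_equal(attr(f91, "denominator"), 10)
  # extension strictly worsens the factor
  fext <- approximation_factor(extend_uhs(u$set, 1L))
  expect_gt(as.numeric(fext), as.numeric(f91))
})

test_that("set files round-trip and reject malformed input", {
  sp <- kmer_space(4)
  s <- docks(sp, 10)$set
  path <- tempfile(fileext = ".txt")
  write_kmer_set(s, path)
  r <- read_kmer_set(path)
  expect_equal(r$codes, s$codes)
  expect_equal(r$space$k, 4L)

  p2 <- tempfile()
  writeLines(c("ACGT", "", "AAAA"), p2)
  r2 <- read_kmer_set(p2)
  expect_equal(length(r2), 2L)
  expect_equal(r2$space$k, 4L)

  p3 <- tempfile()
  writeLines(c("ACGT", "AAAAA"), p3)
  expect_error(read_kmer_set(p3), "ragged")
  expect_error(read_kmer_set(p2, k = 5), "declared")
  p4 <- tempfile()
  writeLines("ACGX", p4)
  expect_error(read_kmer_set(p4), "invalid symbol")
})
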