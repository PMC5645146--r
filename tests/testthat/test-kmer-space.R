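test_that("encoding is a lexicographic bijection", {
  sp <- kmer_space(2)
  expect_equal(kmer_encode("AA", sp), 0L)
  expect_equal(kmer_encode("TT", sp), 15L)
  expect_equal(kmer_encode("ACG", kmer_space(3)), 6L)

  sp3 <- kmer_space(3)
  codes <- 0:(sp3$n_kmers - 1L)
  words <- kmer_decode(codes, sp3)
  expect_equal(kmer_encode(words, sp3), codes)      # round trip
  expect_equal(words, sort(words))                  # code order = lex order

  expect_error(kmer_encode("AXG", sp3), "invalid symbol")
  expect_error(kmer_encode("AC", sp3), "length")
  expect_error(kmer_space(2, "AAC"), "unique")
})

test_that("successors and predecessors are mutually consistent", {
  sp <- kmer_space(2)
  expect_equal(kmer_decode(kmer_successors(kmer_encode("AA", sp), sp), sp),
               c("AA", "AC", "AG", "AT"))
  expect_equal(kmer_decode(kmer_successors(kmer_encode("CG", sp), sp), sp),
               c("GA", "GC", "GG", "GT"))
  for (sp_i in list(kmer_space(3, "01"), kmer_space(2), kmer_space(3))) {
    codes <- 0:(sp_i$n_kmers - 1L)
    succ <- kmer_successors(codes, sp_i)
    expect_equal(ncol(succ), sp_i$sigma)            # out-degree sigma
    pred <- kmer_predecessors(codes, sp_i)
    for (v in codes) {
      for (u in succ[v + 1L, ])
        expect_true(v %in% pred[u + 1L, ])
      for (u in pred[v + 1L, ])
        expect_true(v %in% succ[u + 1L, ])
    }
  }
})

test_that("paths spell overlapping sequences", {
  sp3 <- kmer_space(3)
  expect_equal(spell_path(kmer_encode("ACG", sp3), sp3), "ACG")
  sp2 <- kmer_space(2)
  expect_equal(spell_path(kmer_encode(c("AC", "CG", "GT"), sp2), sp2),
               "ACGT")
  p <- kmer_encode(c("AC", "CG", "GT", "TA"), sp2)  # 3 edges, k = 2
  expect_equal(nchar(spell_path(p, sp2)), 5L)
  expect_error(spell_path(kmer_encode(c("AC", "GT"), sp2), sp2),
               "not joined")
  # every vertex label occurs at its position
  s <- spell_path(p, sp2)
  for (i in seq_along(p))
    expect_equal(substring(s, i, i + 1L), kmer_decode(p[i], sp2))
})

test_that("conjugacy classes partition the k-mers and match the count formula", {
  expect_equal(num_conjugacy_classes(4, 6), 700)
  expect_equal(num_conjugacy_classes(5, 1), 5)
  expect_equal(num_conjugacy_classes(2, 3), 4)  # 000, 001-class, 011-class, 111

  sp3 <- kmer_space(3)
  expect_equal(sort(conjugacy_class(kmer_encode("AAA", sp3), sp3)),
               kmer_encode("AAA", sp3))
  expect_equal(sort(kmer_decode(conjugacy_class(kmer_encode("ACG", sp3), sp3), sp3)),
               sort(c("ACG", "CGA", "GAC")))
  sp4 <- kmer_space(4)
  expect_equal(sort(kmer_decode(conjugacy_class(kmer_encode("ATAT", sp4), sp4), sp4)),
               sort(c("ATAT", "TATA")))

  for (sp_i in list(kmer_space(4, "01"), kmer_space(6, "01"), kmer_space(3),
                    kmer_space(4))) {
    codes <- 0:(sp_i$n_kmers - 1L)
    classes <- unique(lapply(codes, function(v)
      conjugacy_class(v, sp_i)))
    expect_equal(length(classes),
                 num_conjugacy_classes(sp_i$sigma, sp_i$k))
    expect_equal(sum(lengths(classes)), sp_i$n_kmers)   # partition
    expect_equal(sort(unlist(classes)), codes)
    expect_true(all(sp_i$k %% lengths(classes) == 0))   # sizes divide k
  }
})

test_that("kmer_set deduplicates, sorts and tracks provenance", {
  sp <- kmer_space(2)
  s <- kmer_set(c(5L, 1L, 5L), sp, provenance = c("a", "b", "a"))
  expect_equal(s$codes, c(1L, 5L))
  expect_equal(s$provenance, c("b", "a"))
  expect_equal(length(s), 2L)
  expect_equal(as.character(s), c("AC", "CC"))
  expect_error(kmer_set(16L, sp), "codes")
})
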