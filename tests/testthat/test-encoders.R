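test_that("kmer_encode matches hand-enumerated cases", {
  v <- kmer_encode("AAAA", 2)
  expect_equal(unname(v["AA"]), 1)
  expect_equal(sum(v), 1)

  v1 <- kmer_encode("ACD", 1)
  expect_equal(unname(v1[c("A", "C", "D")]), rep(1 / 3, 3))
  expect_equal(sum(v1 > 0), 3)

  v2 <- kmer_encode("ACAC", 2)   # windows AC, CA, AC
  expect_equal(unname(v2["AC"]), 2 / 3)
  expect_equal(unname(v2["CA"]), 1 / 3)

  expect_error(kmer_encode("A", 2, id = "shorty"), "shorty",
               class = "dbpkit_encoding_error")
})

test_that("mono_di_kgap_encode counts X.gap.YZ windows", {
  v <- mono_di_kgap_encode("ACDE", 1)   # single window: A (skip C) DE
  expect_equal(unname(v["g1:A_DE"]), 1)
  expect_equal(sum(v), 1)

  # length-3 sequence has no valid g=1 window: all-zero block
  v3 <- mono_di_kgap_encode("ACD", 1)
  expect_equal(sum(v3), 0)

  # per-g blocks are normalized independently
  v2 <- mono_di_kgap_encode("ACDEF", 2)
  g1 <- v2[startsWith(names(v2), "g1:")]
  g2 <- v2[startsWith(names(v2), "g2:")]
  expect_equal(sum(g1), 1)
  expect_equal(sum(g2), 1)
  expect_equal(unname(v2["g2:A_EF"]), 1)
})

test_that("cc_pssm_encode matches direct evaluation and centering invariance", {
  set.seed(5)
  p <- random_profile(3, "tiny")
  got <- cc_pssm_encode(p, 1)
  expect_equal(got, oracle_cc(p$scores, 1), tolerance = 1e-12)

  # constant columns give an all-zero vector
  sc <- matrix(rep(seq_len(20), each = 6), 6, 20, dimnames = list(NULL, AA20))
  pc <- pssm_profile("const", "ACDEFG", sc)
  expect_true(all(cc_pssm_encode(pc, 2) == 0))

  # invariant to adding a constant to a whole column
  p2 <- p
  p2$scores[, "K"] <- p2$scores[, "K"] + 100
  expect_equal(cc_pssm_encode(p2, 1), got, tolerance = 1e-9)

  expect_error(cc_pssm_encode(p, 3), "lag", class = "dbpkit_encoding_error")
})

test_that("encoders match brute-force oracles on random sequences", {
  set.seed(101)
  for (i in 1:25) {
    L <- sample(5:50, 1)
    s <- random_protein(L)
    k <- sample(1:2, 1)
    expect_equal(kmer_encode(s, k), oracle_kmer(s, k), tolerance = 1e-12)
    expect_equal(mono_di_kgap_encode(s, 2), oracle_kgap(s, 2),
                 tolerance = 1e-12)
  }
  for (i in 1:10) {
    p <- random_profile(sample(4:30, 1), paste0("r", i))
    expect_equal(cc_pssm_encode(p, 2), oracle_cc(p$scores, 2),
                 tolerance = 1e-10)
  }
})

test_that("composition encoders are normalized and length-stable", {
  set.seed(77)
  lens <- sample(4:200, 30, replace = TRUE)
  for (L in lens) {
    s <- random_protein(L)
    expect_equal(sum(kmer_encode(s, 2)), 1)
    expect_length(kmer_encode(s, 2), 400)
    v <- mono_di_kgap_encode(s, 2)
    expect_length(v, 16000)
    for (g in 1:2) {
      blk <- sum(v[startsWith(names(v), paste0("g", g, ":"))])
      expect_true(abs(blk - 1) < 1e-9 || (L < g + 3 && blk == 0))
    }
  }
})

test_that("encode_matrix concatenates encoders with prefixed vocabularies", {
  set.seed(9)
  ds <- tibble::tibble(id = c("a", "b"),
                       sequence = c(random_protein(30), random_protein(40)))
  X <- encode_matrix(ds, list(encoder_monodikgap(2), encoder_kmer(2)))
  expect_equal(dim(X), c(2, 16400))
  expect_equal(rownames(X), ds$id)
  expect_true(all(startsWith(colnames(X)[1:16000], "kgap:")))
  expect_true(all(startsWith(colnames(X)[16001:16400], "kmer2:")))
  expect_equal(unname(X[1, 16001:16400]), unname(kmer_encode(ds$sequence[1], 2)))

  # single encoder equals stacked per-record vectors
  X1 <- encode_matrix(ds, encoder_kmer(1))
  expect_equal(unname(X1[2, ]), unname(kmer_encode(ds$sequence[2], 1)))

  # empty dataset keeps the full vocabulary
  X0 <- encode_matrix(ds[0, ], encoder_kmer(2))
  expect_equal(dim(X0), c(0, 400))

  # missing PSSM profile is an error
  profs <- generate_pssms(ds[1, ], sim_spec(n_pos = 1, n_neg = 1, seed = 1))
  expect_error(encode_matrix(ds, encoder_ccpssm(2, profiles = profs)),
               "b", class = "dbpkit_value_error")
})

test_that("feature matrix TSV round-trips", {
  set.seed(13)
  X <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("a", "b", "c"), c("w", "x", "y", "z")))
  f <- tempfile(fileext = ".tsv")
  write_feature_matrix(X, f)
  expect_equal(read_feature_matrix(f), X, tolerance = 1e-12)
})
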