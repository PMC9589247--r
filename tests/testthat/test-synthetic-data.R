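test_that("generate_dataset respects sizes, lengths, alphabet, determinism", {
  spec <- sim_preset("strong", n_pos = 20, n_neg = 25,
                     length_range = c(50, 80), seed = 42)
  ds <- generate_dataset(spec)
  expect_equal(sum(ds$label == 1), 20)
  expect_equal(sum(ds$label == 0), 25)
  lens <- nchar(ds$sequence)
  expect_true(all(lens >= 50 & lens <= 80))
  expect_true(all(grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", ds$sequence)))

  ds2 <- generate_dataset(spec)
  expect_identical(ds$sequence, ds2$sequence)

  ds3 <- generate_dataset(sim_preset("strong", n_pos = 20, n_neg = 25,
                                     length_range = c(50, 80), seed = 43))
  expect_false(identical(ds$sequence, ds3$sequence))
})

test_that("planted signal enriches the corresponding dimer frequency", {
  hits <- 0
  for (seed in 1:20) {
    spec <- sim_spec(n_pos = 30, n_neg = 30, length_range = c(100, 200),
                     signal_kmers = c(WY = 8),
                     signal_gap_patterns = tibble::tibble(
                       mono = character(), gap = integer(),
                       di = character(), multiplier = numeric()),
                     seed = seed)
    ds <- generate_dataset(spec)
    freq <- vapply(ds$sequence, function(s) kmer_encode(s, 2)[["WY"]],
                   numeric(1))
    if (mean(freq[ds$label == 1]) > mean(freq[ds$label == 0])) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("planted copy counts are Poisson-consistent with the multiplier", {
  spec <- sim_preset("strong", n_pos = 300, n_neg = 300, seed = 7)
  ds <- generate_dataset(spec)
  planted <- attr(ds, "planted")
  pos_mean <- mean(planted$WY[ds$label == 1])
  neg_mean <- mean(planted$WY[ds$label == 0])
  expect_equal(pos_mean, 8, tolerance = 0.2)   # rate base_rate * 8
  expect_equal(neg_mean, 1, tolerance = 0.35)  # rate base_rate
})

test_that("null preset gives exchangeable classes for a linear probe", {
  spec <- sim_preset("null", n_pos = 60, n_neg = 60,
                     length_range = c(80, 120), seed = 3)
  ds <- generate_dataset(spec)
  X <- encode_matrix(ds, encoder_kmer(1))
  ev <- asNamespace("dbpkit")$make_linear_evaluator(seed = 1)
  expect_lt(ev(X, ds$label), 0.72)  # no real signal to exploit
})

test_that("generate_pssms yields sequence-consistent, round-trippable profiles", {
  spec <- sim_spec(n_pos = 3, n_neg = 3, length_range = c(10, 20),
                   pssm_noise_sd = 0, seed = 5)
  ds <- generate_dataset(spec)
  profs <- generate_pssms(ds, spec)
  p <- profs[[1]]
  idx <- match(strsplit(p$residues, "")[[1]], AA20)
  onehot_scores <- p$scores == 7
  expect_true(all(onehot_scores[cbind(seq_along(idx), idx)]))
  expect_equal(sum(onehot_scores), length(idx))  # high only at observed

  # constant-residue sequence with noise 0 -> CC transform is all zeros
  mono <- tibble::tibble(id = "m", sequence = strrep("A", 15))
  pm <- generate_pssms(mono, spec)[["m"]]
  expect_true(all(cc_pssm_encode(pm, 2) == 0))

  # round-trip through the ASCII dialect
  f <- tempfile()
  write_pssm(p, f)
  expect_identical(read_pssm(f, id = p$id)$scores, p$scores)
})

test_that("sim_spec validates its fields", {
  expect_error(sim_spec(length_range = c(2, 10)))
  expect_error(sim_spec(background = rep(0.1, 20)))
  expect_error(sim_spec(signal_kmers = c(WY = -1)))
  expect_error(sim_spec(length_range = c(3, 4),
                        signal_kmers = c(WWWWWWWW = 2)),
               class = "dbpkit_value_error")
})
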