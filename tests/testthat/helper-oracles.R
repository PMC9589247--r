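# Independent brute-force oracles for the encoders, deliberately written as
# direct window enumeration with string operations so they share no code with
# the implementations they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

oracle_kmer <- function(seq, k) {
  words <- AA20
  if (k > 1) for (i in 2:k) {
    words <- unlist(lapply(words, function(w) paste0(w, AA20)))
  }
  v <- setNames(numeric(length(words)), words)
  L <- nchar(seq)
  for (s in 1:(L - k + 1)) {
    w <- substr(seq, s, s + k - 1)
    v[w] <- v[w] + 1
  }
  v / (L - k + 1)
}

oracle_kgap <- function(seq, kgap) {
  di <- unlist(lapply(AA20, function(a) paste0(a, AA20)))
  pats <- unlist(lapply(AA20, function(m) paste0(m, "_", di)))
  L <- nchar(seq)
  out <- numeric(0)
  for (g in seq_len(kgap)) {
    v <- setNames(numeric(length(pats)), paste0("g", g, ":", pats))
    n_win <- L - g - 2
    if (n_win >= 1) {
      for (s in 1:n_win) {
        key <- paste0("g", g, ":", substr(seq, s, s), "_",
                      substr(seq, s + g + 1, s + g + 2))
        v[key] <- v[key] + 1
      }
      v <- v / n_win
    }
    out <- c(out, v)
  }
  out
}

oracle_cc <- function(scores, lag) {
  # scores: L x 20 matrix with alphabetical column names
  L <- nrow(scores)
  means <- colMeans(scores)
  out <- numeric(0)
  for (LG in seq_len(lag)) {
    for (a1 in AA20) for (a2 in AA20) {
      if (a1 == a2) next
      acc <- 0
      for (j in 1:(L - LG)) {
        acc <- acc + (scores[j, a1] - means[a1]) * (scores[j + LG, a2] - means[a2])
      }
      out[paste0("lag", LG, ":", a1, "|", a2)] <- acc / (L - LG)
    }
  }
  out
}

random_protein <- function(L) {
  paste(sample(AA20, L, replace = TRUE), collapse = "")
}

random_profile <- function(L, id = "p") {
  sc <- matrix(sample(-5:9, L * 20, replace = TRUE), L, 20,
               dimnames = list(NULL, AA20))
  pssm_profile(id, random_protein(L), sc)
}

# Tiny labeled dataset with one strongly separating feature for selector tests.
make_signal_matrix <- function(n = 100, p_noise = 30, effect = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(1L, 0L), each = n / 2)
  X <- cbind(effect * y + rnorm(n, sd = 0.5),
             matrix(rnorm(n * p_noise), n, p_noise))
  colnames(X) <- c("signal", paste0("noise", seq_len(p_noise)))
  list(X = X, y = y)
}
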